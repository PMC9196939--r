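#' DCE series description
#'
#' Bundles a dynamic contrast-enhanced 4-D stack with the frame structure of
#' the analysis: the pre-contrast baseline window, the early window used for
#' the muscle normalizer, and the muscle mask. Defaults follow the protocol:
#' 300 frames at 3 s, baseline frames 1-30, early frames 31-120 (the
#' temporalis/masseter normalization window), post-injection frames 31-300.
#'
#' @param stack 4-D `image_stack` of the dynamic series.
#' @param baseline_frames indices of pre-contrast frames.
#' @param early_frames indices of the early normalization window.
#' @param muscle_mask logical array selecting muscle voxels.
#' @return object of class `dce_series`.
#' @export
dce_series <- function(stack, baseline_frames = 1:30, early_frames = 31:120,
                       muscle_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$data)[4]
  stopifnot(length(baseline_frames) >= 2,
            max(baseline_frames) < min(early_frames),
            max(early_frames) <= nf)
  if (is.null(muscle_mask) && !is.null(stack$phantom))
    muscle_mask <- stack$phantom$masks$muscle
  if (is.null(muscle_mask) || !any(muscle_mask))
    stop("a nonempty muscle mask is required for DCE normalization")
  structure(list(stack = stack, baseline_frames = baseline_frames,
                 early_frames = early_frames, muscle_mask = muscle_mask,
                 frame_dt = if (!is.null(stack$acq)) stack$acq$frame_dt else
                   diff(stack$axis_values[1:2])),
            class = "dce_series")
}

#' Fractional enhancement of a DCE series
#'
#' Expresses each frame as the fractional signal change relative to the
#' pre-contrast baseline, \eqn{FE(v,t) = (S(v,t) - \bar S_b(v)) / \bar
#' S_b(v)} with \eqn{\bar S_b} the mean over the baseline frames. Voxels
#' with baseline at or below `min_baseline` are masked (`NA`) and counted.
#'
#' @param series a [dce_series()].
#' @param min_baseline minimum baseline mean for a voxel to be evaluated.
#' @return an `image_stack` of FE values with attribute `n_masked`.
#' @export
fractional_enhancement <- function(series, min_baseline = 1e-6) {
  stopifnot(inherits(series, "dce_series"))
  dat <- series$stack$data
  base <- apply(dat[, , , series$baseline_frames, drop = FALSE], 1:3, mean)
  bad <- base <= min_baseline
  base[bad] <- NA_real_
  fe <- sweep(sweep(dat, 1:3, base, "-"), 1:3, base, "/")
  out <- series$stack
  out$data <- fe
  attr(out, "n_masked") <- sum(bad)
  out
}

#' Muscle normalization factor
#'
#' The maximum, over the early frames, of the muscle-ROI-mean fractional
#' enhancement (ROI mean first, then maximum across frames -- not the mean
#' of per-voxel maxima). A non-positive factor means no contrast arrival
#' and is an error.
#'
#' @param fe fractional-enhancement stack from [fractional_enhancement()].
#' @param series the originating [dce_series()].
#' @return positive scalar normalization factor.
#' @export
muscle_norm_factor <- function(fe, series) {
  dm <- dim(fe$data)
  mus <- which(series$muscle_mask)
  nvox <- prod(dm[1:3])
  curve <- vapply(series$early_frames, function(f)
    mean(fe$data[mus + (f - 1) * nvox], na.rm = TRUE), numeric(1))
  norm <- max(curve)
  if (!is.finite(norm) || norm <= 0)
    stop("non-positive muscle enhancement: no contrast arrival detected")
  norm
}

#' Semi-quantitative DCE area under the curve
#'
#' Sums the muscle-normalized fractional enhancement over the post-injection
#' frames and divides by the post-injection duration,
#' \eqn{AUC(v) = \sum_{t \in post} FE(v,t)/m / (\Delta t \, n_{post})}.
#' With the default frame structure the divisor is 810 s (3 s/frame x 270
#' post-injection frames). Values are per-second ("au" by convention).
#'
#' @param fe fractional-enhancement stack.
#' @param norm muscle normalization factor from [muscle_norm_factor()].
#' @param series the originating [dce_series()].
#' @param post_frames post-injection frame indices; default everything after
#'   the baseline window.
#' @return a [parametric_map()] of AUC (au).
#' @export
compute_auc <- function(fe, norm, series, post_frames = NULL) {
  stopifnot(norm > 0)
  nf <- dim(fe$data)[4]
  if (is.null(post_frames))
    post_frames <- (max(series$baseline_frames) + 1):nf
  divisor <- series$frame_dt * length(post_frames)
  auc <- apply(fe$data[, , , post_frames, drop = FALSE], 1:3, sum) /
    (norm * divisor)
  mask <- !is.na(auc)
  parametric_map(auc, uncertainty = array(0, dim(auc)), mask = mask,
                 param = "DCE_AUC", units = "au",
                 meta = list(norm = norm, divisor_s = divisor,
                             n_post = length(post_frames),
                             frame_dt = series$frame_dt))
}
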