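#' Build a digital mouse-brain label map
#'
#' Constructs the phantom geometry: an elliptical brain (contralateral-cortex
#' tissue), a masseter/temporalis-like muscle band outside the brain, and a
#' lesion in the left hemisphere whose composition depends on the cohort
#' layout. `"tumor"` and `"rn"` place a single round lesion; `"mixed"` places
#' disjoint tumor and radiation-necrosis lesions; `"control"` places none.
#' Lesions span the central slices only. Labels: 0 background, 1 cortex,
#' 2 tumor, 3 radiation necrosis, 4 muscle.
#'
#' @param matrix_size in-plane matrix size (square), voxels.
#' @param n_slices number of slices.
#' @param fov_mm in-plane field of view, mm.
#' @param slice_mm slice thickness, mm.
#' @param layout cohort layout, one of `"tumor"`, `"rn"`, `"mixed"`,
#'   `"control"`.
#' @param presets named list of [tissue_preset()]s; must cover every tissue
#'   placed by the layout.
#' @param noise list with `model` (`"none"`, `"gaussian"` or `"rician"`) and
#'   `sd` (noise SD relative to the equilibrium signal).
#' @param seed integer seed controlling every stochastic element of stacks
#'   simulated from this phantom.
#' @return an object of class `phantom_spec`: the integer label array, the
#'   label dictionary, per-label masks, presets, geometry and noise model.
#' @export
build_label_map <- function(matrix_size = 64, n_slices = 21, fov_mm = 16,
                            slice_mm = 0.5,
                            layout = c("tumor", "rn", "mixed", "control"),
                            presets = default_presets(),
                            noise = list(model = "none", sd = 0),
                            seed = 1L) {
  if (!is.character(layout) || !all(layout %in% c("tumor", "rn", "mixed",
                                                  "control")))
    stop("unknown layout '", layout[1],
         "'; valid layouts are tumor, rn, mixed, control")
  layout <- match.arg(layout)
  stopifnot(matrix_size >= 8, n_slices >= 1, fov_mm > 0, slice_mm > 0)
  if (!noise$model %in% c("none", "gaussian", "rician"))
    stop("noise model must be none, gaussian or rician")

  n <- matrix_size
  lab <- array(0L, dim = c(n, n, n_slices))
  row_i <- matrix(seq_len(n), n, n)
  col_j <- matrix(seq_len(n), n, n, byrow = TRUE)
  cx <- (n + 1) / 2
  # brain ellipse and muscle band (same on every slice; 2-D multislice model)
  brain <- ((row_i - cx) / (0.32 * n))^2 + ((col_j - cx) / (0.38 * n))^2 <= 1
  muscle <- row_i >= round(0.84 * n) & row_i <= round(0.94 * n) &
    col_j >= round(0.20 * n) & col_j <= round(0.80 * n) & !brain
  slice_tpl <- matrix(0L, n, n)
  slice_tpl[brain] <- 1L
  slice_tpl[muscle] <- 4L

  # lesions occupy the central half of the slice stack, left hemisphere
  lesion_slices <- which(abs(seq_len(n_slices) - (n_slices + 1) / 2) <=
                           n_slices / 4)
  disc <- function(ci, cj, r) (row_i - ci)^2 + (col_j - cj)^2 <= r^2
  for (s in seq_len(n_slices)) {
    sl <- slice_tpl
    if (s %in% lesion_slices) {
      if (layout == "tumor") {
        sl[disc(0.47 * n, 0.30 * n, 0.11 * n) & brain] <- 2L
      } else if (layout == "rn") {
        sl[disc(0.47 * n, 0.30 * n, 0.11 * n) & brain] <- 3L
      } else if (layout == "mixed") {
        sl[disc(0.56 * n, 0.33 * n, 0.085 * n) & brain] <- 3L
        sl[disc(0.38 * n, 0.28 * n, 0.085 * n) & brain] <- 2L
      }
    }
    lab[, , s] <- sl
  }

  labels <- c(background = 0L, cortex = 1L, tumor = 2L, rn = 3L, muscle = 4L)
  present <- names(labels)[labels %in% unique(as.integer(lab))]
  needed <- setdiff(present, "background")
  missing <- setdiff(needed, names(presets))
  if (length(missing))
    stop("no preset supplied for tissue(s): ", paste(missing, collapse = ", "))
  masks <- lapply(labels[needed], function(v) lab == v)
  names(masks) <- needed

  structure(list(label_map = lab, labels = labels, masks = masks,
                 presets = presets[needed], layout = layout,
                 geometry = list(matrix_size = n, n_slices = n_slices,
                                 fov_mm = fov_mm, slice_mm = slice_mm,
                                 voxel_mm = c(fov_mm / n, fov_mm / n,
                                              slice_mm)),
                 noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-voxel parameter image from the phantom's presets
.param_image <- function(phantom, getter) {
  out <- array(0, dim = dim(phantom$label_map))
  for (tis in names(phantom$masks))
    out[phantom$masks[[tis]]] <- getter(phantom$presets[[tis]])
  out
}

# discrete enhancement-curve shape over DCE frames: 0 before onset, then
# saturating uptake with optional washout, evaluated at frame times
.dce_shape <- function(dce, n_frames, frame_dt, onset_frame = 31) {
  f <- seq_len(n_frames)
  t_post <- pmax(0, (f - onset_frame + 1)) * frame_dt
  shape <- (1 - exp(-dce$uptake * t_post)) * exp(-dce$washout * t_post)
  shape[f < onset_frame] <- 0
  shape
}

# peak fractional enhancement of each tissue given its target
# muscle-normalized per-second AUC; the muscle preset fixes the normalizer
.dce_amplitudes <- function(presets, acq, baseline_frames = 1:30,
                            early_frames = 31:120) {
  mus <- presets$muscle
  if (is.null(mus) || is.null(mus$dce$amplitude))
    stop("preset 'muscle' with an explicit dce amplitude is required ",
         "for DCE simulation")
  if (acq$n_frames < max(early_frames))
    stop("DCE simulation needs n_frames >= ", max(early_frames),
         " to cover the baseline and early-muscle windows")
  n_post <- acq$n_frames - max(baseline_frames)
  post <- (max(baseline_frames) + 1):acq$n_frames
  m_shape <- .dce_shape(mus$dce, acq$n_frames, acq$frame_dt)
  m_peak <- mus$dce$amplitude * max(m_shape[early_frames])
  vapply(presets, function(p) {
    if (!is.null(p$dce$amplitude)) return(p$dce$amplitude)
    s <- .dce_shape(p$dce, acq$n_frames, acq$frame_dt)
    denom <- sum(s[post])
    if (denom == 0) return(0)
    p$dce$auc * m_peak * (acq$frame_dt * n_post) / denom
  }, numeric(1))
}

#' Simulate a multi-volume image stack from a phantom
#'
#' Evaluates the forward signal model of the requested sequence at every
#' voxel of the phantom, one volume per acquisition setting:
#' \describe{
#'   \item{vfa}{spoiled gradient echo,
#'     \eqn{S(\theta) = S_0 (1 - E) \sin\theta / (1 - E \cos\theta)} with
#'     \eqn{E = e^{-TR \cdot R_1}}.}
#'   \item{mems}{multi-echo spin echo, \eqn{S(TE) = S_0 e^{-TE \cdot R_2}}.}
#'   \item{dwi}{\eqn{S(b) = S_0 \exp(-\sum_{ij} b_{ij} D_{ij})} with the
#'     b-matrix in s/mm^2 and D in um^2/ms (factor 1e-3 internal).}
#'   \item{mt}{an OFF volume equal to the s0-weighted image and an ON volume
#'     OFF x (1 - MTR/100).}
#'   \item{dce}{baseline signal, then the preset enhancement curve scaled so
#'     the muscle-normalized per-second AUC of each tissue equals its preset
#'     value.}
#' }
#' Noiseless output equals the forward model exactly. With `noise$model =
#' "rician"` the magnitude of the signal plus circular complex Gaussian noise
#' is returned; `"gaussian"` adds real Gaussian noise.
#'
#' @param phantom a [build_label_map()] phantom.
#' @param acq an acquisition spec (`acq_vfa()`, `acq_mems()`, `acq_dwi()`,
#'   `acq_mt()`, `acq_dce()`).
#' @return an `image_stack`: 4-D array `[x, y, slice, volume]` plus axis
#'   metadata, the acquisition spec, geometry, and the phantom truth.
#' @export
simulate_stack <- function(phantom, acq) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(acq, "acq_spec"))
  s0 <- .param_image(phantom, function(p) p$s0)
  dm <- dim(phantom$label_map)

  sim <- switch(acq$sequence,
    vfa = {
      r1 <- .param_image(phantom, function(p) p$r1)
      e1 <- exp(-acq$tr * r1)
      vols <- lapply(acq$flip_angles, function(a) {
        th <- a * pi / 180
        s0 * (1 - e1) * sin(th) / (1 - e1 * cos(th))
      })
      list(vols = vols, axis = "flip_angle", axis_values = acq$flip_angles)
    },
    mems = {
      r2 <- .param_image(phantom, function(p) p$r2)
      vols <- lapply(acq$te_list, function(te) s0 * exp(-te * r2))
      list(vols = vols, axis = "echo_time", axis_values = acq$te_list)
    },
    dwi = {
      tens <- lapply(c("11", "22", "33", "12", "13", "23"), function(k) {
        i <- as.integer(substr(k, 1, 1)); j <- as.integer(substr(k, 2, 2))
        .param_image(phantom, function(p) p$adc[i, j])
      })
      names(tens) <- c("11", "22", "33", "12", "13", "23")
      vols <- lapply(acq$b_matrices, function(b) {
        # b [s/mm^2] x D [um^2/ms] -> dimensionless via 1e-3
        expo <- b[1, 1] * tens[["11"]] + b[2, 2] * tens[["22"]] +
          b[3, 3] * tens[["33"]] + 2 * (b[1, 2] * tens[["12"]] +
          b[1, 3] * tens[["13"]] + b[2, 3] * tens[["23"]])
        s0 * exp(-1e-3 * expo)
      })
      bvals <- vapply(acq$b_matrices, function(b) sum(diag(b)), numeric(1))
      list(vols = vols, axis = "b_value", axis_values = bvals)
    },
    mt = {
      mtr <- .param_image(phantom, function(p) p$mtr)
      list(vols = list(s0, s0 * (1 - mtr / 100)), axis = "mt_state",
           axis_values = acq$mt_states)
    },
    dce = {
      amps <- .dce_amplitudes(phantom$presets, acq)
      shape_by_tissue <- lapply(phantom$presets, function(p)
        .dce_shape(p$dce, acq$n_frames, acq$frame_dt))
      vols <- lapply(seq_len(acq$n_frames), function(f) {
        enh <- array(0, dm)
        for (tis in names(phantom$masks))
          enh[phantom$masks[[tis]]] <- amps[[tis]] * shape_by_tissue[[tis]][f]
        s0 * (1 + enh)
      })
      list(vols = vols, axis = "frame_time",
           axis_values = acq$frame_dt * seq_len(acq$n_frames))
    },
    stop("unsupported sequence '", acq$sequence, "' for image simulation")
  )

  dat <- array(unlist(sim$vols, use.names = FALSE),
               dim = c(dm, length(sim$vols)))
  if (phantom$noise$model != "none" && phantom$noise$sd > 0) {
    set.seed(phantom$seed + .seq_seed_offset(acq$sequence))
    sd_abs <- phantom$noise$sd  # relative to s0 = 1
    if (phantom$noise$model == "rician") {
      dat <- sqrt((dat + stats::rnorm(length(dat), sd = sd_abs))^2 +
                    stats::rnorm(length(dat), sd = sd_abs)^2)
    } else {
      dat <- dat + stats::rnorm(length(dat), sd = sd_abs)
    }
  }

  structure(list(data = dat, axis = sim$axis, axis_values = sim$axis_values,
                 acq = acq, geometry = phantom$geometry,
                 phantom = phantom),
            class = "image_stack")
}

# sequence-specific offset so different sequences from one phantom seed get
# independent noise streams while remaining reproducible
.seq_seed_offset <- function(sequence) {
  match(sequence, c("vfa", "mems", "dwi", "mt", "dce", "dmrs")) * 1000L
}

#' Construct an image stack from raw components
#'
#' Mainly for tests and IO round trips; performs shape checks only.
#' @param data 3-D or 4-D numeric array (a 3-D array gains a singleton
#'   volume axis).
#' @param axis label of the 4th axis.
#' @param axis_values per-volume setting values.
#' @param acq optional acquisition spec.
#' @param geometry optional geometry list.
#' @return an `image_stack`.
#' @export
image_stack <- function(data, axis = "volume", axis_values = NULL,
                        acq = NULL, geometry = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  if (is.null(axis_values)) axis_values <- seq_len(dim(data)[4])
  stopifnot(length(axis_values) == dim(data)[4])
  structure(list(data = data, axis = axis, axis_values = axis_values,
                 acq = acq, geometry = geometry, phantom = NULL),
            class = "image_stack")
}
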