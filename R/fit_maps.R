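#' Parametric map container
#'
#' Voxel grids of a fitted parameter and its uncertainty, with an explicit
#' mask of fitted voxels (non-fitted voxels are `NA`, never silently zero)
#' and a fit report counting excluded / non-converged / flagged voxels.
#'
#' @param values fitted parameter array.
#' @param uncertainty per-voxel fit SD (same shape).
#' @param mask logical array of fitted voxels.
#' @param param parameter name.
#' @param units parameter units.
#' @param flags logical array of degenerate/clipped voxels (still fitted).
#' @param meta provenance list.
#' @return object of class `parametric_map`.
#' @export
parametric_map <- function(values, uncertainty, mask, param, units,
                           flags = NULL, meta = list()) {
  values[!mask] <- NA_real_
  uncertainty[!mask] <- NA_real_
  if (is.null(flags)) flags <- array(FALSE, dim(values))
  report <- list(n_fitted = sum(mask), n_excluded = sum(!mask),
                 n_flagged = sum(flags & mask))
  structure(list(values = values, uncertainty = uncertainty, mask = mask,
                 flags = flags, param = param, units = units,
                 report = report, meta = meta),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s [%s]: %d fitted, %d excluded, %d flagged\n",
              x$param, x$units, x$report$n_fitted, x$report$n_excluded,
              x$report$n_flagged))
  v <- x$values[x$mask]
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g, median %.4g\n",
                min(v), max(v), stats::median(v)))
  invisible(x)
}

# background mask: voxels whose mean signal exceeds `thresh` times the
# estimated noise floor (robust floor from the low-signal quintile)
.signal_mask <- function(dat, thresh = 5) {
  ms <- apply(dat, 1:3, mean)
  low <- ms[ms <= stats::quantile(ms, 0.2)]
  floor_est <- stats::median(low)
  ms > thresh * floor_est + .Machine$double.eps
}

# flatten masked voxels of a 4-D stack to [n_active, n_vol]
.stack_rows <- function(dat, mask) {
  nv <- dim(dat)[4]
  matrix(dat[rep(mask, nv)], ncol = nv)
}

#' Fit R1 from a variable-flip-angle acquisition
#'
#' Voxel-wise nonlinear least-squares fit of the spoiled gradient-echo
#' signal equation
#' \eqn{S(\theta) = S_B (1 - E)\sin\theta / (1 - E\cos\theta)},
#' \eqn{E = e^{-TR \cdot R_1}}, for the Boltzmann signal and R1. Starting
#' values come from the linearized (DESPOT1-style) regression of
#' \eqn{S/\sin\theta} on \eqn{S/\tan\theta}; refinement is a
#' Levenberg-Marquardt iteration run simultaneously over all masked voxels.
#' Flip angles are taken as nominal (no B1 correction). Uncertainties are
#' the square roots of the diagonal of the Gauss-Newton covariance.
#'
#' @param stack an `image_stack` from a vfa acquisition.
#' @param acq acquisition spec; defaults to the stack's own.
#' @param mask logical array of voxels to fit; default from background
#'   thresholding (`mask_thresh` times the noise floor).
#' @param mask_thresh background threshold multiplier.
#' @param max_iter,tol Levenberg-Marquardt controls.
#' @return a [parametric_map()] of R1 in 1/s; non-converged voxels are
#'   masked out and counted, never interpolated.
#' @export
fit_r1_vfa <- function(stack, acq = stack$acq, mask = NULL, mask_thresh = 5,
                       max_iter = 50, tol = 1e-12) {
  stopifnot(inherits(stack, "image_stack"))
  th <- acq$flip_angles * pi / 180
  if (length(unique(acq$flip_angles)) < 3)
    stop("R1 fitting requires at least 3 distinct flip angles")
  if (is.null(mask)) mask <- .signal_mask(stack$data, mask_thresh)
  Y <- .stack_rows(stack$data, mask)
  s <- sin(th); co <- cos(th)
  nv <- nrow(Y); na <- length(th)

  # DESPOT1 linear initialization: S/sin = E * S/tan + M(1-E)
  ylin <- sweep(Y, 2, s, "/")
  xlin <- sweep(Y, 2, co / s, "*")
  xm <- rowMeans(xlin); ym <- rowMeans(ylin)
  sl <- rowSums((xlin - xm) * (ylin - ym)) / rowSums((xlin - xm)^2)
  sl <- pmin(pmax(sl, 1e-6), 1 - 1e-6)
  r1 <- -log(sl) / acq$tr
  m0 <- pmax((ym - sl * xm) / (1 - sl), .Machine$double.eps)

  model_sse <- function(m0, r1) {
    e1 <- exp(-acq$tr * r1)
    mod <- (m0 * (1 - e1)) %o% s / (1 + (-e1) %o% co)
    list(mod = mod, sse = rowSums((mod - Y)^2), e1 = e1)
  }
  cur <- model_sse(m0, r1)
  lambda <- rep(1e-3, nv)
  conv <- rep(FALSE, nv)
  for (it in seq_len(max_iter)) {
    e1 <- cur$e1
    denom <- 1 + (-e1) %o% co
    j1 <- cur$mod / m0                       # d/dM
    # dS/dE = M s (c-1)/(1-Ec)^2 ; dE/dR1 = -TR E
    j2 <- (m0 %o% s) * sweep(1 / denom^2, 2, co - 1, "*") *
      ((-acq$tr * e1) %o% rep(1, na))
    r <- cur$mod - Y
    a11 <- rowSums(j1^2); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2^2)
    g1 <- rowSums(j1 * r); g2 <- rowSums(j2 * r)
    d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
    det <- d11 * d22 - a12^2
    det[abs(det) < 1e-300] <- NA
    dm <- -(d22 * g1 - a12 * g2) / det
    dr <- -(d11 * g2 - a12 * g1) / det
    cand_m <- pmax(m0 + ifelse(is.na(dm), 0, dm), .Machine$double.eps)
    cand_r <- pmax(r1 + ifelse(is.na(dr), 0, dr), 1e-8)
    new <- model_sse(cand_m, cand_r)
    better <- !is.na(new$sse) & new$sse <= cur$sse
    step <- pmax(abs(cand_m - m0) / m0, abs(cand_r - r1) / r1)
    conv <- conv | (better & (cur$sse - new$sse <= tol * (cur$sse + tol) |
                                step < 1e-10))
    m0 <- ifelse(better, cand_m, m0)
    r1 <- ifelse(better, cand_r, r1)
    lambda <- ifelse(better, lambda / 3, lambda * 7)
    cur <- model_sse(m0, r1)
    if (all(conv)) break
  }

  # covariance from the undamped normal equations at the optimum
  e1 <- cur$e1
  denom <- 1 + (-e1) %o% co
  j1 <- cur$mod / m0
  j2 <- (m0 %o% s) * sweep(1 / denom^2, 2, co - 1, "*") *
    ((-acq$tr * e1) %o% rep(1, na))
  a11 <- rowSums(j1^2); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2^2)
  det <- a11 * a22 - a12^2
  sigma2 <- cur$sse / max(na - 2, 1)
  sd_r1 <- sqrt(pmax(sigma2 * a11 / det, 0))

  .assemble_map(stack, mask, ok = conv, values = r1, sds = sd_r1,
                param = "R1", units = "1/s",
                meta = list(sequence = "vfa", tr = acq$tr,
                            flip_angles = acq$flip_angles))
}

#' Fit R2 from a multi-echo spin-echo acquisition
#'
#' Voxel-wise 3-parameter fit of
#' \eqn{S(TE) = S(0) e^{-TE \cdot R_2} + C}: amplitude, decay rate, and an
#' additive constant (noise/long-T2 offset). Initialization is a log-linear
#' regression of the offset-subtracted signal; refinement is the same
#' batched Levenberg-Marquardt as the R1 fit. Voxels with vanishing decay
#' amplitude or R2 are flagged degenerate.
#'
#' @inheritParams fit_r1_vfa
#' @return a [parametric_map()] of R2 in 1/s.
#' @export
fit_r2_mems <- function(stack, acq = stack$acq, mask = NULL, mask_thresh = 5,
                        max_iter = 60, tol = 1e-12) {
  stopifnot(inherits(stack, "image_stack"))
  te <- acq$te_list
  if (length(te) < 4)
    stop("R2 fitting with an additive constant requires at least 4 echoes")
  if (is.null(mask)) mask <- .signal_mask(stack$data, mask_thresh)
  Y <- .stack_rows(stack$data, mask)
  nv <- nrow(Y); ne <- length(te)

  c0 <- 0.9 * pmin(apply(Y, 1, min), Y[, ne])
  ylog <- log(pmax(Y - c0, .Machine$double.eps))
  tm <- mean(te); ym <- rowMeans(ylog)
  sl <- rowSums(sweep(ylog, 2, te, function(y, t) y * (t - tm))) /
    sum((te - tm)^2)
  r2 <- pmax(-sl, 1e-6)
  a0 <- pmax(exp(ym - sl * tm), .Machine$double.eps)

  model_sse <- function(a, r2, cc) {
    ex <- exp(-r2 %o% te)
    mod <- a * ex + cc
    list(mod = mod, sse = rowSums((mod - Y)^2), ex = ex)
  }
  pars <- list(a = a0, r2 = r2, cc = c0)
  cur <- model_sse(pars$a, pars$r2, pars$cc)
  lambda <- rep(1e-3, nv)
  conv <- rep(FALSE, nv)
  for (it in seq_len(max_iter)) {
    ex <- cur$ex
    ja <- ex
    jr <- -(pars$a %o% te) * ex
    r <- cur$mod - Y
    # normal equations with jc = 1
    aa <- rowSums(ja^2); ar <- rowSums(ja * jr); ac <- rowSums(ja)
    rr <- rowSums(jr^2); rc <- rowSums(jr); ccn <- ne
    ga <- rowSums(ja * r); gr <- rowSums(jr * r); gc <- rowSums(r)
    da <- aa * (1 + lambda); dr <- rr * (1 + lambda); dc <- ccn * (1 + lambda)
    # closed-form 3x3 solve (symmetric)
    det <- da * (dr * dc - rc^2) - ar * (ar * dc - rc * ac) +
      ac * (ar * rc - dr * ac)
    det[abs(det) < 1e-300] <- NA
    i11 <- (dr * dc - rc^2); i12 <- -(ar * dc - ac * rc)
    i13 <- (ar * rc - ac * dr)
    i22 <- (da * dc - ac^2); i23 <- -(da * rc - ar * ac)
    i33 <- (da * dr - ar^2)
    sa <- -(i11 * ga + i12 * gr + i13 * gc) / det
    sr <- -(i12 * ga + i22 * gr + i23 * gc) / det
    sc <- -(i13 * ga + i23 * gr + i33 * gc) / det
    cand <- list(a = pmax(pars$a + ifelse(is.na(sa), 0, sa), 0),
                 r2 = pmax(pars$r2 + ifelse(is.na(sr), 0, sr), 0),
                 cc = pars$cc + ifelse(is.na(sc), 0, sc))
    new <- model_sse(cand$a, cand$r2, cand$cc)
    better <- !is.na(new$sse) & new$sse <= cur$sse
    conv <- conv | (better & cur$sse - new$sse <= tol * (cur$sse + tol))
    pars$a <- ifelse(better, cand$a, pars$a)
    pars$r2 <- ifelse(better, cand$r2, pars$r2)
    pars$cc <- ifelse(better, cand$cc, pars$cc)
    lambda <- ifelse(better, lambda / 3, lambda * 7)
    cur <- model_sse(pars$a, pars$r2, pars$cc)
    if (all(conv)) break
  }

  ex <- cur$ex
  ja <- ex; jr <- -(pars$a %o% te) * ex
  aa <- rowSums(ja^2); ar <- rowSums(ja * jr); ac <- rowSums(ja)
  rr <- rowSums(jr^2); rc <- rowSums(jr)
  det <- aa * (rr * ne - rc^2) - ar * (ar * ne - rc * ac) +
    ac * (ar * rc - rr * ac)
  i22 <- (aa * ne - ac^2)   # cofactor for the R2 diagonal
  sigma2 <- cur$sse / max(ne - 3, 1)
  sd_r2 <- sqrt(pmax(sigma2 * i22 / det, 0))

  mean_sig <- rowMeans(Y)
  degen <- pars$a < 1e-6 * pmax(mean_sig, .Machine$double.eps) |
    pars$r2 < 1e-6
  .assemble_map(stack, mask, ok = conv, values = pars$r2, sds = sd_r2,
                param = "R2", units = "1/s", degen = degen,
                meta = list(sequence = "mems", te_list = te))
}

#' Fit the apparent diffusion coefficient from diffusion-weighted images
#'
#' Per-voxel weighted log-linear least squares of
#' \eqn{\ln S = \ln S_0 - \sum_{ij} b_{ij} D_{ij}} over the six unique
#' tensor elements, using the supplied b-matrices (which account for the
#' diffusion weighting of the imaging gradients; they are inputs, not
#' recomputed). Weights are the squared signals, the standard correction for
#' log-transformed noise. ADC is trace(D)/3 in um^2/ms; non-positive-
#' semi-definite tensors are flagged.
#'
#' @inheritParams fit_r1_vfa
#' @param weighting `"signal"` (weights S^2) or `"uniform"`.
#' @return a [parametric_map()] of ADC in um^2/ms, with the fitted tensor
#'   elements in `$tensor`.
#' @export
fit_adc <- function(stack, acq = stack$acq, mask = NULL, mask_thresh = 5,
                    weighting = c("signal", "uniform")) {
  stopifnot(inherits(stack, "image_stack"))
  weighting <- match.arg(weighting)
  bm <- acq$b_matrices
  if (length(bm) < 7)
    stop("ADC fitting requires >= 6 diffusion-encoded volumes plus b ~ 0")
  # design: ln S0 and -b_ij (1e-3: b in s/mm^2, D in um^2/ms)
  X <- t(vapply(bm, function(b)
    c(1, -1e-3 * c(b[1, 1], b[2, 2], b[3, 3],
                   2 * b[1, 2], 2 * b[1, 3], 2 * b[2, 3])), numeric(7)))
  qrX <- qr(X)
  if (qrX$rank < 7)
    stop("rank-deficient diffusion encoding: design rank ", qrX$rank,
         " < 7; supply 6 independent b-matrices plus b ~ 0")
  if (is.null(mask)) mask <- .signal_mask(stack$data, mask_thresh)
  Y <- .stack_rows(stack$data, mask)
  nv <- nrow(Y)
  L <- log(pmax(Y, .Machine$double.eps))
  W <- if (weighting == "signal") Y^2 else matrix(1, nrow(Y), ncol(Y))

  coefs <- matrix(NA_real_, nv, 7)
  sds <- rep(NA_real_, nv)
  ok <- rep(FALSE, nv)
  nd <- ncol(X)
  for (v in seq_len(nv)) {
    w <- W[v, ]
    xtwx <- crossprod(X, X * w)
    rhs <- crossprod(X, w * L[v, ])
    beta <- tryCatch(solve(xtwx, rhs), error = function(e) NULL)
    if (is.null(beta)) next
    coefs[v, ] <- beta
    res <- L[v, ] - X %*% beta
    sigma2 <- sum(w * res^2) / max(length(w) - nd, 1)
    cv <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (!is.null(cv))
      sds[v] <- sqrt(pmax(sigma2 * (cv[2, 2] + cv[3, 3] + cv[4, 4]) / 9, 0))
    ok[v] <- TRUE
  }
  adc <- rowMeans(coefs[, 2:4, drop = FALSE])
  # Sylvester criterion on the fitted tensor: flag non-PSD voxels
  d11 <- coefs[, 2]; d22 <- coefs[, 3]; d33 <- coefs[, 4]
  d12 <- coefs[, 5]; d13 <- coefs[, 6]; d23 <- coefs[, 7]
  det2 <- d11 * d22 - d12^2
  det3 <- d11 * (d22 * d33 - d23^2) - d12 * (d12 * d33 - d23 * d13) +
    d13 * (d12 * d23 - d22 * d13)
  not_psd <- !(d11 >= -1e-12 & det2 >= -1e-12 & det3 >= -1e-12)

  map <- .assemble_map(stack, mask, ok = ok, values = adc, sds = sds,
                       param = "ADC", units = "um^2/ms",
                       degen = not_psd & ok,
                       meta = list(sequence = "dwi",
                                   weighting = weighting))
  tens <- array(NA_real_, c(dim(stack$data)[1:3], 6))
  for (k in 1:6) {
    t3 <- array(NA_real_, dim(stack$data)[1:3])
    t3[mask][ok] <- coefs[ok, k + 1]
    tens[, , , k] <- t3
  }
  map$tensor <- tens
  map
}

#' Magnetization transfer ratio map
#'
#' Voxel-wise \eqn{MTR = 100 (OFF - ON)/OFF} percent. Voxels where the OFF
#' signal is at or below `min_off` are masked out; values outside [0, 100]
#' are retained but flagged.
#'
#' @param on MT-weighted (saturation on) image: 3-D array, single-volume
#'   `image_stack`, or a 2-volume mt `image_stack` (then `off` is taken
#'   from it).
#' @param off control (saturation off) image.
#' @param min_off minimum OFF signal for a voxel to be evaluated.
#' @return a [parametric_map()] of MTR in percent.
#' @export
compute_mtr <- function(on, off = NULL, min_off = 1e-6) {
  if (inherits(on, "image_stack") && is.null(off) &&
      identical(on$axis, "mt_state")) {
    off_a <- on$data[, , , match("off", on$axis_values)]
    on_a <- on$data[, , , match("on", on$axis_values)]
  } else {
    pick <- function(x) {
      if (inherits(x, "image_stack")) {
        stopifnot(dim(x$data)[4] == 1)
        x$data[, , , 1]
      } else x
    }
    on_a <- pick(on); off_a <- pick(off)
  }
  if (!identical(dim(on_a), dim(off_a)))
    stop("MT on/off images have mismatched shapes: ",
         paste(dim(on_a), collapse = "x"), " vs ",
         paste(dim(off_a), collapse = "x"))
  mask <- off_a > min_off
  mtr <- 100 * (off_a - on_a) / off_a
  flags <- mask & (mtr < 0 | mtr > 100)
  parametric_map(mtr, uncertainty = array(0, dim(mtr)), mask = mask,
                 param = "MTR", units = "%", flags = flags,
                 meta = list(sequence = "mt", min_off = min_off))
}

# scatter fitted rows back into map arrays
.assemble_map <- function(stack, mask, ok, values, sds, param, units,
                          degen = NULL, meta = list()) {
  dm <- dim(stack$data)[1:3]
  val3 <- array(NA_real_, dm); sd3 <- array(NA_real_, dm)
  fit_mask <- array(FALSE, dm)
  flg <- array(FALSE, dm)
  idx <- which(mask)
  val3[idx[ok]] <- values[ok]
  sd3[idx[ok]] <- sds[ok]
  fit_mask[idx[ok]] <- TRUE
  if (!is.null(degen)) flg[idx[ok & degen]] <- TRUE
  parametric_map(val3, sd3, fit_mask, param = param, units = units,
                 flags = flg, meta = meta)
}
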