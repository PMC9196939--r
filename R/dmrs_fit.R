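#' Starting model for the spectral fit
#'
#' @param names resonance names.
#' @param freq_hz starting frequency offsets from the carrier, Hz.
#' @param r2star starting decay rates, 1/s (recycled).
#' @return a `spectral_init` list.
#' @export
spectral_init <- function(names, freq_hz, r2star = 30) {
  stopifnot(length(names) == length(freq_hz), all(r2star > 0))
  structure(list(names = names, freq_hz = freq_hz,
                 r2star = rep_len(r2star, length(names))),
            class = "spectral_init")
}

#' Default starting model from kinetics-style chemical shifts
#' @param acq an [acq_dmrs()] spec (sets Hz per ppm).
#' @param ppm named chemical shifts; offsets are relative to water at 4.8.
#' @param r2star starting decay rate, 1/s.
#' @return a [spectral_init()].
#' @export
default_spectral_init <- function(acq = acq_dmrs(),
                                  ppm = c(HOD = 4.8, Glc = 3.8, Glx = 2.4,
                                          Lac = 1.3),
                                  r2star = 40) {
  spectral_init(names(ppm), (ppm - 4.8) * acq$ref_mhz, r2star)
}

# real-stacked design matrix of K decaying complex exponentials
.varpro_design <- function(theta, t_fid, K) {
  f <- theta[seq_len(K)]
  r <- theta[K + seq_len(K)]
  phi <- theta[2 * K + 1]
  B <- exp(outer(t_fid, 2i * pi * f - r) + 1i * phi)
  rbind(Re(B), Im(B))
}

# projected residual: solve per-block real amplitudes linearly, return the
# stacked residual vector (variable projection)
.varpro_resid <- function(theta, Ystk, t_fid, K) {
  D <- .varpro_design(theta, t_fid, K)
  qd <- qr(D)
  A <- qr.coef(qd, Ystk)
  as.vector(D %*% A - Ystk)
}

#' Fit a 2H FID time series as sums of decaying sinusoids
#'
#' Joint time-domain model across all blocks of the series: each resonance
#' has one frequency and one decay rate (R2*) shared across blocks, a global
#' zero-order phase is shared, and amplitudes are free per block. The fit is
#' separable (variable projection) nonlinear least squares: at each step of
#' the Levenberg-Marquardt iteration over (frequencies, decay rates, phase),
#' the per-block real amplitudes are solved exactly by linear least squares
#' on the real-stacked data. Parameter SDs come from the Gauss-Newton
#' covariance of the full parameter set at the optimum (a Laplace
#' approximation to the posterior SDs of the original Bayesian treatment).
#'
#' @param fids a `fid_series` (see [simulate_fid_series()] /
#'   [read_fid_series()]).
#' @param init a [spectral_init()]; starting frequencies must lie within the
#'   acquisition bandwidth.
#' @param max_iter maximum LM iterations.
#' @param ftol relative residual-reduction tolerance.
#' @return a `spectral_model`: per-resonance `freq_hz`, `r2star`, `phase`,
#'   the `[block x resonance]` amplitude matrix with SD matrix, per-block
#'   residual power, and fit diagnostics. Resonance pairs closer than half a
#'   mean linewidth are flagged (`degenerate_pairs`) with a warning.
#' @export
fit_fid_series <- function(fids, init, max_iter = 200, ftol = 1e-12) {
  stopifnot(inherits(fids, "fid_series"), inherits(init, "spectral_init"))
  K <- length(init$names)
  bw <- 1 / fids$dwell
  if (any(abs(init$freq_hz) > bw / 2))
    stop("starting frequency outside the acquisition bandwidth (+-",
         bw / 2, " Hz)")
  Y <- fids$fid
  n_blocks <- ncol(Y)
  t_fid <- (seq_len(nrow(Y)) - 1) * fids$dwell
  Ystk <- rbind(Re(Y), Im(Y))

  theta0 <- c(init$freq_hz, init$r2star, 0)
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = .varpro_resid, Ystk = Ystk, t_fid = t_fid, K = K,
    lower = c(rep(-bw / 2, K), rep(1e-3, K), -pi),
    upper = c(rep(bw / 2, K), rep(5000, K), pi),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                         ptol = 1e-12))
  if (fit$info %in% c(0, 5))
    stop("spectral fit did not converge: ", fit$message,
         " (info ", fit$info, ")")
  theta <- fit$par
  f_hat <- theta[seq_len(K)]
  r_hat <- theta[K + seq_len(K)]
  phi_hat <- theta[2 * K + 1]
  D <- .varpro_design(theta, t_fid, K)
  qd <- qr(D)
  A <- qr.coef(qd, Ystk)                       # [K x block]
  resid <- D %*% A - Ystk
  rss <- sum(resid^2)

  # sign/phase convention: amplitudes are magnitudes; a negative solved
  # amplitude of the dominant resonance means phi is off by pi
  dom <- which.max(rowMeans(abs(A)))
  if (mean(A[dom, ]) < 0) {
    A <- -A
    phi_hat <- phi_hat + if (phi_hat <= 0) pi else -pi
  }

  # full Gauss-Newton covariance: analytic amplitude columns, numeric theta
  n_obs <- length(Ystk)
  p_all <- 2 * K + 1 + K * n_blocks
  J <- matrix(0, n_obs, p_all)
  base_res <- as.vector(D %*% A - Ystk)
  h <- pmax(abs(theta) * 1e-6, 1e-8)
  for (j in seq_len(2 * K + 1)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    Dp <- .varpro_design(tp, t_fid, K)
    J[, j] <- (as.vector(Dp %*% A - Ystk) - base_res) / h[j]
  }
  # residual is stacked block-wise: columns of (D %*% A - Ystk) flattened
  nr <- nrow(Ystk)
  for (b in seq_len(n_blocks))
    for (k in seq_len(K))
      J[(b - 1) * nr + seq_len(nr), 2 * K + 1 + (b - 1) * K + k] <- D[, k]
  dof <- max(n_obs - p_all, 1)
  sigma2 <- rss / dof
  cov_all <- tryCatch(sigma2 * chol2inv(chol(crossprod(J))),
                      error = function(e) matrix(NA_real_, p_all, p_all))
  sds <- sqrt(pmax(diag(cov_all), 0))
  amp_sd <- matrix(sds[(2 * K + 2):p_all], nrow = K)  # [K x block]

  lw <- r_hat / pi
  degen <- which(abs(outer(f_hat, f_hat, "-")) <
                   0.5 * outer(lw, lw, "+") / 2 &
                   upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  if (nrow(degen))
    warning("near-degenerate resonance pair(s): ",
            paste(apply(degen, 1, function(ij)
              paste(init$names[ij], collapse = "/")), collapse = ", "))

  structure(list(
    names = init$names, freq_hz = f_hat, r2star = r_hat, phase = phi_hat,
    freq_sd = sds[seq_len(K)], r2star_sd = sds[K + seq_len(K)],
    phase_sd = sds[2 * K + 1],
    amplitudes = t(A), amplitude_sd = t(amp_sd),   # [block x resonance]
    block_start_min = fids$block_start_min, block_min = fids$block_min,
    rss = rss, sigma = sqrt(sigma2),
    residual_power = colSums(matrix(resid^2, nrow = nr)),
    degenerate_pairs = degen, n_iter = fit$niter, info = fit$info),
    class = "spectral_model")
}

#' Correct fitted amplitudes for stoichiometry and relaxation
#'
#' Divides each resonance's amplitudes by its effective label stoichiometry
#' and by the relaxation attenuation
#' \eqn{(1 - e^{-TR/T_1})\, e^{-TE/T_2}} (saturation factor for ideal 90
#' degree excitation), making corrected amplitudes proportional to molecule
#' concentration.
#'
#' @param model a fitted `spectral_model`.
#' @param cfg a [quant_config()] covering every fitted resonance.
#' @return the model with `amplitudes_corrected` / `amplitude_sd_corrected`.
#' @export
correct_amplitudes <- function(model, cfg) {
  stopifnot(inherits(model, "spectral_model"), inherits(cfg, "quant_config"))
  miss <- setdiff(model$names,
                  intersect(names(cfg$stoichiometry), names(cfg$t1)))
  if (length(miss))
    stop("quantification config is missing resonance(s): ",
         paste(miss, collapse = ", "))
  fac <- vapply(model$names, function(nm)
    cfg$stoichiometry[[nm]] * (1 - exp(-cfg$tr / cfg$t1[[nm]])) *
      exp(-cfg$te / cfg$t2[[nm]]), numeric(1))
  model$correction_factors <- fac
  model$amplitudes_corrected <- sweep(model$amplitudes, 2, fac, "/")
  model$amplitude_sd_corrected <- sweep(model$amplitude_sd, 2, fac, "/")
  model
}

#' Convert corrected amplitudes to absolute concentrations
#'
#' Uses the natural-abundance HOD signal acquired before the glucose
#' infusion as internal reference: the mean corrected HOD amplitude over the
#' pre-infusion blocks corresponds to `cfg$c_na` mM, and every metabolite
#' amplitude is scaled accordingly. Uncertainties are first-order
#' propagated, including the reference uncertainty. Negative point
#' estimates are retained in `conc_raw`; the `conc_mM` column floors at 0.
#'
#' @param model a corrected `spectral_model` (see [correct_amplitudes()]).
#' @param cfg a [quant_config()].
#' @param pre_blocks indices of the pre-infusion blocks.
#' @return a `metabolite_timecourse` data.frame: block, time_min,
#'   metabolite, conc_mM, conc_raw, sd_mM.
#' @export
to_concentrations <- function(model, cfg, pre_blocks = 1:2) {
  stopifnot(inherits(model, "spectral_model"), length(pre_blocks) >= 1)
  if (is.null(model$amplitudes_corrected))
    model <- correct_amplitudes(model, cfg)
  if (!"HOD" %in% model$names) stop("HOD resonance required as reference")
  hod <- match("HOD", model$names)
  ref <- mean(model$amplitudes_corrected[pre_blocks, hod])
  if (!is.finite(ref) || ref <= 0)
    stop("non-positive HOD reference amplitude in pre-infusion blocks")
  ref_sd <- sqrt(sum(model$amplitude_sd_corrected[pre_blocks, hod]^2)) /
    length(pre_blocks)

  t_mid <- model$block_start_min + model$block_min / 2
  n_blocks <- nrow(model$amplitudes_corrected)
  out <- do.call(rbind, lapply(seq_along(model$names), function(k) {
    a <- model$amplitudes_corrected[, k]
    s <- model$amplitude_sd_corrected[, k]
    conc <- a / ref * cfg$c_na
    rel2 <- (s / ifelse(a == 0, 1, a))^2 + (ref_sd / ref)^2
    data.frame(block = seq_len(n_blocks), time_min = t_mid,
               metabolite = model$names[k],
               conc_mM = pmax(conc, 0), conc_raw = conc,
               sd_mM = abs(conc) * sqrt(rel2) +
                 ifelse(a == 0, s / ref * cfg$c_na, 0))
  }))
  attr(out, "reference") <- list(amplitude = ref, sd = ref_sd,
                                 c_na = cfg$c_na, pre_blocks = pre_blocks)
  class(out) <- c("metabolite_timecourse", "data.frame")
  out
}

#' Standard-addition estimate of the natural-abundance HOD concentration
#'
#' Ordinary least squares of amplitude on added concentration,
#' `amplitude = a + b * delta`; the analyte concentration is the magnitude
#' of the x-intercept, \eqn{\hat c = a/b}, with the delta-method standard
#' error.
#'
#' @param series a [simulate_titration()] data.frame (columns `delta`,
#'   `amplitude`) or equivalent.
#' @return list with `c_na_hat` (mM), `se` (mM), and the `lm` fit.
#' @export
standard_addition <- function(series) {
  stopifnot(all(c("delta", "amplitude") %in% names(series)),
            length(unique(series$delta)) >= 3, any(series$delta == 0))
  fit <- stats::lm(amplitude ~ delta, data = series)
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  if (b <= 0) stop("non-physical titration: fitted gain <= 0")
  V <- suppressWarnings(stats::vcov(fit))  # exact fits warn harmlessly
  grad <- c(1 / b, -a / b^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  list(c_na_hat = a / b, se = se, fit = fit)
}

#' Isotope mole-fraction to HOD concentration
#'
#' Water is 111.1 M in equivalent 1H protons, so a 2H mole fraction of x
#' ppm corresponds to an HOD concentration of `x * 1e-6 * 111100` mM.
#'
#' @param ratio_ppm 2H mole fraction, parts per million.
#' @return HOD concentration, mM.
#' @export
ppm_to_concentration <- function(ratio_ppm) {
  stopifnot(all(ratio_ppm >= 0))
  ratio_ppm * 1e-6 * 111100
}

#' Glx:Lac ratio time course
#'
#' The oxidative-versus-glycolytic readout: per-block Glx/Lac concentration
#' ratio with first-order propagated SD. Blocks where the lactate estimate
#' is consistent with zero (below twice its SD) are flagged undefined
#' (`NA` ratio, `defined = FALSE`).
#'
#' @param tc a `metabolite_timecourse` from [to_concentrations()].
#' @return data.frame: block, time_min, ratio, sd, defined.
#' @export
glx_lac_timecourse <- function(tc) {
  stopifnot(inherits(tc, "metabolite_timecourse"),
            all(c("Glx", "Lac") %in% tc$metabolite))
  g <- tc[tc$metabolite == "Glx", ]
  l <- tc[tc$metabolite == "Lac", ]
  defined <- l$conc_raw > 2 * l$sd_mM
  ratio <- ifelse(defined, g$conc_raw / l$conc_raw, NA_real_)
  sd <- ifelse(defined,
               abs(ratio) * sqrt((g$sd_mM / pmax(abs(g$conc_raw), 1e-12))^2 +
                                   (l$sd_mM / pmax(abs(l$conc_raw),
                                                   1e-12))^2),
               NA_real_)
  data.frame(block = g$block, time_min = g$time_min, ratio = ratio,
             sd = sd, defined = defined)
}
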