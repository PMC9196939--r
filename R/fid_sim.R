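#' Metabolite kinetics presets for 2H spectroscopy simulation
#'
#' Describes, per resonance (HOD, Glc, Glx, Lac), its chemical shift, its
#' effective decay rate R2*, its relaxation times, and a
#' concentration-versus-time curve: baseline before the glucose infusion,
#' then a saturating rise toward a plateau,
#' \eqn{c(t) = c_0 + (c_\infty - c_0)(1 - e^{-k (t - t_0)})} for
#' \eqn{t > t_0}. The HOD baseline is the configured natural-abundance
#' concentration. Cohort presets encode the qualitative metabolic contrast:
#' tumor converts glucose mostly to lactate (Warburg effect, terminal
#' Glx:Lac < 1) while control and radiation-necrosis tissue favor oxidative
#' Glx production (terminal Glx:Lac > 1). Plateau magnitudes are
#' configuration-exposed model choices, not measured values.
#'
#' @param cohort `"control"`, `"tumor"` or `"rn"`.
#' @param c_na natural-abundance HOD concentration, mM.
#' @param onset_min infusion start, minutes from the first block's start.
#' @param subject_sd between-subject log-normal coefficient of variation
#'   applied to metabolite plateaus (0 = the nominal preset).
#' @param seed seed used when `subject_sd > 0`.
#' @return object of class `dmrs_kinetics`.
#' @export
dmrs_kinetics <- function(cohort = c("control", "tumor", "rn"),
                          c_na = 16.35, onset_min = 20,
                          subject_sd = 0, seed = 1L) {
  cohort <- match.arg(cohort)
  stopifnot(c_na > 0, onset_min >= 0, subject_sd >= 0)
  plateaus <- switch(cohort,
    control = c(Glc = 1.5, Glx = 1.9, Lac = 0.6),
    tumor   = c(Glc = 1.8, Glx = 0.8, Lac = 3.0),
    rn      = c(Glc = 1.5, Glx = 1.7, Lac = 0.8))
  if (subject_sd > 0) {
    set.seed(seed)
    plateaus <- plateaus * exp(stats::rnorm(3, 0, subject_sd))
  }
  if (cohort == "tumor" && plateaus["Lac"] <= plateaus["Glx"])
    plateaus["Lac"] <- plateaus["Glx"] * 1.5  # preserve cohort ordering
  if (cohort != "tumor" && plateaus["Glx"] <= plateaus["Lac"])
    plateaus["Glx"] <- plateaus["Lac"] * 1.5

  res <- list(
    HOD = list(ppm = 4.8, r2star = 50, t1 = 0.320, t2 = 0.030,
               curve = list(baseline = c_na, plateau = c_na,
                            rate = 0.1, onset = onset_min)),
    Glc = list(ppm = 3.8, r2star = 70, t1 = 0.064, t2 = 0.032,
               curve = list(baseline = 0, plateau = unname(plateaus["Glc"]),
                            rate = 0.15, onset = onset_min)),
    Glx = list(ppm = 2.4, r2star = 60, t1 = 0.146, t2 = 0.040,
               curve = list(baseline = 0, plateau = unname(plateaus["Glx"]),
                            rate = 0.06, onset = onset_min)),
    Lac = list(ppm = 1.3, r2star = 55, t1 = 0.297, t2 = 0.061,
               curve = list(baseline = 0, plateau = unname(plateaus["Lac"]),
                            rate = 0.08, onset = onset_min)))
  structure(list(resonances = res, cohort = cohort, c_na = c_na,
                 water_ppm = 4.8),
            class = "dmrs_kinetics")
}

# concentration at time t (min) for one resonance's curve
.kinetic_conc <- function(curve, t_min) {
  rise <- ifelse(t_min > curve$onset,
                 1 - exp(-curve$rate * (t_min - curve$onset)), 0)
  curve$baseline + (curve$plateau - curve$baseline) * rise
}

#' Simulate a 2H FID time series
#'
#' Each 10-minute block's FID is a sum of exponentially decaying sinusoids,
#' \eqn{y(t) = \sum_k A_k e^{-R_{2,k}^* t} e^{i(2\pi f_k t + \phi)}}, with
#' the amplitude of resonance k proportional to its concentration at the
#' block midpoint times its labeling stoichiometry and relaxation
#' attenuation \eqn{(1 - e^{-TR/T_1}) e^{-TE/T_2}} (the exact inverse of the
#' quantification chain). Frequencies are offsets from the water (HOD)
#' carrier, \eqn{f_k = (\delta_k - \delta_{HOD})\, \nu_{ref}}. Pre-infusion
#' blocks therefore contain the HOD resonance only, at natural abundance.
#' Complex circular Gaussian noise of the stated SD is added per point.
#'
#' @param kinetics a [dmrs_kinetics()] object.
#' @param acq an [acq_dmrs()] spec.
#' @param n_blocks number of blocks (>= 3; the first blocks before
#'   `onset_min` are pre-infusion).
#' @param noise_sd complex noise SD per channel, same units as the FID.
#' @param gain receiver gain (scales every amplitude).
#' @param phase global zero-order phase, radians.
#' @param seed integer seed for the noise stream.
#' @param stoichiometry,relaxation named constants matching [quant_config()];
#'   defaults are the quantification defaults so the forward model is the
#'   exact inverse of the analysis chain.
#' @return a `fid_series`: complex matrix `[point, block]`, dwell time,
#'   block start times (min), acquisition spec, and the ground-truth
#'   amplitude/concentration matrices.
#' @export
simulate_fid_series <- function(kinetics, acq = acq_dmrs(), n_blocks = 11,
                                noise_sd = 0, gain = 1, phase = 0, seed = 1L,
                                stoichiometry = c(HOD = 1, Glc = 2,
                                                  Lac = 1.7, Glx = 1.2),
                                relaxation = NULL) {
  stopifnot(inherits(kinetics, "dmrs_kinetics"), inherits(acq, "acq_spec"),
            acq$sequence == "dmrs", n_blocks >= 3, gain > 0, noise_sd >= 0)
  rs <- kinetics$resonances
  t_fid <- (seq_len(acq$n_points) - 1) * acq$dwell
  block_start <- (seq_len(n_blocks) - 1) * acq$block_min
  t_mid <- block_start + acq$block_min / 2

  conc <- vapply(rs, function(r) .kinetic_conc(r$curve, t_mid),
                 numeric(n_blocks))           # [block, resonance]
  if (any(conc < 0)) stop("negative concentration in kinetic curve")
  sat <- vapply(names(rs), function(nm) {
    t1 <- if (!is.null(relaxation)) relaxation$t1[[nm]] else rs[[nm]]$t1
    t2 <- if (!is.null(relaxation)) relaxation$t2[[nm]] else rs[[nm]]$t2
    (1 - exp(-acq$tr / t1)) * exp(-acq$te / t2)
  }, numeric(1))
  amp <- conc * rep(stoichiometry[names(rs)] * sat, each = n_blocks) * gain

  freq <- vapply(rs, function(r) (r$ppm - kinetics$water_ppm) * acq$ref_mhz,
                 numeric(1))                  # Hz (ref_mhz: Hz per ppm)
  decay <- vapply(rs, function(r) r$r2star, numeric(1))
  basis <- exp(outer(t_fid, 2i * pi * freq - decay) + 1i * phase)
  fid <- basis %*% t(amp)                     # [point, block]

  if (noise_sd > 0) {
    set.seed(seed)
    fid <- fid + complex(real = stats::rnorm(length(fid), sd = noise_sd),
                         imaginary = stats::rnorm(length(fid),
                                                  sd = noise_sd))
  }

  structure(list(fid = fid, dwell = acq$dwell, ref_mhz = acq$ref_mhz,
                 block_start_min = block_start, block_min = acq$block_min,
                 acq = acq,
                 truth = list(amplitudes = amp, concentrations = conc,
                              freq_hz = freq, r2star = decay, phase = phase,
                              gain = gain, cohort = kinetics$cohort)),
            class = "fid_series")
}

#' Simulate a standard-addition titration series
#'
#' Emulates the semiheavy-water calibration experiment: samples of tap water
#' spiked with known increments of HOD above natural abundance. The detected
#' amplitude of sample i is `gain * (c_na + delta_i)` plus optional Gaussian
#' noise. The default deltas are the five enriched samples (36--180 mM) plus
#' the un-spiked tap-water sample.
#'
#' @param deltas HOD added above natural abundance, mM.
#' @param c_na true natural-abundance HOD concentration, mM.
#' @param gain detection gain, amplitude units per mM.
#' @param noise_sd amplitude noise SD.
#' @param seed seed for the noise stream.
#' @return data.frame with columns `delta` and `amplitude`, class
#'   `titration_series`.
#' @export
simulate_titration <- function(deltas = c(0, 36, 72, 108, 144, 180),
                               c_na = 16.35, gain = 1, noise_sd = 0,
                               seed = 1L) {
  stopifnot(all(deltas >= 0), c_na > 0, gain > 0, noise_sd >= 0)
  amp <- gain * (c_na + deltas)
  if (noise_sd > 0) {
    set.seed(seed)
    amp <- amp + stats::rnorm(length(amp), sd = noise_sd)
  }
  structure(data.frame(delta = deltas, amplitude = amp),
            class = c("titration_series", "data.frame"))
}
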