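test_that("varpro fit recovers a single damped sinusoid near-exactly", {
  fids <- single_resonance_fid(amp = 1, freq = 50, r2star = 30)
  m <- fit_fid_series(fids, spectral_init("X", 45, 25))
  expect_rel_equal(m$freq_hz, 50, 1e-8)
  expect_rel_equal(m$r2star, 30, 1e-8)
  expect_rel_equal(m$amplitudes[1, 1], 1, 1e-8)

  expect_error(fit_fid_series(fids, spectral_init("X", 2000, 25)),
               "bandwidth")
})

test_that("varpro fit recovers the 4-resonance generator truth", {
  fids <- simulate_fid_series(dmrs_kinetics("tumor"), n_blocks = 11)
  m <- fit_fid_series(fids, default_spectral_init(acq_dmrs()))
  expect_rel_equal(m$freq_hz, fids$truth$freq_hz, 1e-6)
  expect_rel_equal(m$r2star, fids$truth$r2star, 1e-6)
  expect_lt(max(abs(m$amplitudes - fids$truth$amplitudes)), 1e-6)
})

test_that("varpro solution matches brute-force full nonlinear fit", {
  # 2-resonance toy, both routes free in all parameters
  t_fid <- (0:511) / 1500
  truth <- list(f = c(-40, 120), r = c(25, 50), phi = 0.2,
                a = matrix(c(1.5, 0.7, 1.2, 0.9), 2, 2))  # [res x block]
  fid <- sapply(1:2, function(b)
    colSums(truth$a[, b] *
              exp(outer(2i * pi * truth$f - truth$r, t_fid) +
                    1i * truth$phi)))
  fids <- structure(list(fid = fid, dwell = 1 / 1500, ref_mhz = 76.65,
                         block_start_min = c(0, 10), block_min = 10,
                         acq = NULL, truth = NULL), class = "fid_series")
  mv <- fit_fid_series(fids, spectral_init(c("A", "B"), c(-35, 110), 30))

  # brute force: optim over every parameter at once
  obj <- function(p) {
    f <- p[1:2]; r <- p[3:4]; phi <- p[5]
    a <- matrix(p[6:9], 2, 2)
    mod <- sapply(1:2, function(b)
      colSums(a[, b] * exp(outer(2i * pi * f - r, t_fid) + 1i * phi)))
    sum(Mod(mod - fid)^2)
  }
  bf <- optim(c(-35, 110, 30, 30, 0.1, 1, 1, 1, 1), obj, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-15))
  expect_rel_equal(mv$freq_hz, bf$par[1:2], 1e-6)
  expect_rel_equal(mv$r2star, bf$par[3:4], 1e-6)
  expect_rel_equal(as.vector(t(mv$amplitudes)), bf$par[6:9], 1e-6)
  expect_rel_equal(mv$freq_hz, truth$f, 1e-6)
})

test_that("amplitude uncertainty matches Monte-Carlo spread", {
  sd_noise <- 0.05
  set.seed(1)
  amps <- replicate(200, {
    seed <- sample.int(1e6, 1)
    fids <- single_resonance_fid(amp = 1, freq = 50, r2star = 30,
                                 n_points = 256, noise_sd = sd_noise,
                                 seed = seed)
    m <- fit_fid_series(fids, spectral_init("X", 48, 28))
    c(m$amplitudes[1, 1], m$amplitude_sd[1, 1])
  })
  mc_sd <- sd(amps[1, ])
  est_sd <- median(amps[2, ])
  expect_lt(abs(est_sd - mc_sd) / mc_sd, 0.2)
})

test_that("stoichiometry/relaxation correction follows the stated formula", {
  cfg <- quant_config(tr = 1000, te = 0)   # TR >> T1, TE = 0
  m <- structure(list(names = "HOD", amplitudes = matrix(2, 1, 1),
                      amplitude_sd = matrix(0.1, 1, 1)),
                 class = "spectral_model")
  mc <- correct_amplitudes(m, cfg)
  expect_equal(mc$amplitudes_corrected[1, 1], 2, tolerance = 1e-10)

  expect_equal(label_stoichiometry(2, 0.15), 1.7)
  expect_equal(label_stoichiometry(2, 0.40), 1.2)

  # formula vs stepwise arithmetic
  cfg2 <- quant_config(t1 = c(HOD = 0.3), t2 = c(HOD = 0.03),
                       stoichiometry = c(HOD = 1), tr = 0.45, te = 0.00427)
  m2 <- structure(list(names = "HOD", amplitudes = matrix(1, 1, 1),
                       amplitude_sd = matrix(0, 1, 1)),
                  class = "spectral_model")
  got <- correct_amplitudes(m2, cfg2)$correction_factors[["HOD"]]
  sat <- 1 - exp(-0.45 / 0.3)
  t2dec <- exp(-0.00427 / 0.03)
  expect_equal(got, sat * t2dec, tolerance = 1e-12)

  expect_error(correct_amplitudes(
    structure(list(names = c("HOD", "Foo"),
                   amplitudes = matrix(1, 1, 2),
                   amplitude_sd = matrix(0, 1, 2)),
              class = "spectral_model"),
    quant_config()), "Foo")
})

test_that("HOD internal referencing yields absolute concentrations", {
  cfg <- quant_config()
  fac <- vapply(c("HOD", "Lac"), function(nm)
    cfg$stoichiometry[[nm]] * (1 - exp(-cfg$tr / cfg$t1[[nm]])) *
      exp(-cfg$te / cfg$t2[[nm]]), numeric(1))
  # corrected Lac amplitude equal to the HOD reference -> 16.35 mM;
  # equality before correction instead gives 16.35 / 1.7 (up to the
  # relaxation-factor ratio handled below with equal factors)
  amp <- matrix(0, 3, 2, dimnames = list(NULL, c("HOD", "Lac")))
  amp[, "HOD"] <- 5
  amp[, "Lac"] <- 5 * fac[["Lac"]] / fac[["HOD"]]
  m <- structure(list(names = c("HOD", "Lac"), amplitudes = amp,
                      amplitude_sd = amp * 0.01,
                      block_start_min = c(0, 10, 20), block_min = 10),
                 class = "spectral_model")
  tc <- to_concentrations(m, cfg, pre_blocks = 1:2)
  expect_equal(tc$conc_mM[tc$metabolite == "HOD"], rep(16.35, 3),
               tolerance = 1e-12)
  expect_equal(tc$conc_mM[tc$metabolite == "Lac"], rep(16.35, 3),
               tolerance = 1e-12)

  # raw amplitude equality (no stoichiometry correction on Lac's side)
  amp2 <- amp; amp2[, "Lac"] <- 5 * 1 / fac[["HOD"]] *
    (1 - exp(-cfg$tr / cfg$t1[["Lac"]])) * exp(-cfg$te / cfg$t2[["Lac"]])
  m2 <- m; m2$amplitudes <- amp2
  tc2 <- to_concentrations(m2, cfg, pre_blocks = 1:2)
  expect_equal(tc2$conc_mM[tc2$metabolite == "Lac"],
               rep(16.35 / 1.7, 3), tolerance = 1e-12)

  # zero amplitude -> 0 mM
  m3 <- m; m3$amplitudes[, "Lac"] <- 0
  tc3 <- to_concentrations(m3, cfg, pre_blocks = 1:2)
  expect_equal(tc3$conc_mM[tc3$metabolite == "Lac"], rep(0, 3))
})

test_that("standard addition is exact on noiseless data and unbiased", {
  sa <- standard_addition(simulate_titration(gain = 3.7))
  expect_equal(sa$c_na_hat, 16.35, tolerance = 1e-10)

  # amplitudes proportional to delta only -> zero intercept estimate
  s0 <- simulate_titration(c_na = 1e-12, gain = 2)
  expect_lt(standard_addition(s0)$c_na_hat, 1e-9)

  # Monte-Carlo: noise at 1% of max amplitude, mean within 2 SE of truth
  set.seed(99)
  ests <- replicate(500, {
    s <- simulate_titration(gain = 1, noise_sd = 0.01 * 196.35,
                            seed = sample.int(1e6, 1))
    standard_addition(s)$c_na_hat
  })
  expect_lt(abs(mean(ests) - 16.35), 2 * sd(ests) / sqrt(500))
})

test_that("isotope-ratio conversion reproduces printed concentrations", {
  expect_equal(ppm_to_concentration(145.9), 16.21, tolerance = 1e-3)
  expect_equal(ppm_to_concentration(148.3), 16.47, tolerance = 1e-3)
  expect_equal(ppm_to_concentration(0), 0)
})

test_that("Glx:Lac readout separates metabolic phenotypes", {
  run_cohort <- function(cohort) {
    fids <- simulate_fid_series(dmrs_kinetics(cohort), n_blocks = 11)
    m <- fit_fid_series(fids, default_spectral_init(acq_dmrs()))
    tc <- to_concentrations(m, quant_config(), 1:2)
    glx_lac_timecourse(tc)
  }
  rt <- run_cohort("tumor")
  rc <- run_cohort("control")
  expect_lt(rt$ratio[11], 1)
  expect_gt(rc$ratio[11], 1)

  # ratio = 1 when Glx == Lac; scale invariance
  tc <- data.frame(block = 1:2, time_min = c(5, 15),
                   metabolite = rep(c("Glx", "Lac"), each = 2),
                   conc_mM = c(2, 3, 2, 3), conc_raw = c(2, 3, 2, 3),
                   sd_mM = rep(0.01, 4))
  class(tc) <- c("metabolite_timecourse", "data.frame")
  expect_equal(glx_lac_timecourse(tc)$ratio, c(1, 1))
  tc2 <- tc; tc2$conc_raw <- tc$conc_raw * 7; tc2$conc_mM <- tc2$conc_raw
  tc2$sd_mM <- tc$sd_mM * 7
  expect_equal(glx_lac_timecourse(tc2)$ratio, c(1, 1))

  # lactate consistent with zero -> flagged undefined
  tc3 <- tc; tc3$conc_raw[tc3$metabolite == "Lac"] <- c(0.005, 3)
  expect_false(glx_lac_timecourse(tc3)$defined[1])
})

test_that("full inverse-crime round trip recovers kinetic curves to 1%", {
  for (cohort in c("tumor", "control")) {
    fids <- simulate_fid_series(dmrs_kinetics(cohort), n_blocks = 11)
    m <- fit_fid_series(fids, default_spectral_init(acq_dmrs()))
    tc <- to_concentrations(m, quant_config(), 1:2)
    for (met in c("Glc", "Glx", "Lac")) {
      got <- tc$conc_raw[tc$metabolite == met]
      truth <- fids$truth$concentrations[, met]
      expect_lt(max(abs(got - truth)) / max(truth), 0.01)
    }
  }
})

test_that("quantification is invariant to gain and zero-order phase", {
  base <- simulate_fid_series(dmrs_kinetics("tumor"), n_blocks = 5)
  mod <- simulate_fid_series(dmrs_kinetics("tumor"), n_blocks = 5,
                             gain = 4.2, phase = 0.8)
  q <- function(f) {
    m <- fit_fid_series(f, default_spectral_init(acq_dmrs()))
    tc <- to_concentrations(m, quant_config(), 1:2)
    tc$conc_raw
  }
  expect_equal(q(mod), q(base), tolerance = 1e-6)
})

test_that("near-degenerate frequency pairs trigger a warning", {
  t_fid <- (0:511) / 1500
  fid <- matrix(exp((2i * pi * 50 - 30) * t_fid) +
                  0.5 * exp((2i * pi * 53 - 30) * t_fid), ncol = 1)
  fids <- structure(list(fid = fid, dwell = 1 / 1500, ref_mhz = 76.65,
                         block_start_min = 0, block_min = 10,
                         acq = NULL, truth = NULL), class = "fid_series")
  expect_warning(fit_fid_series(fids, spectral_init(c("A", "B"),
                                                    c(49, 54), 30)),
                 "near-degenerate")
})
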