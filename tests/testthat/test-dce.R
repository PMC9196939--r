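# small synthetic dynamic series built directly (not via the phantom):
# 4x4x1 voxels, controllable per-voxel curves
mk_series <- function(curves, n_frames = 300, frame_dt = 3,
                      muscle_vox = 13:16, baseline = 1:30,
                      early = 31:120) {
  nv <- length(curves)
  stopifnot(nv == 16)
  dat <- array(NA_real_, c(4, 4, 1, n_frames))
  for (v in seq_len(nv))
    dat[((v - 1) %% 4) + 1, ((v - 1) %/% 4) + 1, 1, ] <- curves[[v]]
  mm <- array(FALSE, c(4, 4, 1)); mm[muscle_vox] <- TRUE
  st <- image_stack(dat, axis = "frame_time",
                    axis_values = frame_dt * seq_len(n_frames),
                    acq = acq_dce(n_frames = n_frames, frame_dt = frame_dt))
  dce_series(st, baseline_frames = baseline, early_frames = early,
             muscle_mask = mm)
}

flat <- function(level, n = 300) rep(level, n)
ramped <- function(base, amp, peak_frame = 60, n = 300) {
  x <- rep(base, n)
  x[31:n] <- base * (1 + amp * pmin((31:n - 30) / (peak_frame - 30), 1))
  x
}

test_that("fractional enhancement is baseline-relative and scale-free", {
  ser <- mk_series(rep(list(flat(100)), 16))
  fe <- fractional_enhancement(ser)
  expect_true(all(fe$data == 0))

  cur <- flat(100); cur[31:300] <- 150
  ser2 <- mk_series(c(rep(list(cur), 12), rep(list(flat(100)), 4)))
  fe2 <- fractional_enhancement(ser2)
  expect_equal(unique(as.vector(fe2$data[1, 1, 1, 31:300])), 0.5)

  ser3 <- mk_series(c(rep(list(2 * cur), 12), rep(list(flat(200)), 4)))
  fe3 <- fractional_enhancement(ser3)
  expect_equal(fe3$data, fe2$data, tolerance = 1e-12)

  # zero-baseline voxels are masked and counted
  cur0 <- flat(0)
  ser4 <- mk_series(c(list(cur0), rep(list(flat(100)), 15)))
  fe4 <- fractional_enhancement(ser4)
  expect_identical(attr(fe4, "n_masked"), 1L)
  expect_true(all(is.na(fe4$data[1, 1, 1, ])))
})

test_that("muscle normalizer is ROI-mean-then-max over the early window", {
  mus <- ramped(100, 0.4)
  ser <- mk_series(c(rep(list(flat(100)), 12), rep(list(mus), 4)))
  fe <- fractional_enhancement(ser)
  expect_equal(muscle_norm_factor(fe, ser), 0.4, tolerance = 1e-12)

  # two disjoint muscle regions with different peak timing: the factor is
  # the max of the averaged curve (oracle: explicit frame loop), which is
  # smaller than the mean of per-voxel maxima when peaks do not align
  m1 <- ramped(100, 0.6, peak_frame = 40)
  m1[61:300] <- 100                      # washout to baseline
  m2 <- ramped(100, 0.6, peak_frame = 110)
  ser2 <- mk_series(c(rep(list(flat(100)), 12),
                      list(m1, m1, m2, m2)))
  fe2 <- fractional_enhancement(ser2)
  oracle <- max(vapply(31:120, function(f)
    mean(c(m1, m1, m2, m2)[c(f, 300 + f, 600 + f, 900 + f)] / 100 - 1),
    numeric(1)))
  expect_equal(muscle_norm_factor(fe2, ser2), oracle, tolerance = 1e-12)
  expect_lt(muscle_norm_factor(fe2, ser2), 0.6)

  ser3 <- mk_series(rep(list(flat(100)), 16))
  fe3 <- fractional_enhancement(ser3)
  expect_error(muscle_norm_factor(fe3, ser3), "no contrast arrival")
})

test_that("AUC arithmetic matches the 810-s frame structure", {
  # FE/norm = 1 over all 270 post frames -> AUC = 270/810 = 1/3
  cur <- flat(100); cur[31:300] <- 100 * (1 + 0.4)
  ser <- mk_series(c(rep(list(cur), 12),
                     rep(list(ramped(100, 0.4, peak_frame = 31)), 4)))
  fe <- fractional_enhancement(ser)
  norm <- muscle_norm_factor(fe, ser)
  auc <- compute_auc(fe, norm, ser)
  expect_equal(auc$meta$divisor_s, 810)
  expect_equal(auc$values[1, 1, 1], 270 / 810 / norm * 0.4,
               tolerance = 1e-12)

  ser0 <- mk_series(c(rep(list(flat(50)), 12),
                      rep(list(ramped(100, 0.4)), 4)))
  fe0 <- fractional_enhancement(ser0)
  auc0 <- compute_auc(fe0, muscle_norm_factor(fe0, ser0), ser0)
  expect_equal(auc0$values[1, 1, 1], 0)
})

test_that("phantom DCE pipeline reproduces the preset AUC (closed form)", {
  ph <- small_phantom("mixed")
  ser <- dce_series(simulate_stack(ph, acq_dce()))
  fe <- fractional_enhancement(ser)
  norm <- muscle_norm_factor(fe, ser)
  auc <- compute_auc(fe, norm, ser)
  expect_rel_equal(mean(auc$values[ph$masks$tumor]), 0.916, 1e-6)
  expect_rel_equal(mean(auc$values[ph$masks$rn]), 0.784, 1e-6)

  # oracle: independent frame-loop integral of the configured tumor curve
  p <- ph$presets$tumor$dce
  mus <- ph$presets$muscle$dce
  sh_m <- vapply(1:300, function(f) {
    t <- max(0, f - 30) * 3
    if (f < 31) 0 else (1 - exp(-mus$uptake * t)) * exp(-mus$washout * t)
  }, numeric(1))
  m_peak <- mus$amplitude * max(sh_m[31:120])
  sh_t <- vapply(1:300, function(f) {
    t <- max(0, f - 30) * 3
    if (f < 31) 0 else (1 - exp(-p$uptake * t)) * exp(-p$washout * t)
  }, numeric(1))
  amp_t <- p$auc * m_peak * 810 / sum(sh_t[31:300])
  oracle <- sum(amp_t * sh_t[31:300]) / m_peak / 810
  expect_equal(mean(auc$values[ph$masks$tumor]), oracle, tolerance = 1e-9)

  # receiver-gain invariance end to end
  st2 <- simulate_stack(ph, acq_dce()); st2$data <- st2$data * 12.3
  ser2 <- dce_series(st2)
  fe2 <- fractional_enhancement(ser2)
  auc2 <- compute_auc(fe2, muscle_norm_factor(fe2, ser2), ser2)
  expect_equal(auc2$values, auc$values, tolerance = 1e-10)
})
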