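test_that("Gaussian preprocessing has the required kernel properties", {
  m <- matrix(rnorm(64), 8, 8)
  expect_identical(preprocess(m, 0), m)

  u <- matrix(3.7, 16, 16)
  expect_equal(preprocess(u, 1.2), u, tolerance = 1e-12)

  # delta image: center value equals the discrete kernel peak
  # (oracle: explicit 2-D kernel built in the test)
  d <- matrix(0, 15, 15); d[8, 8] <- 1
  sm <- preprocess(d, 0.75)
  r <- ceiling(4 * 0.75)
  k1 <- exp(-(seq(-r, r))^2 / (2 * 0.75^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  expect_equal(sm[8, 8], max(k2), tolerance = 1e-12)
  # full field matches brute-force convolution away from edges
  conv <- matrix(0, 15, 15)
  for (i in (r + 1):(15 - r)) for (j in (r + 1):(15 - r))
    conv[i, j] <- sum(k2 * d[(i - r):(i + r), (j - r):(j + r)])
  inner <- (r + 1):(15 - r)
  expect_equal(sm[inner, inner], conv[inner, inner], tolerance = 1e-12)
})

test_that("VFA R1 fit recovers noiseless truth and preset ROI means", {
  st <- vfa_voxel_stack(r1 = 1.0, n = 8)
  m <- fit_r1_vfa(st, mask = array(TRUE, dim(st$data)[1:3]))
  expect_rel_equal(m$values, 1.0, 1e-6)

  ph <- small_phantom("rn")
  mrn <- fit_r1_vfa(simulate_stack(ph, acq_vfa()))
  expect_rel_equal(mean(mrn$values[ph$masks$rn]), 1.26, 1e-6)
  expect_rel_equal(mean(mrn$values[ph$masks$cortex]), 0.95, 1e-6)

  expect_error(fit_r1_vfa(st, acq = acq_vfa(flip_angles = c(5, 30))),
               "3 distinct flip angles")
})

test_that("VFA fit has small median bias under rician noise at SNR 50", {
  r1_true <- 1.08
  st <- vfa_voxel_stack(r1 = r1_true, n = 1000)
  set.seed(42)
  sd_n <- 1 / 50
  st$data <- sqrt((st$data + rnorm(length(st$data), sd = sd_n))^2 +
                    rnorm(length(st$data), sd = sd_n)^2)
  m <- fit_r1_vfa(st, mask = array(TRUE, dim(st$data)[1:3]))
  bias <- (median(m$values, na.rm = TRUE) - r1_true) / r1_true
  expect_lt(abs(bias), 0.02)
})

test_that("multi-echo R2 fit handles the additive constant correctly", {
  te <- acq_mems()$te_list
  mk_stack <- function(a, r2, cc) {
    sig <- a * exp(-te * r2) + cc
    image_stack(array(rep(sig, each = 8), c(2, 2, 2, 16)),
                axis = "echo_time", axis_values = te, acq = acq_mems())
  }
  full_mask <- array(TRUE, c(2, 2, 2))

  m <- fit_r2_mems(mk_stack(1, 17.6, 0), mask = full_mask)
  expect_rel_equal(m$values, 17.6, 1e-6)

  # nonzero offset: 3-parameter fit stays exact, 2-parameter log-linear
  # fit on the same data is biased low (documented comparison)
  m3 <- fit_r2_mems(mk_stack(1, 17.6, 0.1), mask = full_mask)
  expect_rel_equal(m3$values, 17.6, 1e-6)
  sig <- 1 * exp(-te * 17.6) + 0.1
  r2_loglin <- -coef(lm(log(sig) ~ te))[[2]]
  expect_lt(r2_loglin, 0.9 * 17.6)

  # constant signal: degenerate decay flagged
  mc <- fit_r2_mems(mk_stack(0, 1, 0.8), mask = full_mask)
  expect_true(all(mc$flags[mc$mask] | mc$values[mc$mask] < 1e-3))

  expect_error(fit_r2_mems(mk_stack(1, 10, 0),
                           acq = acq_mems(n_echoes = 3)), "4 echoes")
})

test_that("ADC fit recovers tensors, traces, and flags bad encodings", {
  iso <- small_phantom("tumor",
                       presets = within(default_presets(), {
                         tumor <- tissue_preset("tumor", 1.08, 14.9,
                                                adc = 0.7, mtr = 24.1)
                       }))
  m <- fit_adc(simulate_stack(iso, acq_dwi()))
  expect_rel_equal(mean(m$values[iso$masks$tumor]), 0.7, 1e-6)

  aniso <- small_phantom("tumor",
                         presets = within(default_presets(), {
                           tumor <- tissue_preset("tumor", 1.08, 14.9,
                                                  adc = diag(c(1, 0.5, 0.3)),
                                                  mtr = 24.1)
                         }))
  ma <- fit_adc(simulate_stack(aniso, acq_dwi()))
  expect_rel_equal(mean(ma$values[aniso$masks$tumor]), 0.6, 1e-6)

  ph <- small_phantom("tumor")
  mt <- fit_adc(simulate_stack(ph, acq_dwi()))
  expect_rel_equal(mean(mt$values[ph$masks$tumor]), 0.833, 1e-6)

  bad <- acq_dwi()
  bad$b_matrices <- bad$b_matrices[c(1, 2, 3, 2, 3, 2, 3)]
  expect_error(fit_adc(simulate_stack(ph, acq_dwi()), acq = bad),
               "rank-deficient")
})

test_that("MTR map follows its definition and edge conventions", {
  a <- array(100, c(4, 4, 2))
  expect_true(all(compute_mtr(a, a)$values == 0))
  expect_equal(unique(as.vector(compute_mtr(array(75.9, c(4, 4, 2)),
                                            a)$values)),
               24.1, tolerance = 1e-12)
  expect_true(all(compute_mtr(array(0, c(4, 4, 2)), a)$values == 100))
  expect_error(compute_mtr(array(1, c(4, 4, 2)), array(1, c(4, 4, 3))),
               "mismatch")

  # MTR invariant under preprocessing of a spatially uniform pair
  u_off <- array(100, c(8, 8, 1)); u_on <- array(70, c(8, 8, 1))
  sm <- compute_mtr(preprocess(image_stack(u_on), 0.75)$data[, , , 1],
                    preprocess(image_stack(u_off), 0.75)$data[, , , 1])
  expect_equal(unique(as.vector(sm$values)), 30, tolerance = 1e-12)
})

test_that("all map fits are scale-equivariant in the input signal", {
  ph <- small_phantom("mixed")
  stacks <- list(vfa = simulate_stack(ph, acq_vfa()),
                 mems = simulate_stack(ph, acq_mems()),
                 dwi = simulate_stack(ph, acq_dwi()))
  fits <- list(vfa = fit_r1_vfa, mems = fit_r2_mems, dwi = fit_adc)
  for (sq in names(stacks)) {
    base <- fits[[sq]](stacks[[sq]])
    scaled <- stacks[[sq]]
    scaled$data <- scaled$data * 37.5
    res <- fits[[sq]](scaled)
    expect_equal(res$values, base$values, tolerance = 1e-6,
                 info = sq)
  }
  mt <- simulate_stack(ph, acq_mt())
  mt2 <- mt; mt2$data <- mt$data * 0.3
  expect_equal(compute_mtr(mt2)$values, compute_mtr(mt)$values,
               tolerance = 1e-12)
})

test_that("fit uncertainties shrink as 1/sqrt(averages)", {
  r1_true <- 1.0
  n_vox <- 216
  mk <- function(n_avg, seed) {
    st <- vfa_voxel_stack(r1 = r1_true, n = n_vox)
    set.seed(seed)
    acc <- 0
    for (i in seq_len(n_avg))
      acc <- acc + st$data + rnorm(length(st$data), sd = 0.01)
    st$data <- acc / n_avg
    st
  }
  m1 <- fit_r1_vfa(mk(1, 1), mask = array(TRUE, c(6, 6, 6)))
  m4 <- fit_r1_vfa(mk(4, 2), mask = array(TRUE, c(6, 6, 6)))
  ratio <- mean(m1$uncertainty, na.rm = TRUE) /
    mean(m4$uncertainty, na.rm = TRUE)
  expect_equal(ratio, 2, tolerance = 0.25)
})
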