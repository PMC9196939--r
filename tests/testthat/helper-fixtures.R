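# small shared fixtures, generated in code

# compact phantom for fast round-trip tests (presets are slice-invariant,
# so few slices lose no generality)
small_phantom <- function(layout = "tumor", matrix_size = 32, n_slices = 3,
                          ...) {
  build_label_map(matrix_size, n_slices, layout = layout, ...)
}

# a stack of n identical voxels following the VFA forward model
vfa_voxel_stack <- function(r1, s0 = 1, n = 1, acq = acq_vfa()) {
  e1 <- exp(-acq$tr * r1)
  th <- acq$flip_angles * pi / 180
  sig <- s0 * (1 - e1) * sin(th) / (1 - e1 * cos(th))
  d <- ceiling(n^(1 / 3))
  dat <- array(rep(sig, each = d^3), c(d, d, d, length(th)))
  image_stack(dat, axis = "flip_angle", axis_values = acq$flip_angles,
              acq = acq)
}

# single-resonance fid_series built directly from the damped-sinusoid model
single_resonance_fid <- function(amp = 1, freq = 50, r2star = 30,
                                 phase = 0, n_points = 1024,
                                 dwell = 1 / 1500, n_blocks = 1,
                                 noise_sd = 0, seed = 1) {
  t_fid <- (seq_len(n_points) - 1) * dwell
  fid <- matrix(rep(amp * exp((2i * pi * freq - r2star) * t_fid +
                                1i * phase), n_blocks),
                n_points, n_blocks)
  if (noise_sd > 0) {
    set.seed(seed)
    fid <- fid + complex(real = rnorm(length(fid), sd = noise_sd),
                         imaginary = rnorm(length(fid), sd = noise_sd))
  }
  structure(list(fid = fid, dwell = dwell, ref_mhz = 76.65,
                 block_start_min = (seq_len(n_blocks) - 1) * 10,
                 block_min = 10, acq = NULL, truth = NULL),
            class = "fid_series")
}

# relative comparison with the overall scale of `expected` as floor, so
# exact zeros among the expected values do not blow up the ratio
expect_rel_equal <- function(actual, expected, rel_tol) {
  scale <- max(abs(expected), 1e-300)
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 0.01 * scale)),
            rel_tol)
}
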