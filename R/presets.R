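#' Tissue preset: ground-truth quantitative parameters for one tissue class
#'
#' A preset bundles the quantitative MR parameters of a single tissue class
#' (tumor, radiation necrosis, contralateral cortex, muscle, ...). It is both
#' the forward-simulation truth of the digital phantom and the recovery target
#' for the fitting stages.
#'
#' @param name tissue label, e.g. `"tumor"`.
#' @param r1 longitudinal relaxation rate, 1/s.
#' @param r2 transverse relaxation rate, 1/s.
#' @param adc apparent diffusion tensor in um^2/ms: either a scalar (isotropic,
#'   expanded to `adc * I`) or a symmetric positive semi-definite 3x3 matrix.
#' @param mtr magnetization transfer ratio, percent (0--100).
#' @param s0 equilibrium (Boltzmann) signal, arbitrary units.
#' @param dce enhancement-curve description, a list with elements `auc`
#'   (target muscle-normalized per-second AUC, au), `uptake` and `washout`
#'   (rate constants, 1/s), and optionally `amplitude` (peak fractional
#'   enhancement; if present it overrides derivation from `auc` -- used for
#'   the muscle normalizer itself).
#' @return an object of class `tissue_preset`.
#' @export
tissue_preset <- function(name, r1, r2, adc, mtr, s0 = 1,
                          dce = list(auc = 0, uptake = 0.02, washout = 0)) {
  if (length(adc) == 1L) adc <- diag(3) * adc
  adc <- as.matrix(adc)
  stopifnot(r1 > 0, r2 > 0, mtr >= 0, mtr <= 100, s0 > 0,
            identical(dim(adc), c(3L, 3L)),
            isTRUE(all.equal(adc, t(adc))))
  ev <- eigen(adc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12)
    stop("adc tensor for '", name, "' is not positive semi-definite")
  if (!is.null(dce$amplitude) && dce$amplitude < 0)
    stop("dce amplitude must be >= 0")
  structure(list(name = name, r1 = r1, r2 = r2, adc = adc, mtr = mtr,
                 s0 = s0, dce = dce),
            class = "tissue_preset")
}

#' Default tissue presets
#'
#' Lesion presets carry reference cohort-mean parameter values for GL261
#' glioblastoma and radiation-necrosis tissue
#' (tumor:
#' R1 1.08 1/s, R2 14.9 1/s, ADC 0.833 um^2/ms, MTR 24.1%, DCE AUC 0.916 au;
#' radiation necrosis: 1.26, 17.6, 0.736, 30.2%, 0.784 au).
#' Contralateral cortex and muscle are literature-informed defaults: the
#' reference values cover lesion tissue only, so cortex is set
#' near healthy mouse gray matter at 4.7 T and muscle is given a fast, strong
#' contrast-uptake curve because it serves as the DCE normalization
#' reference.
#'
#' @return named list of [tissue_preset()] objects keyed by tissue name.
#' @export
default_presets <- function() {
  list(
    cortex = tissue_preset("cortex", r1 = 0.95, r2 = 16.5, adc = 0.74,
                           mtr = 32.0,
                           dce = list(auc = 0.05, uptake = 0.02, washout = 0)),
    tumor  = tissue_preset("tumor", r1 = 1.08, r2 = 14.9, adc = 0.833,
                           mtr = 24.1,
                           dce = list(auc = 0.916, uptake = 0.02,
                                      washout = 0.001)),
    rn     = tissue_preset("rn", r1 = 1.26, r2 = 17.6, adc = 0.736,
                           mtr = 30.2,
                           dce = list(auc = 0.784, uptake = 0.01,
                                      washout = 0.0005)),
    muscle = tissue_preset("muscle", r1 = 1.40, r2 = 28, adc = 1.50,
                           mtr = 40.0,
                           dce = list(amplitude = 0.40, uptake = 0.05,
                                      washout = 0.0005))
  )
}

#' Acquisition specifications
#'
#' Constructors for the per-sequence timing/encoding parameters of the
#' multi-contrast protocol. Defaults reproduce the small-animal protocol: variable
#' flip angle (TR 0.1 s, flips 5/10/15/30/50/70 deg), 16 echoes at 11 ms
#' spacing, 6-direction diffusion encoding with maximum b 1000 s/mm^2 plus a
#' b = 0 volume, an MT on/off pair at 2000 Hz offset, a 300-frame x 3-s DCE
#' series, and 2H spectroscopy blocks of 1024 complex points at 1500 Hz
#' bandwidth (TR 0.45 s, TE 4.27 ms, 10-min blocks).
#'
#' @param tr repetition time, s.
#' @param te echo time, s.
#' @param flip_angles excitation flip angles, degrees.
#' @return an `acq_spec` list with a `sequence` tag.
#' @export
acq_vfa <- function(tr = 0.1, te = 0.0016,
                    flip_angles = c(5, 10, 15, 30, 50, 70)) {
  stopifnot(tr > 0, length(flip_angles) >= 1, all(flip_angles > 0))
  structure(list(sequence = "vfa", tr = tr, te = te,
                 flip_angles = flip_angles),
            class = "acq_spec")
}

#' @rdname acq_vfa
#' @param echo_spacing inter-echo spacing, s.
#' @param n_echoes number of echoes.
#' @export
acq_mems <- function(tr = 6.0, echo_spacing = 0.011, n_echoes = 16) {
  stopifnot(tr > 0, echo_spacing > 0, n_echoes >= 2)
  structure(list(sequence = "mems", tr = tr,
                 te_list = echo_spacing * seq_len(n_echoes)),
            class = "acq_spec")
}

#' @rdname acq_vfa
#' @param b_max maximum b-value, s/mm^2.
#' @param directions matrix of unit gradient directions (rows); default the
#'   standard 6-direction dual-gradient scheme.
#' @export
acq_dwi <- function(b_max = 1000,
                    directions = rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
                                       c(1, -1, 0), c(1, 0, -1), c(0, 1, -1)) /
                      sqrt(2)) {
  stopifnot(b_max > 0, ncol(directions) == 3)
  bmats <- c(list(matrix(0, 3, 3)),
             lapply(seq_len(nrow(directions)), function(i) {
               g <- directions[i, ]
               b_max * tcrossprod(g / sqrt(sum(g^2)))
             }))
  structure(list(sequence = "dwi", b_matrices = bmats), class = "acq_spec")
}

#' @rdname acq_vfa
#' @param offset_hz MT saturation offset from the water resonance, Hz.
#' @export
acq_mt <- function(tr = 2.0, te = 0.0065, offset_hz = 2000) {
  structure(list(sequence = "mt", tr = tr, te = te, offset_hz = offset_hz,
                 mt_states = c("off", "on")),
            class = "acq_spec")
}

#' @rdname acq_vfa
#' @param n_frames number of dynamic frames.
#' @param frame_dt frame spacing, s.
#' @export
acq_dce <- function(tr = 0.047, te = 0.0016, n_frames = 300, frame_dt = 3) {
  stopifnot(n_frames >= 2, frame_dt > 0)
  structure(list(sequence = "dce", tr = tr, te = te, n_frames = n_frames,
                 frame_dt = frame_dt, flip = 30),
            class = "acq_spec")
}

#' @rdname acq_vfa
#' @param bandwidth_hz spectral acquisition bandwidth, Hz.
#' @param n_points complex points per FID.
#' @param block_min nominal duration of one signal-averaged block, minutes.
#' @param ref_mhz 2H reference (carrier) frequency, MHz; amplitudes are
#'   modeled at the carrier placed on the water (HOD) resonance.
#' @export
acq_dmrs <- function(tr = 0.45, te = 0.00427, bandwidth_hz = 1500,
                     n_points = 1024, block_min = 10, ref_mhz = 76.65) {
  stopifnot(tr > 0, te > 0, bandwidth_hz > 0, n_points >= 2)
  structure(list(sequence = "dmrs", tr = tr, te = te,
                 dwell = 1 / bandwidth_hz, n_points = as.integer(n_points),
                 block_min = block_min, ref_mhz = ref_mhz),
            class = "acq_spec")
}

#' Quantification configuration for 2H spectroscopy
#'
#' Carries the constants that turn fitted resonance amplitudes into absolute
#' concentrations: effective label stoichiometry per molecule (HOD 1; glucose
#' 2; lactate 1.7, i.e. 2 labels with 15% loss; Glx 1.2, i.e. 2 labels with
#' 40% loss), published relaxation times used for the saturation/TE
#' correction, the sequence TR/TE, and the natural-abundance semiheavy-water
#' (HOD) concentration used as internal reference. The default T1/T2 values
#' are literature defaults (the correction is configuration-exposed because
#' published values vary with field strength).
#'
#' @param stoichiometry named numeric, effective 2H labels per molecule.
#' @param t1,t2 named numeric relaxation times, s.
#' @param tr,te sequence repetition and echo time, s.
#' @param c_na natural-abundance HOD concentration, mM.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(stoichiometry = c(HOD = 1, Glc = 2, Lac = 1.7,
                                           Glx = 1.2),
                         t1 = c(HOD = 0.320, Glc = 0.064, Lac = 0.297,
                                Glx = 0.146),
                         t2 = c(HOD = 0.030, Glc = 0.032, Lac = 0.061,
                                Glx = 0.040),
                         tr = 0.45, te = 0.00427, c_na = 16.35) {
  stopifnot(all(stoichiometry > 0), all(t1 > 0), all(t2 > 0),
            tr > 0, te >= 0, c_na > 0)
  structure(list(stoichiometry = stoichiometry, t1 = t1, t2 = t2,
                 tr = tr, te = te, c_na = c_na),
            class = "quant_config")
}

# stoichiometry = n_labels * (1 - loss); kept as a helper so the printed
# label-loss fractions (15% Lac, 40% Glx) map onto the constants explicitly
#' Effective labeling stoichiometry from label count and loss fraction
#' @param n_labels 2H labels per molecule at the observed position.
#' @param loss fraction of label lost en route to the observed pool.
#' @return effective labels per molecule.
#' @export
label_stoichiometry <- function(n_labels, loss) {
  stopifnot(n_labels > 0, loss >= 0, loss < 1)
  n_labels * (1 - loss)
}

#' Moles of glucose in an administered dose
#' @param mass_mg dose mass, mg.
#' @param mw molar mass, g/mol (anhydrous glucose).
#' @return amount, mol.
#' @export
glucose_dose_moles <- function(mass_mg, mw = 180.16) {
  stopifnot(mass_mg >= 0, mw > 0)
  mass_mg / 1000 / mw
}
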