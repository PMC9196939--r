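---
title: "Methods: quantitative MRI relaxometry and deuterium metabolic spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative MRI relaxometry and deuterium metabolic spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmridmi)
```

## The problem this package addresses

After radiotherapy for malignant brain tumors, anatomic MRI cannot reliably
tell recurrent tumor from radiation necrosis (RN) — delayed radiation injury
that mimics tumor on contrast-enhanced images. Two complementary
quantitative approaches address this: a multi-contrast proton MRI pipeline
(R1, R2, ADC, MTR, and semi-quantitative DCE AUC parametric maps, compared
over lesion ROIs), and deuterium (²H) MR spectroscopy after administration
of ²H-labeled glucose, where the ratio of glutamate+glutamine (Glx, the
oxidative fate) to lactate (Lac, the glycolytic fate) reads out the Warburg
effect: tumors ferment glucose to lactate even in the presence of oxygen,
so tumor tissue shows high Lac and Glx:Lac well below one, while normal
brain and RN favor oxidative metabolism and Glx:Lac above one.

`qmridmi` implements both analysis chains and a digital mouse-brain phantom
generator, so every stage can be exercised end to end — forward simulation
with known truth, inversion, and statistics — without any acquired data.

## Image signal models and their fits

All fits act voxel-wise on 4-D stacks (x, y, slice, acquisition setting).

**R1 (variable flip angle).** Spoiled gradient echo:
$$S(\theta) = S_B\,(1 - E)\,\sin\theta \,/\, (1 - E\cos\theta),
\qquad E = e^{-TR \cdot R_1}.$$
The fit is full nonlinear least squares in $(S_B, R_1)$, initialized by the
linearized (DESPOT1-style) regression of $S/\sin\theta$ on $S/\tan\theta$,
refined by a Levenberg–Marquardt iteration run simultaneously over all
masked voxels (batched 2×2 normal equations). Flip angles are taken as
nominal: no B1 correction is applied, which matches how the VFA method is
commonly run; the known consequence is that VFA R1 in tissue with a large
magnetization-transfer effect overestimates inversion-recovery R1 (roughly
1.8× in the literature). This confound is documented, not modeled.

**R2 (multi-echo spin echo).** $S(TE) = S(0)\,e^{-TE \cdot R_2} + C$, a
3-parameter fit including the additive constant $C$ (noise floor /
long-T2 offset). Omitting $C$ biases R2 low when an offset is present; the
test suite demonstrates this with a 2-parameter log-linear comparison fit.
At least 4 echoes are required (3 free parameters). Voxels with vanishing
decay amplitude or R2 are flagged degenerate rather than reported silently.

**ADC (tensor trace).** For each volume the full b-matrix (s/mm²) is an
input — it accounts for the diffusion weighting of imaging gradients and is
never recomputed from gradient shapes. The fit is per-voxel weighted
log-linear least squares of $\ln S = \ln S_0 - \sum_{ij} b_{ij} D_{ij}$
over the six unique tensor elements (weights $S^2$, the standard
first-order correction for log-transformed noise), and
$ADC = \mathrm{tr}(D)/3$ in µm²/ms (b in s/mm², conversion factor $10^{-3}$
handled internally and unit-tested). Encoding sets whose design matrix is
rank-deficient raise an error; fitted tensors failing the Sylvester
positive-semi-definiteness test are flagged.

**MTR.** $MTR = 100\,(OFF - ON)/OFF$ percent, with voxels below an OFF
signal threshold masked and out-of-range values flagged, never clipped
silently.

**DCE AUC.** Signal is expressed as fractional enhancement against the mean
of the 30 pre-contrast frames, normalized by the maximum over frames
31–120 of the *muscle-ROI-mean* enhancement curve, then summed over the 270
post-injection frames and divided by 810 s (3 s/frame × 270 frames). The
normalizer deliberately averages the muscle ROI first and takes the
maximum second; the alternative (per-voxel maxima, then mean) inflates the
factor whenever voxel peaks do not align in time and was rejected — a test
contrasts the two readings. The injection frame is fixed at 30 (so 270
post-injection frames out of 300) to match the printed arithmetic;
both the frame windows and the injection frame are configuration-exposed.

**Preprocessing.** In-plane Gaussian smoothing with σ = 0.75 voxels is the
standard display/fit preprocessing. It is implemented as a truncated
separable discrete kernel (radius ⌈4σ⌉) with replicate-edge padding, so
constant regions are exactly invariant and no signal wraps across image
edges. Because it is not stated whether smoothing should precede every fit
or only map display, smoothing is optional per stage (`preprocess()`),
applied by default in the orchestrated pipeline and logged in provenance;
the recovery tests run unsmoothed so that round-trip identities are exact.

**Masking and failure handling.** Background voxels (mean signal below 5×
a robust noise-floor estimate; multiplier exposed) are excluded before
fitting. Non-convergent voxels are masked and counted in the fit report —
never interpolated. Every map carries values, per-voxel uncertainty (from
the Gauss–Newton covariance), the fitted-voxel mask, and flags.

## ²H spectral model and quantification

Each 10-minute signal block's FID is modeled in the time domain as a sum of
exponentially decaying sinusoids (Lorentzian lineshape only — no Voigt,
matching the stated model):
$$y(t) = \sum_k A_k \, e^{-R^*_{2,k} t}\, e^{i(2\pi f_k t + \phi)}.$$
Across the blocks of one time course, each resonance's frequency and
$R^*_2$ and the global phase $\phi$ are shared; amplitudes are free per
block. The fit is separable (variable-projection) nonlinear least squares:
at each Levenberg–Marquardt step over the nonlinear parameters, the
per-block real amplitudes are solved exactly by linear least squares on the
real-stacked data. Parameter uncertainties are taken from the Gauss–Newton
covariance of the full parameter set at the optimum — a Laplace
approximation standing in for posterior SDs of a fully Bayesian treatment;
on well-conditioned data the point estimates coincide, and the test suite
verifies the variable-projection solution against a brute-force
all-parameters-free fit to ≤ 10⁻⁶. The fit starts at the first acquired
complex point with no first-point scaling correction. Resonance pairs
closer than half a mean linewidth are flagged as near-degenerate with a
warning.

Quantification proceeds in three explicit steps:

1. **Stoichiometry and relaxation correction.**
   $A^{corr} = A / [s \cdot (1 - e^{-TR/T_1}) \cdot e^{-TE/T_2}]$ with
   effective label stoichiometries HOD 1, Glc 2, Lac 1.7 (two labels, 15%
   loss), Glx 1.2 (two labels, 40% loss). The saturation factor assumes
   ideal 90° excitation per repetition (adiabatic pulses). The default
   T1/T2 values (HOD 320/30 ms, Glc 64/32 ms, Lac 297/61 ms, Glx
   146/40 ms) are literature-informed defaults, configuration-exposed,
   and should be treated as assumptions rather than measured values.
2. **Internal referencing.** The mean corrected HOD amplitude over the
   pre-infusion blocks corresponds to the natural-abundance HOD
   concentration (default 16.35 mM); all metabolite amplitudes scale
   accordingly, with first-order error propagation that includes the
   reference uncertainty. Negative point estimates are retained in a raw
   column and floored only in the reported concentration column, so
   downstream ratios are not biased by one-sided truncation.
3. **Warburg readout.** Per-block Glx:Lac with propagated SD; blocks whose
   lactate estimate is consistent with zero (below twice its SD) are
   flagged undefined rather than reported as unstable ratios.

Two calibration utilities anchor the reference concentration: the
mole-fraction conversion $c = x \cdot 10^{-6} \cdot 111{,}100$ mM (water
being 111.1 M in equivalent ¹H), and the standard-addition estimator
(ordinary least squares of amplitude on added HOD; the analyte
concentration is the x-intercept magnitude $a/b$ with a delta-method SE),
which is exactly unbiased on noiseless linear data.

## The phantom generator

The generator is the study's ground truth, not a tuning dial.

* **Geometry.** 2-D multislice: a 64×64 in-plane matrix over a 16×16 mm²
  FOV and 21 × 0.5 mm slices by default; an elliptical brain, a muscle
  band outside it (the DCE normalization reference), and a left-hemisphere
  lesion on the central slices — a single tumor or RN disc for the pure
  cohorts, two disjoint discs for the mixed cohort, none for controls.
  Through-plane partial volume is not modeled.
* **Tissue truth.** Lesion presets carry the reference cohort-mean values
  (tumor R1 1.08 s⁻¹, R2 14.9 s⁻¹, ADC 0.833 µm²/ms, MTR 24.1%, AUC
  0.916 au; RN 1.26, 17.6, 0.736, 30.2%, 0.784 au). Cortex and muscle have
  no reference values and use literature-informed defaults. DCE curves are
  an onset step at frame 31 with mono-exponential uptake and optional
  washout; lesion amplitudes are derived so that each tissue's
  muscle-normalized per-second AUC equals its preset value exactly.
* **Noise.** Rician on ¹H magnitude images (magnitude reconstruction);
  circular complex Gaussian on ²H FIDs (raw acquisition). Tests verify the
  Rician floor mean σ√(π/2) at zero signal and vanishing bias at high SNR.
* **²H kinetics.** Per-resonance saturating-exponential concentration
  curves with onset at the infusion (20 min; two 10-min pre-infusion
  blocks). Plateau magnitudes are design choices reproducing the
  qualitative cohort ordering — tumor Lac high / Glx low, control the
  opposite, RN close to control — since no absolute tissue concentrations
  are specified; they are configuration-exposed. Chemical shifts default to
  HOD 4.8, Glc 3.8, Glx 2.4, Lac 1.3 ppm at 76.65 MHz (literature
  conventions). Between-subject variability is a 10% log-normal CV on
  metabolite plateaus; FID noise SD defaults to 0.05 amplitude units per
  complex channel, chosen so a single 10-min block resolves lactate at a
  few percent — plausible for heavily signal-averaged blocks.
* **Determinism.** A fixed seed makes label maps, stacks and FIDs
  bit-identical; different seeds change only the noise stream.

What passing tests on this phantom do *not* show: robustness to B0/B1
inhomogeneity, surface-coil sensitivity profiles, motion, Gibbs ringing
(un-ringing is out of scope), chemical exchange, partial volume, or
lineshape distortions — none of these are simulated, so real-data
performance is a separate question. The inverse-crime structure (the
fitting model equals the generating model) is intentional: it isolates
implementation correctness from model adequacy.

## Statistics

ROI summaries are mean and SD (n−1) over fitted voxels only. Cohort
contrasts use two-tailed t-tests — Welch by default, since equal variances
are not guaranteed across lesion types; the pooled-variance variant is
available by flag and is the closer analog of least-squares-means contrasts
from a pooled-error ANOVA, which is why the cohort-separation checks on the
²H terminal blocks use it. Within the mixed cohort, tumor vs RN is a paired
test. Families of p-values (one parameter across its cohort contrasts,
mirroring the comparison table's rows) are adjusted by the Holm step-down
procedure (the standard reading of "step-down Bonferroni"). Degenerate
inputs follow explicit conventions: zero variance with equal means gives
p = 1, constant nonzero differences give p → 0, both flagged. Across-subject
SD of ROI means (not pooled voxel SD) is what the summary tables report.

The two-way repeated-measures ANOVA with least-squares-means post-hoc used
for the original time-course analysis is out of scope; the cohort
separation is asserted through the t-test machinery on terminal blocks and
through generator-ordering invariants instead.

## Numerical choices

* Levenberg–Marquardt: damping per voxel (start 10⁻³, ÷3 on acceptance,
  ×7 on rejection), convergence on relative SSE change ≤ 10⁻¹²,
  parameter clamps keep R1, R2 and amplitudes physical.
* Variable projection: bounds keep frequencies inside the acquisition
  bandwidth and decay rates positive; starting frequencies come from the
  nominal chemical shifts, starting R2* of 40 s⁻¹ spans in-vivo
  linewidths.
* The amplitude-sign/phase ambiguity ($A, \phi$) vs ($-A, \phi+\pi$) is
  resolved by convention: the dominant resonance's mean amplitude is made
  positive.
* Problem sizes in tests and scripts are chosen to keep the default runs
  fast while preserving the study conditions that matter: full 64×64×21
  members are used where ROI-level bias is the claim; slice counts are
  reduced where presets are slice-invariant and nothing is lost; the
  replicate ²H study uses n = 4 subjects per cohort and 11 blocks,
  matching the study design.

## Known limitations

* VFA R1 carries the MT-effect overestimation by construction (no B1/MT
  correction).
* The Laplace SDs understate uncertainty when the residual surface is
  non-quadratic (e.g., near-degenerate resonances); an optional residual
  bootstrap can be layered on, but the package reports covariance SDs.
* T1/T2 correction constants are assumptions; absolute concentrations
  inherit their error in proportion to the correction-factor ratio.
* The phantom's DCE curve family is parametric and smooth; real
  arterial-input variability, dispersion, and T1-based nonlinearity of the
  signal–concentration relation are not modeled (no pharmacokinetic
  modeling is attempted anywhere).
* HOD concentration is modeled as constant over the experiment; in vivo,
  metabolism of labeled glucose slowly raises tissue HOD, which would bias
  late-block references if pre-infusion referencing were not used.
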