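# qmridmi

Quantitative MRI relaxometry and deuterium (²H) metabolic spectroscopy for
distinguishing brain tumor from radiation necrosis — implemented as a fully
synthetic, testable analysis pipeline.

## The problem

Radiation necrosis (RN), a delayed injury of irradiated brain, mimics
recurrent tumor on anatomic MRI. Two quantitative approaches can separate
them:

1. **Multi-contrast ¹H MRI**: voxel-wise parametric maps of
   - R1 from a variable-flip-angle gradient-echo series,
     `S(θ) = S_B (1 − E) sinθ / (1 − E cosθ)`, `E = exp(−TR·R1)`;
   - R2 from a multi-echo spin-echo series,
     `S(TE) = S(0) exp(−TE·R2) + C`;
   - ADC as `trace(D)/3` from a 6-direction diffusion acquisition with
     supplied b-matrices, `S(b) = S(0) exp(−Σ b_ij D_ij)`;
   - MTR as `100·(OFF − ON)/OFF` from a magnetization-transfer pair;
   - semi-quantitative DCE AUC: fractional enhancement over a 30-frame
     baseline, normalized by peak early muscle enhancement, summed over
     270 post-injection frames and divided by 810 s;

   followed by ROI statistics (Welch/paired t-tests, Holm step-down
   adjustment) across tumor, RN, and mixed-lesion cohorts.

2. **²H MRS of deuterated glucose**: block-wise FIDs fit in the time domain
   as sums of exponentially decaying sinusoids (shared frequencies/R2*,
   per-block amplitudes, variable-projection least squares), corrected for
   labeling stoichiometry (Lac 1.7, Glx 1.2) and relaxation, and converted
   to absolute mM via the natural-abundance semiheavy-water (HOD) internal
   reference (16.35 mM, anchored by a standard-addition calibration). The
   terminal Glx:Lac ratio reads out the Warburg effect: `< 1` in tumor,
   `> 1` in normal brain and RN.

A digital mouse-brain phantom generator produces every input the pipeline
consumes — multi-contrast image stacks with tissue ground truth, DCE
enhancement curves, ²H FID series with prescribed metabolite kinetics, and
titration series — so each stage is verified by exact round trips and
Monte-Carlo bias checks. The intended audience is researchers building or
validating quantitative MRI / deuterium metabolic imaging (DMI) analysis
chains.

## Worked example

Simulate a pure-tumor phantom, recover its maps, and run the ²H arm:

```r
library(qmridmi)

ph  <- build_label_map(64, 21, layout = "tumor")
mtr <- compute_mtr(simulate_stack(ph, acq_mt()))
summarize_roi(mtr, ph$masks$tumor, cohort = "tumor", roi = "tumor")
#>   subject cohort   roi param mean sd n_voxels n_excluded
#> 1      NA  tumor tumor   MTR 24.1  0     1705          0

fids  <- simulate_fid_series(dmrs_kinetics("tumor"), acq_dmrs(),
                             n_blocks = 11, noise_sd = 0.05, seed = 501)
model <- fit_fid_series(fids, default_spectral_init(acq_dmrs()))
tc    <- to_concentrations(model, quant_config(), pre_blocks = 1:2)
subset(tc, block == 11 & metabolite %in% c("Glx", "Lac"))
#>    block time_min metabolite   conc_mM  conc_raw      sd_mM
#> 33    11      105        Glx 0.7928793 0.7928793 0.01462421
#> 44    11      105        Lac 3.0038729 3.0038729 0.01181723
glx_lac_timecourse(tc)$ratio[11]
#> [1] 0.2639523
```

The MTR ROI mean returns the tumor preset (24.1%) exactly on noiseless
data; the terminal-block concentrations show the tumor phenotype — lactate
(~3 mM here) far above Glx, hence Glx:Lac ≈ 0.26, the aerobic-glycolysis
signature. A control-preset run gives the opposite ordering (ratio ≈ 3).

The numbered scripts under `analysis/` walk the whole study: `01` simulates
cohort inputs (NIfTI + JSON sidecars, FID containers, ground-truth CSVs),
`02` verifies parametric-map recovery (noiseless to machine precision;
ROI-mean bias ≤ 2% under Rician noise at SNR 50), `03` runs the DCE chain,
`04` produces the cohort summary and Holm-adjusted p-value tables, and `05`
runs the standard-addition calibration and the ²H cohort study. Each writes
its tables under `results/`.

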