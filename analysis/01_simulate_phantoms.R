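#!/usr/bin/env Rscript
# Simulate the digital-phantom study inputs: one multi-contrast cohort
# member per layout (pure tumor, pure radiation necrosis, mixed, control),
# with ground-truth sidecars, plus a 2H FID block series per metabolic
# cohort. Everything downstream (02-05) regenerates what it needs from the
# package, so this script's role is to materialize example inputs on disk
# and document the containers.

library(qmridmi)

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (layout in c("tumor", "rn", "mixed", "control")) {
  ph <- build_label_map(64, 21, layout = layout,
                        noise = list(model = "rician", sd = 1 / 50),
                        seed = 100 + match(layout,
                                           c("tumor", "rn", "mixed",
                                             "control")))
  write_ground_truth(ph, file.path(out, layout))
  st <- simulate_stack(ph, acq_vfa())
  write_image_stack(st, file.path(out, paste0(layout, "_vfa")))
  message(sprintf("%-8s labels: %s voxels lesioned", layout,
                  sum(ph$label_map %in% c(2L, 3L))))
}

for (cohort in c("control", "tumor", "rn")) {
  fids <- simulate_fid_series(dmrs_kinetics(cohort), acq_dmrs(),
                              n_blocks = 11, noise_sd = 0.05,
                              seed = 200 + match(cohort,
                                                 c("control", "tumor",
                                                   "rn")))
  write_fid_series(fids, file.path(out, paste0("fids_", cohort, ".json")))
}
message("wrote image stacks, ground truth, and FID containers to ", out)
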