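#!/usr/bin/env Rscript
# Generate the synthetic study datasets for all four assays.
#
# Four genotype cohorts (DmCRY positive control, diurnal AeCRY1, nocturnal
# AgCRY1, cry_null negative control) are simulated and written in the same
# on-disk formats a real study would arrive in: a DAM-style monitor file for
# locomotor activity, a two-environment choice table, and an ROI
# fluorescence table, each with a JSON ground-truth sidecar recording the
# latent parameters (so later stages can be read as parameter-recovery
# exercises).  Voltage recordings are large and are re-simulated from seed
# in 03_ephys.R instead of being stored.

library(crylight)

seed <- 20240101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
presets <- default_presets()

# locomotor: 8 flies per genotype, 4 d LD + 5 d DD, one monitor per genotype
for (gi in seq_along(presets)) {
  p <- presets[[gi]]
  coh <- simulate_locomotor(p, n_flies = 8, days_ld = 4, days_dd = 5,
                            lux = 400, seed = seed + gi)
  write_dam(coh, file.path(out, sprintf("dam_%s.txt", p$name)))
  write_ground_truth(attr(coh, "ground_truth"),
                     file.path(out, sprintf("dam_%s.truth.json", p$name)))
  message(sprintf("locomotor %-8s: %d flies x %d bins", p$name, length(coh),
                  length(coh[[1]]$counts)))
}

# choice: 20 flies per genotype, 30 min at low-intensity blue light
for (gi in seq_along(presets)) {
  p <- presets[[gi]]
  coh <- simulate_choice(p, n_flies = 20, minutes = 30, seed = seed + 100 + gi,
                         wavelength_nm = 450, intensity_uw_cm2 = 10)
  write_choice_table(coh, file.path(out, sprintf("choice_%s.tsv", p$name)))
  write_ground_truth(attr(coh, "ground_truth"),
                     file.path(out, sprintf("choice_%s.truth.json", p$name)))
  message(sprintf("choice    %-8s: mean p_lit %.2f", p$name,
                  mean(attr(coh, "ground_truth")$p_lit)))
}

# ICC: 3 brains x 4 neurons per genotype at each measured ZT point
roi <- do.call(rbind, unlist(lapply(seq_along(presets), function(gi) {
  lapply(c(5, 11, 17, 23), function(z)
    simulate_roi(presets[[gi]], n_brains = 3, neurons_per_brain = 4,
                 zt = z, seed = seed + 200 + 10 * gi + z))
}), recursive = FALSE))
write_roi_table(roi, file.path(out, "roi_all.tsv"))
message(sprintf("icc       : %d neuron rows over %d genotypes x 4 ZT points",
                nrow(roi), length(presets)))

message("fixtures written under ", out)
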