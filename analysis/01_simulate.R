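#!/usr/bin/env Rscript
# Generate one example dataset per condition: three-channel filament scenes
# (16-bit TIFFs), single-fluorophore calibration scenes, and FRAP trace CSVs.
# Everything downstream (02-05) can be re-derived from these files or directly
# from the presets; this script exists to show the raw data the study works
# on and to exercise the disk formats.

suppressPackageStartupMessages(library(cstquant))

seed <- 1L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating condition scenes (256 x 256 px, one cell each) ...")
for (cond in c("CST-untreated", "CST-P301L")) {
  sc <- generate_filament_scene(cst_preset(cond), derive_seed(seed, cond))
  paths <- write_image_set(sc$images, out, cond)
  message(sprintf("  %s: on-filament truth NFRET %.1f, %d filament px -> %s",
                  cond, cst_preset(cond)$nfret_filament,
                  sum(sc$truth$filament_mask), paths[1]))
}

message("Simulating single-fluorophore calibration scenes ...")
bt <- cst_preset("paper-typical-bleedthrough")
for (kind in c("donor-only", "acceptor-only")) {
  cal <- generate_calibration_scene(kind, bt, derive_seed(seed, kind))
  write_image_set(cal, out, paste0("calib-", kind))
}
message(sprintf("  true leak fractions: A = %.2f (donor), B = %.2f (acceptor)",
                bt$bleed_A, bt$bleed_B))

message("Simulating FRAP traces (10 pre + 120 post frames at 1 s) ...")
for (cond in c("CST-untreated", "CST-nocodazole", "CST-P301L", "CST-AT8mut")) {
  series <- generate_frap_series(cst_preset(cond),
                                 derive_seed(seed, paste0("frap-", cond)),
                                 n_traces = 3)
  for (i in seq_along(series))
    write_frap_trace(series[[i]]$trace,
                     file.path(out, sprintf("frap_%s_%02d.csv", cond, i)))
  p <- cst_preset(cond)
  message(sprintf("  %s: truth Mob %.2f (A1* %.3f @ %.1fs, A2* %.3f @ %.1fs)",
                  cond, sum(p$frap_fractions), p$frap_fractions[1],
                  p$frap_taus[1], p$frap_fractions[2], p$frap_taus[2]))
}
message("Done; files under ", out)
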