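#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses consume --
# pore-water tracer profiles under the published transport parameters, the
# seawater-brine interface halocline, and negative-mode DOM peak lists --
# and write them as delimited text under results/synthetic/.

suppressPackageStartupMessages(library(brinetrace))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("== simulating study inputs (seed ", seed, ") ==")

# Pore-water profiles: a 3.2-m core sampled every 0.2 m, 2% relative noise
# for the ions, 0.5 permil absolute for deuterium.
presets <- c("hephaestus_mg", "hephaestus_cl", "hephaestus_dD", "discovery_cl")
for (k in seq_along(presets)) {
  prof <- make_pore_profile(presets[k], seed = seed + k)
  path <- file.path(out_dir, paste0(presets[k], ".csv"))
  write_tracer_profile(prof, path)
  message(sprintf("  %-14s t = %.3g s (%.0f yr)  %d depths -> %s",
                  presets[k], attr(prof, "truth")$t,
                  seconds_to_years(attr(prof, "truth")$t), nrow(prof), path))
}

# Interface halocline: sigmoidal Mg gradient 70 -> 4,720 mM over 3 m.
iface <- make_interface_profile(n = 61, shape = "logistic",
                                noise = noise_spec(sigma = 0))
write_tracer_profile(iface, file.path(out_dir, "interface_mg.csv"))
message(sprintf("  interface      Mg %0.f -> %.0f mM over %.1f m (%d samples)",
                min(iface$value), max(iface$value), max(iface$depth_m),
                nrow(iface)))

# DOM pools: a brine pool and an interface pool sharing a third of their
# formulas, ionized as [M-H]- with calibration-level (0.1 ppm) mass error.
pool <- synthetic_dom_formulas(300, seed = seed + 10)
brine_fs <- pool[1:200, ]
iface_fs <- pool[101:300, ]
for (nm in c("brine", "interface")) {
  fs <- if (nm == "brine") brine_fs else iface_fs
  pk <- make_peak_list(fs, ppm_jitter = 0.1, seed = seed + 20 +
                         (nm == "interface"))
  write_peak_list(pk, file.path(out_dir, paste0("dom_", nm, ".tsv")))
  truth <- attr(pk, "truth")
  write.csv(truth, file.path(out_dir, paste0("dom_", nm, "_truth.csv")),
            row.names = FALSE)
  message(sprintf("  dom_%-10s %d peaks, %.0f-%.0f u", nm, nrow(pk),
                  min(truth$neutral_mass), max(truth$neutral_mass)))
}
message("done.")
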