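#!/usr/bin/env Rscript
# Stage 3: map the Mg2+ / water-activity structure of the seawater-brine
# interface. Fits the monotone activity curve through the measured anchors,
# assigns each halocline sample to its named layer, locates the recognized
# water-activity limit for cell division (a_w = 0.585), and classifies
# habitability against both criteria. Writes results/interface.csv.

suppressPackageStartupMessages(library(brinetrace))

in_path <- "results/synthetic/interface_mg.csv"
if (!file.exists(in_path)) stop("run analysis/01_simulate_profiles.R first")
prof <- read_tracer_profile(in_path)

message("== interface habitability ==")
curve <- fit_activity_curve(hephaestus_anchors())
message(sprintf("  activity curve: %d anchors, a_w %.3f (seawater) -> %.3f (brine)",
                nrow(curve$anchors), max(curve$anchors$aw),
                min(curve$anchors$aw)))

hit <- locate_threshold_depth(prof, curve, aw_threshold = 0.585)
message(sprintf("  a_w = 0.585 crossing: %s at %.2f m of the %.1f-m interface",
                hit$status, hit$depth_m, max(prof$depth_m)))

layers <- assign_layer(prof$value)
hab <- lapply(prof$value, function(m) classify_habitability(m, curve))
tab <- data.frame(depth_m = prof$depth_m,
                  mg_mM = prof$value,
                  layer = layers,
                  aw = vapply(hab, `[[`, numeric(1), "aw"),
                  status = vapply(hab, `[[`, character(1), "status"))

for (ly in c("SEAWATER", "UIF", "GAP", "MIF", "LIF", "BRINE")) {
  n <- sum(tab$layer == ly)
  if (n > 0)
    message(sprintf("  %-9s %2d samples, a_w %.3f-%.3f, %s", ly, n,
                    min(tab$aw[tab$layer == ly]), max(tab$aw[tab$layer == ly]),
                    paste(unique(tab$status[tab$layer == ly]), collapse = "/")))
}

deepest_active <- max(tab$depth_m[tab$status == "active-window"])
message(sprintf("  deepest active-window sample: %.2f m (%.0f mM Mg2+)",
                deepest_active, tab$mg_mM[tab$depth_m == deepest_active]))

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/interface.csv", row.names = FALSE)
message("wrote results/interface.csv")
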