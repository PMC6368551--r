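#!/usr/bin/env Rscript
# Stage 4: CHNOS characterization of the dissolved organic matter. Assigns
# molecular formulas to the synthetic brine and interface peak lists,
# summarizes compound classes, van Krevelen structure, sulfur counts and
# the between-sample unique fraction, and checks assignment accuracy
# against the generators' ground truth. Writes results/dom_*.csv.

suppressPackageStartupMessages(library(brinetrace))

in_dir <- "results/synthetic"
if (!file.exists(file.path(in_dir, "dom_brine.tsv")))
  stop("run analysis/01_simulate_profiles.R first")

message("== DOM molecular formulas ==")
bounds <- element_bounds(ppm_tol = 1)
assigned <- list()
for (nm in c("brine", "interface")) {
  pk <- read_peak_list(file.path(in_dir, paste0("dom_", nm, ".tsv")))
  asg <- assign_formulas(pk, bounds)
  assigned[[nm]] <- asg
  truth <- read.csv(file.path(in_dir, paste0("dom_", nm, "_truth.csv")))
  idx <- match(round(asg$mz, 9), round(pk$mz, 9))
  ok <- vapply(seq_len(nrow(asg)), function(i)
    all(asg[i, c("nC", "nH", "nN", "nO", "nS")] ==
          truth[idx[i], c("nC", "nH", "nN", "nO", "nS")]), logical(1))
  counts <- table(asg$cls)
  r1 <- class_ratio(asg, "CHOS", "CHO")
  r2 <- class_ratio(asg, "CHNOS", "CHNO")
  vk <- van_krevelen(asg)
  message(sprintf("  %-9s %d/%d peaks assigned, %.1f%% top-rank correct",
                  nm, nrow(asg), nrow(pk), 100 * mean(ok)))
  message(sprintf("            classes %s", paste(names(counts), counts,
                                                  sep = "=", collapse = " ")))
  message(sprintf("            CHOS/CHO %.2f  CHNOS/CHNO %.2f  O/C>0.6: %.1f%%",
                  r1$ratio, r2$ratio, 100 * mean(vk$highly_oxygenated)))
  sh <- sulfur_histogram(asg)
  message(sprintf("            S counts: %s",
                  paste(names(sh), sh, sep = "x", collapse = " ")))
  write.csv(as.data.frame(asg), sprintf("results/dom_%s_assignments.csv", nm),
            row.names = FALSE)
}

u <- unique_shared_fraction(assigned$brine, assigned$interface)
message(sprintf("  brine vs interface: %.0f%% of the %d-formula union unique to one sample",
                u$pct_unique, u$n_union))

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(comparison = "brine_vs_interface",
                     pct_unique = u$pct_unique, pct_shared = u$pct_shared,
                     n_union = u$n_union, n_shared = u$n_shared),
          "results/dom_comparison.csv", row.names = FALSE)
message("wrote results/dom_*_assignments.csv, results/dom_comparison.csv")
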