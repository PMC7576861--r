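#!/usr/bin/env Rscript

# Step 3 — the study's statistical comparisons.
#
# Reads the cohort analysis from step 2 and reproduces the statistical
# layout of the study: normality-gated paired before/after comparisons per
# maneuver (GI, dependent and non-dependent regional compliance, global
# compliance, EELI; Bonferroni m = 3 within each metric family) and the
# pairwise delta-GI contrasts between maneuvers. Outputs:
#   results/before_after.csv    Table-1-style before/after/p block
#   results/delta_gi_contrasts.csv

library(eitrm)

res <- tibble::as_tibble(utils::read.csv("results/cohort_results.csv"))
dg <- tibble::as_tibble(utils::read.csv("results/delta_gi.csv"))

ba <- maneuver_before_after(res)
utils::write.csv(ba, "results/before_after.csv", row.names = FALSE)

message("before/after comparisons:")
for (i in seq_len(nrow(ba)))
  message(sprintf("  %-4s %-18s %6.3f +/- %5.3f -> %6.3f +/- %5.3f  p_adj %.4g (%s)",
                  ba$maneuver[i], ba$metric[i],
                  ba$before_mean[i], ba$before_sd[i],
                  ba$after_mean[i], ba$after_sd[i],
                  ba$p_adjusted[i], ba$method[i]))

cmp <- compare_maneuver_deltas(dg)
tab <- attr(cmp, "table")
utils::write.csv(tab, "results/delta_gi_contrasts.csv", row.names = FALSE)

message("delta-GI contrasts:")
for (i in seq_len(nrow(tab)))
  message(sprintf("  %-9s effect %+.4f  p %.4g  p_adj %.4g (%s)",
                  tab$contrast[i], tab$effect[i], tab$p_raw[i],
                  tab$p_adjusted[i], tab$method[i]))
message("wrote results/before_after.csv and results/delta_gi_contrasts.csv")
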