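#!/usr/bin/env Rscript

# Step 1 — simulate the study cohort.
#
# Ten supine ARDS phantoms undergo the three recruitment maneuvers
# (sustained inflation, incremental PEEP, PCV) in randomized order, with
# EIT + airway pressure recorded before and after each maneuver. This
# driver materializes one example recording pair as an on-disk EIT bundle
# (with its ground truth) for inspection, and writes the cohort's maneuver
# order table. The full cohort is re-simulated in-memory by step 2; frames
# for all 60 recordings are deliberately not written to disk.

library(eitrm)

seed <- 1L
dir.create("results/bundles", recursive = TRUE, showWarnings = FALSE)

message("simulating example subject (pig01), IP maneuver ...")
cfg <- ards_phantom_config(seed = 42L)
ph <- make_phantom(cfg)
ph <- withr::with_seed(seed, {
  ph <- ards_induction(ph)
  equilibrate(ph, baseline_program(duration = 60), 40)
})
trace <- pressure_waveform(baseline_program(duration = 60), 40)

pre <- withr::with_seed(seed + 1L,
  simulate_sequence(ph, trace, subject_id = "pig01",
                    recording_label = "pre_IP"))
ph2 <- withr::with_seed(seed + 2L, {
  ph2 <- equilibrate(pre$phantom, ip_program(), 40)
  equilibrate(ph2, baseline_program(duration = 5), 40)
})
post <- withr::with_seed(seed + 3L,
  simulate_sequence(ph2, trace, subject_id = "pig01",
                    recording_label = "post_IP"))

write_bundle(pre$sequence, trace, "results/bundles/pig01_pre_IP")
write_bundle(post$sequence, trace, "results/bundles/pig01_post_IP")

# ground truth alongside: per-frame ROI open fractions and pixel parameters
for (nm in c("pre", "post")) {
  sim <- get(nm)
  ofr <- as.data.frame(sim$truth$open_fraction_by_roi)
  names(ofr) <- paste0("open_frac_ROI", 1:4)
  ofr$frame <- seq_len(nrow(ofr))
  utils::write.csv(ofr[, c("frame", paste0("open_frac_ROI", 1:4))],
                   sprintf("results/bundles/pig01_%s_IP/truth.csv", nm),
                   row.names = FALSE)
}
utils::write.csv(phantom_pixels(ph),
                 "results/bundles/pig01_pre_IP/truth_pixels.csv",
                 row.names = FALSE)

message("dependent-region open fraction: pre ",
        round(mean(pre$truth$open_fraction_by_roi[1, 3:4]), 3),
        " -> post ",
        round(mean(post$truth$open_fraction_by_roi[1, 3:4]), 3))

message("drawing cohort maneuver order table (seed ", seed, ") ...")
orders <- withr::with_seed(seed, {
  invisible(sample.int(2^31 - 2, 10))          # subject seeds drawn first
  maneuver_orders(10)
})
order_tbl <- do.call(rbind, lapply(seq_along(orders), function(s)
  data.frame(subject = sprintf("pig%02d", s), position = 1:3,
             maneuver = orders[[s]])))
utils::write.csv(order_tbl, "results/maneuver_order.csv", row.names = FALSE)
message("wrote results/bundles/ and results/maneuver_order.csv")
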