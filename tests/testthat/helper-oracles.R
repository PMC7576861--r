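# Brute-force GI oracle: explicit per-pixel loop, independent of the
# vectorized implementation. Median of an even-sized set = midpoint mean.
gi_index_loop <- function(di, mask = rep(TRUE, length(di))) {
  vals <- c()
  for (k in seq_along(di)) if (mask[k]) vals <- c(vals, di[k])
  sv <- sort(vals)
  nn <- length(sv)
  med <- if (nn %% 2 == 1) sv[(nn + 1) / 2] else
    (sv[nn / 2] + sv[nn / 2 + 1]) / 2
  num <- 0; den <- 0
  for (v in vals) {
    num <- num + abs(v - med)
    den <- den + v
  }
  num / den
}

# small, fast ARDS phantom brought to the collapsed pre-maneuver state
induced_test_phantom <- function(seed = 1, grid = 16) {
  cfg <- ards_phantom_config(grid_rows = grid, grid_cols = grid, seed = seed)
  ph <- make_phantom(cfg)
  ards_induction(ph, duration = 60, closing_multiplier = 100,
                 stabilize_s = 300)
}

# compressed cohort settings for pipeline-level tests
compressed_cohort <- function(n_subjects = 2, seed = 1, ...) {
  simulate_cohort(
    n_subjects = n_subjects, seed = seed,
    config = ards_phantom_config(grid_rows = 16, grid_cols = 16),
    recording_s = 12, sample_rate = 20,
    baseline = baseline_program(duration = 12),
    maneuvers = list(SI = si_program(),
                     IP = ip_program(),
                     PCV = pcv_program(duration = 60)),
    equilibration_s = 20, post_settle_s = 2, washout_s = 120,
    induction_s = 60, induction_multiplier = 100, ...)
}
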