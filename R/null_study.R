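#' Type-I error calibration under a no-recruitment null
#'
#' Freezes the recruitment dynamics (`opening_rate = closing_rate = 0`) so
#' that the pre and post recordings of every simulated subject differ only
#' by measurement noise, runs the GI pipeline on both, applies the
#' normality-gated paired comparison across subjects, and reports the
#' fraction of replicates rejecting at `alpha`. A calibrated pipeline
#' rejects in about `alpha` of replicates.
#'
#' The study is run at a reduced problem size (small grid, short
#' recordings, modest frame rate) so a thousand replicates complete in
#' minutes; the null property does not depend on scale.
#'
#' @param n_replicates number of simulated experiments.
#' @param n_subjects subjects per experiment.
#' @param seed master seed.
#' @param alpha rejection level.
#' @param grid grid side length.
#' @param sample_rate frames/s.
#' @param recording_s recording length (s).
#' @param settle_s lag-settling interval before each recording (s).
#' @return list with `rate` (rejection fraction), `n_replicates`,
#'   `p_values`.
#' @export
null_rejection_rate <- function(n_replicates = 1000, n_subjects = 10,
                                seed = 1, alpha = 0.05, grid = 16,
                                sample_rate = 10, recording_s = 10,
                                settle_s = 1) {
  cfg <- phantom_config(grid_rows = grid, grid_cols = grid,
                        opening_rate = 0, closing_rate = 0,
                        psf_sigma_px = 1.0, seed = 1L)
  prog <- baseline_program(duration = recording_s)
  settle <- baseline_program(duration = settle_s)
  withr::local_seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_replicates)
  p_values <- numeric(n_replicates)
  for (rr in seq_len(n_replicates)) {
    p_values[rr] <- withr::with_seed(rep_seeds[rr], {
      trace <- pressure_waveform(prog, sample_rate)
      gi_pre <- numeric(n_subjects)
      gi_post <- numeric(n_subjects)
      subj_seeds <- sample.int(2^31 - 2, n_subjects)
      for (s in seq_len(n_subjects)) {
        cfg_s <- cfg
        cfg_s$seed <- subj_seeds[s]
        ph <- make_phantom(cfg_s)
        ph <- equilibrate(ph, settle, sample_rate)
        pre <- simulate_sequence(ph, trace, record_truth = FALSE)
        ph <- pre$phantom
        post <- simulate_sequence(ph, trace, record_truth = FALSE)
        gi_pre[s] <- analyze_recording(pre$sequence, trace)$gi
        gi_post[s] <- analyze_recording(post$sequence, trace)$gi
      }
      paired_compare(gi_pre, gi_post)$p_value
    })
  }
  list(rate = mean(p_values < alpha), n_replicates = n_replicates,
       p_values = p_values)
}
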