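# Core simulation engine. One step per pressure sample:
#   1. stochastic opening/closing against the instantaneous pressure
#   2. effective compliance = compliance * (residual + (1 - residual) * open)
#   3. first-order lag of pixel impedance toward compliance_eff * P(t)
#   4. (synthesis only) point-spread blur, cardiac patch, additive noise
# State (open, lag, t_s) lives on the phantom and carries across phases.
run_engine <- function(phantom, trace, synth = TRUE, record_truth = TRUE,
                       closing_multiplier = 1) {
  cfg <- phantom$config
  fs <- trace$sample_rate
  dt <- 1 / fs
  samples <- trace$samples
  n <- length(samples)
  if (n == 0L) stop("pressure trace is empty")

  rows <- phantom$rows; cols <- phantom$cols
  npx <- rows * cols
  li <- which(phantom$lung)
  comp <- phantom$compliance[li]
  op <- phantom$open_p[li]
  cl <- phantom$close_p[li]
  open <- phantom$open[li]
  zlag <- phantom$lag[li]
  resid <- cfg$residual_fraction

  p_open <- 1 - exp(-cfg$opening_rate * dt)
  p_close <- 1 - exp(-cfg$closing_rate * closing_multiplier * dt)
  alpha <- 1 - exp(-dt / cfg$lag_tau_s)

  frames <- if (synth) matrix(0, nrow = n, ncol = npx) else NULL
  ofr <- if (record_truth) matrix(NA_real_, nrow = n, ncol = 4L) else NULL
  if (record_truth) {
    part <- partition_rois(rows, cols)
    roi_of_lung <- part$band_of_row[pixel_row(li, cols)]
    roi_counts <- tabulate(roi_of_lung, nbins = 4L)
  }

  do_blur <- synth && cfg$psf_sigma_px > 0
  if (do_blur) {
    Br <- gauss_blur_matrix(rows, cfg$psf_sigma_px)
    Bc <- gauss_blur_matrix(cols, cfg$psf_sigma_px)
  }
  do_cardiac <- synth && cfg$cardiac_amplitude > 0
  if (do_cardiac) {
    patch <- as.vector(outer(cfg$cardiac_patch$rows, cfg$cardiac_patch$cols,
                             pixel_index, cols = cols))
    w_card <- 2 * pi * cfg$cardiac_rate_bpm / 60
  }
  do_noise <- synth && cfg$noise_sd > 0
  t0 <- phantom$t_s
  base <- numeric(npx)

  if (p_open == 0 && p_close == 0) {
    # frozen recruitment dynamics: the lag recursion is linear with a
    # shared scalar driver, so z_i(t) = z_i(0) (1-alpha)^t + ceff_i pl(t)
    # with pl the lag-filtered pressure; blur is linear, so whole frames
    # are a rank-2 outer product plus noise
    ceff <- comp * (resid + (1 - resid) * open)
    pl <- as.numeric(stats::filter(alpha * samples, 1 - alpha,
                                   method = "recursive"))
    decay <- (1 - alpha)^seq_len(n)
    if (synth) {
      z0_img <- base; z0_img[li] <- zlag
      ceff_img <- base; ceff_img[li] <- ceff
      if (do_blur) {
        z0_img <- blur_vec(z0_img, rows, cols, Br, Bc)
        ceff_img <- blur_vec(ceff_img, rows, cols, Br, Bc)
      }
      frames <- outer(decay, z0_img) + outer(pl, ceff_img)
      if (do_cardiac)
        frames[, patch] <- frames[, patch] +
          cfg$cardiac_amplitude *
            sin(w_card * (t0 + (seq_len(n) - 1) * dt))
      if (do_noise)
        frames <- frames +
          matrix(stats::rnorm(n * npx), n, npx, byrow = TRUE) * cfg$noise_sd
    }
    if (record_truth) {
      of <- tabulate(roi_of_lung[open], nbins = 4L) / pmax(1L, roi_counts)
      ofr <- matrix(of, nrow = n, ncol = 4L, byrow = TRUE)
    }
    phantom$lag[li] <- zlag * decay[n] + ceff * pl[n]
    phantom$t_s <- t0 + n * dt
    return(list(frames = frames, phantom = phantom,
                open_fraction_by_roi = ofr))
  }

  for (i in seq_len(n)) {
    p <- samples[i]
    if (p_open > 0) {
      cand <- which(!open & op < p)
      if (length(cand)) {
        u <- stats::runif(length(cand))
        open[cand[u < p_open]] <- TRUE
      }
    }
    if (p_close > 0) {
      cand <- which(open & cl > p)
      if (length(cand)) {
        u <- stats::runif(length(cand))
        open[cand[u < p_close]] <- FALSE
      }
    }
    ceff <- comp * (resid + (1 - resid) * open)
    zlag <- zlag + alpha * (ceff * p - zlag)
    if (record_truth) {
      ofr[i, ] <- tabulate(roi_of_lung[open], nbins = 4L) / pmax(1L, roi_counts)
    }
    if (synth) {
      img <- base
      img[li] <- zlag
      if (do_blur) img <- blur_vec(img, rows, cols, Br, Bc)
      if (do_cardiac)
        img[patch] <- img[patch] +
          cfg$cardiac_amplitude * sin(w_card * (t0 + (i - 1) * dt))
      if (do_noise) img <- img + stats::rnorm(npx) * cfg$noise_sd
      frames[i, ] <- img
    }
  }

  phantom$open[li] <- open
  phantom$lag[li] <- zlag
  phantom$t_s <- t0 + n * dt
  list(frames = frames, phantom = phantom, open_fraction_by_roi = ofr)
}

#' Simulate an EIT frame sequence from a phantom and a pressure trace
#'
#' Advances the phantom's recruitment/derecruitment state along the pressure
#' trace and synthesizes one relative-impedance image per pressure sample:
#' each open lung pixel contributes `compliance * P(t)` through a
#' first-order lag, collapsed pixels contribute a residual fraction of that,
#' the image is blurred by the point-spread function and measurement noise
#' (and optionally a localized cardiac oscillation) is added.
#'
#' @param phantom an [make_phantom()] phantom; its open/closed and lag state
#'   are advanced and returned.
#' @param trace a [pressure_trace()] (nonempty).
#' @param seed optional integer; if supplied the simulation is a
#'   deterministic function of (phantom, trace, seed), otherwise the ambient
#'   RNG stream is used.
#' @param subject_id,recording_label metadata stored on the sequence.
#' @param record_truth record per-frame ROI open fractions (ground truth).
#' @return list with `sequence` (a [frame_sequence()]), `phantom` (updated
#'   state) and `truth` (list: `open_fraction_by_roi` matrix frames x 4,
#'   `open_start`, `open_end`, `tidal_volume_ml`).
#' @export
simulate_sequence <- function(phantom, trace, seed = NULL,
                              subject_id = "", recording_label = "",
                              record_truth = TRUE) {
  stopifnot(inherits(phantom, "eit_phantom"), inherits(trace, "pressure_trace"))
  open_start <- phantom$open
  runner <- function() run_engine(phantom, trace, synth = TRUE,
                                  record_truth = record_truth)
  res <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())
  seq <- frame_sequence(res$frames, rows = phantom$rows, cols = phantom$cols,
                        frame_rate = trace$sample_rate,
                        subject_id = subject_id,
                        recording_label = recording_label)
  list(sequence = seq,
       phantom = res$phantom,
       truth = list(open_fraction_by_roi = res$open_fraction_by_roi,
                    open_start = open_start,
                    open_end = res$phantom$open,
                    tidal_volume_ml = tidal_volume_ml(res$phantom)))
}

#' Advance the phantom state without synthesizing frames
#'
#' Runs the recruitment/derecruitment dynamics along a ventilator program
#' (or explicit trace) and returns the updated phantom. Used for
#' equilibration, washout and maneuver phases whose images are not analyzed.
#'
#' @param phantom an `eit_phantom`.
#' @param program a [ventilator_program()], or `trace` given directly.
#' @param sample_rate state-update rate, Hz.
#' @param trace optional [pressure_trace()] overriding `program`.
#' @param closing_multiplier transient multiplier on the closing hazard
#'   (used by [ards_induction()]).
#' @return updated `eit_phantom`.
#' @export
equilibrate <- function(phantom, program = NULL, sample_rate = 40,
                        trace = NULL, closing_multiplier = 1) {
  if (is.null(trace)) {
    stopifnot(inherits(program, "ventilator_program"))
    trace <- pressure_waveform(program, sample_rate)
  }
  run_engine(phantom, trace, synth = FALSE, record_truth = FALSE,
             closing_multiplier = closing_multiplier)$phantom
}

#' Induce the ARDS-like collapsed state
#'
#' Two phases. A lavage phase models surfactant depletion as a transiently
#' elevated closing hazard while the phantom sits at low CPAP: every pixel
#' whose closing pressure exceeds the applied pressure collapses. A
#' stabilization phase then runs baseline ventilation to quasi-steady
#' state, reopening the units whose opening pressures lie below the
#' baseline peak pressure; what remains closed is the gravity-dependent
#' atelectasis encoded in the opening-pressure gradient, plus a flickering
#' boundary band undergoing tidal recruitment.
#'
#' @param phantom an `eit_phantom`.
#' @param duration seconds of lavage phase.
#' @param peep applied pressure during lavage, cmH2O.
#' @param closing_multiplier hazard multiplier during lavage.
#' @param stabilize_s seconds of baseline ventilation after lavage.
#' @param stabilize_program baseline [ventilator_program()] used for
#'   stabilization.
#' @param sample_rate state-update rate, Hz.
#' @return updated `eit_phantom`.
#' @export
ards_induction <- function(phantom, duration = 120, peep = 5,
                           closing_multiplier = 50, stabilize_s = 1800,
                           stabilize_program = NULL, sample_rate = 10) {
  prog <- ventilator_program("CPAP", peak_or_plateau = peep, peep = peep,
                             duration = duration)
  phantom <- equilibrate(phantom, prog, sample_rate = sample_rate,
                         closing_multiplier = closing_multiplier)
  if (stabilize_s > 0) {
    if (is.null(stabilize_program))
      stabilize_program <- baseline_program(duration = stabilize_s,
                                            peep = peep)
    phantom <- equilibrate(phantom, stabilize_program,
                           sample_rate = sample_rate)
  }
  phantom
}

# Ground-truth tidal volume for the phantom's current state: a pressure-
# driven lung delivers vt_ref scaled by the open effective compliance.
tidal_volume_ml <- function(phantom, vt_ref_ml = 300) {
  li <- phantom$lung
  resid <- phantom$config$residual_fraction
  ceff <- phantom$compliance[li] *
    (resid + (1 - resid) * phantom$open[li])
  vt_ref_ml * sum(ceff) / sum(phantom$compliance[li])
}

#' Simulate a pre/post recruitment-maneuver cohort
#'
#' For each subject: instantiate a phantom, induce the ARDS-like collapsed
#' state, then apply the three recruitment maneuvers (sustained inflation,
#' incremental PEEP, PCV) in a seeded random order. Around each maneuver a
#' pre recording (after 60 s equilibration on baseline ventilation) and a
#' post recording (after a short lag-settling interval) are synthesized at
#' the baseline program; between maneuvers the phantom derecruits during a
#' compressed washout at PEEP 5.
#'
#' @param n_subjects number of simulated animals (>= 1).
#' @param config a [phantom_config()]; per-subject phantoms draw their pixel
#'   parameters from subject-specific seeds derived from `seed`.
#' @param seed integer master seed; the whole cohort is a deterministic
#'   function of it.
#' @param recording_s duration of each analyzed recording (s).
#' @param sample_rate frame/pressure rate, Hz.
#' @param baseline baseline [ventilator_program()] used for recordings,
#'   equilibration and washout (the post-maneuver recording program is the
#'   same baseline program).
#' @param maneuvers named list of maneuver programs.
#' @param equilibration_s pre-recording equilibration (s).
#' @param post_settle_s lag-settling interval before the post recording (s).
#' @param washout_s inter-maneuver washout at baseline PEEP (s); run
#'   state-only at `washout_rate` Hz, so long washouts are cheap.
#' @param washout_rate state-update rate during washout (Hz).
#' @param induction_s,induction_multiplier lavage phase length (s) and
#'   closing-hazard multiplier for [ards_induction()]; `induction_s = 0`
#'   skips induction (healthy cohort).
#' @param on_recording optional `function(recording)` called on each
#'   recording as it is produced; when supplied, frames are discarded after
#'   the call and only its return value is kept (memory-friendly).
#' @return list of class `eit_cohort`: `recordings` (list of recordings or
#'   of `on_recording` results; a recording is a list with `sequence`,
#'   `trace`, `truth`, `subject`, `maneuver`, `phase`), `order` (tibble of
#'   maneuver order per subject), `config`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 10,
                            config = ards_phantom_config(),
                            seed = 1,
                            recording_s = 60,
                            sample_rate = 40,
                            baseline = baseline_program(duration = recording_s),
                            maneuvers = list(SI = si_program(),
                                             IP = ip_program(),
                                             PCV = pcv_program()),
                            equilibration_s = 60,
                            post_settle_s = 5,
                            washout_s = 1800,
                            washout_rate = 10,
                            induction_s = 120,
                            induction_multiplier = 50,
                            on_recording = NULL) {
  stopifnot(n_subjects >= 1)
  withr::local_seed(seed)
  subject_seeds <- sample.int(2^31 - 2, n_subjects)
  orders <- maneuver_orders(n_subjects, names(maneuvers))
  equil_prog <- baseline_program(duration = equilibration_s,
                                 peep = baseline$peep,
                                 driving = baseline$driving)
  washout_prog <- baseline_program(duration = washout_s,
                                   peep = baseline$peep,
                                   driving = baseline$driving)
  rec_trace <- pressure_waveform(baseline, sample_rate)

  recordings <- list()
  order_rows <- list()
  keep <- function(rec) if (is.null(on_recording)) rec else on_recording(rec)

  for (s in seq_len(n_subjects)) {
    subject <- sprintf("pig%02d", s)
    cfg_s <- config
    cfg_s$seed <- subject_seeds[s]
    ph <- make_phantom(cfg_s)
    if (induction_s > 0)
      ph <- ards_induction(ph, duration = induction_s,
                           peep = baseline$peep,
                           closing_multiplier = induction_multiplier)
    order_s <- orders[[s]]
    order_rows[[s]] <- tibble::tibble(subject = subject,
                                      position = seq_along(order_s),
                                      maneuver = order_s)
    for (m in order_s) {
      ph <- equilibrate(ph, equil_prog, sample_rate)
      pre <- simulate_sequence(ph, rec_trace, subject_id = subject,
                               recording_label = paste0("pre_", m))
      ph <- pre$phantom
      recordings[[paste(subject, m, "pre", sep = "_")]] <-
        keep(list(sequence = pre$sequence, trace = rec_trace,
                  truth = pre$truth, subject = subject, maneuver = m,
                  phase = "pre"))
      ph <- equilibrate(ph, maneuvers[[m]], sample_rate)
      if (post_settle_s > 0)
        ph <- equilibrate(ph, baseline_program(duration = post_settle_s,
                                               peep = baseline$peep,
                                               driving = baseline$driving),
                          sample_rate)
      post <- simulate_sequence(ph, rec_trace, subject_id = subject,
                                recording_label = paste0("post_", m))
      ph <- post$phantom
      recordings[[paste(subject, m, "post", sep = "_")]] <-
        keep(list(sequence = post$sequence, trace = rec_trace,
                  truth = post$truth, subject = subject, maneuver = m,
                  phase = "post"))
      if (m != order_s[length(order_s)])
        ph <- equilibrate(ph, washout_prog, washout_rate)
    }
  }
  structure(list(recordings = recordings,
                 order = do.call(rbind, order_rows),
                 config = config, seed = seed),
            class = "eit_cohort")
}

#' Draw per-subject maneuver orders
#'
#' One uniformly random permutation of the maneuver labels per subject,
#' drawn from the ambient RNG stream (the in-silico analogue of the random
#' number table used to order maneuvers within each animal).
#'
#' @param n_subjects number of subjects.
#' @param labels maneuver labels to permute.
#' @return list of `n_subjects` character permutations.
#' @export
maneuver_orders <- function(n_subjects, labels = c("SI", "IP", "PCV")) {
  lapply(seq_len(n_subjects), function(s) sample(labels))
}

#' @export
print.eit_cohort <- function(x, ...) {
  cat(sprintf("<eit_cohort> %d recordings, %d subjects, seed %s\n",
              length(x$recordings), length(unique(x$order$subject)),
              format(x$seed)))
  invisible(x)
}
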