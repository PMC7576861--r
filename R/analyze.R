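#' Analyze one EIT recording
#'
#' Full per-recording pipeline: global impedance waveform, breath
#' detection, per-breath tidal images, functional lung mask (one mask per
#' recording, from the mean tidal image), per-breath GI and its mean,
#' regional tidal impedance change and EIT-estimated regional compliance
#' over the four ROI bands, driving pressure, global respiratory-system
#' compliance (when a tidal volume is supplied), and end-expiratory lung
#' impedance.
#'
#' @param seq a [frame_sequence()].
#' @param trace the time-aligned [pressure_trace()].
#' @param vt_ml optional tidal volume (ml) for global compliance
#'   Crs = Vt / driving pressure; the EIT pipeline itself never converts
#'   impedance units to ml.
#' @param mask_threshold functional lung-region threshold
#'   (see [lung_mask()]).
#' @param gi_scope `"mask"` (default: GI over functional lung pixels) or
#'   `"all"` (all image pixels, sensitivity analysis).
#' @param min_breath_s,prominence_fraction passed to [detect_breaths()].
#' @return object of class `eit_result`: list with `gi` (mean per-breath
#'   GI), `gi_per_breath`, `delta_z_roi` (4, au), `regional_compliance`
#'   (4, au/cmH2O), `driving_pressure` (cmH2O, median over breaths),
#'   `global_compliance` (ml/cmH2O or `NA`), `eeli` (see [eeli()]),
#'   `n_breaths`, `mask` (logical pixel vector), `mean_tidal`
#'   (a `tidal_image`), `subject_id`, `recording_label`.
#' @export
analyze_recording <- function(seq, trace, vt_ml = NA_real_,
                              mask_threshold = 0.10,
                              gi_scope = c("mask", "all"),
                              min_breath_s = 1,
                              prominence_fraction = 0.25) {
  gi_scope <- match.arg(gi_scope)
  sig <- global_signal(seq)
  breaths <- detect_breaths(sig, seq$frame_rate, min_breath_s = min_breath_s,
                            prominence_fraction = prominence_fraction)
  if (nrow(breaths) == 0L)
    stop("no breaths detected in recording ", seq$recording_label)
  part <- partition_rois(seq$rows, seq$cols)
  tis <- lapply(seq_len(nrow(breaths)), function(b)
    tidal_image(seq, breaths[b, ]))
  # accept breaths whose global tidal amplitude is commensurate with the
  # recording's median breath; refinement slips and transient state flips
  # can otherwise yield near-zero tidal images that destabilize GI
  amp <- vapply(tis, function(ti) sum(ti$di), numeric(1))
  keep <- amp > 0 & amp >= prominence_fraction * stats::median(amp)
  if (!any(keep))
    stop("no acceptable breaths in recording ", seq$recording_label)
  breaths <- breaths[keep, ]
  tis <- tis[keep]
  mt <- mean_tidal_image(seq, breaths)
  mask <- lung_mask(mt, mask_threshold)
  gi_mask <- if (gi_scope == "mask") mask else NULL
  gi_b <- vapply(tis, gi_index, numeric(1), mask = gi_mask)
  dz_b <- vapply(tis, delta_z_roi, numeric(4), part = part)
  dp_b <- vapply(seq_len(nrow(breaths)), function(b)
    driving_pressure(trace, breaths[b, ], seq$frame_rate), numeric(1))
  dp <- stats::median(dp_b)
  dz <- rowMeans(dz_b)
  structure(list(
    gi = gi_summary(gi_b),
    gi_per_breath = gi_b,
    delta_z_roi = dz,
    regional_compliance = regional_compliance(dz, dp),
    driving_pressure = dp,
    global_compliance = if (is.finite(vt_ml)) vt_ml / dp else NA_real_,
    eeli = eeli(seq, breaths, part),
    n_breaths = nrow(breaths),
    mask = mask,
    mean_tidal = mt,
    breaths = breaths,
    subject_id = seq$subject_id,
    recording_label = seq$recording_label
  ), class = "eit_result")
}

#' @export
print.eit_result <- function(x, ...) {
  cat(sprintf(
    "<eit_result> %s %s: %d breaths, GI %.3f, dP %.1f cmH2O, Crs %s\n",
    x$subject_id, x$recording_label, x$n_breaths, x$gi, x$driving_pressure,
    if (is.finite(x$global_compliance))
      sprintf("%.1f ml/cmH2O", x$global_compliance) else "NA"))
  invisible(x)
}

#' One-row tibble view of an analyzed recording
#'
#' @param res an [analyze_recording()] result.
#' @param truth optional recording truth list (from the simulator) whose
#'   open fractions are appended.
#' @return one-row tibble.
#' @export
result_row <- function(res, truth = NULL) {
  row <- tibble::tibble(
    subject = res$subject_id,
    recording = res$recording_label,
    n_breaths = res$n_breaths,
    gi = res$gi,
    gi_sd = stats::sd(res$gi_per_breath),
    dz_roi1 = res$delta_z_roi[[1]], dz_roi2 = res$delta_z_roi[[2]],
    dz_roi3 = res$delta_z_roi[[3]], dz_roi4 = res$delta_z_roi[[4]],
    comp_roi1 = res$regional_compliance[[1]],
    comp_roi2 = res$regional_compliance[[2]],
    comp_roi3 = res$regional_compliance[[3]],
    comp_roi4 = res$regional_compliance[[4]],
    comp_dependent = res$regional_compliance[[3]] +
      res$regional_compliance[[4]],
    comp_nondependent = res$regional_compliance[[1]] +
      res$regional_compliance[[2]],
    driving_pressure = res$driving_pressure,
    global_compliance = res$global_compliance,
    eeli_global = res$eeli$global_absolute,
    eeli_roi3 = res$eeli$roi_absolute[["ROI3"]],
    eeli_roi4 = res$eeli$roi_absolute[["ROI4"]],
    mask_px = sum(res$mask))
  if (!is.null(truth)) {
    ofr <- truth$open_fraction_by_roi
    row$open_frac_start <- mean(ofr[1, ])
    row$open_frac_end <- mean(ofr[nrow(ofr), ])
    row$open_frac_dependent_start <- mean(ofr[1, 3:4])
    row$open_frac_dependent_end <- mean(ofr[nrow(ofr), 3:4])
    row$tidal_volume_ml <- truth$tidal_volume_ml
  }
  row
}

#' Analyze every recording of a simulated cohort
#'
#' Maps [analyze_recording()] over the cohort and returns a tidy table,
#' one row per recording, with subject, maneuver and phase labels and the
#' simulator's ground-truth open fractions alongside.
#'
#' @param cohort an [simulate_cohort()] result whose recordings still carry
#'   frames (i.e. built without `on_recording`).
#' @param ... passed to [analyze_recording()].
#' @return tibble, one row per recording.
#' @export
analyze_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "eit_cohort"))
  rows <- lapply(cohort$recordings, function(rec) {
    res <- analyze_recording(rec$sequence, rec$trace,
                             vt_ml = rec$truth$tidal_volume_ml, ...)
    row <- result_row(res, rec$truth)
    row$maneuver <- rec$maneuver
    row$phase <- rec$phase
    row
  })
  out <- do.call(rbind, rows)
  out[, c("subject", "maneuver", "phase",
          setdiff(names(out), c("subject", "maneuver", "phase")))]
}

#' Subject x maneuver delta-GI table
#'
#' @param results an [analyze_cohort()]-style tibble (columns `subject`,
#'   `maneuver`, `phase`, `gi`).
#' @return tibble with columns `subject`, `SI`, `IP`, `PCV`, each cell the
#'   subject's delta-GI (pre minus post) for that maneuver.
#' @export
delta_gi_table <- function(results) {
  need <- c("subject", "maneuver", "phase", "gi")
  if (!all(need %in% names(results)))
    stop("results must have columns: ", paste(need, collapse = ", "))
  subjects <- unique(results$subject)
  get_gi <- function(s, m, ph) {
    v <- results$gi[results$subject == s & results$maneuver == m &
                      results$phase == ph]
    if (length(v) != 1L) NA_real_ else v
  }
  tibble::tibble(
    subject = subjects,
    SI = vapply(subjects, function(s)
      delta_gi(get_gi(s, "SI", "pre"), get_gi(s, "SI", "post")), numeric(1)),
    IP = vapply(subjects, function(s)
      delta_gi(get_gi(s, "IP", "pre"), get_gi(s, "IP", "post")), numeric(1)),
    PCV = vapply(subjects, function(s)
      delta_gi(get_gi(s, "PCV", "pre"), get_gi(s, "PCV", "post")), numeric(1)))
}

#' Before/after comparisons for each maneuver
#'
#' For each maneuver and each requested metric, pairs the pre and post
#' values by subject and runs the normality-gated paired comparison; the
#' per-metric family of three maneuvers is Bonferroni-adjusted (m = 3).
#'
#' @param results an [analyze_cohort()]-style tibble.
#' @param metrics character vector of result columns to compare.
#' @return tibble: maneuver, metric, n, before/after summaries (mean, sd),
#'   method, effect, p_raw, p_adjusted.
#' @export
maneuver_before_after <- function(results,
                                  metrics = c("gi", "comp_dependent",
                                              "comp_nondependent",
                                              "global_compliance",
                                              "eeli_global")) {
  out <- list()
  for (met in metrics) {
    if (!met %in% names(results)) next
    cmp_rows <- list()
    for (m in unique(results$maneuver)) {
      pre <- results[results$maneuver == m & results$phase == "pre", ]
      post <- results[results$maneuver == m & results$phase == "post", ]
      post <- post[match(pre$subject, post$subject), ]
      b <- pre[[met]]; a <- post[[met]]
      if (all(!is.finite(b)) || all(!is.finite(a))) next
      cr <- paired_compare(b, a)
      cmp_rows[[m]] <- tibble::tibble(
        maneuver = m, metric = met, n = cr$n,
        before_mean = mean(b, na.rm = TRUE),
        before_sd = stats::sd(b, na.rm = TRUE),
        after_mean = mean(a, na.rm = TRUE),
        after_sd = stats::sd(a, na.rm = TRUE),
        method = cr$method, effect = cr$effect, p_raw = cr$p_value)
    }
    if (!length(cmp_rows)) next
    tab <- do.call(rbind, cmp_rows)
    tab$p_adjusted <- bonferroni(tab$p_raw, m = 3)
    out[[met]] <- tab
  }
  do.call(rbind, out)
}
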