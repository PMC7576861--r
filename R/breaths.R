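#' Global impedance waveform
#'
#' Per-frame sum of all pixel values: the standard global EIT signal whose
#' maxima mark end-inspiration and minima end-expiration.
#'
#' @param seq a [frame_sequence()].
#' @return numeric vector, one value per frame.
#' @export
global_signal <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (nrow(seq$frames) == 0L) stop("empty frame sequence")
  rowSums(seq$frames)
}

# zero-phase low-pass (2nd order Butterworth, applied forward and backward);
# a no-op when the cutoff is at/above Nyquist
lowpass <- function(x, fs, cutoff) {
  if (cutoff <= 0 || cutoff >= fs / 2 * 0.99 || length(x) < 12L) return(x)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# alternating local extrema of a series; plateaus collapse to their midpoint.
# Returns data.frame(idx, type) with type in c("min", "max"), alternating.
alternating_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # carry the previous nonzero slope through plateaus
  nz <- s != 0
  if (!any(nz)) return(data.frame(idx = integer(), type = character()))
  s_f <- s
  last <- s_f[which(nz)[1]]
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  turn <- which(diff(s_f) != 0)           # slope changes after sample turn+1
  if (!length(turn)) return(data.frame(idx = integer(), type = character()))
  idx <- integer(length(turn)); type <- character(length(turn))
  for (j in seq_along(turn)) {
    i <- turn[j] + 1L                     # last index of the old slope run
    # plateau: step back to its start and take the midpoint
    k <- i
    while (k > 1L && x[k - 1L] == x[i]) k <- k - 1L
    idx[j] <- (k + i) %/% 2L
    type[j] <- if (s_f[turn[j]] > 0) "max" else "min"
  }
  keep <- !duplicated(idx)
  data.frame(idx = idx[keep], type = type[keep])
}

# enforce strict min/max alternation, keeping the more extreme of runs
enforce_alternation <- function(ext, x) {
  if (nrow(ext) < 2L) return(ext)
  out_idx <- ext$idx[1]; out_type <- ext$type[1]
  for (j in 2:nrow(ext)) {
    last <- length(out_idx)
    if (ext$type[j] == out_type[last]) {
      better <- if (ext$type[j] == "max") x[ext$idx[j]] > x[out_idx[last]]
                else x[ext$idx[j]] < x[out_idx[last]]
      if (better) out_idx[last] <- ext$idx[j]
    } else {
      out_idx <- c(out_idx, ext$idx[j])
      out_type <- c(out_type, ext$type[j])
    }
  }
  data.frame(idx = out_idx, type = out_type)
}

#' Detect breath cycles in a global impedance signal
#'
#' Low-pass filters the signal (default 2 Hz, suppressing cardiac-band
#' oscillation), finds alternating minima (end-expiration) and maxima
#' (end-inspiration), discards cycles whose peak-to-trough amplitude falls
#' below `prominence_fraction` of the median tidal amplitude or whose peaks
#' are closer than `min_breath_s`, refines the surviving indices on the raw
#' signal, and returns complete end-expiration / end-inspiration /
#' next-end-expiration triplets only.
#'
#' @param signal global impedance waveform (e.g. [global_signal()]).
#' @param frame_rate Hz.
#' @param min_breath_s minimum seconds between successive breaths.
#' @param prominence_fraction minimum cycle amplitude as a fraction of the
#'   median tidal amplitude.
#' @param lowpass_hz low-pass cutoff (Hz).
#' @return data.frame of class `breath_cycles` with integer frame-index
#'   columns `end_expiration`, `end_inspiration`, `next_end_expiration` and
#'   their times in seconds. Zero rows (with a warning) when no breaths are
#'   found.
#' @export
detect_breaths <- function(signal, frame_rate, min_breath_s = 1,
                           prominence_fraction = 0.25, lowpass_hz = 2) {
  stopifnot(is.numeric(signal), frame_rate > 0)
  if (length(signal) < 2 * min_breath_s * frame_rate)
    stop("signal shorter than two minimum-length breaths")
  empty <- function() {
    warning("no breaths detected")
    structure(data.frame(end_expiration = integer(),
                         end_inspiration = integer(),
                         next_end_expiration = integer(),
                         t_end_expiration = numeric(),
                         t_end_inspiration = numeric(),
                         t_next_end_expiration = numeric()),
              class = c("breath_cycles", "data.frame"))
  }
  lp <- lowpass(signal, frame_rate, lowpass_hz)
  ext <- alternating_extrema(lp)
  ext <- enforce_alternation(ext, lp)
  if (sum(ext$type == "max") == 0L) return(empty())

  # iterative amplitude gate: drop sub-threshold peaks, re-alternate
  repeat {
    peaks <- which(ext$type == "max")
    amps <- vapply(peaks, function(j) {
      lo <- if (j > 1L) lp[ext$idx[j - 1L]] else NA_real_
      hi <- if (j < nrow(ext)) lp[ext$idx[j + 1L]] else NA_real_
      lp[ext$idx[j]] - mean(c(lo, hi), na.rm = TRUE)
    }, numeric(1))
    med_amp <- stats::median(amps, na.rm = TRUE)
    if (!is.finite(med_amp) || med_amp <= 0) return(empty())
    bad <- peaks[amps < prominence_fraction * med_amp]
    if (!length(bad)) break
    ext <- ext[-bad, , drop = FALSE]
    ext <- enforce_alternation(ext, lp)
    if (!nrow(ext) || sum(ext$type == "max") == 0L) return(empty())
  }

  # minimum spacing between successive peaks: drop the smaller peak
  repeat {
    peaks <- which(ext$type == "max")
    if (length(peaks) < 2L) break
    gaps <- diff(ext$idx[peaks]) / frame_rate
    close_j <- which(gaps < min_breath_s)
    if (!length(close_j)) break
    j <- close_j[1]
    drop <- if (lp[ext$idx[peaks[j]]] <= lp[ext$idx[peaks[j + 1L]]])
      peaks[j] else peaks[j + 1L]
    ext <- ext[-drop, , drop = FALSE]
    ext <- enforce_alternation(ext, lp)
  }

  peaks <- which(ext$type == "max")
  triplets <- peaks[peaks > 1L & peaks < nrow(ext)]
  if (!length(triplets)) return(empty())

  # refine each index on the raw signal within a +/- window
  period <- stats::median(diff(ext$idx[peaks])) / frame_rate
  w <- as.integer(max(1, round(0.2 * period * frame_rate)))
  refine <- function(i, fun) {
    lo <- max(1L, as.integer(i) - w)
    hi <- min(length(signal), as.integer(i) + w)
    lo + as.integer(fun(signal[lo:hi])) - 1L
  }
  ee <- vapply(ext$idx[triplets - 1L], refine, integer(1), fun = which.min)
  ei <- vapply(ext$idx[triplets], refine, integer(1), fun = which.max)
  ne <- vapply(ext$idx[triplets + 1L], refine, integer(1), fun = which.min)
  ok <- ee < ei & ei < ne
  ee <- ee[ok]; ei <- ei[ok]; ne <- ne[ok]
  if (!length(ee)) return(empty())
  structure(data.frame(end_expiration = ee, end_inspiration = ei,
                       next_end_expiration = ne,
                       t_end_expiration = (ee - 1) / frame_rate,
                       t_end_inspiration = (ei - 1) / frame_rate,
                       t_next_end_expiration = (ne - 1) / frame_rate),
            class = c("breath_cycles", "data.frame"))
}

#' Tidal image of one breath
#'
#' Per-pixel end-inspiratory minus end-expiratory impedance (the tidal
#' image), the pixel map whose dispersion the GI index summarizes.
#'
#' @param seq a [frame_sequence()].
#' @param breath one row of a [detect_breaths()] result (or any list with
#'   `end_expiration` and `end_inspiration` frame indices).
#' @return object of class `tidal_image`: list with `di` (row-major pixel
#'   vector), `rows`, `cols`, `breath`.
#' @export
tidal_image <- function(seq, breath) {
  stopifnot(inherits(seq, "frame_sequence"))
  ei <- breath$end_inspiration; ee <- breath$end_expiration
  nf <- nrow(seq$frames)
  if (any(c(ei, ee) < 1L) || any(c(ei, ee) > nf))
    stop("breath indices out of range")
  structure(list(di = seq$frames[ei, ] - seq$frames[ee, ],
                 rows = seq$rows, cols = seq$cols,
                 breath = list(end_expiration = ee, end_inspiration = ei)),
            class = "tidal_image")
}

#' @export
as.matrix.tidal_image <- function(x, ...) {
  matrix(x$di, nrow = x$rows, ncol = x$cols, byrow = TRUE)
}

#' Mean tidal image over all breaths of a recording
#'
#' @param seq a [frame_sequence()].
#' @param breaths a [detect_breaths()] result with >= 1 row.
#' @return a `tidal_image` whose `di` is the per-pixel mean.
#' @export
mean_tidal_image <- function(seq, breaths) {
  if (nrow(breaths) == 0L) stop("no breaths to average")
  di <- rowMeans(vapply(seq_len(nrow(breaths)),
                        function(b) tidal_image(seq, breaths[b, ])$di,
                        numeric(ncol(seq$frames))))
  structure(list(di = di, rows = seq$rows, cols = seq$cols, breath = NULL),
            class = "tidal_image")
}

#' Functional lung mask from a mean tidal image
#'
#' A pixel belongs to the functional lung region iff its mean tidal signal
#' is at least `threshold_fraction` of the maximum pixel tidal signal (the
#' standard functional-region rule). The mask is computed once per
#' recording, from the recording's mean tidal image, and reused for every
#' breath so per-breath GI values are comparable.
#'
#' @param mean_tidal a [mean_tidal_image()] (or any `tidal_image`).
#' @param threshold_fraction fraction of the maximum pixel amplitude.
#' @return logical vector over pixels (row-major).
#' @export
lung_mask <- function(mean_tidal, threshold_fraction = 0.10) {
  stopifnot(inherits(mean_tidal, "tidal_image"))
  m <- max(mean_tidal$di)
  if (!is.finite(m) || m <= 0)
    stop("mean tidal image has no positive maximum; cannot build lung mask")
  mean_tidal$di >= threshold_fraction * m
}
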