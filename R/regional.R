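#' Four ventral-to-dorsal regions of interest
#'
#' Splits the image rows into four equal contiguous bands, ROI1 (ventral,
#' non-dependent) to ROI4 (dorsal, dependent). When `rows` is not a
#' multiple of 4 the remainder rows go to the ventral-most bands first
#' (deterministic, irrelevant at the default 32). ROI1+2 form the
#' non-dependent half, ROI3+4 the dependent half.
#'
#' @param rows,cols image dimensions (`rows >= 4`).
#' @return object of class `roi_partition`: list with `rows`, `cols`,
#'   `heights` (4 band heights), `band_of_row` (length-`rows` integer
#'   vector), `pixels` (list of 4 row-major pixel index vectors).
#' @export
partition_rois <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || rows < 4L) stop("need at least 4 image rows")
  if (is.na(cols) || cols < 1L) stop("need at least 1 image column")
  base <- rows %/% 4L
  rem <- rows %% 4L
  heights <- base + as.integer(seq_len(4L) <= rem)
  band_of_row <- rep.int(seq_len(4L), heights)
  pixels <- lapply(seq_len(4L), function(b) {
    r <- which(band_of_row == b)
    as.vector(t(outer(r, seq_len(cols), pixel_index, cols = cols)))
  })
  structure(list(rows = rows, cols = cols, heights = heights,
                 band_of_row = band_of_row, pixels = pixels),
            class = "roi_partition")
}

#' Regional tidal impedance change per ROI
#'
#' Sum of the tidal image over each ROI band. The full fixed band is used
#' (the lung mask is not applied) unless `mask` is supplied for sensitivity
#' analysis. The four values sum exactly to the global tidal impedance
#' change.
#'
#' @param ti a [tidal_image()].
#' @param part a [partition_rois()] partition of matching shape.
#' @param mask optional logical pixel mask restricting the sums.
#' @return numeric vector of 4 values (au), names `ROI1..ROI4`.
#' @export
delta_z_roi <- function(ti, part, mask = NULL) {
  stopifnot(inherits(ti, "tidal_image"), inherits(part, "roi_partition"))
  if (ti$rows != part$rows || ti$cols != part$cols)
    stop("tidal image and ROI partition shapes disagree")
  di <- ti$di
  if (!is.null(mask)) di <- di * as.numeric(mask)
  out <- vapply(part$pixels, function(px) sum(di[px]), numeric(1))
  names(out) <- paste0("ROI", 1:4)
  out
}

#' Driving pressure of one breath
#'
#' Airway pressure at end-inspiration minus at end-expiration, each taken
#' as the median of the pressure trace over a +/- `window_s` window around
#' the corresponding frame index (no-flow estimates).
#'
#' @param trace a [pressure_trace()] time-aligned to the frames.
#' @param breath one row of a [detect_breaths()] result.
#' @param frame_rate frame rate of the sequence the breath indices refer to.
#' @param window_s half-window in seconds (default 0.05 = 50 ms).
#' @return driving pressure, cmH2O.
#' @export
driving_pressure <- function(trace, breath, frame_rate, window_s = 0.05) {
  stopifnot(inherits(trace, "pressure_trace"))
  sr <- trace$sample_rate
  half <- round(window_s * sr)
  med_at <- function(frame_idx) {
    s <- round((frame_idx - 1) * sr / frame_rate) + 1L - trace$alignment
    lo <- s - half; hi <- s + half
    if (lo < 1L || hi > length(trace$samples))
      stop("pressure window outside trace")
    stats::median(trace$samples[lo:hi])
  }
  med_at(breath$end_inspiration) - med_at(breath$end_expiration)
}

#' EIT-estimated regional compliance
#'
#' Regional tidal impedance change divided by driving pressure, in arbitrary
#' impedance units per cmH2O. No au-to-ml conversion is attempted.
#'
#' @param delta_z tidal impedance change(s), au (e.g. [delta_z_roi()]).
#' @param dp driving pressure, cmH2O (> 0).
#' @return compliance value(s), au/cmH2O.
#' @export
regional_compliance <- function(delta_z, dp) {
  if (!is.finite(dp) || dp <= 0)
    stop("undefined compliance: driving pressure must be > 0 (got ",
         format(dp), ")")
  delta_z / dp
}

#' Global inhomogeneity (GI) index of a tidal image
#'
#' Sum over the lung region of the absolute deviations of pixel tidal
#' values from their median, normalized by the sum of the pixel tidal
#' values over the same region:
#' \deqn{GI = \sum_{xy \in lung} |DI_{xy} - median(DI_{lung})| /
#'   \sum_{xy \in lung} DI_{xy}.}
#' 0 means perfectly homogeneous tidal ventilation; larger is more
#' inhomogeneous. The median of an even-sized set is the mean of the two
#' middle values. By default the lung-region pixels (`mask`) both define
#' the median/deviation set and the normalizer; pass `mask = NULL` to use
#' all image pixels for sensitivity analysis.
#'
#' @param ti a [tidal_image()], or a numeric pixel vector/matrix.
#' @param mask logical pixel mask (nonempty); `NULL` means all pixels.
#' @return dimensionless GI value.
#' @export
gi_index <- function(ti, mask = NULL) {
  di <- if (inherits(ti, "tidal_image")) ti$di else as.numeric(ti)
  if (is.null(mask)) mask <- rep(TRUE, length(di))
  if (length(mask) != length(di)) stop("mask and image sizes disagree")
  v <- di[mask]
  if (!length(v)) stop("empty lung mask")
  s <- sum(v)
  if (!is.finite(s) || s <= 0)
    stop("GI undefined: nonpositive tidal impedance sum over the mask")
  sum(abs(v - stats::median(v))) / s
}

#' Summary GI of a recording
#'
#' Arithmetic mean of the per-breath GI values accepted in the recording
#' window (one GI per recording is reported).
#'
#' @param gis numeric vector of per-breath GI values (>= 1).
#' @return mean GI.
#' @export
gi_summary <- function(gis) {
  if (!length(gis)) stop("no per-breath GI values")
  mean(gis)
}

#' Change in GI across a recruitment maneuver
#'
#' `pre - post`: positive values mean ventilation became more homogeneous.
#'
#' @param pre,post recording-level GI values (finite).
#' @return delta-GI.
#' @export
delta_gi <- function(pre, post) {
  if (!all(is.finite(c(pre, post)))) stop("GI values must be finite")
  pre - post
}

#' End-expiratory lung impedance (EELI)
#'
#' Mean over breaths of the end-expiration frame's pixel sum, globally and
#' per ROI. `change` entries are expressed relative to the recording's
#' first end-expiration frame (within-recording drift); `absolute` entries
#' are the raw means, used to compare recordings against each other.
#' Per-ROI values sum exactly to the global value.
#'
#' @param seq a [frame_sequence()].
#' @param breaths a [detect_breaths()] result with >= 1 row.
#' @param part a [partition_rois()] partition.
#' @return list with `global_change`, `roi_change` (4), `global_absolute`,
#'   `roi_absolute` (4), and `per_breath` (breaths x 5 matrix of global +
#'   ROI end-expiratory sums).
#' @export
eeli <- function(seq, breaths, part) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(part, "roi_partition"))
  if (nrow(breaths) == 0L) stop("no breaths")
  ee <- breaths$end_expiration
  per_breath <- t(vapply(ee, function(i) {
    fr <- seq$frames[i, ]
    roi <- vapply(part$pixels, function(px) sum(fr[px]), numeric(1))
    c(global = sum(fr), roi)
  }, numeric(5)))
  colnames(per_breath) <- c("global", paste0("ROI", 1:4))
  abs_mean <- colMeans(per_breath)
  ref <- per_breath[1, ]
  list(global_change = abs_mean[["global"]] - ref[["global"]],
       roi_change = abs_mean[-1] - ref[-1],
       global_absolute = abs_mean[["global"]],
       roi_absolute = abs_mean[-1],
       per_breath = per_breath)
}
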