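#' EIT frame sequence container
#'
#' A time-ordered stack of 2-D relative-impedance images. Frames are stored
#' as an `n_frames x (rows * cols)` numeric matrix in row-major pixel order
#' (pixel `k` is row `(k - 1) %/% cols + 1`, column `(k - 1) %% cols + 1`;
#' row 1 is ventral). One fixed pixel convention everywhere prevents silent
#' dependent/non-dependent flips.
#'
#' @param frames `n_frames x (rows * cols)` matrix, or a `rows x cols x n`
#'   array (converted).
#' @param rows,cols image dimensions.
#' @param frame_rate Hz (> 0).
#' @param subject_id,recording_label metadata strings.
#' @param orientation fixed to `"row1_ventral"`.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, rows, cols, frame_rate,
                           subject_id = "", recording_label = "",
                           orientation = "row1_ventral") {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    d <- dim(frames)
    if (d[1] != rows || d[2] != cols)
      stop("frame array dimensions disagree with rows/cols")
    frames <- t(apply(frames, 3, function(m) as.vector(t(m))))
  }
  frames <- as.matrix(frames)
  if (ncol(frames) != rows * cols)
    stop("validation error: flattened frame length ", ncol(frames),
         " != rows * cols = ", rows * cols)
  if (!all(is.finite(frames)))
    stop("validation error: frames must contain finite values only")
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("validation error: frame_rate must be > 0")
  if (!identical(orientation, "row1_ventral"))
    stop("validation error: unsupported orientation: ", orientation)
  structure(list(frames = frames, rows = as.integer(rows),
                 cols = as.integer(cols), frame_rate = frame_rate,
                 orientation = orientation,
                 subject_id = as.character(subject_id),
                 recording_label = as.character(recording_label)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %dx%d @ %g Hz (%.1f s) %s %s\n",
              nrow(x$frames), x$rows, x$cols, x$frame_rate,
              nrow(x$frames) / x$frame_rate, x$subject_id,
              x$recording_label))
  invisible(x)
}

#' Number of frames
#' @param seq a [frame_sequence()].
#' @return integer.
#' @export
n_frames <- function(seq) nrow(seq$frames)

#' Extract one frame as a rows x cols matrix
#'
#' @param seq a [frame_sequence()].
#' @param i frame index (1-based).
#' @return `rows x cols` matrix, row 1 ventral.
#' @export
get_frame <- function(seq, i) {
  if (i < 1L || i > nrow(seq$frames)) stop("frame index out of range")
  matrix(seq$frames[i, ], nrow = seq$rows, ncol = seq$cols, byrow = TRUE)
}

#' Write an EIT recording bundle
#'
#' A bundle is a directory holding `meta.json` (dimensions, rates,
#' orientation, labels), `frames.csv` (one row per frame, row-major
#' flattened pixels) and `pressure.csv` (`time_s, pressure_cmH2O`). Values
#' round-trip losslessly (shortest round-trip decimal representation).
#'
#' @param seq a [frame_sequence()].
#' @param trace a [pressure_trace()].
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(seq, trace, path) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(trace, "pressure_trace"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  meta <- list(format = "eit-bundle", version = 1L,
               rows = seq$rows, cols = seq$cols,
               n_frames = nrow(seq$frames), frame_rate = seq$frame_rate,
               orientation = seq$orientation,
               subject_id = seq$subject_id,
               recording_label = seq$recording_label,
               pressure_sample_rate = trace$sample_rate,
               pressure_alignment = trace$alignment)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fr <- data.table::as.data.table(seq$frames)
  data.table::setnames(fr, sprintf("px%04d", seq_len(ncol(seq$frames))))
  data.table::fwrite(fr, file.path(path, "frames.csv"))
  pt <- data.table::data.table(
    time_s = (seq_along(trace$samples) - 1L + trace$alignment) /
      trace$sample_rate,
    pressure_cmH2O = trace$samples)
  data.table::fwrite(pt, file.path(path, "pressure.csv"))
  invisible(path)
}

#' Read an EIT recording bundle
#'
#' Validates `meta.json` against the stored frames and reconstructs the
#' [frame_sequence()]/[pressure_trace()] pair written by [write_bundle()].
#'
#' @param path bundle directory.
#' @return list with elements `sequence` and `trace`.
#' @export
read_bundle <- function(path) {
  meta_file <- file.path(path, "meta.json")
  frames_file <- file.path(path, "frames.csv")
  pressure_file <- file.path(path, "pressure.csv")
  for (f in c(meta_file, frames_file, pressure_file))
    if (!file.exists(f)) stop("corrupt bundle: missing ", basename(f))
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  required <- c("rows", "cols", "n_frames", "frame_rate", "orientation",
                "pressure_sample_rate")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("corrupt bundle: meta.json is missing field(s): ",
         paste(missing, collapse = ", "))
  fr <- data.table::fread(frames_file)
  frames <- as.matrix(fr)
  if (ncol(frames) != meta$rows * meta$cols)
    stop("corrupt bundle: frames.csv has ", ncol(frames),
         " pixels per frame, expected rows * cols = ",
         meta$rows * meta$cols)
  if (nrow(frames) != meta$n_frames)
    stop("corrupt bundle: frames.csv has ", nrow(frames),
         " frames, meta.json says ", meta$n_frames)
  seq <- frame_sequence(frames, rows = meta$rows, cols = meta$cols,
                        frame_rate = meta$frame_rate,
                        subject_id = meta$subject_id %||% "",
                        recording_label = meta$recording_label %||% "",
                        orientation = meta$orientation)
  pt <- data.table::fread(pressure_file)
  if (!all(c("time_s", "pressure_cmH2O") %in% names(pt)))
    stop("corrupt bundle: pressure.csv must have columns time_s, ",
         "pressure_cmH2O")
  trace <- pressure_trace(pt$pressure_cmH2O, meta$pressure_sample_rate,
                          alignment = meta$pressure_alignment %||% 0L)
  list(sequence = seq, trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
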