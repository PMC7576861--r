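#' Ventilator program
#'
#' Describes one phase of the pressure protocol applied to the phantom.
#' Four modes:
#' \describe{
#'   \item{`volume_control_proxy`}{baseline ventilation: a pressure ramp from
#'     PEEP to a plateau (`peep + driving`) held to end-inspiration, then
#'     release to PEEP. A pressure-domain proxy for volume-control breaths;
#'     the simulator is pressure-driven.}
#'   \item{`CPAP`}{constant airway pressure at `peak_or_plateau` (sustained
#'     inflation when held at 40 cmH2O for 40 s).}
#'   \item{`incremental_PEEP`}{PEEP staircase from `peep` up to
#'     `peak_or_plateau` in `step_size` increments and back down, each step
#'     lasting `step_duration`, with square inspiratory cycles of amplitude
#'     `driving` riding on each step, capped at `peak_or_plateau`.}
#'   \item{`PCV`}{square wave between `peep` and `peak_or_plateau` with
#'     inspiratory fraction `i_to_e / (1 + i_to_e)` of each cycle.}
#' }
#'
#' @param mode one of `"volume_control_proxy"`, `"CPAP"`,
#'   `"incremental_PEEP"`, `"PCV"`.
#' @param respiratory_rate breaths/min (> 0).
#' @param i_to_e inspiratory:expiratory time ratio as a single number I/E
#'   (1:2 -> 0.5).
#' @param peep cmH2O (>= 0).
#' @param peak_or_plateau peak/plateau pressure, cmH2O (>= peep).
#' @param duration phase duration in seconds (> 0); for `incremental_PEEP`
#'   it is derived from the staircase and ignored if supplied.
#' @param step_size,step_duration staircase increment (cmH2O) and per-step
#'   duration (s); `incremental_PEEP` only.
#' @param driving driving pressure (cmH2O) of the baseline proxy and of the
#'   cycles riding on the PEEP staircase.
#' @return object of class `ventilator_program`.
#' @export
ventilator_program <- function(mode = c("volume_control_proxy", "CPAP",
                                        "incremental_PEEP", "PCV"),
                               respiratory_rate = 30,
                               i_to_e = 0.5,
                               peep = 5,
                               peak_or_plateau = 40,
                               duration = 60,
                               step_size = 5,
                               step_duration = 30,
                               driving = 15) {
  mode <- match.arg(mode)
  if (!is.finite(respiratory_rate) || respiratory_rate <= 0)
    stop("respiratory_rate must be > 0")
  if (!is.finite(peep) || peep < 0 || !is.finite(peak_or_plateau) ||
      peak_or_plateau < peep)
    stop("need peak_or_plateau >= peep >= 0")
  if (!is.finite(i_to_e) || i_to_e <= 0)
    stop("i_to_e must be > 0")
  if (mode == "incremental_PEEP") {
    if (step_size <= 0 || step_duration <= 0)
      stop("step_size and step_duration must be > 0")
    n_up <- floor((peak_or_plateau - peep) / step_size)
    duration <- (2 * n_up + 1) * step_duration
  }
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  structure(list(mode = mode, respiratory_rate = respiratory_rate,
                 i_to_e = i_to_e, peep = peep,
                 peak_or_plateau = peak_or_plateau, duration = duration,
                 step_size = step_size, step_duration = step_duration,
                 driving = driving),
            class = "ventilator_program")
}

#' Protocol presets
#'
#' `baseline_program()` is the pre/post-maneuver ventilation (volume-control
#' proxy, RR 30/min, I:E 1:2, PEEP 5, driving pressure 15 cmH2O).
#' `si_program()` is sustained inflation (CPAP 40 cmH2O for 40 s),
#' `ip_program()` the incremental PEEP staircase (5 -> 40 -> 5 cmH2O in
#' 5 cmH2O steps of 30 s), and `pcv_program()` pressure-controlled
#' ventilation at 40/20 cmH2O, I:E 1:2, for 2 min.
#'
#' @param duration recording/phase duration in seconds where applicable.
#' @param peep,driving cmH2O.
#' @name protocol_presets
#' @return a [ventilator_program()].
NULL

#' @rdname protocol_presets
#' @export
baseline_program <- function(duration = 180, peep = 5, driving = 15) {
  ventilator_program("volume_control_proxy", respiratory_rate = 30,
                     i_to_e = 0.5, peep = peep,
                     peak_or_plateau = peep + driving, duration = duration,
                     driving = driving)
}

#' @rdname protocol_presets
#' @export
si_program <- function() {
  ventilator_program("CPAP", peak_or_plateau = 40, duration = 40, peep = 0)
}

#' @rdname protocol_presets
#' @export
ip_program <- function(driving = 15) {
  ventilator_program("incremental_PEEP", respiratory_rate = 30, i_to_e = 0.5,
                     peep = 5, peak_or_plateau = 40, step_size = 5,
                     step_duration = 30, driving = driving)
}

#' @rdname protocol_presets
#' @export
pcv_program <- function(duration = 120) {
  ventilator_program("PCV", respiratory_rate = 30, i_to_e = 0.5, peep = 20,
                     peak_or_plateau = 40, duration = duration)
}

#' Airway pressure trace container
#'
#' @param samples pressure samples, cmH2O (finite).
#' @param sample_rate Hz (> 0).
#' @param alignment offset in samples of sample 1 relative to frame 1 of the
#'   accompanying frame sequence (0 = simultaneous start).
#' @return object of class `pressure_trace`.
#' @export
pressure_trace <- function(samples, sample_rate, alignment = 0L) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("pressure samples must be finite")
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  structure(list(samples = samples, sample_rate = sample_rate,
                 alignment = as.integer(alignment)),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples @ %g Hz (%.1f s), %.1f-%.1f cmH2O\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Synthesize the airway pressure waveform of a ventilator program
#'
#' @param program a [ventilator_program()].
#' @param sample_rate Hz (> 0).
#' @return a [pressure_trace()] of length `floor(duration * sample_rate)`.
#' @export
pressure_waveform <- function(program, sample_rate) {
  stopifnot(inherits(program, "ventilator_program"))
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  n <- floor(program$duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  period <- 60 / program$respiratory_rate
  fi <- program$i_to_e / (1 + program$i_to_e)   # inspiratory fraction
  phase <- t %% period
  insp <- phase < fi * period

  p <- switch(program$mode,
    CPAP = rep(program$peak_or_plateau, n),
    PCV = ifelse(insp, program$peak_or_plateau, program$peep),
    volume_control_proxy = {
      ti <- fi * period
      ramp_frac <- 0.6                 # reach plateau at 60% of insp time
      u <- pmin(1, (phase / ti) / ramp_frac)
      ifelse(insp,
             program$peep + (program$peak_or_plateau - program$peep) * u,
             program$peep)
    },
    incremental_PEEP = {
      steps <- c(seq(program$peep, program$peak_or_plateau, by = program$step_size),
                 rev(seq(program$peep, program$peak_or_plateau,
                         by = program$step_size))[-1])
      idx <- pmin(length(steps), floor(t / program$step_duration) + 1L)
      base <- steps[idx]
      ifelse(insp, pmin(base + program$driving, program$peak_or_plateau), base)
    },
    stop("unknown ventilator mode: ", program$mode)
  )
  pressure_trace(p, sample_rate)
}

#' Cumulative time a waveform spends at or above a pressure
#'
#' @param trace a [pressure_trace()].
#' @param threshold cmH2O.
#' @return seconds.
#' @export
time_at_or_above <- function(trace, threshold) {
  sum(trace$samples >= threshold) / trace$sample_rate
}
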