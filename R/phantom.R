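#' Configuration for a synthetic EIT thorax phantom
#'
#' Defines a supine thorax on a pixel grid (row 1 = ventral, i.e. the
#' non-dependent surface) with two elliptical lung fields. Each lung pixel
#' carries a compliance (arbitrary impedance units per cmH2O) and a pair of
#' critical pressures: an opening pressure, drawn around a ventral-to-dorsal
#' collapse gradient, and a closing pressure a fixed offset below it. While
#' airway pressure exceeds a closed pixel's opening pressure the pixel opens
#' with a constant hazard `opening_rate`; while pressure is below an open
#' pixel's closing pressure it collapses with hazard `closing_rate`.
#'
#' Compliance is lognormal with an independent per-pixel component
#' (`compliance_sdlog`) multiplied by a spatially correlated component
#' (`compliance_spatial_sdlog`, Gaussian correlation length
#' `compliance_corr_px`), so ventilation varies smoothly across the lung the
#' way regional mechanics do, rather than pixel-by-pixel.
#'
#' `psf_sigma_px` blurs every synthesized frame with a Gaussian point-spread
#' function, emulating the low spatial resolution of reconstructed
#' 16-electrode EIT images; set 0 to disable.
#'
#' @param grid_rows,grid_cols image dimensions (>= 8).
#' @param lung_geometry list of ellipses, each
#'   `list(center = c(row, col), radii = c(row, col))` in pixel units.
#' @param compliance_meanlog,compliance_sdlog meanlog/sdlog of the
#'   independent lognormal compliance component (au/cmH2O).
#' @param compliance_spatial_sdlog sdlog of the spatially correlated
#'   compliance component.
#' @param compliance_corr_px correlation length (pixels) of the spatial
#'   component.
#' @param collapse_gradient function mapping normalized dorsal depth
#'   `d` in \[0, 1\] (0 = ventral) to mean opening pressure (cmH2O).
#' @param opening_pressure_sd per-pixel SD (cmH2O) around the gradient.
#' @param closing_offset closing pressure = opening pressure - offset
#'   (cmH2O, > 0).
#' @param opening_rate,closing_rate per-second hazards of opening/closing
#'   while pressure is above/below the respective critical pressure.
#' @param residual_fraction fraction of the open-pixel signal a collapsed
#'   pixel still contributes (collapsed lung is not impedance-silent).
#' @param lag_tau_s first-order time constant (s) of the pixel impedance
#'   response to pressure.
#' @param noise_sd additive Gaussian measurement noise per pixel per frame
#'   (impedance units).
#' @param psf_sigma_px Gaussian point-spread SD (pixels); 0 disables.
#' @param cardiac_amplitude,cardiac_rate_bpm amplitude (impedance units) and
#'   rate of a sinusoidal cardiac oscillation confined to `cardiac_patch`;
#'   amplitude 0 (default) disables it.
#' @param cardiac_patch `list(rows =, cols =)` pixel patch carrying the
#'   cardiac signal (default 4x4, mid-ventral, left of the midline).
#' @param seed integer seed for the per-pixel parameter draws.
#' @return object of class `phantom_config`.
#' @seealso [ards_phantom_config()], [healthy_phantom_config()],
#'   [make_phantom()]
#' @export
phantom_config <- function(grid_rows = 32L,
                           grid_cols = 32L,
                           lung_geometry = default_lung_geometry(grid_rows, grid_cols),
                           compliance_meanlog = log(0.1),
                           compliance_sdlog = 0.25,
                           compliance_spatial_sdlog = 0.35,
                           compliance_corr_px = 4,
                           collapse_gradient = function(d) 10 + 25 * d,
                           opening_pressure_sd = 3,
                           closing_offset = 10,
                           opening_rate = 0.02,
                           closing_rate = 0.002,
                           residual_fraction = 0.02,
                           lag_tau_s = 0.1,
                           noise_sd = 0.05,
                           psf_sigma_px = 1.0,
                           cardiac_amplitude = 0,
                           cardiac_rate_bpm = 90,
                           cardiac_patch = NULL,
                           seed = 1L) {
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  if (is.na(grid_rows) || is.na(grid_cols) || grid_rows < 8L || grid_cols < 8L)
    stop("configuration error: grid dimensions must be integers >= 8")
  if (!is.list(lung_geometry) || length(lung_geometry) == 0L)
    stop("configuration error: lung_geometry must be a nonempty list of ellipses")
  if (!is.function(collapse_gradient))
    stop("configuration error: collapse_gradient must be a function of depth")
  num_nonneg <- c(compliance_sdlog = compliance_sdlog,
                  compliance_spatial_sdlog = compliance_spatial_sdlog,
                  opening_pressure_sd = opening_pressure_sd,
                  opening_rate = opening_rate, closing_rate = closing_rate,
                  residual_fraction = residual_fraction, noise_sd = noise_sd,
                  psf_sigma_px = psf_sigma_px,
                  cardiac_amplitude = cardiac_amplitude)
  bad <- names(num_nonneg)[!is.finite(num_nonneg) | num_nonneg < 0]
  if (length(bad))
    stop("configuration error: must be finite and >= 0: ",
         paste(bad, collapse = ", "))
  if (!is.finite(closing_offset) || closing_offset <= 0)
    stop("configuration error: closing_offset must be > 0 (opening pressure ",
         "must exceed closing pressure for every pixel)")
  if (!is.finite(lag_tau_s) || lag_tau_s <= 0)
    stop("configuration error: lag_tau_s must be > 0")
  if (residual_fraction >= 1)
    stop("configuration error: residual_fraction must be < 1")
  if (is.null(cardiac_patch)) {
    r0 <- max(1L, grid_rows %/% 4L)
    c0 <- max(1L, grid_cols %/% 2L - grid_cols %/% 8L)
    cardiac_patch <- list(rows = r0:min(grid_rows, r0 + 3L),
                          cols = c0:min(grid_cols, c0 + 3L))
  }
  structure(list(
    grid_rows = grid_rows, grid_cols = grid_cols,
    lung_geometry = lung_geometry,
    compliance_meanlog = compliance_meanlog,
    compliance_sdlog = compliance_sdlog,
    compliance_spatial_sdlog = compliance_spatial_sdlog,
    compliance_corr_px = compliance_corr_px,
    collapse_gradient = collapse_gradient,
    opening_pressure_sd = opening_pressure_sd,
    closing_offset = closing_offset,
    opening_rate = opening_rate,
    closing_rate = closing_rate,
    residual_fraction = residual_fraction,
    lag_tau_s = lag_tau_s,
    noise_sd = noise_sd,
    psf_sigma_px = psf_sigma_px,
    cardiac_amplitude = cardiac_amplitude,
    cardiac_rate_bpm = cardiac_rate_bpm,
    cardiac_patch = cardiac_patch,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default two-lung elliptical geometry
#'
#' @param rows,cols grid dimensions.
#' @return list of two ellipses (left and right lung fields).
#' @export
default_lung_geometry <- function(rows, cols) {
  rc <- (rows + 1) / 2 + rows / 32      # lung fields sit slightly dorsal
  list(
    list(center = c(rc, cols * 0.30), radii = c(rows * 0.34, cols * 0.21)),
    list(center = c(rc, cols * 0.70), radii = c(rows * 0.34, cols * 0.21))
  )
}

#' ARDS preset phantom configuration
#'
#' Gravity-dependent collapse gradient (mean opening pressure rising
#' 10 -> 35 cmH2O ventral to dorsal, SD 5), closing offset 10 cmH2O, slow
#' derecruitment (0.01 s^-1) and an opening hazard (0.03 s^-1) slow enough
#' that maneuvers differing in cumulative time at high pressure recruit to
#' different degrees. These are calibration choices for a plausible severe
#' ARDS phantom, not measurements.
#'
#' @param ... overrides passed to [phantom_config()].
#' @return `phantom_config`.
#' @export
ards_phantom_config <- function(...) {
  phantom_config(...)
}

#' Healthy (non-ARDS) preset phantom configuration
#'
#' Opening pressures near zero everywhere: the whole lung is open at any
#' PEEP >= 0 and no pixel ever closes at physiologic pressures.
#'
#' @param ... overrides passed to [phantom_config()].
#' @return `phantom_config`.
#' @export
healthy_phantom_config <- function(...) {
  phantom_config(collapse_gradient = function(d) rep(0, length(d)),
                 opening_pressure_sd = 0, ...)
}

# row-major pixel index helpers: pixel k <-> (row, col), row 1 = ventral
pixel_row <- function(k, cols) ((k - 1L) %/% cols) + 1L
pixel_col <- function(k, cols) ((k - 1L) %% cols) + 1L
pixel_index <- function(row, col, cols) (row - 1L) * cols + col

# Gaussian blur matrix (rows x rows), row-normalized, truncated at 4 sigma
gauss_blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  k <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  k[abs(outer(idx, idx, "-")) > ceiling(4 * sigma)] <- 0
  sweep(k, 1, rowSums(k), "/")
}

# blur a row-major image vector; Br/Bc precomputed blur matrices
blur_vec <- function(v, rows, cols, Br, Bc) {
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  m <- Br %*% m %*% Bc                # Bc symmetric => right-multiply ok
  as.vector(t(m))
}

#' Instantiate a phantom from a configuration
#'
#' Draws the per-pixel ground truth: compliance, opening and closing
#' pressures. All lung pixels start open; run [ards_induction()] and/or
#' [equilibrate()] to bring the open/closed state to the regime of interest.
#' Deterministic given `config$seed` (the ambient RNG state is left
#' untouched).
#'
#' @param config a [phantom_config()].
#' @return object of class `eit_phantom` holding, over the full row-major
#'   pixel grid: `lung` (logical), `compliance`, `open_p`, `close_p`
#'   (au/cmH2O and cmH2O; `NA` outside the lung), the current binary `open`
#'   state and first-order lag state `lag`, plus `rows`, `cols`, `t_s`
#'   (simulated time) and the config.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  rows <- config$grid_rows; cols <- config$grid_cols
  npx <- rows * cols
  k <- seq_len(npx)
  r <- pixel_row(k, cols); cc <- pixel_col(k, cols)
  lung <- rep(FALSE, npx)
  for (e in config$lung_geometry) {
    ctr <- e$center; rad <- e$radii
    if (any(!is.finite(c(ctr, rad))) || any(rad <= 0))
      stop("configuration error: invalid lung ellipse")
    lung <- lung | (((r - ctr[1]) / rad[1])^2 + ((cc - ctr[2]) / rad[2])^2 <= 1)
  }
  if (!any(lung))
    stop("configuration error: lung geometry covers no pixels")

  state <- withr::with_seed(config$seed, {
    z_iid <- stats::rnorm(npx)
    field <- stats::rnorm(npx)
    Bs <- gauss_blur_matrix(rows, config$compliance_corr_px)
    Cs <- gauss_blur_matrix(cols, config$compliance_corr_px)
    sm <- blur_vec(field, rows, cols, Bs, Cs)
    sm <- (sm - mean(sm[lung])) / stats::sd(sm[lung])
    compliance <- exp(config$compliance_meanlog +
                        config$compliance_sdlog * z_iid +
                        config$compliance_spatial_sdlog * sm)
    d <- (r - 1) / max(1L, rows - 1L)          # normalized dorsal depth
    open_p <- config$collapse_gradient(d) +
      config$opening_pressure_sd * stats::rnorm(npx)
    list(compliance = compliance, open_p = open_p)
  })
  compliance <- ifelse(lung, state$compliance, NA_real_)
  open_p <- ifelse(lung, state$open_p, NA_real_)
  close_p <- open_p - config$closing_offset
  structure(list(
    rows = rows, cols = cols, lung = lung,
    compliance = compliance, open_p = open_p, close_p = close_p,
    open = lung,                    # all lung pixels start open
    lag = rep(0, npx),
    t_s = 0,
    config = config
  ), class = "eit_phantom")
}

#' @export
print.eit_phantom <- function(x, ...) {
  cat(sprintf("<eit_phantom> %dx%d grid, %d lung pixels, %.0f%% open, t = %.1f s\n",
              x$rows, x$cols, sum(x$lung),
              100 * sum(x$open & x$lung) / sum(x$lung), x$t_s))
  invisible(x)
}

#' Fraction of lung pixels currently open
#'
#' @param phantom an `eit_phantom`.
#' @param rows optional row indices restricting the computation (e.g. the
#'   dorsal half).
#' @return scalar in \[0, 1\].
#' @export
open_fraction <- function(phantom, rows = NULL) {
  sel <- phantom$lung
  if (!is.null(rows)) {
    r <- pixel_row(seq_along(sel), phantom$cols)
    sel <- sel & r %in% rows
  }
  if (!any(sel)) return(NA_real_)
  sum(phantom$open[sel]) / sum(sel)
}

#' Per-pixel ground-truth table
#'
#' @param phantom an `eit_phantom`.
#' @return tibble with one row per lung pixel: row, col, compliance,
#'   opening/closing pressure, current open state.
#' @export
phantom_pixels <- function(phantom) {
  k <- which(phantom$lung)
  tibble::tibble(
    row = pixel_row(k, phantom$cols),
    col = pixel_col(k, phantom$cols),
    compliance = phantom$compliance[k],
    open_p = phantom$open_p[k],
    close_p = phantom$close_p[k],
    open = phantom$open[k]
  )
}
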