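test_that("constant pressure with frozen noise gives identical frames after lag settling", {
  cfg <- healthy_phantom_config(noise_sd = 0, psf_sigma_px = 1.0,
                                opening_rate = 0, closing_rate = 0)
  ph <- make_phantom(cfg)
  cp <- function(d) ventilator_program("CPAP", peak_or_plateau = 15,
                                       peep = 15, duration = d)
  ph <- equilibrate(ph, cp(30), 40)
  sim <- simulate_sequence(ph, pressure_waveform(cp(2), 40), seed = 1)
  fr <- sim$sequence$frames
  for (i in 2:nrow(fr)) expect_equal(fr[i, ], fr[1, ], tolerance = 1e-9)
})

test_that("frozen hazards keep the open-state matrix constant through a maneuver", {
  cfg <- ards_phantom_config(opening_rate = 0, closing_rate = 0, seed = 5L)
  ph <- make_phantom(cfg)
  ph$open[ph$lung] <- ph$open_p[ph$lung] < 20       # arbitrary mixed state
  tr <- pressure_waveform(pcv_program(duration = 10), 20)
  sim <- simulate_sequence(ph, tr, seed = 2)
  expect_identical(sim$truth$open_start, sim$truth$open_end)
  ofr <- sim$truth$open_fraction_by_roi
  expect_true(all(apply(ofr, 2, function(x) length(unique(x)) == 1L)))
})

test_that("opening frequency follows the exposure-time hazard law", {
  # >= 200 pixel-trials, all with the same opening pressure, held above it
  cfg <- phantom_config(grid_rows = 24, grid_cols = 24,
                        collapse_gradient = function(d) rep(10, length(d)),
                        opening_pressure_sd = 0, opening_rate = 0.05,
                        closing_rate = 0, noise_sd = 0, psf_sigma_px = 0,
                        seed = 2L)
  ph <- make_phantom(cfg)
  ph$open[ph$lung] <- FALSE
  n <- sum(ph$lung)
  expect_gte(n, 200)
  t_expose <- 15
  tr <- pressure_waveform(ventilator_program("CPAP", peak_or_plateau = 20,
                                             peep = 20,
                                             duration = t_expose), 40)
  ph2 <- withr::with_seed(9, equilibrate(ph, trace = tr))
  phat <- sum(ph2$open[ph2$lung]) / n
  p_exp <- 1 - exp(-0.05 * t_expose)
  half <- 2.576 * sqrt(p_exp * (1 - p_exp) / n)     # binomial 99% CI
  expect_lt(abs(phat - p_exp), half)
})

test_that("raising the maneuver pressure never decreases the recovered open fraction", {
  openfrac_after <- function(seed, pmax) {
    ph <- induced_test_phantom(seed)
    withr::with_seed(seed + 1, open_fraction(
      equilibrate(ph, ventilator_program("CPAP", peak_or_plateau = pmax,
                                         peep = pmax, duration = 40), 20)))
  }
  seeds <- 201:220
  o25 <- vapply(seeds, openfrac_after, numeric(1), pmax = 25)
  o40 <- vapply(seeds, openfrac_after, numeric(1), pmax = 40)
  expect_gte(mean(o40), mean(o25))
  expect_gt(mean(o40) - mean(o25), 0.05)   # and clearly so at these presets
})

test_that("PCV recruits the dependent half of the ARDS phantom", {
  ph <- make_phantom(ards_phantom_config(seed = 11L))
  ph <- withr::with_seed(12, ards_induction(ph))
  tr <- pressure_waveform(pcv_program(), 40)
  sim <- simulate_sequence(ph, tr, seed = 8)
  ofr <- sim$truth$open_fraction_by_roi
  expect_gt(mean(ofr[nrow(ofr), 3:4]), mean(ofr[1, 3:4]))
  expect_true(all(ofr >= 0 & ofr <= 1))
})

test_that("identical phantom state and seed give bit-identical frame sequences", {
  ph <- induced_test_phantom(31)
  tr <- pressure_waveform(baseline_program(duration = 8), 20)
  s1 <- simulate_sequence(ph, tr, seed = 77)
  s2 <- simulate_sequence(ph, tr, seed = 77)
  expect_identical(s1$sequence$frames, s2$sequence$frames)
  expect_identical(s1$truth$open_end, s2$truth$open_end)
  s3 <- simulate_sequence(ph, tr, seed = 78)
  expect_false(identical(s1$sequence$frames, s3$sequence$frames))
})

test_that("the cardiac oscillation stays confined to its para-cardiac patch", {
  cfg <- healthy_phantom_config(noise_sd = 0, psf_sigma_px = 0,
                                cardiac_amplitude = 0.5,
                                opening_rate = 0, closing_rate = 0)
  ph <- make_phantom(cfg)
  cp <- function(d) ventilator_program("CPAP", peak_or_plateau = 10,
                                       peep = 10, duration = d)
  ph <- equilibrate(ph, cp(10), 40)
  sim <- simulate_sequence(ph, pressure_waveform(cp(6), 40), seed = 2)
  v <- apply(sim$sequence$frames, 2, stats::sd)
  patch <- as.vector(outer(cfg$cardiac_patch$rows, cfg$cardiac_patch$cols,
                           function(r, c) (r - 1) * cfg$grid_cols + c))
  expect_gt(min(v[patch]), 0.3)
  expect_equal(max(v[-patch]), 0, tolerance = 1e-10)
})

test_that("tidal volume truth tracks the aerated fraction", {
  ph <- make_phantom(ards_phantom_config(seed = 4L))
  vt_open <- eitrm:::tidal_volume_ml(ph)
  expect_equal(vt_open, 300)
  ph$open[ph$lung] <- FALSE
  vt_closed <- eitrm:::tidal_volume_ml(ph)
  expect_equal(vt_closed, 300 * ph$config$residual_fraction)
})
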