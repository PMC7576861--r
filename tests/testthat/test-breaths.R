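test_that("global signal is the per-frame pixel sum", {
  seq <- frame_sequence(matrix(1, 5, 1024), 32, 32, 40)
  expect_equal(global_signal(seq), rep(1024, 5))
  one <- frame_sequence(matrix(rnorm(16), 1, 16), 4, 4, 40)
  expect_length(global_signal(one), 1L)
})

test_that("a noiseless sinusoid yields the expected breath count and period", {
  n <- 60 * 40
  sig <- 1000 + 100 * sin(2 * pi * 0.5 * (0:(n - 1)) / 40)
  br <- detect_breaths(sig, 40)
  expect_true(nrow(br) %in% 29:30)     # boundary cycles may be incomplete
  expect_equal(stats::median(diff(br$end_inspiration)) / 40, 2,
               tolerance = 1 / 40)     # period matches within one frame
  expect_true(all(br$end_expiration < br$end_inspiration &
                    br$end_inspiration < br$next_end_expiration))
})

test_that("a constant signal yields zero breaths with a warning, not an error", {
  expect_warning(br <- detect_breaths(rep(3, 400), 40), "no breaths")
  expect_equal(nrow(br), 0L)
})

test_that("simulated baseline ventilation yields one breath per cycle within edge tolerance", {
  cfg <- healthy_phantom_config(noise_sd = 0, psf_sigma_px = 0)
  ph <- make_phantom(cfg)
  ph <- equilibrate(ph, baseline_program(duration = 10), 40)
  tr <- pressure_waveform(baseline_program(duration = 60), 40)
  sim <- simulate_sequence(ph, tr, seed = 4, record_truth = FALSE)
  br <- detect_breaths(global_signal(sim$sequence), 40)
  expect_true(abs(nrow(br) - 30) <= 2)  # RR 30 for 60 s
})

test_that("tidal image arithmetic and linearity", {
  fr <- matrix(0, 3, 16)
  fr[1, ] <- 1; fr[2, ] <- 2; fr[3, ] <- 1
  seq <- frame_sequence(fr, 4, 4, 10)
  b <- list(end_expiration = 1L, end_inspiration = 2L,
            next_end_expiration = 3L)
  ti <- tidal_image(seq, b)
  expect_equal(ti$di, rep(1, 16))
  same <- tidal_image(seq, list(end_expiration = 1L, end_inspiration = 1L))
  expect_equal(same$di, rep(0, 16))
  # linearity: di(a * seq) = a * di(seq)
  seq3 <- frame_sequence(3.5 * fr, 4, 4, 10)
  expect_equal(tidal_image(seq3, b)$di, 3.5 * ti$di)
  expect_error(tidal_image(seq, list(end_expiration = 1L,
                                     end_inspiration = 9L)), "out of range")
})

test_that("lung mask follows the fractional-threshold rule", {
  uni <- structure(list(di = rep(2, 16), rows = 4, cols = 4, breath = NULL),
                   class = "tidal_image")
  expect_true(all(lung_mask(uni, 0.10)))
  hot <- structure(list(di = c(1, rep(0.01, 15)), rows = 4, cols = 4,
                        breath = NULL), class = "tidal_image")
  expect_equal(sum(lung_mask(hot, 0.10)), 1L)
  zero <- structure(list(di = rep(0, 16), rows = 4, cols = 4, breath = NULL),
                    class = "tidal_image")
  expect_error(lung_mask(zero), "positive maximum")
})

test_that("raising the mask threshold never grows the mask", {
  set.seed(3)
  ti <- structure(list(di = abs(rnorm(256)), rows = 16, cols = 16,
                       breath = NULL), class = "tidal_image")
  prev <- lung_mask(ti, 0.02)
  for (thr in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    cur <- lung_mask(ti, thr)
    expect_true(all(prev[cur]))          # cur subset of prev
    prev <- cur
  }
})

test_that("collapse shrinks the functional lung mask relative to a healthy phantom", {
  mask_px <- function(seed, ards) {
    cfg <- if (ards) ards_phantom_config(seed = seed) else
      healthy_phantom_config(seed = seed)
    ph <- make_phantom(cfg)
    ph <- withr::with_seed(seed + 1, {
      if (ards) ards_induction(ph, duration = 60, closing_multiplier = 100,
                               stabilize_s = 300)
      else equilibrate(ph, baseline_program(duration = 5), 20)
    })
    tr <- pressure_waveform(baseline_program(duration = 12), 20)
    sim <- simulate_sequence(ph, tr, seed = seed + 2)
    sum(analyze_recording(sim$sequence, tr)$mask)
  }
  seeds <- 301:320
  m_ards <- vapply(seeds, mask_px, numeric(1), ards = TRUE)
  m_healthy <- vapply(seeds, mask_px, numeric(1), ards = FALSE)
  expect_true(all(m_ards < m_healthy))
})

test_that("noiseless tidal images recover compliance x driving pressure within lag tolerance", {
  cfg <- healthy_phantom_config(noise_sd = 0, psf_sigma_px = 0)
  ph <- make_phantom(cfg)
  ph <- equilibrate(ph, baseline_program(duration = 10), 40)
  tr <- pressure_waveform(baseline_program(duration = 30), 40)
  sim <- simulate_sequence(ph, tr, seed = 4, record_truth = FALSE)
  br <- detect_breaths(global_signal(sim$sequence), 40)
  ti <- tidal_image(sim$sequence, br[3, ])
  li <- which(ph$lung)
  relerr <- abs(ti$di[li] / (ph$compliance[li] * 15) - 1)
  expect_lt(max(relerr), 0.05)
})
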