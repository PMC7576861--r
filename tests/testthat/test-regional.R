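test_that("ROI partition splits rows into four ventral-to-dorsal bands", {
  p32 <- partition_rois(32, 32)
  expect_equal(p32$heights, rep(8L, 4))
  expect_equal(which(p32$band_of_row == 1L), 1:8)
  expect_equal(which(p32$band_of_row == 4L), 25:32)
  p4 <- partition_rois(4, 4)
  expect_equal(p4$heights, rep(1L, 4))
  # remainder rows go to the ventral-most bands first
  p10 <- partition_rois(10, 6)
  expect_equal(p10$heights, c(3L, 3L, 2L, 2L))
  # bands are disjoint and cover the grid
  all_px <- sort(unlist(p10$pixels))
  expect_equal(all_px, 1:60)
  expect_error(partition_rois(3, 8), "at least 4")
})

test_that("regional delta-Z sums bands and conserves the global total", {
  part <- partition_rois(32, 32)
  ones <- structure(list(di = rep(1, 1024), rows = 32, cols = 32,
                         breath = NULL), class = "tidal_image")
  expect_equal(unname(delta_z_roi(ones, part)), rep(256, 4))
  row1 <- structure(list(di = c(rep(2, 32), rep(0, 992)), rows = 32,
                         cols = 32, breath = NULL), class = "tidal_image")
  dz <- delta_z_roi(row1, part)
  expect_equal(unname(dz), c(64, 0, 0, 0))
  set.seed(4)
  for (i in 1:20) {
    ti <- structure(list(di = rnorm(1024), rows = 32, cols = 32,
                         breath = NULL), class = "tidal_image")
    expect_equal(sum(delta_z_roi(ti, part)), sum(ti$di))
  }
})

test_that("driving pressure reads the no-flow pressures around the breath marks", {
  # square PCV-like trace: 40 during inspiration, 20 during expiration
  prog <- pcv_program(duration = 10)
  trace <- pressure_waveform(prog, 40)
  breath <- list(end_expiration = 75L,     # late expiration of cycle 1
                 end_inspiration = 100L)   # late inspiration of cycle 2
  expect_equal(driving_pressure(trace, breath, 40), 20)
  const <- pressure_trace(rep(8, 400), 40)
  expect_equal(driving_pressure(const, breath, 40), 0)
  expect_error(driving_pressure(trace, list(end_expiration = 1L,
                                            end_inspiration = 100L), 40),
               "outside")
})

test_that("regional compliance is delta-Z over driving pressure and guards dp <= 0", {
  expect_equal(regional_compliance(10, 10), 1)
  expect_equal(regional_compliance(0, 7), 0)
  expect_equal(unname(regional_compliance(c(4, 8), 2)), c(2, 4))
  expect_error(regional_compliance(5, 0), "undefined compliance")
  expect_error(regional_compliance(5, -2), "undefined compliance")
})

test_that("GI index matches its definition on worked values", {
  expect_equal(gi_index(c(1, 1, 1, 5)), 0.5)
  expect_equal(gi_index_loop(c(1, 1, 1, 5)), 0.5)
  # even-count median is the midpoint of the two middle values
  expect_equal(gi_index(c(0, 2, 3, 5)), 0.6)
  expect_equal(gi_index_loop(c(0, 2, 3, 5)), 0.6)
  # uniform image is perfectly homogeneous
  expect_equal(gi_index(rep(3, 100)), 0)
  # masked computation uses mask pixels only
  di <- c(1, 1, 1, 5, 100, -7)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(gi_index(di, mask), 0.5)
})

test_that("GI is scale invariant and errors on degenerate input", {
  set.seed(5)
  di <- abs(rnorm(64)) + 0.1
  for (c_scale in c(0.25, 3.7, 1e4))
    expect_equal(gi_index(c_scale * di), gi_index(di))
  expect_error(gi_index(rep(0, 16)), "nonpositive")
  expect_error(gi_index(di, rep(FALSE, 64)), "empty")
  expect_error(gi_index(di, rep(TRUE, 10)), "disagree")
})

test_that("vectorized GI equals the brute-force loop oracle on random masked images", {
  set.seed(6)
  for (i in 1:100) {
    n <- sample(c(64, 256, 1024), 1)
    di <- stats::rlnorm(n, 0, 1)
    mask <- stats::runif(n) < stats::runif(1, 0.2, 0.9)
    if (!any(mask)) mask[1] <- TRUE
    expect_equal(gi_index(di, mask), gi_index_loop(di, mask),
                 tolerance = 1e-12)
  }
})

test_that("GI rises strictly as the collapsed fraction of a uniform image grows", {
  set.seed(7)
  n <- 400
  base <- rep(1, n)
  gi_at <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(f) {
    di <- base
    di[seq_len(round(f * n))] <- 0.02    # residual level of collapsed lung
    gi_index(di)
  }, numeric(1))
  expect_true(all(diff(gi_at) > 0))
})

test_that("per-breath GI aggregates by the arithmetic mean", {
  expect_equal(gi_summary(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(gi_summary(c(0.4, 0.6)), 0.5)
  expect_error(gi_summary(numeric()), "no per-breath")
})

test_that("delta-GI is the pre minus post difference", {
  expect_equal(delta_gi(0.62, 0.42), 0.20)
  expect_equal(delta_gi(0.55, 0.42), 0.13)
  expect_equal(delta_gi(0.47, 0.47), 0)
  expect_error(delta_gi(NA, 0.4), "finite")
})

test_that("per-ROI EELI sums exactly to global EELI and is stable on steady recordings", {
  set.seed(8)
  part <- partition_rois(16, 16)
  fr <- matrix(rnorm(20 * 256), 20, 256)
  seq <- frame_sequence(fr, 16, 16, 10)
  breaths <- data.frame(end_expiration = c(2L, 8L, 14L),
                        end_inspiration = c(5L, 11L, 17L),
                        next_end_expiration = c(8L, 14L, 20L))
  ee <- eeli(seq, breaths, part)
  expect_equal(sum(ee$roi_absolute), ee$global_absolute)
  expect_equal(sum(ee$roi_change), ee$global_change)
  # steady recording: every end-expiratory frame identical -> change 0
  fr2 <- matrix(rep(runif(256), each = 20), 20, 256)
  ee2 <- eeli(frame_sequence(fr2, 16, 16, 10), breaths, part)
  expect_equal(ee2$global_change, 0)
})

test_that("EELI rises across a recording that spans a recruitment maneuver", {
  ph <- induced_test_phantom(21)
  base <- pressure_waveform(baseline_program(duration = 16), 20)$samples
  si <- pressure_waveform(si_program(), 20)$samples
  trace <- pressure_trace(c(base, si, base), 20)
  sim <- simulate_sequence(ph, trace, seed = 5)
  br <- detect_breaths(global_signal(sim$sequence), 20)
  br <- br[br$end_expiration < 16 * 20 | br$end_expiration > 56 * 20, ]
  ee <- eeli(sim$sequence, br, partition_rois(16, 16))
  expect_gt(ee$global_change, 0)
  expect_gt(sim$truth$open_fraction_by_roi[nrow(sim$truth$open_fraction_by_roi), 4],
            sim$truth$open_fraction_by_roi[1, 4])
})
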