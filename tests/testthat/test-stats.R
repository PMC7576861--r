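test_that("the normality gate routes clean and heavy-tailed differences correctly", {
  d_norm <- withr::with_seed(1, rnorm(10))
  expect_equal(choose_test(d_norm), "paired_t")
  # heavy-tailed contaminated mixture: one gross outlier among small values
  d_heavy <- withr::with_seed(4, c(rnorm(9, 0, 0.05), 8))
  expect_equal(choose_test(d_heavy), "wilcoxon_signed_rank")
  expect_warning(m <- choose_test(rep(2, 10)), "identical")
  expect_equal(m, "wilcoxon_signed_rank")
  expect_error(choose_test(c(1, 2)), "at least 3")
})

test_that("the Pratt signed-rank test reproduces the exact classical test without zeros or ties", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    d <- round(rnorm(n, sd = 10), 4)
    while (any(d == 0) || any(duplicated(abs(d))))
      d <- round(rnorm(n, sd = 10), 4)
    ref <- stats::wilcox.test(d, exact = TRUE, correct = FALSE)
    mine <- signed_rank_pratt(d)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$method, "exact")
  }
})

test_that("Pratt zero handling keeps zeros in the ranking but out of the statistic", {
  # |d| = 0,0,1,2 -> ranks 1.5, 1.5, 3, 4; positive d ranks: 3 + 4
  res <- signed_rank_pratt(c(0, 0, 1, 2))
  expect_equal(res$statistic, 7)
  expect_equal(res$n_nonzero, 2L)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_warning(deg <- signed_rank_pratt(c(0, 0, 0)), "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("paired comparisons handle degenerate inputs per contract", {
  x <- c(0.5, 0.6, 0.7, 0.4, 0.55)
  # before = after elementwise: degenerate Wilcoxon path, zero effect
  # (warns twice: once from the gate, once from the signed-rank test)
  expect_warning(expect_warning(res <- paired_compare(x, x), "degenerate"),
                 "identical")
  expect_equal(res$effect, 0)
  expect_equal(res$p_value, 1)
  # constant shift under forced paired t: zero-variance differences
  expect_error(paired_compare(x + 1, x, method = "paired_t"),
               "zero variance")
})

test_that("paired t and Wilcoxon results carry the right summaries", {
  set.seed(2)
  before <- rnorm(10, 0.6, 0.1)
  after <- before - rnorm(10, 0.15, 0.03)
  rt <- paired_compare(before, after, method = "paired_t")
  expect_named(rt$summary_before, c("mean", "sd"))
  expect_equal(rt$effect, mean(before - after))
  expect_lt(rt$p_value, 0.01)
  rw <- paired_compare(before, after, method = "wilcoxon_signed_rank")
  expect_named(rw$summary_before, c("median", "q1", "q3"))
  expect_equal(rw$effect, median(before - after))
  expect_lt(rw$p_value, 0.01)
  # both detect the same effect direction
  expect_equal(sign(rt$effect), sign(rw$effect))
})

test_that("effect directions agree between tests across shift alternatives", {
  set.seed(3)
  for (i in 1:20) {
    shift <- sample(c(-0.3, 0.3), 1)
    before <- rnorm(12, 1, 0.1)
    after <- before - shift + rnorm(12, 0, 0.05)
    rt <- paired_compare(before, after, method = "paired_t")
    rw <- paired_compare(before, after, method = "wilcoxon_signed_rank")
    expect_equal(sign(rt$effect), sign(rw$effect))
    expect_equal(sign(rt$effect), sign(shift))
  }
})

test_that("Bonferroni adjustment multiplies, caps at one, and preserves order", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0, 5), 0)
  p <- c(0.001, 0.04, 0.2, 0.6)
  padj <- bonferroni(p, 4)
  expect_true(all(padj >= p))
  expect_true(all(diff(padj) >= 0))
  expect_true(all(padj <= 1))
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("the paired machinery holds its size under a pure-noise null", {
  set.seed(9)
  n_rep <- 400
  rej <- 0
  for (i in 1:n_rep) {
    before <- rnorm(10)
    after <- rnorm(10)
    suppressWarnings(p <- paired_compare(before, after)$p_value)
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / n_rep, 0.02)
  expect_lt(rej / n_rep, 0.09)
})

test_that("pairwise maneuver contrasts detect a constructed IP advantage", {
  set.seed(11)
  si <- rnorm(10, 0.13, 0.03)
  tbl <- tibble::tibble(subject = sprintf("pig%02d", 1:10),
                        SI = si,
                        IP = si + 0.07 + rnorm(10, 0, 0.02),
                        PCV = si + rnorm(10, 0, 0.02))
  res <- compare_maneuver_deltas(tbl)
  expect_gt(res$IP_vs_SI$effect, 0)
  expect_lt(res$IP_vs_SI$p_adjusted, 0.05)
  expect_true(all(attr(res, "table")$p_adjusted >= attr(res, "table")$p_raw))
})

test_that("identical delta-GI columns give zero effects, and missing cells name the subject", {
  x <- c(0.1, 0.12, 0.09, 0.15, 0.11)
  tbl <- tibble::tibble(subject = sprintf("pig%02d", 1:5),
                        SI = x, IP = x, PCV = x)
  suppressWarnings(res <- compare_maneuver_deltas(tbl))
  expect_equal(res$IP_vs_SI$effect, 0)
  tbl$IP[3] <- NA
  expect_error(compare_maneuver_deltas(tbl), "pig03")
})
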