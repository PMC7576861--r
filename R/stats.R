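#' Choose the paired test from the distribution of differences
#'
#' Shapiro-Wilk on the paired differences at alpha = 0.05: normal-looking
#' differences go to the paired t test, the rest to the Wilcoxon signed-rank
#' test. Normality is assessed on the differences, not the raw arms,
#' because the differences are what the tests assume. Identical
#' differences cannot be assessed and fall through to the Wilcoxon path
#' with a degeneracy warning.
#'
#' @param differences numeric vector of paired differences (n >= 3).
#' @param alpha normality rejection level.
#' @return `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @export
choose_test <- function(differences, alpha = 0.05) {
  differences <- differences[is.finite(differences)]
  if (length(differences) < 3L) stop("need at least 3 paired differences")
  if (length(unique(differences)) == 1L) {
    warning("all paired differences identical; normality not assessable, ",
            "using Wilcoxon signed-rank")
    return("wilcoxon_signed_rank")
  }
  sw <- stats::shapiro.test(differences)
  if (sw$p.value >= alpha) "paired_t" else "wilcoxon_signed_rank"
}

#' Exact Wilcoxon signed-rank test with Pratt zero handling
#'
#' Signed-rank test of the null that the differences are symmetric about
#' zero. Zero differences are included when ranking the absolute values and
#' then dropped from the statistic (Pratt), which is stable for the small,
#' tied samples paired physiological designs produce. The null distribution
#' of the statistic is computed exactly by a shift algorithm (on doubled
#' midranks, so ties are exact too) when the number of nonzero differences
#' is at most `exact_max`; beyond that a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest nonzero-count for the exact null.
#' @return list with `statistic` (V = sum of ranks of positive
#'   differences), `p_value` (two-sided), `method` (`"exact"` or
#'   `"normal_approx"`), `n_nonzero`.
#' @export
signed_rank_pratt <- function(d, exact_max = 25L) {
  d <- d[is.finite(d)]
  if (!length(d)) stop("no finite differences")
  nz <- d != 0
  m <- sum(nz)
  if (m == 0L) {
    warning("all differences are zero; signed-rank test is degenerate")
    return(list(statistic = 0, p_value = 1, method = "degenerate",
                n_nonzero = 0L))
  }
  r_all <- rank(abs(d))              # zeros participate in the ranking
  r <- r_all[nz]
  v <- sum(r[d[nz] > 0])
  r2 <- as.integer(round(2 * r))     # midranks doubled -> integers
  if (m <= exact_max) {
    # pmf of sum over random sign assignments, support 0..sum(r2) (scaled x2)
    f <- 1
    for (ri in r2) f <- (c(f, numeric(ri)) + c(numeric(ri), f)) / 2
    v2 <- as.integer(round(2 * v))
    cdf_le <- sum(f[seq_len(v2 + 1L)])
    cdf_ge <- sum(f[(v2 + 1L):length(f)])
    p <- min(1, 2 * min(cdf_le, cdf_ge))
    list(statistic = v, p_value = p, method = "exact", n_nonzero = m)
  } else {
    mu <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4)
    z <- (v - mu - sign(v - mu) * 0.5) / sig
    list(statistic = v, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal_approx", n_nonzero = m)
  }
}

#' Paired before/after comparison
#'
#' Two-sided test on `before - after`, with the method either supplied or
#' chosen by [choose_test()]. Arm summaries follow the method family:
#' mean +/- SD for the paired t test, median \[IQR\] for the Wilcoxon path.
#'
#' @param before,after aligned numeric vectors (n >= 3).
#' @param method `NULL` (auto), `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return object of class `comparison_result`: list with `method`,
#'   `statistic`, `p_value`, `p_adjusted` (`NA` until adjusted), `n`,
#'   `effect` (mean difference for t, median difference for Wilcoxon),
#'   `summary_before`, `summary_after`.
#' @export
paired_compare <- function(before, after, method = NULL) {
  stopifnot(length(before) == length(after))
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  n <- length(before)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- before - after
  if (is.null(method)) method <- choose_test(d)
  method <- match.arg(method, c("paired_t", "wilcoxon_signed_rank"))

  if (method == "paired_t") {
    if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1e-300))
      stop("degenerate input: paired differences have zero variance; ",
           "the paired t statistic is undefined")
    tt <- tryCatch(stats::t.test(before, after, paired = TRUE),
                   error = function(e)
                     stop("degenerate input: paired differences have zero ",
                          "variance; the paired t statistic is undefined"))
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    effect <- mean(d)
    sb <- c(mean = mean(before), sd = stats::sd(before))
    sa <- c(mean = mean(after), sd = stats::sd(after))
  } else {
    wt <- signed_rank_pratt(d)
    statistic <- wt$statistic
    p <- wt$p_value
    effect <- stats::median(d)
    qb <- stats::quantile(before, c(0.25, 0.5, 0.75), names = FALSE)
    qa <- stats::quantile(after, c(0.25, 0.5, 0.75), names = FALSE)
    sb <- c(median = qb[2], q1 = qb[1], q3 = qb[3])
    sa <- c(median = qa[2], q1 = qa[1], q3 = qa[3])
  }
  structure(list(method = method, statistic = statistic, p_value = p,
                 p_adjusted = NA_real_, n = n, effect = effect,
                 summary_before = sb, summary_after = sa),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s, n = %d, effect = %.4g, p = %.4g%s\n",
              x$method, x$n, x$effect, x$p_value,
              if (is.finite(x$p_adjusted))
                sprintf(" (adj %.4g)", x$p_adjusted) else ""))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`.
#'
#' @param p_values numeric vector of raw p-values.
#' @param m number of comparisons in the family (>= `length(p_values)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values))
    stop("m must be at least the number of p-values")
  pmin(1, p_values * m)
}

#' Pairwise comparison of per-maneuver delta-GI
#'
#' Paired contrasts IP vs SI, IP vs PCV and SI vs PCV on the subject-level
#' delta-GI values, each gated by [choose_test()] and Bonferroni-adjusted
#' with m = 3.
#'
#' @param dgi data.frame/tibble with columns `subject`, `SI`, `IP`, `PCV`
#'   (delta-GI per subject per maneuver), complete.
#' @return named list of three [paired_compare()] results
#'   (`IP_vs_SI`, `IP_vs_PCV`, `SI_vs_PCV`) with `p_adjusted` filled in;
#'   attribute `"table"` holds a tibble summary.
#' @export
compare_maneuver_deltas <- function(dgi) {
  need <- c("subject", "SI", "IP", "PCV")
  if (!all(need %in% names(dgi)))
    stop("delta-GI table needs columns: ", paste(need, collapse = ", "))
  bad <- dgi$subject[!stats::complete.cases(dgi[, c("SI", "IP", "PCV")])]
  if (length(bad))
    stop("incomplete delta-GI table; missing cells for subject(s): ",
         paste(bad, collapse = ", "))
  if (nrow(dgi) < 3L) stop("need at least 3 subjects")
  contrasts <- list(IP_vs_SI = c("IP", "SI"),
                    IP_vs_PCV = c("IP", "PCV"),
                    SI_vs_PCV = c("SI", "PCV"))
  out <- lapply(contrasts, function(ab)
    paired_compare(dgi[[ab[1]]], dgi[[ab[2]]]))
  padj <- bonferroni(vapply(out, `[[`, numeric(1), "p_value"), m = 3)
  for (i in seq_along(out)) out[[i]]$p_adjusted <- padj[i]
  tab <- tibble::tibble(
    contrast = names(out),
    method = vapply(out, `[[`, character(1), "method"),
    effect = vapply(out, `[[`, numeric(1), "effect"),
    p_raw = vapply(out, `[[`, numeric(1), "p_value"),
    p_adjusted = padj)
  attr(out, "table") <- tab
  out
}
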