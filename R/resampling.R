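#' Randomized permutation test for a two-group difference
#'
#' Tests the null hypothesis of no group difference by permuting group
#' membership while keeping group sizes fixed, building an empirical null
#' distribution of the group statistic. When the number of distinct label
#' assignments is at most `exhaustive_limit` the test enumerates all of them
#' and the p-value is exact; otherwise `n_perm` random permutations are drawn
#' and the p-value uses the add-one estimator (1 + count) / (1 + n_perm),
#' which is always positive and counts the observed assignment in the null.
#'
#' @param values_a,values_b Numeric vectors, the two groups (non-empty).
#' @param n_perm Number of Monte-Carlo permutations (ignored when exhaustive).
#' @param seed Optional seed for the Monte-Carlo path.
#' @param statistic Group statistic; only `"mean_difference"` is supported.
#' @param exhaustive_limit Enumerate all assignments when
#'   `choose(n_a + n_b, n_a)` does not exceed this.
#' @return A `permutation_result`: list with `observed_stat`, `p_value`,
#'   `n_permutations`, `seed`, `exhaustive`.
#' @export
permutation_group_test <- function(values_a, values_b, n_perm = 1999L,
                                   seed = NULL,
                                   statistic = "mean_difference",
                                   exhaustive_limit = 20000) {
  statistic <- match.arg(statistic, "mean_difference")
  assert_that(length(values_a) >= 1 && length(values_b) >= 1,
              "invalid input: both groups must be non-empty")
  assert_that(is_count(n_perm), "invalid input: n_perm must be a positive integer")
  pooled <- c(values_a, values_b)
  assert_that(all(is.finite(pooled)), "invalid input: values must be finite")
  n_a <- length(values_a)
  n <- length(pooled)
  observed <- mean(values_a) - mean(values_b)
  # tolerance so permutations tied with the observed statistic count as >=
  tol <- 1e-12 * max(1, abs(observed))

  n_assign <- choose(n, n_a)
  if (n_assign <= exhaustive_limit) {
    idx <- utils::combn(n, n_a)
    stats_null <- apply(idx, 2L, function(i) mean(pooled[i]) - mean(pooled[-i]))
    p <- sum(abs(stats_null) >= abs(observed) - tol) / n_assign
    res <- list(observed_stat = observed, p_value = p,
                n_permutations = as.integer(n_assign), seed = seed,
                exhaustive = TRUE)
  } else {
    stats_null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        i <- sample.int(n, n_a)
        mean(pooled[i]) - mean(pooled[-i])
      }, numeric(1))
    })
    count <- sum(abs(stats_null) >= abs(observed) - tol)
    p <- (1 + count) / (1 + n_perm)
    res <- list(observed_stat = observed, p_value = p,
                n_permutations = as.integer(n_perm), seed = seed,
                exhaustive = FALSE)
  }
  class(res) <- "permutation_result"
  res
}

#' Two-sample Kolmogorov-Smirnov contrast
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value is the asymptotic two-sided approximation (ties allowed,
#' as the voxel-wise value samples compared here routinely contain ties).
#'
#' @param values_a,values_b Non-empty numeric samples.
#' @return A `ks_result`: list with `d`, `p_value`, `n_a`, `n_b`.
#' @export
ks_statistic <- function(values_a, values_b) {
  assert_that(length(values_a) >= 1 && length(values_b) >= 1,
              "invalid input: both samples must be non-empty")
  ht <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  res <- list(d = unname(ht$statistic), p_value = ht$p.value,
              n_a = length(values_a), n_b = length(values_b))
  class(res) <- "ks_result"
  res
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level in (0, 1).
#' @param seed Optional seed.
#' @return Named numeric vector `c(lower, upper)` with attribute `mean`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 2000L, level = 0.95, seed = NULL) {
  assert_that(length(values) >= 1, "invalid input: values must be non-empty")
  assert_that(level > 0 && level < 1, "invalid input: level must be in (0, 1)")
  n <- length(values)
  means <- with_seed(seed, {
    colMeans(matrix(sample(values, n * n_boot, replace = TRUE), nrow = n))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(means, probs = c(alpha, 1 - alpha), names = FALSE)
  names(ci) <- c("lower", "upper")
  attr(ci, "mean") <- mean(values)
  ci
}

#' Paired t test
#'
#' Standard paired t on the element-wise differences, df = n - 1. A
#' zero-variance difference vector is flagged degenerate: t = 0 when all
#' differences are zero, +/- Inf otherwise.
#'
#' @param values_a,values_b Equal-length numeric vectors (n >= 2).
#' @return List with `t`, `df`, `p_value`, `mean_difference`, `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  assert_that(length(values_a) == length(values_b),
              "invalid input: paired samples must have equal length")
  n <- length(values_a)
  assert_that(n >= 2, "invalid input: need at least 2 pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    t_val <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_val, df = n - 1L,
                p_value = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = unname(ht$estimate),
       degenerate = FALSE)
}

#' Pearson correlation with both df conventions
#'
#' Reports the conventional df = n - 2 inference, plus the p-value under the
#' df = n - 1 convention that some clinical reports use when quoting r(n-1).
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return List with `r`, `df`, `p_value`, `df_alt`, `p_value_alt`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  assert_that(length(x) == length(y), "invalid input: x and y must have equal length")
  n <- length(x)
  assert_that(n >= 3, "invalid input: need at least 3 observations")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "degenerate input: correlation undefined for constant input")
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  df_alt <- n - 1L
  p_alt <- if (1 - r^2 < .Machine$double.eps) 0 else {
    t_alt <- r * sqrt(df_alt / (1 - r^2))
    2 * stats::pt(-abs(t_alt), df_alt)
  }
  list(r = r, df = unname(ht$parameter), p_value = ht$p.value,
       df_alt = df_alt, p_value_alt = p_alt, n = n)
}

#' Bonferroni-corrected per-comparison threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_that(alpha > 0 && alpha < 1, "invalid input: alpha must be in (0, 1)")
  assert_that(is_count(m), "invalid input: m must be a positive integer")
  alpha / m
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: stat = %.4g, p = %.4g (%s, %d assignments)\n",
              x$observed_stat, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: d = %.4g, p = %.4g (n = %d vs %d)\n",
              x$d, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
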