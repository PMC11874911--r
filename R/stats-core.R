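#' @keywords internal
test_result <- function(statistic, p_value, method, n_a, n_b,
                        seed = NA_integer_, degenerate = FALSE) {
  out <- tibble(
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    method = method,
    n_a = as.integer(n_a),
    n_b = as.integer(n_b),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    degenerate = degenerate
  )
  class(out) <- c("tx_test", class(out))
  out
}

#' Two-sided Welch t-test
#'
#' Thin wrapper around [stats::t.test()] returning the package's uniform
#' one-row test-result tibble.
#'
#' @param a,b Numeric vectors (each of length >= 3).
#' @return A one-row tibble with `statistic`, `p_value`, `method`, `n_a`,
#'   `n_b`, `seed`, `degenerate`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_result(0, 1, "welch_t", length(a), length(b), degenerate = TRUE))
    }
    return(test_result(sign(mean(a) - mean(b)) * Inf, .Machine$double.xmin,
                       "welch_t", length(a), length(b), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  test_result(unname(ht$statistic), ht$p.value, "welch_t", length(a), length(b))
}

#' Two-sided paired t-test
#'
#' All-zero paired differences return `p = 1` with the degenerate flag set;
#' constant nonzero differences (zero variance) return the smallest
#' representable p-value rather than failing.
#'
#' @param a,b Paired numeric vectors of equal length (>= 2).
#' @return A one-row test-result tibble (see [welch_t()]).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (all(d == 0)) {
    return(test_result(0, 1, "paired_t", length(a), length(b), degenerate = TRUE))
  }
  if (stats::sd(d) == 0) {
    return(test_result(sign(mean(d)) * Inf, .Machine$double.xmin,
                       "paired_t", length(a), length(b), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  test_result(unname(ht$statistic), ht$p.value, "paired_t", length(a), length(b))
}

#' Two-sided Wilcoxon test (rank-sum or signed-rank)
#'
#' Uses the exact distribution for small samples (max group size <= 25 and
#' no ties) and the normal approximation with continuity correction
#' otherwise.
#'
#' @param a,b Numeric vectors; equal length when `paired = TRUE`.
#' @param paired Signed-rank on paired differences (`TRUE`) or rank-sum
#'   (`FALSE`, default).
#' @return A one-row test-result tibble (see [welch_t()]).
#' @export
wilcoxon_rank <- function(a, b, paired = FALSE) {
  if (paired) {
    stopifnot(length(a) == length(b))
    d <- a - b
    if (all(d == 0)) {
      return(test_result(0, 1, "wilcoxon_signed_rank",
                         length(a), length(b), degenerate = TRUE))
    }
  }
  exact <- max(length(a), length(b)) <= 25 && !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact, correct = TRUE)
  )
  test_result(unname(ht$statistic), ht$p.value,
              if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum",
              length(a), length(b))
}

#' Seeded two-group permutation test
#'
#' Computes an observed two-sample statistic and its null distribution over
#' `n_perm` random permutations of the pooled group labels; the two-sided
#' p-value uses the add-one rule `p = (1 + #{|s_perm| >= |s_obs|}) /
#' (n_perm + 1)`, so it is never exactly zero. Built-in statistics are the
#' Welch t (`"welch_t"`) and the Pearson correlation between values and group
#' membership (`"pearson"`, the point-biserial reading of a
#' "permutation-based t-test (Pearson)"); any function `f(a, b) -> scalar`
#' can be supplied instead.
#'
#' @param a,b Numeric vectors.
#' @param statistic `"welch_t"`, `"pearson"`, or a function of two vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; `NULL` uses the ambient RNG state.
#' @return A one-row test-result tibble (see [welch_t()]).
#' @export
permutation_engine <- function(a, b, statistic = "welch_t",
                               n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 100)
  method <- if (is.function(statistic)) "permutation_custom"
            else paste0("permutation_", match.arg(statistic, c("welch_t", "pearson")))
  stat_fn <- if (is.function(statistic)) {
    statistic
  } else if (identical(statistic, "pearson")) {
    function(x, y) {
      g <- c(rep(0, length(x)), rep(1, length(y)))
      v <- c(x, y)
      if (stats::sd(v) == 0) return(0)
      stats::cor(v, g)
    }
  } else {
    function(x, y) {
      vx <- stats::var(x); vy <- stats::var(y)
      se <- sqrt(vx / length(x) + vy / length(y))
      if (se == 0) return(0)
      (mean(x) - mean(y)) / se
    }
  }
  pooled <- c(a, b)
  n_a <- length(a)
  if (stats::sd(pooled) == 0) {
    return(test_result(0, 1, method, n_a, length(b), seed, degenerate = TRUE))
  }
  s_obs <- stat_fn(a, b)
  with_seed_maybe(seed, {
    s_perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n_a)
      stat_fn(pooled[idx], pooled[-idx])
    }, numeric(1))
    p <- (1 + sum(abs(s_perm) >= abs(s_obs))) / (n_perm + 1)
    test_result(s_obs, p, method, n_a, length(b), seed)
  })
}

#' Empirical type-I error rate of a two-group test
#'
#' Calibration harness: draws `n_rep` null datasets from `generator(n)`
#' (both groups from the same distribution), applies `test_fn(a, b)`, and
#' returns the rejection rate at `alpha`. A well-calibrated test lands near
#' `alpha`.
#'
#' @param test_fn Function of two vectors returning a test-result tibble (or
#'   anything with a `p_value` element).
#' @param generator Function of a single integer `n` returning a numeric
#'   vector of draws; default standard normal.
#' @param n Per-group sample size.
#' @param n_rep Number of null replicates (default 200).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return A list with `rate`, `n_rep`, `alpha`, and the vector `p_values`.
#' @export
calibrate_type1 <- function(test_fn, generator = stats::rnorm, n = 50,
                            n_rep = 200, alpha = 0.05, seed = NULL) {
  with_seed_maybe(seed, {
    p_values <- vapply(seq_len(n_rep), function(i) {
      res <- test_fn(generator(n), generator(n))
      as.numeric(res$p_value[[1L]])
    }, numeric(1))
    list(rate = mean(p_values <= alpha), n_rep = n_rep, alpha = alpha,
         p_values = p_values)
  })
}
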