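# Resampling inference: with-replacement exceedance test, permutation ANOVA,
# rank-sum comparison, and bootstrap effect sizes. All resampling operations
# are deterministic given a seed and use the add-one p-value convention
# p = (exceedances + 1) / (resamples + 1), which keeps p in (0, 1].

.resampling_result <- function(observed, n_resamples, exceedance_count,
                               seed, extra = list()) {
  structure(
    c(list(observed = observed, n_resamples = n_resamples,
           exceedance_count = exceedance_count,
           p_value = (exceedance_count + 1) / (n_resamples + 1),
           seed = seed), extra),
    class = "resampling_result"
  )
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "Resampling test: observed %.4g, %d/%d resamples at or beyond, p = %.4g\n",
    x$observed, x$exceedance_count, x$n_resamples, x$p_value))
  invisible(x)
}

#' Exceedance test for a small target group against a pooled null
#'
#' Pools the activation calls of both groups, draws `n_resamples` samples of
#' the target-group size with replacement from the pool, and counts how many
#' resampled fractions reach or exceed (inclusive) the observed target
#' fraction. A target group whose fraction is never matched among the
#' resamples yields the minimum attainable p-value
#' `1 / (n_resamples + 1)`.
#'
#' @param target_group Logical (or 0/1) calls for the target group.
#' @param reference_group Logical (or 0/1) calls for the reference group.
#' @param n_resamples Number of with-replacement resamples (at least 100).
#' @param seed Integer seed.
#' @return A `resampling_result`; `observed` is the target fraction.
#' @export
exceedance_test <- function(target_group, reference_group,
                            n_resamples = 5000, seed = 1L) {
  target_group <- .as_calls(target_group, "target_group")
  reference_group <- .as_calls(reference_group, "reference_group")
  if (n_resamples < 100) stop("n_resamples must be at least 100")
  pool <- c(target_group, reference_group)
  k <- length(target_group)
  observed <- mean(target_group)
  fracs <- withr::with_seed(as.integer(seed), {
    draws <- matrix(sample(pool, k * n_resamples, replace = TRUE),
                    nrow = n_resamples)
    rowMeans(draws)
  })
  .resampling_result(observed, n_resamples,
                     sum(fracs >= observed - 1e-12), as.integer(seed),
                     extra = list(pool_fraction = mean(pool), n_target = k))
}

.as_calls <- function(x, what) {
  if (is.data.frame(x)) x <- x$called
  x <- as.logical(x)
  if (length(x) == 0 || anyNA(x)) {
    stop(what, " must be a non-empty vector of binary calls")
  }
  x
}

# weighted between-group sum of squares of group means about the grand mean
.between_ss <- function(values, g_idx, g_sizes) {
  grand <- mean(values)
  means <- vapply(g_idx, function(i) mean(values[i]), numeric(1))
  sum(g_sizes * (means - grand)^2)
}

#' Permutation ANOVA
#'
#' Tests whether two or more groups of per-cell values share a common
#' location. The statistic is the size-weighted between-group sum of squares
#' of group means about the grand mean (equivalent in ordering to the F
#' statistic under label permutation); group labels are permuted `n_perm`
#' times and the add-one p-value counts permutations whose statistic reaches
#' the observed one.
#'
#' @param groups List of two or more numeric vectors, each of length >= 2.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return A `resampling_result`; `observed` is the between-group SS.
#' @export
permutation_anova <- function(groups, n_perm = 5000, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group must contain at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  stopifnot(is.numeric(values), !anyNA(values))
  n <- length(values)
  g_idx <- split(seq_len(n), rep(seq_along(groups), sizes))
  obs <- .between_ss(values, g_idx, sizes)
  count <- withr::with_seed(as.integer(seed), {
    stats <- vapply(seq_len(n_perm), function(i) {
      .between_ss(values[sample.int(n)], g_idx, sizes)
    }, numeric(1))
    sum(stats >= obs - 1e-12)
  })
  .resampling_result(obs, n_perm, count, as.integer(seed),
                     extra = list(group_sizes = sizes))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mid-ranks are used for ties. When both samples have at most 8 values the
#' null distribution is enumerated exactly over all group assignments of the
#' observed ranks; otherwise the normal approximation with tie correction
#' and continuity correction is used. Two constant identical samples give
#' p = 1.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return List with `statistic` (rank sum of `sample_a`, named `W` as the
#'   Mann-Whitney U of sample_a is `statistic - n_a (n_a + 1) / 2`),
#'   `p_value`, and `method`.
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  stopifnot(is.numeric(sample_a), is.numeric(sample_b),
            length(sample_a) >= 1, length(sample_b) >= 1,
            !anyNA(sample_a), !anyNA(sample_b))
  na <- length(sample_a); nb <- length(sample_b)
  r <- rank(c(sample_a, sample_b)) # mid-ranks for ties
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (na + nb + 1) / 2
  if (na <= 8 && nb <= 8) {
    combos <- utils::combn(na + nb, na)
    w_all <- colSums(matrix(r[combos], nrow = na))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
    method <- "exact enumeration (mid-ranks)"
  } else {
    n <- na + nb
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2) # continuity correction
      z <- max(z, 0)
      p <- 2 * stats::pnorm(z, lower.tail = FALSE)
      p <- min(p, 1)
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = c(W = w_obs), p_value = p, method = method)
}

#' Bootstrap difference in fraction activated, in percentage points
#'
#' Difference of activated fractions between two groups of calls, with a
#' bootstrap standard error from independent with-replacement resampling
#' within each group. Reported in percentage points (a difference of 0.79
#' is returned as 79).
#'
#' @param calls_a,calls_b Logical (or 0/1) calls, or per-cell tables with a
#'   `called` column.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `difference_pp`, `se_pp`, `fraction_a`, `fraction_b`,
#'   `n_a`, `n_b`.
#' @export
effect_size_difference <- function(calls_a, calls_b, n_boot = 5000,
                                   seed = 1L) {
  a <- .as_calls(calls_a, "calls_a")
  b <- .as_calls(calls_b, "calls_b")
  na <- length(a); nb <- length(b)
  diffs <- withr::with_seed(as.integer(seed), {
    fa <- rowMeans(matrix(sample(a, na * n_boot, replace = TRUE),
                          nrow = n_boot))
    fb <- rowMeans(matrix(sample(b, nb * n_boot, replace = TRUE),
                          nrow = n_boot))
    fa - fb
  })
  list(
    difference_pp = 100 * (mean(a) - mean(b)),
    se_pp = 100 * stats::sd(diffs),
    fraction_a = mean(a), fraction_b = mean(b),
    n_a = na, n_b = nb, n_boot = n_boot, seed = as.integer(seed)
  )
}

#' Bootstrap percent change in median ratio
#'
#' Percent change of the median nuclear/cytoplasmic ratio from group A to
#' group B, `100 * (median_b - median_a) / median_a`, with a bootstrap
#' standard error from independent resampling within each group.
#'
#' @param group_a,group_b Numeric ratio samples, each with at least 5 values.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `percent_change`, `se`, `median_a`, `median_b`.
#' @export
median_ratio_effect <- function(group_a, group_b, n_boot = 5000, seed = 1L) {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 5, length(group_b) >= 5,
            !anyNA(group_a), !anyNA(group_b))
  ma <- stats::median(group_a)
  if (ma == 0) stop("median of group_a is zero; percent change undefined")
  mb <- stats::median(group_b)
  na <- length(group_a); nb <- length(group_b)
  changes <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      bma <- stats::median(sample(group_a, na, replace = TRUE))
      bmb <- stats::median(sample(group_b, nb, replace = TRUE))
      100 * (bmb - bma) / bma
    }, numeric(1))
  })
  list(percent_change = 100 * (mb - ma) / ma, se = stats::sd(changes),
       median_a = ma, median_b = mb, n_boot = n_boot,
       seed = as.integer(seed))
}
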