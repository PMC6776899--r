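#' Exact Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sample location test computed, whenever feasible, by full enumeration
#' of all `choose(n1 + n2, n1)` assignments of the pooled mid-ranks to the
#' first sample. Ties receive mid-ranks both in the observed statistic and in
#' the enumeration, so the exact p-value is the permutation p-value of the
#' rank-sum statistic. Above the enumeration cap of 2e5 combinations the
#' tie-corrected, continuity-corrected normal approximation is used instead.
#'
#' For two completely separated samples the minimal attainable one-sided
#' p-value is `1 / choose(n1 + n2, n1)`: 1/126 = 0.0079 for sizes 4 and 5,
#' 1/252 = 0.004 for sizes 5 and 5.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger than y) or
#'   `"less"`. The two-sided p is `min(1, 2 * min(one-sided))`.
#' @param enumeration_cap Maximum number of combinations to enumerate
#'   exactly.
#' @return A `rank_sum_test` list: `U` (Mann-Whitney statistic for x), `W`
#'   (rank sum of x), `p_value`, `method` (`"exact-enumeration"` or
#'   `"normal-approximation"`), `alternative`, `n1`, `n2`.
#' @examples
#' rank_sum_exact(c(1, 2, 3, 4), c(5, 6, 7, 8, 9), alternative = "less")$p_value
#' @export
rank_sum_exact <- function(x, y,
                           alternative = c("two.sided", "greater", "less"),
                           enumeration_cap = 2e5) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  r <- rank(c(x, y)) # mid-ranks for ties
  W_obs <- sum(r[seq_len(n1)])
  U_obs <- W_obs - n1 * (n1 + 1) / 2
  eps <- 1e-9
  if (choose(N, n1) <= enumeration_cap) {
    combs <- utils::combn(N, n1)
    W_all <- colSums(matrix(r[combs], nrow = n1))
    p_greater <- mean(W_all >= W_obs - eps)
    p_less <- mean(W_all <= W_obs + eps)
    method <- "exact-enumeration"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    sigma <- sqrt(sigma2)
    p_greater <- stats::pnorm((W_obs - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((W_obs + 0.5 - mu) / sigma)
    method <- "normal-approximation"
  }
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
  structure(
    list(
      U = U_obs, W = W_obs, p_value = p, method = method,
      alternative = alternative, n1 = n1, n2 = n2
    ),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Wilcoxon rank-sum test (", x$method, ")\n", sep = "")
  cat(sprintf(
    "  n1 = %d, n2 = %d, U = %.1f, W = %.1f\n  alternative = %s, p = %.6g\n",
    x$n1, x$n2, x$U, x$W, x$alternative, x$p_value
  ))
  invisible(x)
}

#' Tidy a rank-sum test
#'
#' @param x A `rank_sum_test`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, p-value and metadata.
#' @method tidy rank_sum_test
#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$U, W = x$W, p.value = x$p_value,
    method = x$method, alternative = x$alternative,
    n1 = x$n1, n2 = x$n2
  )
}

#' Compare two groups in a tidy table with the exact rank-sum test
#'
#' Convenience wrapper for long-format data: splits `value` by the two
#' levels of `group` (first level plays the role of x) and runs
#' [rank_sum_exact()].
#'
#' @param data A data frame.
#' @param group,value Column names (strings) of the grouping factor (exactly
#'   two levels) and the response.
#' @param alternative Passed to [rank_sum_exact()].
#' @return A one-row tidy tibble (see [tidy.rank_sum_test()]) with the group
#'   labels attached.
#' @export
compare_groups <- function(data, group = "group", value = "value",
                           alternative = "two.sided") {
  data <- tibble::as_tibble(data)
  g <- data[[group]]
  lv <- unique(g)
  if (length(lv) != 2) {
    stop("`", group, "` must have exactly two levels, found ", length(lv),
      call. = FALSE
    )
  }
  res <- rank_sum_exact(
    data[[value]][g == lv[1]], data[[value]][g == lv[2]],
    alternative = alternative
  )
  dplyr::mutate(tidy(res),
    group1 = as.character(lv[1]), group2 = as.character(lv[2])
  )
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Tests whether a sample is consistent with a normal distribution by
#' z-scoring the data and computing the supremum distance between the
#' empirical CDF and the standard normal CDF, with the asymptotic Kolmogorov
#' p-value. This is the plain one-sample KS test (no Lilliefors correction
#' for estimating the mean and sd from the data), which is known to be
#' anti-conservative; it mirrors the pre-test commonly used to decide
#' between parametric and rank-based two-sample tests.
#'
#' @param x Numeric sample, `n >= 3`, non-constant.
#' @return A list with `statistic` (D), `p_value` and `n`.
#' @export
ks_normality <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("ks_normality requires n >= 3", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: sample is constant", call. = FALSE)
  }
  z <- sort((x - mean(x)) / s)
  Fz <- stats::pnorm(z)
  D <- max(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n)
  # asymptotic Kolmogorov distribution with small-sample adjustment
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = D, p_value = min(max(p, 0), 1), n = n)
}

#' Mean and standard deviation summary
#'
#' The reporting convention used throughout: sample mean with the n-1
#' standard deviation, which is 0 for a single observation.
#'
#' @param x Non-empty numeric vector.
#' @return A one-row tibble with `mean`, `sd`, `n`.
#' @export
summarize_mean_sd <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1) stop("empty sample", call. = FALSE)
  tibble::tibble(
    mean = mean(x),
    sd = if (length(x) == 1) 0 else stats::sd(x),
    n = length(x)
  )
}

#' Fold change between two rates
#'
#' @param a,b Numerator and denominator (b != 0).
#' @return A list with `ratio` and a nearest-integer `label` such as
#'   `"3-fold"`.
#' @export
fold_change <- function(a, b) {
  if (!is.finite(b) || b == 0) stop("denominator must be nonzero", call. = FALSE)
  ratio <- a / b
  list(ratio = ratio, label = sprintf("%d-fold", round(ratio)))
}
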