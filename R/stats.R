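#' Exact Mann-Whitney U comparison of two groups
#'
#' Computes the Mann-Whitney U statistic from mid-ranks and a two-sided
#' p-value. For small samples (`n_a + n_b <= max_exact`, default 12) the
#' p-value is exact by full enumeration over all `choose(n_a + n_b, n_a)`
#' assignments of the observed pooled values to the groups — this handles
#' ties correctly, since the enumeration permutes the observed multiset.
#' The one-tailed arrangement count at least as extreme as observed is
#' doubled and capped at 1. Larger samples use the normal approximation
#' with the tie-corrected variance.
#'
#' Complete separation at n = 4 vs 4 gives the smallest attainable
#' two-sided p, 2 / choose(8, 4) = 2/70 = 0.0286.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact `TRUE`, `FALSE`, or `NULL` (default) to decide by
#'   `n_a + n_b <= max_exact`.
#' @param max_exact Total size up to which enumeration is used.
#' @return A `group_comparison` list: `u_statistic` (U of group `a`),
#'   `p_two_sided`, `n_a`, `n_b`, `method` (`"exact"` or `"asymptotic"`).
#' @export
mann_whitney_exact <- function(a, b, exact = NULL, max_exact = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("values must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (is.null(exact)) exact <- n <= max_exact

  if (exact) {
    idx <- utils::combn(n, na)
    csum <- colSums(matrix(r[idx], nrow = na))
    u_all <- csum - na * (na + 1) / 2
    eps <- 1e-9
    one_tail <- if (u_obs >= mu) mean(u_all >= u_obs - eps) else
      mean(u_all <= u_obs + eps)
    p <- min(1, 2 * one_tail)
    method <- "exact"
  } else {
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "asymptotic"
  }
  structure(list(u_statistic = u_obs, p_two_sided = p,
                 n_a = na, n_b = nb, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$u_statistic, x$n_a, x$n_b, x$p_two_sided, x$method))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation with the p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both with non-zero
#'   variance.
#' @return A `correlation_result` list: `r`, `p_two_sided`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (any(!is.finite(c(x, y)))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_two_sided = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.3f (n = %d), two-sided p = %.4g\n",
              x$r, x$n, x$p_two_sided))
  invisible(x)
}

#' Remove extreme outliers by the 1.5 x IQR fence
#'
#' Drops values more than `multiplier` interquartile ranges above the third
#' or below the first quartile (quartiles by linear interpolation, type 7).
#' A single pass by contract: the fences are computed once from the input.
#'
#' @param values Numeric vector.
#' @param multiplier Fence multiplier (default 1.5, as used with the
#'   box-plot outlier rule).
#' @return The filtered vector. With fewer than 4 values the input is
#'   returned unchanged with a warning.
#' @export
remove_extreme_outliers <- function(values, multiplier = 1.5) {
  values <- as.numeric(values)
  if (length(values) < 4) {
    warning("fewer than 4 values: returning input unchanged")
    return(values)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - multiplier * iqr & values <= q[2] + multiplier * iqr]
}
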