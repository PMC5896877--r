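#' @importFrom stats pchisq pt quantile sd var
NULL

new_test_result <- function(method, statistic, df, p_value, n,
                            extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, df = df,
           p_value = p_value, n = n), extra),
    class = "icms_test"
  )
}

#' @export
print.icms_test <- function(x, ...) {
  df_txt <- if (length(x$df) == 2)
    sprintf("(%g, %g)", x$df[1], x$df[2]) else sprintf("(%g)", x$df)
  cat(sprintf("%s: statistic = %.4g, df %s, p = %.4g, n = %s\n",
              x$method, x$statistic, df_txt, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Nonparametric one-way ANOVA on ranks. Because stimulation amplitudes
#' take a handful of discrete levels, samples are heavily tied; the H
#' statistic is therefore divided by the standard tie-correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size `t`. The p-value
#' uses the chi-square approximation with `k - 1` degrees of freedom. The
#' result also carries `N - k`, so the common `(k - 1, N - k)`
#' degrees-of-freedom display convention is recoverable.
#'
#' @param groups List of numeric vectors, one per group (>= 2 non-empty
#'   groups, total n >= 3).
#' @return An `icms_test` with `statistic` (tie-corrected H), `df = k - 1`,
#'   `p_value`, per-group `n`, and `n_minus_k`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) stop("empty group supplied", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("NA values not allowed", call. = FALSE)
  N <- length(x)
  if (N < 3) stop("need total n >= 3", call. = FALSE)
  k <- length(groups)
  g <- rep(seq_len(k), sizes)
  r <- rank(x) # average ranks for ties
  R <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction <= 0) {
    # every observation identical: no evidence of any difference
    H <- 0
    p <- 1
  } else {
    H <- H / correction
    H <- max(H, 0) # guard tiny negative rounding
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  new_test_result("kruskal_wallis", H, k - 1L, p, sizes,
                  extra = list(n_minus_k = N - k))
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return An `icms_test` with `statistic = r`, `df = n - 2` and a
#'   two-sided p-value from the exact t transform
#'   `t = r * sqrt((n - 2) / (1 - r^2))`.
#' @export
#' @examples
#' pearson_corr(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- sum(sx * sy) / sqrt(vx * vy)
  r <- max(min(r, 1), -1)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  new_test_result("pearson", r, n - 2L, p, n)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D`, the supremum distance between the two empirical CDFs, by a
#' merge over the pooled sorted values, with the two-sided p-value from the
#' asymptotic Kolmogorov distribution (with the standard small-sample
#' effective-n refinement of the argument).
#'
#' @param x,y Non-empty numeric samples.
#' @return An `icms_test` with `statistic = D` and sample sizes `n`.
#' @export
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50, 2))
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty",
                               call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  ex <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  ey <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  D <- max(abs(ex - ey))
  en <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(en) + 0.12 + 0.11 / sqrt(en)) * D
  p <- kolmogorov_q(lambda)
  new_test_result("ks_two_sample", D, NA_integer_, p, c(n1, n2))
}

# Asymptotic two-sided Kolmogorov tail Q(lambda) = 2 sum (-1)^(k-1)
# exp(-2 k^2 lambda^2), clipped to [0, 1].
kolmogorov_q <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(q, 0), 1)
}

#' Dunn-Sidak multiple-comparisons correction
#'
#' Adjusts p-values for `m` independent comparisons:
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`. Monotone in `p` and never
#' larger than the Bonferroni adjustment `m * p`.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (defaults to `length(p_values)`).
#' @return Adjusted p-values.
#' @export
#' @examples
#' dunn_sidak(c(0.01, 0.04), m = 3)
dunn_sidak <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(pmax(1 - (1 - p_values)^m, 0), 1)
}

#' First-order polynomial (least squares) fit
#'
#' Ordinary least-squares straight line through `(x, y)`, computed in
#' closed form from centred sums.
#'
#' @param x,y Numeric vectors of equal length with >= 2 distinct `x`.
#' @return Named numeric `c(slope, intercept)`.
#' @export
#' @examples
#' polyfit1(c(20, 100), c(2.4, 4.0)) # slope 0.02
polyfit1 <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2) {
    stop("degenerate fit: need at least two distinct x", call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(slope = slope, intercept = my - slope * mx)
}

#' Gaussian kernel density estimate
#'
#' Plain Gaussian-kernel KDE with Silverman's rule-of-thumb bandwidth
#' `0.9 * min(sd, IQR / 1.34) * n^(-1/5)` by default. Used for amplitude
#' distributions and bootstrap-slope distributions.
#'
#' @param values Numeric sample (>= 2 values, positive variance).
#' @param bandwidth Optional positive bandwidth override.
#' @param n_grid Number of evaluation points.
#' @param cut Grid extension beyond the data range, in bandwidths.
#' @return List of class `icms_kde` with `x` (grid), `y` (density),
#'   `bandwidth`, and `n`.
#' @export
#' @examples
#' kde <- gaussian_kde(rnorm(500))
#' sum(diff(kde$x) * (head(kde$y, -1) + tail(kde$y, -1)) / 2) # ~1
gaussian_kde <- function(values, bandwidth = NULL, n_grid = 512L,
                         cut = 5) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least two values", call. = FALSE)
  if (is.null(bandwidth)) {
    s <- sd(values)
    iqr <- unname(diff(quantile(values, c(0.25, 0.75))))
    spread <- min(s, iqr / 1.34)
    if (spread == 0) spread <- s
    if (spread == 0) {
      stop(paste("constant sample: no data-driven bandwidth exists;",
                 "supply `bandwidth` explicitly"), call. = FALSE)
    }
    bandwidth <- 0.9 * spread * n^(-1 / 5)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  grid <- seq(min(values) - cut * bandwidth,
              max(values) + cut * bandwidth, length.out = n_grid)
  y <- vapply(grid, function(g) {
    mean(stats::dnorm((g - values) / bandwidth)) / bandwidth
  }, numeric(1))
  structure(list(x = grid, y = y, bandwidth = bandwidth, n = n),
            class = "icms_kde")
}

#' Evaluate a fitted KDE on new points
#'
#' @param object An `icms_kde` object.
#' @param x Points at which to interpolate the density.
#' @param ... Unused.
#' @return Densities at `x` (linear interpolation on the KDE grid; 0
#'   outside).
#' @export
predict.icms_kde <- function(object, x, ...) {
  stats::approx(object$x, object$y, xout = x, yleft = 0, yright = 0)$y
}
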