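# Independent brute-force oracles for the core statistics. These are
# deliberately naive re-derivations from the defining formulas (explicit
# sort-based ranks, direct ECDF enumeration, raw-moment arithmetic) and
# share no code with the package implementations they check.

# Midranks from the counting definition: rank = (#smaller) + (#tied + 1)/2.
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Tie-corrected Kruskal-Wallis H and p from the textbook formula.
oracle_kw <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  r <- oracle_ranks(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (N + 1)
  tie_sizes <- as.numeric(table(x))
  C <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  H <- H / C
  list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Pearson r from raw sums, p from the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  r <- num / den
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# KS D by brute force over every observed threshold.
oracle_ks_D <- function(x, y) {
  max(vapply(c(x, y), function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# OLS line from the normal equations on raw sums.
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  c(slope = slope, intercept = (sum(y) - slope * sum(x)) / n)
}
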