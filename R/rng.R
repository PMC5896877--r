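#' Derive a named sub-seed from a master seed
#'
#' All stochastic components of the package (electrode population, schedule
#' construction, per-trial responses, impedance snapshots, resampling) draw
#' their randomness from independent streams keyed by a short name, so that
#' changing e.g. the schedule does not perturb the response stream. The
#' derivation is a small deterministic string hash folded into the master
#' seed; it stays within the 32-bit range `set.seed()` accepts.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name, e.g. `"responses"`.
#' @return An integer seed, deterministic in `(seed, stream)`.
#' @export
#' @examples
#' derive_seed(1L, "population")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1; all arithmetic stays exact in doubles
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer(((seed %% m) * 48271 + h) %% m)
}

# Evaluate `code` under a temporary RNG seeded with `seed`; NULL seed means
# use (and advance) the caller's RNG state.
with_stream <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
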