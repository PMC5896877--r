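#' @importFrom stats rhyper
NULL

#' Bootstrap modality proportions against amplitude
#'
#' Resamples detected responses to de-bias the uneven distribution of
#' reports across amplitudes: each iteration draws a fixed number of
#' responses (default 15) at every amplitude from that amplitude's pooled
#' responses, computes the percentage of proprioceptive and cutaneous
#' reports per amplitude, and fits a first-order polynomial of percentage
#' versus amplitude for each modality. The slope distributions (percentage
#' points per microamp) summarize how strongly modality composition shifts
#' with amplitude; their kernel density estimates are returned for
#' plotting.
#'
#' Draws are with replacement by default (the standard bootstrap, which
#' also tolerates pools smaller than the draw count); a without-replacement
#' mode is available when every pool is large enough.
#'
#' @param responses Tibble of detected responses with `amplitude_uA` and
#'   `modality` (`"cutaneous"`/`"proprioceptive"`).
#' @param amplitudes Amplitude levels to resample at (default: the sorted
#'   distinct amplitudes present).
#' @param n_iter Bootstrap iterations.
#' @param draws_per_amplitude Responses drawn per amplitude per iteration.
#' @param replace Draw with replacement?
#' @param seed Optional stream seed.
#' @return An `icms_bootstrap` list: `amplitudes`, `pool_n`, `pool_pct_prop`,
#'   `median_pct_prop`, `median_pct_cut`, `slopes_prop`, `slopes_cut`,
#'   `kde_prop`, `kde_cut`, `n_iter`, `draws_per_amplitude`.
#' @export
bootstrap_modality_slopes <- function(responses, amplitudes = NULL,
                                      n_iter = 10000L,
                                      draws_per_amplitude = 15L,
                                      replace = TRUE, seed = NULL) {
  stopifnot(all(c("amplitude_uA", "modality") %in% names(responses)))
  responses <- responses[responses$modality %in%
                           c("cutaneous", "proprioceptive"), ]
  if (is.null(amplitudes)) {
    amplitudes <- sort(unique(responses$amplitude_uA))
  }
  pools <- lapply(amplitudes, function(a) {
    responses$modality[responses$amplitude_uA == a]
  })
  empty <- amplitudes[vapply(pools, length, integer(1)) == 0]
  if (length(empty)) {
    stop("no responses at amplitude(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  pool_n <- vapply(pools, length, integer(1))
  n_prop <- vapply(pools, function(p) sum(p == "proprioceptive"),
                   integer(1))
  if (!replace && any(pool_n < draws_per_amplitude)) {
    stop("without-replacement draws need >= ", draws_per_amplitude,
         " responses at every amplitude", call. = FALSE)
  }

  with_stream(seed, {
    # Drawing `k` responses from a pool and counting proprioceptive ones is
    # binomial (with replacement) or hypergeometric (without); sampling the
    # counts directly is draw-for-draw equivalent and fully vectorized.
    k <- draws_per_amplitude
    pct_prop <- matrix(NA_real_, n_iter, length(amplitudes))
    for (j in seq_along(amplitudes)) {
      cnt <- if (replace) {
        rbinom(n_iter, k, n_prop[j] / pool_n[j])
      } else {
        rhyper(n_iter, n_prop[j], pool_n[j] - n_prop[j], k)
      }
      pct_prop[, j] <- 100 * cnt / k
    }
    xc <- amplitudes - mean(amplitudes)
    sxx <- sum(xc^2)
    slopes_prop <- as.numeric(pct_prop %*% xc) / sxx
    slopes_cut <- as.numeric((100 - pct_prop) %*% xc) / sxx

    kde_or_null <- function(s) {
      if (length(unique(s)) < 2) NULL else gaussian_kde(s)
    }
    structure(
      list(
        amplitudes = amplitudes,
        pool_n = pool_n,
        pool_pct_prop = 100 * n_prop / pool_n,
        median_pct_prop = apply(pct_prop, 2, stats::median),
        median_pct_cut = apply(100 - pct_prop, 2, stats::median),
        slopes_prop = slopes_prop,
        slopes_cut = slopes_cut,
        kde_prop = kde_or_null(slopes_prop),
        kde_cut = kde_or_null(slopes_cut),
        n_iter = as.integer(n_iter),
        draws_per_amplitude = as.integer(draws_per_amplitude),
        replace = replace
      ),
      class = "icms_bootstrap"
    )
  })
}

#' @export
print.icms_bootstrap <- function(x, ...) {
  cat("<icms_bootstrap>", x$n_iter, "iterations,", x$draws_per_amplitude,
      "draws per amplitude\n")
  cat(sprintf("  proprioceptive slope: median %.4f %%/uA (%.1f%% positive)\n",
              stats::median(x$slopes_prop), 100 * mean(x$slopes_prop > 0)))
  cat(sprintf("  cutaneous slope:      median %.4f %%/uA (%.1f%% negative)\n",
              stats::median(x$slopes_cut), 100 * mean(x$slopes_cut < 0)))
  invisible(x)
}

#' Permutation null for trial-history dependence
#'
#' Asks whether the probability of reporting a sensation depends on the
#' outcome of the preceding trial. For every amplitude the empirical
#' proportions of reports on trials following a hit and following a miss
#' are compared with a shuffle distribution obtained by permuting detection
#' outcomes across trial positions within each (session, amplitude) stratum
#' (holding per-stratum hit counts fixed) and recomputing the conditionals.
#' The first trial of each session has no predecessor and is excluded from
#' conditioning. A companion Kruskal-Wallis test compares detection
#' outcomes across the three conditions (all trials, after hit, after miss)
#' at each amplitude, with Dunn-Sidak correction across amplitudes.
#'
#' @param sessions Session tibble (catch trials are dropped from history
#'   conditioning unless `include_catch_as_miss`).
#' @param n_perm Number of permutations.
#' @param include_catch_as_miss Treat catch trials as forced-miss
#'   predecessors instead of removing them from the sequence.
#' @param seed Optional stream seed.
#' @return An `icms_history` list with `table` (per-amplitude empirical
#'   conditionals, 5th/95th percentile envelopes for display, and
#'   `within_envelope` flags computed from the empirical value's add-one
#'   percentile rank among the shuffle draws — the tie-safe form of the
#'   percentile-range criterion for a discrete null), `kw` (per-amplitude
#'   tests with `p_adjusted`), and `n_perm`.
#' @export
trial_history_null <- function(sessions, n_perm = 10000L,
                               include_catch_as_miss = FALSE,
                               seed = NULL) {
  t <- sessions[order(sessions$session_day, sessions$block,
                      sessions$trial_index), ]
  if (!include_catch_as_miss) t <- t[!t$is_catch, ]
  if (nrow(t) < 2) stop("need at least two trials", call. = FALSE)
  d <- as.integer(t$detected & !t$is_catch)
  amp <- t$amplitude_uA
  sess <- t$session_day
  n <- length(d)
  # position of the previous trial within the same session (NA for firsts)
  prev_pos <- c(NA_integer_, seq_len(n - 1L))
  prev_pos[c(TRUE, sess[-1] != sess[-n])] <- NA_integer_

  amps <- sort(unique(amp[!is.na(amp)]))
  amp_id <- match(amp, amps)
  n_amp <- length(amps)
  # catch predecessors are defined misses; catch rows themselves carry no
  # amplitude and never enter the per-amplitude conditionals
  cur_ok <- !is.na(amp_id)

  conditionals <- function(outcomes) {
    prev <- outcomes[prev_pos] # NA where no predecessor
    sel_hit <- cur_ok & !is.na(prev) & prev == 1L
    sel_miss <- cur_ok & !is.na(prev) & prev == 0L
    ph <- tabulate(amp_id[sel_hit & outcomes == 1L], n_amp) /
      tabulate(amp_id[sel_hit], n_amp)
    pm <- tabulate(amp_id[sel_miss & outcomes == 1L], n_amp) /
      tabulate(amp_id[sel_miss], n_amp)
    list(hit = ph, miss = pm)
  }
  emp <- conditionals(d)
  n_after_hit <- tabulate(amp_id[cur_ok & !is.na(d[prev_pos]) &
                                   d[prev_pos] == 1L], n_amp)
  n_after_miss <- tabulate(amp_id[cur_ok & !is.na(d[prev_pos]) &
                                    d[prev_pos] == 0L], n_amp)

  strata <- split(seq_len(n),
                  interaction(sess, amp, drop = TRUE))
  null_hit <- matrix(NA_real_, n_perm, n_amp)
  null_miss <- matrix(NA_real_, n_perm, n_amp)
  with_stream(seed, {
    for (b in seq_len(n_perm)) {
      d2 <- d
      for (s in strata) d2[s] <- d[s][sample.int(length(s))]
      cc <- conditionals(d2)
      null_hit[b, ] <- cc$hit
      null_miss[b, ] <- cc$miss
    }
  })

  # Envelope bounds are order statistics (inverse-ECDF quantiles) of the
  # shuffle distribution: the permutation null is discrete, and linear
  # interpolation between its atoms could exclude a boundary atom that the
  # percentile range should contain.
  q <- function(m, p) apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col)) unname(quantile(col, p, type = 1)) else NA_real_
  })
  tab <- tibble::tibble(
    amplitude_uA = amps,
    n_after_hit = n_after_hit,
    n_after_miss = n_after_miss,
    p_after_hit = emp$hit,
    p_after_miss = emp$miss,
    p_all = tabulate(amp_id[cur_ok & d == 1L], n_amp) /
      tabulate(amp_id[cur_ok], n_amp),
    hit_lo = q(null_hit, 0.05), hit_hi = q(null_hit, 0.95),
    miss_lo = q(null_miss, 0.05), miss_hi = q(null_miss, 0.95)
  )
  # The within-envelope flag is computed from the empirical value's rank
  # among the shuffle draws (add-one permutation percentile, ties counted
  # on both sides): "between the 5th and 95th percentile" of a discrete
  # permutation distribution is a rank statement, and the rank form keeps
  # the outside probability at or below 10% under exchangeability, which
  # interpolated sample quantiles do not guarantee.
  within_rank <- function(emp, null_m) {
    vapply(seq_along(emp), function(j) {
      if (is.na(emp[j])) return(NA)
      draws <- null_m[, j]
      draws <- draws[!is.na(draws)]
      if (!length(draws)) return(NA)
      p_lo <- (1 + sum(draws <= emp[j])) / (length(draws) + 1)
      p_hi <- (1 + sum(draws >= emp[j])) / (length(draws) + 1)
      p_lo > 0.05 && p_hi > 0.05
    }, logical(1))
  }
  tab$within_envelope_hit <- within_rank(tab$p_after_hit, null_hit)
  tab$within_envelope_miss <- within_rank(tab$p_after_miss, null_miss)

  # Kruskal-Wallis across the three trial-history conditions per amplitude
  prev <- d[prev_pos]
  kw_p <- rep(NA_real_, n_amp)
  kw_stat <- rep(NA_real_, n_amp)
  for (j in seq_len(n_amp)) {
    at <- cur_ok & amp_id == j
    groups <- list(all = d[at],
                   after_hit = d[at & !is.na(prev) & prev == 1L],
                   after_miss = d[at & !is.na(prev) & prev == 0L])
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups) < 2) next
    res <- kruskal_wallis(groups)
    kw_p[j] <- res$p_value
    kw_stat[j] <- res$statistic
  }
  kw <- tibble::tibble(amplitude_uA = amps, statistic = kw_stat,
                       p_value = kw_p,
                       p_adjusted = ifelse(is.na(kw_p), NA_real_,
                                           dunn_sidak(ifelse(is.na(kw_p),
                                                             0, kw_p),
                                                      m = sum(!is.na(kw_p)))))

  structure(list(table = tab, kw = kw, n_perm = as.integer(n_perm),
                 null_hit = null_hit, null_miss = null_miss),
            class = "icms_history")
}

#' @export
print.icms_history <- function(x, ...) {
  cat("<icms_history>", x$n_perm, "permutations\n")
  ok <- c(x$table$within_envelope_hit, x$table$within_envelope_miss)
  cat(sprintf("  conditionals within 5th-95th shuffle envelope: %d/%d\n",
              sum(ok, na.rm = TRUE), sum(!is.na(ok))))
  print(x$table[, c("amplitude_uA", "p_after_hit", "p_after_miss",
                    "p_all")])
  invisible(x)
}
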