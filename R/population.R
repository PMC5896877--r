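#' Generate an electrode population
#'
#' Builds the stimulable electrode profiles for a two-array implant: each
#' array is a 7x7 grid with 48 physically connected sites (one reference
#' site is unconnected and never stimulated). Each connected electrode
#' receives a baseline impedance, a responsiveness flag, detection and
#' modality parameters, and receptive-field weights concentrated on a home
#' (region, plane) cell drawn from its array's somatotopic weights.
#'
#' @param config An [simulation_config()] object.
#' @param seed Optional seed overriding `config$seed` for the population
#'   stream.
#' @return A tibble with one row per connected electrode: `electrode_id`,
#'   `array`, `row`, `col`, `connected`, `impedance_kohm`, `responsive`,
#'   `p_detect_base`, `detect_amp_slope`, `modality_beta0`,
#'   `modality_beta1`, and a `region_weights` list-column of named
#'   per-electrode weights.
#' @export
#' @examples
#' pop <- make_electrode_population(simulation_config(seed = 1))
#' table(pop$array)
make_electrode_population <- function(config = simulation_config(),
                                      seed = NULL) {
  stopifnot(inherits(config, "icms_config"))
  seed <- if (is.null(seed)) derive_seed(config$seed, "population") else seed
  g <- config$grid_dim
  arrays <- c("medial", "lateral")[seq_len(config$n_arrays)]

  with_stream(seed, {
    pieces <- lapply(seq_along(arrays), function(ai) {
      array <- arrays[ai]
      cells <- expand.grid(row = 0:(g - 1), col = 0:(g - 1))
      # one site per array is an unconnected reference channel
      n_off <- g^2 - config$connected_per_array
      off <- sample.int(g^2, n_off)
      keep <- setdiff(seq_len(g^2), off)
      aw_name <- if (array %in% names(config$region_weights)) array else
        names(config$region_weights)[1]
      aw <- config$region_weights[[aw_name]]
      n <- length(keep)

      # per-electrode generative parameters
      a <- config$p_detect_base_mean * config$p_detect_base_conc
      b <- (1 - config$p_detect_base_mean) * config$p_detect_base_conc
      p_base <- stats::rbeta(n, a, b)
      beta0 <- stats::rnorm(n, config$modality_beta0,
                            config$modality_beta0_sd)
      responsive <- stats::runif(n) < config$responsive_fraction
      impedance <- stats::rlnorm(n, config$impedance_meanlog,
                                 config$impedance_sdlog)
      home <- sample(names(aw), n, replace = TRUE, prob = aw)
      rc <- config$region_concentration
      rw <- lapply(home, function(h) {
        w <- (1 - rc) * aw
        w[h] <- w[h] + rc
        w
      })

      tibble::tibble(
        electrode_id = (ai - 1L) * config$connected_per_array + seq_len(n),
        array = array,
        row = cells$row[keep],
        col = cells$col[keep],
        connected = TRUE,
        impedance_kohm = impedance,
        responsive = responsive,
        p_detect_base = p_base,
        detect_amp_slope = config$detect_amp_slope,
        modality_beta0 = beta0,
        modality_beta1 = config$modality_beta1,
        region_weights = rw
      )
    })
    dplyr::bind_rows(pieces)
  })
}
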