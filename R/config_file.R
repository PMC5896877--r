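#' Read a structured plain-text configuration file
#'
#' Configuration lives in a YAML-style key-value file with per-module
#' sections (`simulation`, `design`, `resampling`); every generative and
#' design default of the package can be overridden there. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Config file path.
#' @return Named list with `simulation`, `design` and `resampling` lists.
#' @export
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("simulation:", "  seed: 4", "  responsive_fraction: 0.5"),
#'            cfg_file)
#' read_config_file(cfg_file)$simulation$responsive_fraction
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("simulation", "design", "resampling")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim_keys <- names(formals(simulation_config))
  bad <- setdiff(names(raw$simulation), sim_keys)
  if (length(bad)) {
    stop("unknown simulation key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(simulation = raw$simulation %||% list(),
       design = raw$design %||% list(),
       resampling = raw$resampling %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a simulator configuration from a config file
#'
#' @param path Config file path (see [read_config_file()]).
#' @param seed Optional seed overriding the file's value.
#' @return An [simulation_config()] object.
#' @export
simulation_config_from_file <- function(path, seed = NULL) {
  cfg <- read_config_file(path)
  args <- cfg$simulation
  if (!is.null(seed)) args$seed <- seed
  do.call(simulation_config, args)
}
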