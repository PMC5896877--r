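#' Session table column schema
#'
#' The canonical column set and order of the per-trial session CSV: one row
#' per scheduled trial, stimulation parameters and subject report side by
#' side, with the session's impedance snapshot for the stimulated
#' electrode. Missing values are written as empty fields.
#'
#' @return Character vector of column names, in file order.
#' @export
session_columns <- function() {
  c("experiment", "session_day", "block", "trial_index", "electrode_id",
    "array", "row", "col", "amplitude_uA", "frequency_hz",
    "pulse_width_us", "interphase_us", "duration_s", "is_catch",
    "detected", "modality", "descriptor", "region", "plane", "grid_cell",
    "intensity", "duration_category", "impedance_kohm")
}

session_col_types <- function() {
  readr::cols(
    experiment = readr::col_character(),
    session_day = readr::col_integer(),
    block = readr::col_integer(),
    trial_index = readr::col_integer(),
    electrode_id = readr::col_integer(),
    array = readr::col_character(),
    row = readr::col_integer(),
    col = readr::col_integer(),
    amplitude_uA = readr::col_double(),
    frequency_hz = readr::col_double(),
    pulse_width_us = readr::col_double(),
    interphase_us = readr::col_double(),
    duration_s = readr::col_double(),
    is_catch = readr::col_logical(),
    detected = readr::col_logical(),
    modality = readr::col_character(),
    descriptor = readr::col_character(),
    region = readr::col_character(),
    plane = readr::col_character(),
    grid_cell = readr::col_character(),
    intensity = readr::col_integer(),
    duration_category = readr::col_character(),
    impedance_kohm = readr::col_double()
  )
}

empty_session_table <- function() {
  tpl <- list(
    experiment = character(0), session_day = integer(0),
    block = integer(0), trial_index = integer(0),
    electrode_id = integer(0), array = character(0), row = integer(0),
    col = integer(0), amplitude_uA = numeric(0), frequency_hz = numeric(0),
    pulse_width_us = numeric(0), interphase_us = numeric(0),
    duration_s = numeric(0), is_catch = logical(0), detected = logical(0),
    modality = character(0), descriptor = character(0),
    region = character(0), plane = character(0), grid_cell = character(0),
    intensity = integer(0), duration_category = character(0),
    impedance_kohm = numeric(0)
  )
  tibble::as_tibble(tpl)
}

#' Validate a session table
#'
#' Row-level consistency checks: a non-detected trial must carry modality
#' `"none"` and no report fields; intensity, when present, must be an
#' integer rating 1-10; a descriptor must belong to its modality's
#' vocabulary (see [descriptor_modality_map()]); `trial_index` must be
#' unique within `(session_day, block)`.
#'
#' @param data Session tibble.
#' @return Tibble of violations with columns `row`, `field`, `problem`
#'   (zero rows when valid).
#' @export
validate_sessions <- function(data) {
  missing_cols <- setdiff(session_columns(), names(data))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  v <- list()
  flag <- function(rows, field, problem) {
    if (length(rows)) {
      v[[length(v) + 1L]] <<- tibble::tibble(row = rows, field = field,
                                             problem = problem)
    }
  }
  det <- data$detected %in% TRUE
  flag(which(det & !(data$modality %in% c("cutaneous", "proprioceptive"))),
       "modality", "detected trial without a cutaneous/proprioceptive modality")
  nondet <- !det
  flag(which(nondet & !(is.na(data$modality) | data$modality == "none")),
       "modality", "non-detected trial with a modality")
  flag(which(nondet & !is.na(data$intensity)), "intensity",
       "non-detected trial with an intensity")
  flag(which(nondet & !is.na(data$duration_category)), "duration_category",
       "non-detected trial with a duration")
  flag(which(nondet & !is.na(data$region)), "region",
       "non-detected trial with a receptive field")
  flag(which(!is.na(data$intensity) &
               (data$intensity < 1 | data$intensity > 10)),
       "intensity", "intensity outside 1-10")
  map <- descriptor_modality_map()
  has_desc <- !is.na(data$descriptor)
  unknown <- has_desc & !(data$descriptor %in% names(map))
  flag(which(unknown), "descriptor", "descriptor outside the vocabulary")
  check <- has_desc & !unknown
  mism <- check &
    !(map[data$descriptor] == "any" | map[data$descriptor] == data$modality)
  flag(which(mism), "descriptor", "descriptor inconsistent with modality")
  key <- interaction(data$session_day, data$block, data$trial_index,
                     drop = TRUE)
  flag(which(duplicated(key)), "trial_index",
       "duplicate trial_index within (session_day, block)")
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(row = integer(0), field = character(0),
                   problem = character(0))
}

#' Write a session table to CSV
#'
#' Deterministic serialization: fixed column order, reals at 6 significant
#' digits, missing values as empty fields. Re-writing the same data yields
#' a byte-identical file, and a write/read/write cycle is a fixed point.
#'
#' @param data Session tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(data, path) {
  viol <- validate_sessions(data)
  if (nrow(viol)) {
    stop("invalid session data; first problem (row ", viol$row[1], "): ",
         viol$problem[1], call. = FALSE)
  }
  fmt <- lapply(session_columns(), function(col) {
    x <- data[[col]]
    if (is.double(x)) as.character(signif(x, 6)) else as.character(x)
  })
  names(fmt) <- session_columns()
  readr::write_csv(tibble::as_tibble(fmt), path, na = "")
  invisible(path)
}

#' Read a session table from CSV
#'
#' Parses a file written by [write_sessions()] (or hand-built to the same
#' schema), types every column, and rejects files whose rows violate the
#' session invariants.
#'
#' @param path CSV path.
#' @return Validated session tibble.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(session_columns(), header)
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- readr::read_csv(path, col_types = session_col_types(), na = "",
                          show_col_types = FALSE)
  data <- data[, session_columns()]
  viol <- validate_sessions(data)
  if (nrow(viol)) {
    msgs <- utils::head(paste0("row ", viol$row, ": ", viol$problem), 5)
    stop("validation error in ", path, ":\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  data
}
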