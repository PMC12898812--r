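# Delimited-text I/O and validation for foot-level datasets.

#' Read and validate a foot-level CSV dataset
#'
#' Reads a delimited text file of foot-level records, renames columns to
#' the canonical names via `schema_map`, validates every row, and returns
#' the accepted rows as a tibble. Rejected rows are *reported*, never
#' silently dropped: the returned tibble carries a `validation` attribute
#' listing each rejected row with its reason, and a message summarises the
#' counts.
#'
#' Validation rules: `injured` must be 0/1 (other codings are mapped
#' explicitly through `injured_values`, never guessed; unmapped values are
#' an error); `ssndt_mm` must be finite and inside `ssndt_window` (rows
#' outside are rejected with a reason); rows missing training load or
#' experience are rejected (the models adjust for both covariates);
#' `(participant_id, foot_side)` must be unique and no participant may
#' contribute more than two feet (errors). Only dot-decimal numerics are
#' accepted; comma-decimal input is rejected with a clear message.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema_map Named character vector mapping canonical names to file
#'   column names, e.g. `c(participant_id = "id", ssndt_mm = "ssndt")`;
#'   canonical names already present need not be mapped.
#' @param delim Field delimiter; `NULL` (default) auto-detects among
#'   comma, semicolon and tab from the header line.
#' @param injured_values Optional named vector mapping outcome codes to
#'   0/1, e.g. `c(yes = 1, no = 0)`.
#' @param ssndt_window Plausibility window for SSNDT in mm
#'   (default `c(0, 25)`).
#' @return A validated tibble of foot-level records (canonical columns),
#'   with attribute `validation`: a tibble of rejected rows and reasons.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(simulate_feet(n_participants = 10, seed = 1), path)
#' feet <- read_feet(path)
#' attr(feet, "validation")
#' @export
read_feet <- function(path, schema_map = NULL, delim = NULL,
                      injured_values = NULL, ssndt_window = c(0, 25)) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0 || !nzchar(header)) {
    abort("Schema error: the file is empty.")
  }
  if (is.null(delim)) {
    counts <- vapply(
      c(",", ";", "\t"),
      function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
      integer(1)
    )
    delim <- names(counts)[which.max(counts)]
    if (max(counts) == 0) delim <- ","
  }
  # read everything as text first: numeric conversion is done explicitly so
  # that comma decimals are detected instead of being misparsed
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE, col_types = readr::cols(.default = readr::col_character())
  )
  if (nrow(raw) == 0) abort("Schema error: the file contains no data rows.")

  # apply the schema map: canonical <- file column
  for (canon in names(schema_map)) {
    src <- schema_map[[canon]]
    if (!src %in% names(raw)) {
      abort(paste0("Schema error: mapped column `", src, "` not found."))
    }
    raw[[canon]] <- raw[[src]]
    if (src != canon) raw[[src]] <- NULL
  }
  missing <- setdiff(foot_columns, names(raw))
  if (length(missing) > 0) {
    abort(paste0(
      "Schema error: missing required column(s): ",
      paste0("`", missing, "`", collapse = ", "), "."
    ))
  }
  if (!"cohort_year" %in% names(raw)) raw$cohort_year <- NA_integer_

  # dot-decimal only
  for (col in c("ssndt_mm", "load_h_per_week", "experience_years")) {
    if (any(grepl(",", raw[[col]], fixed = TRUE), na.rm = TRUE)) {
      abort(paste0(
        "Column `", col, "` appears to use comma decimals; ",
        "only dot-decimal input is accepted."
      ))
    }
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  if ("cohort_year" %in% names(raw)) {
    raw$cohort_year <- suppressWarnings(as.integer(raw$cohort_year))
  }

  # outcome coding
  if (!is.null(injured_values)) {
    mapped <- unname(injured_values[as.character(raw$injured)])
    if (anyNA(mapped)) {
      abort("Validation error: `injured` contains values not covered by `injured_values`.")
    }
    raw$injured <- as.numeric(mapped)
  } else {
    raw$injured <- suppressWarnings(as.numeric(raw$injured))
  }
  if (any(!raw$injured %in% c(0, 1))) {
    abort("Validation error: `injured` must be coded 0/1 (map other codings via `injured_values`).")
  }

  raw$foot_side <- tolower(as.character(raw$foot_side))
  raw$foot_side[raw$foot_side %in% c("l", "left")] <- "left"
  raw$foot_side[raw$foot_side %in% c("r", "right")] <- "right"
  if (any(!raw$foot_side %in% c("left", "right"))) {
    abort("Validation error: `foot_side` must be left/right (or L/R).")
  }

  # row-level rejection with reasons
  reason <- rep(NA_character_, nrow(raw))
  bad_ssndt <- !is.finite(raw$ssndt_mm) |
    raw$ssndt_mm < ssndt_window[1] | raw$ssndt_mm > ssndt_window[2]
  reason[bad_ssndt] <- paste0(
    "ssndt_mm outside [", ssndt_window[1], ", ", ssndt_window[2], "] mm"
  )
  bad_cov <- is.na(reason) &
    (!is.finite(raw$load_h_per_week) | !is.finite(raw$experience_years) |
      raw$load_h_per_week < 0 | raw$experience_years < 0)
  reason[bad_cov] <- "missing or negative load/experience covariate"

  rejected <- tibble::tibble(
    row = which(!is.na(reason)),
    participant_id = raw$participant_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  data <- raw[is.na(reason), c(foot_columns, "cohort_year")]
  if (nrow(data) == 0) {
    abort("Validation error: every row was rejected.")
  }

  key <- paste(data$participant_id, data$foot_side)
  if (anyDuplicated(key)) {
    abort(paste0(
      "Validation error: duplicate (participant_id, foot_side) pair(s): ",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  check_foot_data(data)

  if (nrow(rejected) > 0) {
    inform(paste0(
      nrow(rejected), " row(s) rejected during validation (see attr(., \"validation\"))."
    ))
  }
  attr(data, "validation") <- rejected
  data
}

#' Write a result table to CSV
#'
#' Plain RFC-4180-style CSV with dot decimals and full numeric precision,
#' so that reading the file back reproduces the table field-for-field.
#'
#' @param x A data frame (any of the package's result tables).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_result <- function(x, path) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}
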