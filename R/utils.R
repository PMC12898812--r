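# Internal helpers shared across modules.

# cache Gauss-Hermite rules; recomputing them inside bootstrap loops is waste
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(k) {
  stopifnot(k >= 1)
  key <- as.character(k)
  if (is.null(.gh_cache[[key]])) {
    if (k == 1L) {
      .gh_cache[[key]] <- list(x = 0, w = sqrt(pi))
    } else {
      .gh_cache[[key]] <- pracma::gaussHermite(k)
    }
  }
  .gh_cache[[key]]
}

# Required foot-level columns (canonical names).
foot_columns <- c(
  "participant_id", "foot_side", "ssndt_mm", "injured",
  "load_h_per_week", "experience_years"
)

check_foot_data <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of foot-level records.", call = call)
  }
  missing <- setdiff(foot_columns, names(data))
  if (length(missing) > 0) {
    abort(
      paste0(
        "`data` is missing required column(s): ",
        paste0("`", missing, "`", collapse = ", "), "."
      ),
      call = call
    )
  }
  if (nrow(data) == 0) {
    abort("`data` contains no rows.", call = call)
  }
  bad <- !data$injured %in% c(0, 1)
  if (any(bad)) {
    abort(
      paste0(
        sum(bad), " row(s) have a non-binary `injured` value; ",
        "outcomes must be coded 0/1."
      ),
      call = call
    )
  }
  sizes <- table(data$participant_id)
  if (any(sizes > 2)) {
    abort(
      paste0(
        "Participant(s) ", paste(names(sizes)[sizes > 2], collapse = ", "),
        " contribute more than 2 feet."
      ),
      call = call
    )
  }
  invisible(data)
}

# Deterministic per-stage child seeds from one global seed (counter scheme),
# kept below 2^31 so they remain valid R integers.
derive_seed <- function(seed, stage) {
  # arithmetic in doubles (exact below 2^53), reduced into integer range
  as.integer((as.numeric(seed) * 1103 + as.numeric(stage) * 12289) %% 2147483629)
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)
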