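# Intra-rater test-retest reliability: single-measure intraclass
# correlation from the two-way ANOVA decomposition (Shrout-Fleiss ICC(3,1)
# consistency form; the absolute-agreement single-measure variant is
# available under a flag).

#' ICC(3,1) test-retest reliability
#'
#' Computes the single-measure consistency intraclass correlation from a
#' subjects-by-trials table of repeated measurements:
#' \eqn{ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS)}, with BMS the
#' between-subjects and EMS the residual mean square of the two-way ANOVA
#' decomposition. The F test is \eqn{BMS / EMS} on
#' \eqn{(n - 1, (n - 1)(k - 1))} degrees of freedom, and the confidence
#' interval is the standard F-based interval. The consistency form ignores
#' a fixed shift between trials; `type = "agreement"` gives the
#' absolute-agreement single-measure ICC, which does not.
#'
#' @param ratings Numeric matrix or data frame, one row per subject (foot),
#'   one column per repeated measurement; no missing cells, at least 2
#'   subjects and 2 trials.
#' @param ci_level Confidence level (default 0.95).
#' @param type `"consistency"` (ICC(3,1), default) or `"agreement"`.
#' @return A one-row tibble: `icc`, `ci_lo`, `ci_hi`, `f_statistic`,
#'   `df1`, `df2`, `p.value`, and `interpretation` per the conventional
#'   bands (< 0.50 poor, 0.50–0.75 moderate, 0.75–0.90 good,
#'   > 0.90 excellent).
#' @examples
#' set.seed(1)
#' truth <- rnorm(18, 8, 3)
#' ratings <- cbind(trial1 = truth + rnorm(18, 0, 1), trial2 = truth + rnorm(18, 0, 1))
#' icc_consistency(ratings)
#' @export
icc_consistency <- function(ratings, ci_level = 0.95,
                            type = c("consistency", "agreement")) {
  type <- match.arg(type)
  m <- as.matrix(ratings)
  if (!is.numeric(m)) abort("`ratings` must be numeric.")
  if (anyNA(m)) abort("`ratings` must have no missing cells.")
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("At least 2 repeated measurements (columns) are required.")
  if (n < 2) abort("At least 2 subjects (rows) are required.")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols

  bms <- ss_rows / (n - 1)
  jms <- ss_cols / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  if (bms <= 0 && ems <= 0) {
    abort("All ratings are identical: ICC is undefined (zero variance).")
  }

  icc <- if (type == "consistency") {
    (bms - ems) / (bms + (k - 1) * ems)
  } else {
    (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  }

  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  f_obs <- bms / ems
  p <- pf(f_obs, df1, df2, lower.tail = FALSE)
  # F-based interval for the single-measure consistency ICC
  alpha <- 1 - ci_level
  fl <- f_obs / qf(1 - alpha / 2, df1, df2)
  fu <- f_obs * qf(1 - alpha / 2, df2, df1)
  ci_lo <- (fl - 1) / (fl + k - 1)
  ci_hi <- (fu - 1) / (fu + k - 1)

  interp <- cut(icc,
    breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
    labels = c("poor", "moderate", "good", "excellent"),
    right = FALSE
  )
  # band edges: 0.50 and 0.75 belong to "moderate", 0.90 to "good"
  if (icc == 0.75) interp <- factor("moderate", levels = levels(interp))
  if (icc == 0.90) interp <- factor("good", levels = levels(interp))

  tibble::tibble(
    icc = icc, ci_lo = ci_lo, ci_hi = ci_hi,
    f_statistic = f_obs, df1 = df1, df2 = df2, p.value = p,
    interpretation = as.character(interp),
    type = type
  )
}
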