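# Participant-level nonparametric bootstrap of the full pipeline
# (refit -> minimum-risk point -> thresholds) and redundancy classification
# of adjacent OR levels.

#' Bootstrap threshold confidence intervals
#'
#' Nonparametric bootstrap at the participant level: each replicate draws
#' `n_participants` participants with replacement (both feet of a sampled
#' participant enter together, under a fresh cluster id per draw), refits
#' the adjusted quadratic random-intercept model, recomputes the
#' minimum-risk point and the two-sided thresholds at every OR target.
#' Percentile confidence intervals are formed from the successful
#' replicates; replicates whose fit fails or whose curvature is not
#' positive (no U shape) are dropped and counted.
#'
#' @param data Foot-level data frame.
#' @param targets Odds-ratio targets (default `seq(1.1, 2.0, by = 0.1)`).
#' @param B Number of bootstrap replicates (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed (mandatory: resampling must be reproducible).
#' @param nagq Quadrature nodes per refit; default 1 (Laplace), which keeps
#'   1000 refits fast; set 15 for full adaptive quadrature.
#' @return A tibble of class `ssndt_boot` with one row per target:
#'   `or_target`, point estimates `lower_mm`/`upper_mm` from the full-data
#'   fit, percentile CI bounds `lower_lo`, `lower_hi`, `upper_lo`,
#'   `upper_hi`, plus `x_min_mm` point and CI columns and `n_effective`.
#' @examples
#' feet <- simulate_feet(n_participants = 60, seed = 5)
#' bootstrap_thresholds(feet, targets = c(1.5, 2.0), B = 20, seed = 9)
#' @export
bootstrap_thresholds <- function(data, targets = seq(1.1, 2.0, by = 0.1),
                                 B = 1000, ci_level = 0.95, seed,
                                 nagq = 1) {
  check_foot_data(data)
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: bootstrap results must be reproducible.")
  }
  if (B < 2) abort("`B` must be >= 2.")
  targets <- sort(targets)

  full_fit <- fit_injury_model(data, degree = 2, adjust = TRUE, nagq = nagq)
  full_curve <- risk_curve(full_fit)
  point <- threshold_grid(full_curve, targets = targets)

  pids <- unique(data$participant_id)
  np <- length(pids)
  rows_of <- split(seq_len(nrow(data)), data$participant_id)
  sizes_of <- lengths(rows_of)

  centering <- full_fit$centering
  warm <- c(full_fit$beta, log(max(full_fit$sigma_u, 1e-3)))
  # design built once on the full data; replicates index its rows
  X_full <- build_design(data, degree = 2, adjust = TRUE, centering = centering)
  y_full <- data$injured

  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = B, ncol = 2 * length(targets) + 1)
  for (b in seq_len(B)) {
    take <- sample.int(np, np, replace = TRUE)
    idx <- unlist(rows_of[take], use.names = FALSE)
    grp <- rep(seq_len(np), sizes_of[take])
    est <- tryCatch({
      core <- ri_logit_core(X_full[idx, , drop = FALSE], y_full[idx], grp,
        nagq = nagq, start = warm, hessian = FALSE
      )
      b2 <- core$beta[3]
      if (b2 <= 0 || !core$converged) NULL else {
        curve <- risk_curve(
          beta1 = core$beta[2], beta2 = b2,
          ssndt_mean = centering[["ssndt_mean"]]
        )
        hw <- sqrt(log(targets) / curve$beta2)
        c(curve$x_min_mm, curve$x_min_mm - hw, curve$x_min_mm + hw)
      }
    }, error = function(e) NULL)
    if (!is.null(est)) draws[b, ] <- est
  }

  ok <- stats::complete.cases(draws)
  n_eff <- sum(ok)
  if (n_eff < B / 2) {
    abort(paste0(
      "Only ", n_eff, " of ", B, " bootstrap refits succeeded; ",
      "interval estimates would be unreliable."
    ))
  }
  draws <- draws[ok, , drop = FALSE]
  alpha <- (1 - ci_level) / 2
  # type-1 (inverse-ECDF) percentile rule: with B = 2 the interval is the
  # min/max of the two draws
  qlo <- apply(draws, 2, quantile, alpha, type = 1, names = FALSE)
  qhi <- apply(draws, 2, quantile, 1 - alpha, type = 1, names = FALSE)

  k <- length(targets)
  out <- tibble::tibble(
    or_target = targets,
    lower_mm = point$lower_mm,
    lower_lo = qlo[1 + seq_len(k)],
    lower_hi = qhi[1 + seq_len(k)],
    upper_mm = point$upper_mm,
    upper_lo = qlo[1 + k + seq_len(k)],
    upper_hi = qhi[1 + k + seq_len(k)],
    x_min_mm = full_curve$x_min_mm,
    x_min_lo = qlo[1],
    x_min_hi = qhi[1],
    n_effective = n_eff
  )
  class(out) <- c("ssndt_boot", class(out))
  attr(out, "ci_level") <- ci_level
  attr(out, "B") <- B
  out
}

#' Classify adjacent OR levels as redundant or distinct
#'
#' The classification is binary: an OR level is *non-redundant* (a
#' statistically distinct threshold pair) only when its bootstrap
#' confidence intervals are non-overlapping with the previous level's on
#' *both* sides (lower-threshold CIs disjoint AND upper-threshold CIs
#' disjoint); any overlap on either side leaves the pair statistically
#' indistinguishable, i.e. redundant. Interval overlap is
#' `max(lo1, lo2) <= min(hi1, hi2)`. The first level has no predecessor
#' (`NA`). Pervasive redundancy across a dense grid indicates a smooth,
#' continuous risk gradient rather than discrete risk steps.
#'
#' @param rows A tibble with columns `or_target`, `lower_lo`, `lower_hi`,
#'   `upper_lo`, `upper_hi`, sorted by `or_target` (as returned by
#'   [bootstrap_thresholds()]).
#' @return The input with a logical `redundant_vs_previous` column
#'   (`NA` for the first row).
#' @export
classify_redundancy <- function(rows) {
  need <- c("or_target", "lower_lo", "lower_hi", "upper_lo", "upper_hi")
  if (!all(need %in% names(rows))) {
    abort(paste0(
      "`rows` needs columns ", paste0("`", need, "`", collapse = ", "), "."
    ))
  }
  if (is.unsorted(rows$or_target, strictly = TRUE)) {
    abort("`rows` must be sorted by strictly increasing `or_target`.")
  }
  overlap <- function(lo1, hi1, lo2, hi2) pmax(lo1, lo2) <= pmin(hi1, hi2)
  n <- nrow(rows)
  red <- rep(NA, n)
  if (n > 1) {
    i <- 2:n
    # distinct only when BOTH sides are disjoint; otherwise redundant
    red[i] <- overlap(
      rows$lower_lo[i - 1], rows$lower_hi[i - 1],
      rows$lower_lo[i], rows$lower_hi[i]
    ) |
      overlap(
        rows$upper_lo[i - 1], rows$upper_hi[i - 1],
        rows$upper_lo[i], rows$upper_hi[i]
      )
  }
  dplyr::mutate(rows, redundant_vs_previous = red)
}

#' Plot bootstrap threshold intervals
#'
#' Point estimates and percentile CIs of the lower and upper thresholds
#' against the OR target.
#'
#' @param object An `ssndt_boot` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssndt_boot
#' @export
autoplot.ssndt_boot <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(
      or_target = object$or_target, side = "lower",
      est = object$lower_mm, lo = object$lower_lo, hi = object$lower_hi
    ),
    tibble::tibble(
      or_target = object$or_target, side = "upper",
      est = object$upper_mm, lo = object$upper_lo, hi = object$upper_hi
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$or_target, y = .data$est,
    ymin = .data$lo, ymax = .data$hi, colour = .data$side
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(fill = .data$side),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "OR target", y = "SSNDT threshold (mm)",
      title = "Bootstrap threshold estimates with percentile CIs"
    ) +
    ggplot2::theme_minimal()
}
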