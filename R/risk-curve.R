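# Closed-form geometry of the fitted quadratic logit: minimum-risk point,
# odds-ratio function relative to that minimum, two-sided OR thresholds and
# the local risk gradient. All user-facing values are on the raw mm scale.

#' Risk curve of a quadratic injury model
#'
#' Constructs the U-shaped risk curve from a quadratic fit (or directly from
#' coefficients, e.g. a published table). The minimum-risk point on the raw
#' scale is \eqn{x_{min} = \bar{x} - \beta_1 / (2 \beta_2)}, where
#' \eqn{\bar{x}} is the SSNDT centering mean and \eqn{\beta_1, \beta_2} are
#' the centered-scale linear and quadratic coefficients. The odds ratio of
#' any SSNDT value relative to that minimum is
#' \eqn{OR(x) = \exp(\beta_2 (x - x_{min})^2)}; covariates held at their
#' means cancel out of the ratio.
#'
#' @param fit An `ssndt_fit` with `degree = 2`, or `NULL` when supplying
#'   coefficients directly.
#' @param beta1,beta2 Centered-scale coefficients (per mm, per mm²); read
#'   from `fit` when given. `beta2` must be positive — otherwise the logit
#'   has no interior minimum and construction fails.
#' @param ssndt_mean Centering mean (mm); read from `fit` when given.
#' @return An object of class `risk_curve` with fields `beta1`, `beta2`,
#'   `ssndt_mean` and the derived `x_min_mm`.
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' curve$x_min_mm
#' odds_ratio_at(curve, c(1.8, 5.5, 9.2))
#' @export
risk_curve <- function(fit = NULL, beta1 = NULL, beta2 = NULL,
                       ssndt_mean = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "ssndt_fit"))
    if (fit$degree != 2) {
      abort("`fit` must be a quadratic (degree = 2) model.")
    }
    beta1 <- unname(fit$beta[["ssndt_c"]])
    beta2 <- unname(fit$beta[["ssndt_c^2"]])
    ssndt_mean <- unname(fit$centering[["ssndt_mean"]])
  }
  if (is.null(beta1) || is.null(beta2) || is.null(ssndt_mean)) {
    abort("Provide either `fit` or all of `beta1`, `beta2`, `ssndt_mean`.")
  }
  if (!is.finite(beta2) || beta2 <= 0) {
    abort("`beta2` must be positive: no interior minimum-risk point exists.")
  }
  structure(
    list(
      beta1 = beta1, beta2 = beta2, ssndt_mean = ssndt_mean,
      x_min_mm = ssndt_mean - beta1 / (2 * beta2)
    ),
    class = "risk_curve"
  )
}

#' @rdname risk_curve
#' @export
minimum_risk_point <- function(fit) risk_curve(fit)

#' @export
print.risk_curve <- function(x, ...) {
  cat("Quadratic SSNDT risk curve\n")
  cat("  beta1 =", fmt_num(x$beta1, 4), "per mm (centered),",
      "beta2 =", fmt_num(x$beta2, 4), "per mm^2\n")
  cat("  minimum-risk point:", fmt_num(x$x_min_mm, 2), "mm (OR = 1 reference)\n")
  invisible(x)
}

#' Odds ratio relative to the minimum-risk point
#'
#' @param curve A [risk_curve()].
#' @param ssndt_mm Raw-scale SSNDT values (mm); vectorised.
#' @return Numeric vector of odds ratios (>= 1), exactly 1 at the
#'   minimum-risk point and symmetric about it.
#' @export
odds_ratio_at <- function(curve, ssndt_mm) {
  stopifnot(inherits(curve, "risk_curve"))
  exp(curve$beta2 * (ssndt_mm - curve$x_min_mm)^2)
}

# bracketed root-finder used as a built-in cross-check of the closed form
or_root <- function(curve, or_target, side) {
  f <- function(x) odds_ratio_at(curve, x) - or_target
  interval <- if (side == "lower") {
    c(curve$x_min_mm - 20, curve$x_min_mm)
  } else {
    c(curve$x_min_mm, curve$x_min_mm + 20)
  }
  uniroot(f, interval = interval, tol = 1e-12)$root
}

#' Two-sided SSNDT thresholds at an odds-ratio target
#'
#' Solves \eqn{OR(x) = OR_{target}} on both arms of the U. The closed form
#' \eqn{x_{min} \pm \sqrt{\ln(OR_{target}) / \beta_2}} is used as the
#' primary solution and cross-validated against bracketed numerical
#' root-finding on each arm; the two must agree to 1e-6 mm.
#'
#' @param curve A [risk_curve()].
#' @param or_target Odds-ratio target, must be > 1.
#' @return A one-row tibble: `or_target`, `lower_mm`, `upper_mm`.
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' thresholds_for_or(curve, 2.0)
#' @export
thresholds_for_or <- function(curve, or_target) {
  stopifnot(inherits(curve, "risk_curve"))
  if (!is.finite(or_target) || or_target <= 1) {
    abort("`or_target` must be a finite value > 1.")
  }
  half_width <- sqrt(log(or_target) / curve$beta2)
  lower <- curve$x_min_mm - half_width
  upper <- curve$x_min_mm + half_width
  lower_num <- or_root(curve, or_target, "lower")
  upper_num <- or_root(curve, or_target, "upper")
  if (abs(lower - lower_num) > 1e-6 || abs(upper - upper_num) > 1e-6) {
    abort("Closed-form and root-finding threshold solutions disagree beyond 1e-6 mm.")
  }
  tibble::tibble(or_target = or_target, lower_mm = lower, upper_mm = upper)
}

#' Threshold grid over odds-ratio targets
#'
#' One two-sided threshold pair per target. Lower thresholds decrease and
#' upper thresholds increase strictly with the target (bands widen as the
#' tolerated relative risk grows); this monotonicity is verified.
#'
#' @param curve A [risk_curve()].
#' @param targets Odds-ratio targets, all > 1
#'   (default `seq(1.1, 2.0, by = 0.1)`).
#' @return A tibble with columns `or_target`, `lower_mm`, `upper_mm`,
#'   ordered by target.
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' threshold_grid(curve)
#' @export
threshold_grid <- function(curve, targets = seq(1.1, 2.0, by = 0.1)) {
  stopifnot(inherits(curve, "risk_curve"))
  if (length(targets) < 1) abort("`targets` must be nonempty.")
  targets <- sort(targets)
  grid <- purrr::map_dfr(targets, ~ thresholds_for_or(curve, .x))
  if (nrow(grid) > 1 &&
    (any(diff(grid$lower_mm) >= 0) || any(diff(grid$upper_mm) <= 0))) {
    abort("Threshold grid is not strictly monotone in the OR target.")
  }
  grid
}

#' Local odds ratio per 1 mm of SSNDT
#'
#' The pointwise risk gradient along the curve. The default (finite
#' contrast) definition is the exact odds ratio of a 1 mm increase,
#' \eqn{\exp(\eta(x+1) - \eta(x)) = \exp(\beta_1 + \beta_2 (2 x_c + 1))};
#' the instantaneous variant exponentiates the derivative of the logit,
#' \eqn{\exp(\beta'(x)) = \exp(\beta_1 + 2 \beta_2 x_c)}. Values below 1
#' indicate decreasing risk (left arm of the U), values above 1 increasing
#' risk.
#'
#' @param curve A [risk_curve()].
#' @param ssndt_mm Raw-scale SSNDT values (mm); vectorised.
#' @param method `"contrast"` (default) for the exact 1 mm odds ratio or
#'   `"derivative"` for the instantaneous gradient.
#' @return Numeric vector of positive local odds ratios.
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' local_or_per_mm(curve, c(3, 5.5, 8))
#' @export
local_or_per_mm <- function(curve, ssndt_mm,
                            method = c("contrast", "derivative")) {
  stopifnot(inherits(curve, "risk_curve"))
  method <- match.arg(method)
  x_c <- ssndt_mm - curve$ssndt_mean
  if (method == "contrast") {
    exp(curve$beta1 + curve$beta2 * (2 * x_c + 1))
  } else {
    exp(curve$beta1 + 2 * curve$beta2 * x_c)
  }
}

#' Plot a risk curve
#'
#' Draws the odds-ratio curve over a raw-scale SSNDT range, marking the
#' minimum-risk point; optionally shades the risk zones of a
#' [build_zone_scheme()] scheme.
#'
#' @param object A [risk_curve()].
#' @param scheme Optional `zone_scheme` whose bands are shaded.
#' @param xlim SSNDT range to draw (mm).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_curve
#' @export
autoplot.risk_curve <- function(object, scheme = NULL, xlim = c(0, 15), ...) {
  xs <- seq(xlim[1], xlim[2], length.out = 400)
  df <- tibble::tibble(ssndt_mm = xs, or = odds_ratio_at(object, xs))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ssndt_mm, y = .data$or))
  if (!is.null(scheme)) {
    bands <- zone_bands(scheme, xlim = xlim)
    p <- p + ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = -Inf, ymax = Inf, fill = .data$zone
      ),
      alpha = 0.25
    ) +
      ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1, name = "Zone")
  }
  p +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = object$x_min_mm, linetype = "dashed") +
    ggplot2::labs(
      x = "SSNDT (mm)",
      y = "Odds ratio vs. minimum-risk point",
      title = "U-shaped SSNDT injury-risk curve"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the local risk gradient
#'
#' Line plot of the local odds ratio per 1 mm along the SSNDT range, with
#' the minimum-risk point marked; the smooth monotone rise away from the
#' minimum illustrates a continuous risk gradient without discrete
#' transitions.
#'
#' @param curve A [risk_curve()].
#' @param xlim SSNDT range to draw (mm).
#' @param method Passed to [local_or_per_mm()].
#' @return A ggplot object.
#' @export
plot_local_gradient <- function(curve, xlim = c(0, 15), method = "contrast") {
  xs <- seq(xlim[1], xlim[2], length.out = 400)
  df <- tibble::tibble(
    ssndt_mm = xs,
    local_or = local_or_per_mm(curve, xs, method = method)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ssndt_mm, y = .data$local_or)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = curve$x_min_mm, linetype = "dashed") +
    ggplot2::labs(
      x = "SSNDT (mm)", y = "Local OR per +1 mm",
      title = "Local injury-risk gradient"
    ) +
    ggplot2::theme_minimal()
}
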