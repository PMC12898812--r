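# OR-anchored bands, ordered risk zones, per-zone prevalence and screening
# metrics for the High+Extreme positive rule.

zone_labels5 <- c("Safe", "Mild", "Moderate", "High", "Extreme")

#' Build an OR-anchored risk-zone scheme
#'
#' Computes one two-sided threshold band per anchor OR and forms the ordered
#' risk zones as nested rings: the innermost band is the Safe zone, each
#' further zone is the next band minus the previous one, and everything
#' outside the widest band is the Extreme zone. With the default anchors
#' (1.2, 1.5, 1.8, 2.0) this yields the five zones Safe, Mild, Moderate,
#' High, Extreme.
#'
#' @param curve A [risk_curve()].
#' @param anchor_ors Strictly increasing odds-ratio anchors, all > 1
#'   (default `c(1.2, 1.5, 1.8, 2.0)`).
#' @return An object of class `zone_scheme`: a tibble of band boundaries
#'   (`$bands`), the zone labels in order (`$labels`) and the minimum-risk
#'   point (`$x_min_mm`).
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' scheme <- build_zone_scheme(curve)
#' scheme$bands
#' @export
build_zone_scheme <- function(curve, anchor_ors = c(1.2, 1.5, 1.8, 2.0)) {
  stopifnot(inherits(curve, "risk_curve"))
  if (length(anchor_ors) < 1 || any(anchor_ors <= 1)) {
    abort("`anchor_ors` must all be > 1.")
  }
  if (any(diff(anchor_ors) <= 0)) {
    abort("`anchor_ors` must be strictly increasing.")
  }
  bands <- threshold_grid(curve, targets = anchor_ors)
  # nesting is implied by grid monotonicity; verify defensively
  if (nrow(bands) > 1 &&
    (any(diff(bands$lower_mm) >= 0) || any(diff(bands$upper_mm) <= 0))) {
    abort("Anchor bands are not nested.")
  }
  n_zones <- nrow(bands) + 1
  labels <- if (n_zones == 5) {
    zone_labels5
  } else if (n_zones == 2) {
    c("Safe", "Extreme")
  } else {
    c("Safe", paste0("Zone", seq_len(n_zones - 2)), "Extreme")
  }
  structure(
    list(bands = bands, labels = labels, x_min_mm = curve$x_min_mm),
    class = "zone_scheme"
  )
}

#' @export
print.zone_scheme <- function(x, ...) {
  cat("SSNDT risk-zone scheme (", length(x$labels), " zones, minimum risk at ",
    fmt_num(x$x_min_mm, 2), " mm)\n",
    sep = ""
  )
  print(dplyr::mutate(
    x$bands,
    band = paste0("[", fmt_num(.data$lower_mm), ", ", fmt_num(.data$upper_mm), "] mm")
  ))
  invisible(x)
}

# rectangles for plotting: innermost band plus nested rings, clipped to xlim
zone_bands <- function(scheme, xlim = c(0, 15)) {
  b <- scheme$bands
  k <- nrow(b)
  lowers <- c(b$lower_mm, xlim[1])
  uppers <- c(b$upper_mm, xlim[2])
  rows <- list(tibble::tibble(
    zone = scheme$labels[1], xmin = b$lower_mm[1], xmax = b$upper_mm[1]
  ))
  for (i in seq_len(k)) {
    lo_out <- if (i < k) b$lower_mm[i + 1] else xlim[1]
    hi_out <- if (i < k) b$upper_mm[i + 1] else xlim[2]
    rows[[length(rows) + 1]] <- tibble::tibble(
      zone = scheme$labels[i + 1],
      xmin = c(lo_out, b$upper_mm[i]),
      xmax = c(b$lower_mm[i], hi_out)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$zone <- factor(out$zone, levels = scheme$labels)
  out[out$xmax > out$xmin, ]
}

#' Assign SSNDT values to risk zones
#'
#' Each value is assigned to the innermost zone whose band contains it.
#' Bands are closed on both ends, so a value exactly on a boundary maps to
#' the safer (inner) zone — the conservative screening convention.
#'
#' @param scheme A [build_zone_scheme()] scheme.
#' @param ssndt_mm Raw-scale SSNDT values (mm); vectorised.
#' @return An ordered factor of zone labels.
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' scheme <- build_zone_scheme(curve)
#' assign_zone(scheme, c(5.5, 9.5, 7.37))
#' @export
assign_zone <- function(scheme, ssndt_mm) {
  stopifnot(inherits(scheme, "zone_scheme"))
  if (any(!is.finite(ssndt_mm))) {
    abort("`ssndt_mm` must be finite to be assigned a zone.")
  }
  b <- scheme$bands
  # the widest band a value falls outside of determines its ring
  idx <- vapply(ssndt_mm, function(x) {
    outside <- x < b$lower_mm | x > b$upper_mm
    if (!any(outside)) 1L else max(which(outside)) + 1L
  }, integer(1))
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Per-zone counts and injury prevalence
#'
#' Tabulates feet, injuries and empirical injury prevalence per risk zone.
#' Zones are interpretive segments of a continuous risk gradient, so
#' empirical prevalence need not be monotone across zones even when the
#' underlying model risk is.
#'
#' @param scheme A [build_zone_scheme()] scheme.
#' @param data Foot-level data frame (needs `ssndt_mm` and `injured`).
#' @return A tibble with one row per zone plus a `Total` row: `zone`,
#'   `n_feet`, `n_injured`, `prevalence_pct` (0 with `empty = TRUE` flag for
#'   zones containing no feet).
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' scheme <- build_zone_scheme(curve)
#' feet <- simulate_feet(n_participants = 137, seed = 1)
#' zone_report(scheme, feet)
#' @export
zone_report <- function(scheme, data) {
  stopifnot(inherits(scheme, "zone_scheme"))
  if (!all(c("ssndt_mm", "injured") %in% names(data))) {
    abort("`data` needs columns `ssndt_mm` and `injured`.")
  }
  zone <- assign_zone(scheme, data$ssndt_mm)
  by_zone <- tibble::tibble(zone = zone, injured = data$injured) %>%
    dplyr::group_by(.data$zone, .drop = FALSE) %>%
    dplyr::summarise(
      n_feet = dplyr::n(),
      n_injured = sum(.data$injured),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      prevalence_pct = ifelse(.data$n_feet == 0, 0,
        100 * .data$n_injured / .data$n_feet
      ),
      empty = .data$n_feet == 0,
      zone = as.character(.data$zone)
    )
  total <- tibble::tibble(
    zone = "Total",
    n_feet = nrow(data),
    n_injured = sum(data$injured),
    prevalence_pct = 100 * sum(data$injured) / nrow(data),
    empty = FALSE
  )
  stopifnot(
    sum(by_zone$n_feet) == total$n_feet,
    sum(by_zone$n_injured) == total$n_injured
  )
  dplyr::bind_rows(by_zone, total)
}

#' Screening metrics for a positive-zone rule
#'
#' Treats membership of the `positive_zones` (default High and Extreme) as
#' a positive screening classification and computes the confusion matrix
#' against the injury outcome, plus sensitivity, specificity, PPV, NPV and
#' accuracy. Metrics with an empty margin are returned as `NA`.
#'
#' @param data Foot-level data frame (needs `ssndt_mm` and `injured`), or a
#'   data frame that already has a `zone` column (then `scheme` may be
#'   omitted).
#' @param scheme A [build_zone_scheme()] scheme used to assign zones when
#'   `data` has no `zone` column.
#' @param positive_zones Zone labels counted as test-positive
#'   (default `c("High", "Extreme")`).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @examples
#' curve <- risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
#' scheme <- build_zone_scheme(curve)
#' feet <- simulate_feet(n_participants = 137, seed = 1)
#' screening_metrics(feet, scheme)
#' @export
screening_metrics <- function(data, scheme = NULL,
                              positive_zones = c("High", "Extreme")) {
  if (!"zone" %in% names(data)) {
    if (is.null(scheme)) {
      abort("Provide `scheme` when `data` has no `zone` column.")
    }
    data <- dplyr::mutate(data, zone = assign_zone(scheme, .data$ssndt_mm))
  }
  if (!"injured" %in% names(data)) abort("`data` needs an `injured` column.")
  positive <- as.character(data$zone) %in% positive_zones
  y <- data$injured
  tp <- sum(positive & y == 1)
  fp <- sum(positive & y == 0)
  tn <- sum(!positive & y == 0)
  fn <- sum(!positive & y == 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    accuracy = (tp + tn) / length(y)
  )
}

#' Sample size for estimating a proportion
#'
#' The standard formula \eqn{n = (z / \delta)^2 p (1 - p)} for estimating a
#' prevalence `p` to within margin of error `delta` at the confidence level
#' implied by `z` (default 1.96, i.e. 95%).
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param delta Margin of error, > 0.
#' @param z Normal quantile (default 1.96).
#' @param ceiling Return the integer ceiling instead of the raw value.
#' @return Required sample size (raw value, or integer when
#'   `ceiling = TRUE`).
#' @examples
#' sample_size_proportion(0.25, 0.05) # 288.12
#' sample_size_proportion(0.50, 0.05) # 384.16
#' @export
sample_size_proportion <- function(p, delta, z = 1.96, ceiling = FALSE) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  if (any(delta <= 0)) abort("`delta` must be > 0.")
  n <- (z / delta)^2 * p * (1 - p)
  if (ceiling) base::ceiling(n) else n
}

#' Plot a zone report
#'
#' Bar chart of per-zone injury prevalence with foot counts annotated.
#'
#' @param object A [zone_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_zone_report <- function(object, ...) {
  df <- dplyr::filter(object, .data$zone != "Total")
  df$zone <- factor(df$zone, levels = df$zone)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone, y = .data$prevalence_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = paste0("n=", .data$n_feet)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      x = "Risk zone", y = "Injury prevalence (%)",
      title = "Empirical injury prevalence by SSNDT risk zone"
    ) +
    ggplot2::theme_minimal()
}
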