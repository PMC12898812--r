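# End-to-end orchestration of the full analysis workflow.

#' Run the full SSNDT risk analysis
#'
#' Executes the complete workflow on a foot-level dataset: functional-form
#' comparison (linear/quadratic/cubic), the adjusted quadratic fit and its
#' coefficient table, the minimum-risk point, the OR threshold grid, the
#' participant-level bootstrap with redundancy classification, the
#' segmented-regression check, the risk-zone scheme with per-zone
#' prevalence, and the High+Extreme screening metrics. Every stochastic
#' stage receives a child seed derived deterministically from `seed`, so
#' the whole bundle is reproducible from (data, configuration, seed).
#'
#' @param data Foot-level data frame.
#' @param seed Integer seed driving the bootstrap and segmented stages.
#' @param or_targets Threshold grid targets
#'   (default `seq(1.1, 2.0, by = 0.1)`).
#' @param anchor_ors Zone anchors (default `c(1.2, 1.5, 1.8, 2.0)`).
#' @param B Bootstrap replicates (default 1000).
#' @param nagq Quadrature nodes for the headline fits (default 15;
#'   bootstrap refits use the Laplace approximation).
#' @param skip_bootstrap,skip_segmented Skip the corresponding stage.
#' @param out_dir Optional directory; when given, every table is also
#'   written as CSV and the manifest as JSON-like text.
#' @return A named list of tibbles: `model_comparison`, `fit_table`,
#'   `fit_summary`, `minimum_risk`, `threshold_grid`, `bootstrap` (with
#'   redundancy column), `segmented`, `zone_bands`, `zone_report`,
#'   `screening`, and `manifest`.
#' @examples
#' feet <- simulate_feet(n_participants = 60, seed = 4)
#' res <- run_full_analysis(feet, seed = 4, B = 30, skip_segmented = TRUE)
#' res$threshold_grid
#' @export
run_full_analysis <- function(data, seed = 1,
                              or_targets = seq(1.1, 2.0, by = 0.1),
                              anchor_ors = c(1.2, 1.5, 1.8, 2.0),
                              B = 1000, nagq = 15,
                              skip_bootstrap = FALSE,
                              skip_segmented = FALSE,
                              out_dir = NULL) {
  check_foot_data(data)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage `", name, "` failed: ", conditionMessage(e)))
    })
  }

  comparison <- stage("model_comparison", compare_functional_forms(data, nagq = nagq))
  fit <- stage("quadratic_fit", fit_injury_model(data, degree = 2, nagq = nagq))
  curve <- stage("risk_curve", risk_curve(fit))
  grid <- stage("threshold_grid", threshold_grid(curve, targets = or_targets))

  boot <- NULL
  if (!skip_bootstrap) {
    boot <- stage("bootstrap", {
      bt <- bootstrap_thresholds(
        data,
        targets = or_targets, B = B,
        seed = derive_seed(seed, 1L), nagq = 1
      )
      classify_redundancy(bt)
    })
  }

  seg <- NULL
  if (!skip_segmented) {
    seg <- stage("segmented", {
      sf <- fit_segmented(data, n_breakpoints = 1, nagq = 1)
      tibble::tibble(
        psi_mm = sf$psi, psi_se = sf$psi_se,
        slope_left = sf$slopes[1], slope_right = sf$slopes[2],
        loglik = sf$loglik, aic = sf$aic, bic = sf$bic,
        unstable = sf$unstable
      )
    })
  }

  scheme <- stage("zones", build_zone_scheme(curve, anchor_ors = anchor_ors))
  report <- stage("zone_report", zone_report(scheme, data))
  screening <- stage("screening", screening_metrics(data, scheme))

  manifest <- tibble::tibble(
    key = c(
      "package_version", "seed", "n_feet", "n_participants",
      "or_targets", "anchor_ors", "B", "nagq", "elapsed_s"
    ),
    value = c(
      as.character(utils::packageVersion("ssndtrisk")),
      as.character(seed),
      as.character(nrow(data)),
      as.character(length(unique(data$participant_id))),
      paste(or_targets, collapse = " "),
      paste(anchor_ors, collapse = " "),
      as.character(if (skip_bootstrap) NA else B),
      as.character(nagq),
      fmt_num(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    )
  )

  bundle <- list(
    model_comparison = comparison,
    fit_table = tidy(fit),
    fit_summary = glance(fit),
    minimum_risk = tibble::tibble(
      x_min_mm = curve$x_min_mm,
      beta1 = curve$beta1, beta2 = curve$beta2,
      ssndt_mean = curve$ssndt_mean
    ),
    threshold_grid = grid,
    bootstrap = boot,
    segmented = seg,
    zone_bands = scheme$bands,
    zone_report = report,
    screening = screening,
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(bundle)) {
      if (!is.null(bundle[[nm]])) {
        write_result(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")))
      }
    }
  }
  bundle
}
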