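# Synthetic clustered foot-level data with a U-shaped injury logit.
#
# The generator emulates the study conditions the analysis assumes: two feet
# per participant correlated through a participant-level random intercept,
# SSNDT drawn from a truncated Normal matching the observed mean/SD, and a
# quadratic (centered) injury logit adjusted for training load and
# experience.

#' Generator configuration for synthetic foot-level data
#'
#' Defaults reproduce the observed cohort: SSNDT mean 7.8 mm / SD 3.0 mm,
#' load 7.7 ± 3.1 h/week, experience 4.3 ± 0.6 years, and a quadratic injury
#' logit with intercept −1.960, linear term 0.238/mm and curvature
#' 0.051/mm² on the centered scale (minimum-risk point near 5.5 mm, overall
#' injury prevalence near 21%). The random-intercept SD defaults to 1.0 on
#' the logit scale — a plausible degree of within-participant clustering;
#' the fitted value is never reported for the original cohort, so this is a
#' free knob.
#'
#' @param n_participants Number of participants (each contributes
#'   `feet_per_participant` feet).
#' @param feet_per_participant Feet per participant (default 2).
#' @param ssndt_mean,ssndt_sd SSNDT marginal moments (mm) before truncation
#'   to `ssndt_range`.
#' @param beta0,beta1,beta2 True fixed effects of the quadratic logit on the
#'   centered scale (intercept; per-mm; per-mm²). `beta2 > 0` enforces a
#'   U shape with a unique minimum.
#' @param gamma_load,gamma_exp True covariate effects (per centered h/week,
#'   per centered year).
#' @param sigma_u Random-intercept SD on the logit scale (≥ 0).
#' @param load_mean,load_sd Weekly training load moments (h/week).
#' @param exp_mean,exp_sd Training experience moments (years).
#' @param ssndt_range Plausibility window for SSNDT (mm); draws are from the
#'   Normal truncated to this window, mirroring the validation window used
#'   for real data.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_participants = 137)
#' feet <- simulate_feet(config = cfg, seed = 42)
#' mean(feet$injured)
#' @export
sim_config <- function(n_participants = 137,
                       feet_per_participant = 2,
                       ssndt_mean = 7.8, ssndt_sd = 3.0,
                       beta0 = -1.960, beta1 = 0.238, beta2 = 0.051,
                       gamma_load = 0.005, gamma_exp = 0.341,
                       sigma_u = 1.0,
                       load_mean = 7.7, load_sd = 3.1,
                       exp_mean = 4.3, exp_sd = 0.6,
                       ssndt_range = c(0, 25)) {
  if (n_participants < 1) abort("`n_participants` must be >= 1.")
  if (!feet_per_participant %in% 1:2) {
    abort("`feet_per_participant` must be 1 or 2.")
  }
  if (beta2 <= 0) {
    abort("`beta2` must be > 0: the U shape requires positive curvature.")
  }
  if (sigma_u < 0) abort("`sigma_u` must be >= 0.")
  if (ssndt_sd <= 0 || load_sd <= 0 || exp_sd <= 0) {
    abort("Scale parameters must be positive.")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      feet_per_participant = as.integer(feet_per_participant),
      ssndt_mean = ssndt_mean, ssndt_sd = ssndt_sd,
      beta0 = beta0, beta1 = beta1, beta2 = beta2,
      gamma_load = gamma_load, gamma_exp = gamma_exp,
      sigma_u = sigma_u,
      load_mean = load_mean, load_sd = load_sd,
      exp_mean = exp_mean, exp_sd = exp_sd,
      ssndt_range = ssndt_range
    ),
    class = "sim_config"
  )
}

# inverse-CDF truncated-normal draw; deterministic given the RNG stream
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Simulate a clustered foot-level dataset
#'
#' Draws one random intercept per participant, participant-level covariates
#' shared by both feet, foot-level SSNDT from the truncated Normal, and the
#' injury indicator from the quadratic logit
#' \eqn{logit(p) = \beta_0 + \beta_1 x_c + \beta_2 x_c^2 +
#' \gamma_L load_c + \gamma_E exp_c + u_i}, where centering is at the
#' generator means.
#'
#' @param n_participants Convenience override of `config$n_participants`.
#' @param config A [sim_config()]; defaults to the calibrated configuration.
#' @param seed Integer seed; fully determines the output.
#' @return A tibble of foot-level records with columns `participant_id`,
#'   `foot_side`, `ssndt_mm`, `injured`, `load_h_per_week`,
#'   `experience_years`, `cohort_year`.
#' @examples
#' feet <- simulate_feet(n_participants = 50, seed = 1)
#' dplyr::count(feet, injured)
#' @export
simulate_feet <- function(n_participants = NULL, config = sim_config(),
                          seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by `sim_config()`.")
  }
  if (!is.null(n_participants)) config$n_participants <- as.integer(n_participants)
  if (!is.null(seed)) set.seed(as.integer(seed))

  np <- config$n_participants
  k <- config$feet_per_participant
  u <- rnorm(np, 0, config$sigma_u)
  load <- pmax(rtruncnorm(np, config$load_mean, config$load_sd, 0, Inf), 0)
  expr <- pmax(rtruncnorm(np, config$exp_mean, config$exp_sd, 0, Inf), 0)
  cohort <- sample(2023:2025, np, replace = TRUE)

  idx <- rep(seq_len(np), each = k)
  side <- rep(c("left", "right")[seq_len(k)], times = np)
  ssndt <- rtruncnorm(
    np * k, config$ssndt_mean, config$ssndt_sd,
    config$ssndt_range[1], config$ssndt_range[2]
  )
  x_c <- ssndt - config$ssndt_mean
  eta <- config$beta0 + config$beta1 * x_c + config$beta2 * x_c^2 +
    config$gamma_load * (load[idx] - config$load_mean) +
    config$gamma_exp * (expr[idx] - config$exp_mean) +
    u[idx]
  injured <- rbinom(np * k, 1, plogis(eta))

  tibble::tibble(
    participant_id = sprintf("P%04d", idx),
    foot_side = side,
    ssndt_mm = ssndt,
    injured = injured,
    load_h_per_week = load[idx],
    experience_years = expr[idx],
    cohort_year = cohort[idx]
  )
}

# default per-replicate analysis for the scenario harness
default_scenario_analysis <- function(targets = c(1.1, 2.0), nagq = 1) {
  function(data) {
    fit <- fit_injury_model(data, degree = 2, adjust = TRUE, nagq = nagq)
    curve <- risk_curve(fit)
    grid <- threshold_grid(curve, targets = targets)
    out <- c(
      beta1 = unname(fit$beta[["ssndt_c"]]),
      beta2 = unname(fit$beta[["ssndt_c^2"]]),
      sigma_u = fit$sigma_u,
      x_min_mm = curve$x_min_mm
    )
    for (i in seq_len(nrow(grid))) {
      out[paste0("lower_", grid$or_target[i])] <- grid$lower_mm[i]
      out[paste0("upper_", grid$or_target[i])] <- grid$upper_mm[i]
    }
    out
  }
}

#' Monte Carlo scenario harness
#'
#' Generates `replicates` synthetic datasets per sample-size scenario,
#' applies an analysis function to each (by default: quadratic adjusted fit,
#' minimum-risk point, and threshold pairs at OR targets 1.1 and 2.0), and
#' summarises each extracted quantity across replicates by mean, SD and
#' empirical 2.5/97.5 percentiles. The fraction of replicates preserving the
#' threshold ordering (lower at OR 1.1 above lower at OR 2.0, upper at OR
#' 1.1 below upper at OR 2.0) is reported per scenario.
#'
#' @param sizes Scenario sample sizes counted in feet
#'   (default `c(380, 288, 274)`); participants per scenario are
#'   `ceiling(size / feet_per_participant)`.
#' @param replicates Replicates per scenario (>= 1).
#' @param config Generator truth, a [sim_config()].
#' @param analysis Function mapping a dataset to a named numeric vector;
#'   defaults to the quadratic-fit-plus-thresholds extraction.
#' @param seed Integer seed for the whole harness.
#' @param nagq Quadrature nodes used by the default analysis (default 1,
#'   the Laplace approximation, for speed across many replicates).
#' @return A list with `summary` (one row per scenario × quantity:
#'   mean, sd, q2.5, q97.5), `ordering` (per scenario, fraction of
#'   replicates preserving the threshold ordering) and `failures`
#'   (count of replicate-level fit failures per scenario).
#' @examples
#' sc <- run_scenarios(sizes = c(120, 80), replicates = 5, seed = 3)
#' sc$summary
#' @export
run_scenarios <- function(sizes = c(380, 288, 274), replicates = 200,
                          config = sim_config(), analysis = NULL,
                          seed = 1, nagq = 1) {
  if (any(sizes < 2)) abort("Scenario sizes must be at least 2 feet.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  analysis <- analysis %||% default_scenario_analysis(nagq = nagq)

  summaries <- list()
  ordering <- numeric(0)
  failures <- integer(0)

  for (s_i in seq_along(sizes)) {
    n_feet <- sizes[s_i]
    np <- ceiling(n_feet / config$feet_per_participant)
    res <- vector("list", replicates)
    n_fail <- 0L
    for (r in seq_len(replicates)) {
      dat <- simulate_feet(
        n_participants = np, config = config,
        seed = derive_seed(seed, s_i * 100000L + r)
      )
      res[r] <- list(tryCatch(analysis(dat), error = function(e) NULL))
      if (is.null(res[[r]])) n_fail <- n_fail + 1L
    }
    if (n_fail > replicates / 2) {
      abort(paste0(
        "Scenario n=", n_feet, ": more than half of the replicate fits ",
        "failed (", n_fail, "/", replicates, ")."
      ))
    }
    ok <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    qn <- colnames(ok)
    single <- nrow(ok) == 1
    summaries[[s_i]] <- tibble::tibble(
      n_feet = n_feet,
      quantity = qn,
      mean = apply(ok, 2, mean),
      sd = if (single) NA_real_ else apply(ok, 2, sd),
      q2.5 = apply(ok, 2, quantile, 0.025, names = FALSE),
      q97.5 = apply(ok, 2, quantile, 0.975, names = FALSE)
    )
    lowers <- grep("^lower_", qn, value = TRUE)
    uppers <- grep("^upper_", qn, value = TRUE)
    ordering[s_i] <- if (length(lowers) >= 2 && length(uppers) >= 2) {
      first_l <- lowers[1]; last_l <- lowers[length(lowers)]
      first_u <- uppers[1]; last_u <- uppers[length(uppers)]
      mean(ok[, first_l] > ok[, last_l] & ok[, first_u] < ok[, last_u])
    } else {
      NA_real_
    }
    failures[s_i] <- n_fail
  }

  list(
    summary = dplyr::bind_rows(summaries),
    ordering = tibble::tibble(
      n_feet = sizes,
      ordering_preserved = ordering,
      replicates = replicates - failures
    ),
    failures = tibble::tibble(n_feet = sizes, failed = failures)
  )
}
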