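# Random-intercept logistic regression by maximum marginal likelihood,
# with the integral over the participant intercept evaluated by adaptive
# Gauss-Hermite quadrature (1 node = Laplace approximation).

# ---- internal core ---------------------------------------------------------

# X, y ordered by cluster; grp an integer cluster index (1..G) aligned to rows.
# Returns the fitted parameter vector and (optionally) an observed-information
# covariance matrix for the fixed effects.
ri_logit_core <- function(X, y, grp, nagq = 15L, start = NULL,
                          hessian = TRUE, tol = 1e-12) {
  if (is.unsorted(grp)) {
    ord <- order(grp)
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
    grp <- grp[ord]
  }
  sizes <- tabulate(grp)
  sizes <- sizes[sizes > 0L]
  starts <- as.integer(c(0L, cumsum(sizes)[-length(sizes)]))
  rule <- gh_rule(nagq)
  p <- ncol(X)

  fn <- function(par) {
    par[p + 1] <- min(max(par[p + 1], -10), 3)
    v <- agq_nll(par, X, y, starts, sizes, rule$x, rule$w)
    if (!is.finite(v)) v <- 1e10
    v
  }
  gr <- function(par) {
    par[p + 1] <- min(max(par[p + 1], -10), 3)
    g <- agq_nll_grad(par, X, y, starts, sizes, rule$x, rule$w)
    g[!is.finite(g)] <- 0
    g
  }

  if (is.null(start)) {
    init_beta <- tryCatch(
      suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial())$coefficients
      ),
      error = function(e) rep(0, p)
    )
    init_beta[!is.finite(init_beta)] <- 0
    start <- c(init_beta, log(0.5))
  }

  opt <- optim(
    start, fn, gr,
    method = "BFGS",
    control = list(maxit = 500L, reltol = tol)
  )
  par_hat <- unname(opt$par)
  par_hat[p + 1] <- min(max(par_hat[p + 1], -10), 3)
  converged <- opt$convergence == 0 && all(is.finite(par_hat))

  vcov_beta <- NULL
  se <- rep(NA_real_, p)
  H <- NULL
  if (hessian) {
    # Newton polish to drive the gradient to ~0: BFGS stops on relative
    # function change, which leaves parameters reproducible only to ~1e-7;
    # a couple of Newton steps pin the optimum. At a sigma boundary the
    # log-sigma direction is flat, so only beta is polished there.
    active <- if (par_hat[p + 1] <= -6) seq_len(p) else seq_len(p + 1)
    fn_a <- function(q) {
      full <- par_hat
      full[active] <- q
      fn(full)
    }
    gr_a <- function(q) {
      full <- par_hat
      full[active] <- q
      gr(full)[active]
    }
    for (it in 1:8) {
      g <- gr_a(par_hat[active])
      if (max(abs(g)) < 1e-9) break
      H <- tryCatch(optimHess(par_hat[active], fn_a, gr_a),
        error = function(e) NULL
      )
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- par_hat
      cand[active] <- cand[active] - step
      cand[p + 1] <- min(max(cand[p + 1], -10), 3)
      # accept near-optimum steps: the objective is flat to ~1e-9 here
      if (fn(cand) <= fn(par_hat) + 1e-8) par_hat <- cand else break
    }
    # an optimizer that ran out of iterations but whose polished gradient
    # vanishes has converged for every practical purpose
    if (!converged && max(abs(gr(par_hat))) < 1e-5) converged <- TRUE
    H <- tryCatch(optimHess(par_hat[active], fn_a, gr_a),
      error = function(e) NULL
    )
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        vcov_beta <- V[seq_len(p), seq_len(p), drop = FALSE]
        # symmetrise against numerical asymmetry of the finite differences
        vcov_beta <- (vcov_beta + t(vcov_beta)) / 2
        if (all(diag(vcov_beta) > 0)) {
          se <- sqrt(diag(vcov_beta))
        } else {
          vcov_beta <- NULL
        }
      }
    }
  }
  beta <- par_hat[seq_len(p)]
  log_sigma <- par_hat[p + 1]
  sigma <- exp(log_sigma)
  loglik <- -fn(par_hat)

  list(
    beta = beta, sigma = sigma, loglik = loglik, vcov = vcov_beta, se = se,
    converged = converged, nagq = as.integer(nagq), n_obs = length(y),
    n_groups = length(sizes), par = c(beta, log_sigma)
  )
}

# Design matrix for the polynomial SSNDT model on the centered scale.
build_design <- function(data, degree, adjust, centering) {
  x_c <- data$ssndt_mm - centering[["ssndt_mean"]]
  cols <- list("(Intercept)" = rep(1, nrow(data)))
  if (degree >= 1) cols[["ssndt_c"]] <- x_c
  if (degree >= 2) cols[["ssndt_c^2"]] <- x_c^2
  if (degree >= 3) cols[["ssndt_c^3"]] <- x_c^3
  if (adjust) {
    cols[["load_c"]] <- data$load_h_per_week - centering[["load_mean"]]
    cols[["experience_c"]] <- data$experience_years - centering[["exp_mean"]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# ---- user-facing fit -------------------------------------------------------

#' Fit a random-intercept logistic injury model
#'
#' Fits a mixed-effects logistic regression of the binary injury outcome on
#' polynomial terms of SSNDT (mm), with a participant-level random intercept
#' accounting for the correlation between a participant's two feet, optionally
#' adjusted for weekly training load and training experience. Estimation is by
#' maximum marginal likelihood; the random-intercept integral is evaluated by
#' adaptive Gauss-Hermite quadrature with `nagq` nodes (`nagq = 1` gives the
#' Laplace approximation). SSNDT and the covariates are mean-centered before
#' fitting and the centering constants are stored in the fit, so raw-scale
#' predictions and thresholds are always recoverable.
#'
#' @param data Data frame of foot-level records with columns
#'   `participant_id`, `foot_side`, `ssndt_mm`, `injured` (0/1),
#'   `load_h_per_week`, `experience_years` (see [simulate_feet()] or
#'   [read_feet()]).
#' @param degree Degree of the SSNDT polynomial: 1 (linear), 2 (quadratic,
#'   default — the U-shaped model), or 3 (cubic). Degree 0 fits the
#'   intercept-plus-random-intercept null model used by [fit_indices()].
#' @param adjust Include training load and experience as covariates
#'   (default `TRUE`).
#' @param nagq Number of adaptive Gauss-Hermite quadrature nodes
#'   (default 15).
#' @param center Center predictors at their sample means (default `TRUE`;
#'   turning this off is only useful for diagnostic comparisons).
#'
#' @return An object of class `ssndt_fit`: fixed effects (logit scale,
#'   centered-predictor parameterisation), standard errors and covariance
#'   from the observed information, random-intercept SD `sigma_u`, marginal
#'   log-likelihood, and the centering constants. Use [tidy()] for a
#'   coefficient table, [glance()] for fit summaries, [predict_risk()] for
#'   probabilities and [risk_curve()] for the threshold geometry.
#'
#' @examples
#' feet <- simulate_feet(n_participants = 137, seed = 1)
#' fit <- fit_injury_model(feet)
#' tidy(fit)
#' glance(fit)
#' @export
fit_injury_model <- function(data, degree = 2, adjust = TRUE, nagq = 15,
                             center = TRUE) {
  check_foot_data(data)
  if (!degree %in% 0:3) {
    abort("`degree` must be 0 (null model), 1, 2, or 3.")
  }
  y <- data$injured
  if (length(unique(y)) < 2) {
    abort(paste0(
      "All outcomes are ", y[1], "; both outcome classes must be present ",
      "(complete separation / degenerate outcome)."
    ))
  }
  if (length(unique(data$participant_id)) < 2) {
    abort("At least 2 participants (clusters) are required.")
  }

  centering <- c(
    ssndt_mean = if (center) mean(data$ssndt_mm) else 0,
    load_mean = if (center) mean(data$load_h_per_week) else 0,
    exp_mean = if (center) mean(data$experience_years) else 0
  )
  X <- build_design(data, degree, adjust, centering)
  grp <- as.integer(factor(data$participant_id))

  core <- ri_logit_core(X, y, grp, nagq = nagq)
  if (any(abs(core$beta) > 15)) {
    abort(paste0(
      "Separation detected: fixed-effect estimate(s) diverging ",
      "(max |beta| = ", fmt_num(max(abs(core$beta)), 1), ")."
    ))
  }
  if (!core$converged) {
    warn("Model fit did not converge; estimates are flagged (converged = FALSE).")
  }

  names(core$beta) <- colnames(X)
  names(core$se) <- colnames(X)
  if (!is.null(core$vcov)) dimnames(core$vcov) <- list(colnames(X), colnames(X))

  structure(
    list(
      beta = core$beta,
      se = core$se,
      vcov = core$vcov,
      sigma_u = core$sigma,
      loglik = core$loglik,
      n_obs = core$n_obs,
      n_groups = core$n_groups,
      centering = centering,
      degree = as.integer(degree),
      adjust = isTRUE(adjust),
      converged = core$converged,
      nagq = core$nagq
    ),
    class = "ssndt_fit"
  )
}

#' @export
print.ssndt_fit <- function(x, ...) {
  kind <- c("null (intercept-only)", "linear", "quadratic", "cubic")[x$degree + 1]
  cat("Random-intercept logistic injury model (", kind, " SSNDT",
    if (x$adjust) ", adjusted" else "", ")\n",
    sep = ""
  )
  cat(
    "  feet:", x$n_obs, " participants:", x$n_groups,
    " AGQ nodes:", x$nagq, "\n"
  )
  print(tidy(x), n = Inf)
  cat(
    "  sigma_u =", fmt_num(x$sigma_u, 3),
    " logLik =", fmt_num(x$loglik, 2),
    if (!x$converged) " [NOT CONVERGED]" else "", "\n"
  )
  invisible(x)
}

#' Tidy a fitted injury model
#'
#' @param x An `ssndt_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`
#'   (logit scale, centered predictors), `std.error`, `statistic` (Wald z)
#'   and `p.value`.
#' @method tidy ssndt_fit
#' @export
tidy.ssndt_fit <- function(x, ...) {
  z <- x$beta / x$se
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' Glance at a fitted injury model
#'
#' @param x An `ssndt_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, `sigma_u`, the marginal
#'   log-likelihood, deviance, AIC and BIC (the parameter count includes the
#'   random-intercept variance), and convergence status.
#' @method glance ssndt_fit
#' @export
glance.ssndt_fit <- function(x, ...) {
  k <- length(x$beta) + 1 # fixed effects + random-intercept variance
  tibble::tibble(
    n_obs = x$n_obs,
    n_groups = x$n_groups,
    sigma_u = x$sigma_u,
    logLik = x$loglik,
    deviance = -2 * x$loglik,
    AIC = -2 * x$loglik + 2 * k,
    BIC = -2 * x$loglik + k * log(x$n_obs),
    df = k,
    converged = x$converged
  )
}

# ---- model comparison ------------------------------------------------------

#' Fit indices for model comparison
#'
#' Computes AIC, BIC, deviance and Nagelkerke's pseudo-R² for a fitted
#' injury model against the intercept-plus-random-intercept null model on the
#' same rows. Cox-Snell R² = 1 − exp((2/n)(ll₀ − ll₁)) is rescaled by its
#' maximum 1 − exp((2/n)·ll₀) to give the Nagelkerke index. The parameter
#' count includes the random-intercept variance.
#'
#' @param fit An `ssndt_fit`.
#' @param null_fit The null `ssndt_fit` on the same rows
#'   (`fit_injury_model(data, degree = 0, adjust = FALSE)`).
#' @return A one-row tibble: `aic`, `bic`, `nagelkerke_r2`, `deviance`.
#' @examples
#' feet <- simulate_feet(n_participants = 100, seed = 7)
#' fit <- fit_injury_model(feet)
#' null <- fit_injury_model(feet, degree = 0, adjust = FALSE)
#' fit_indices(fit, null)
#' @export
fit_indices <- function(fit, null_fit) {
  stopifnot(inherits(fit, "ssndt_fit"), inherits(null_fit, "ssndt_fit"))
  if (fit$n_obs != null_fit$n_obs || fit$n_groups != null_fit$n_groups) {
    abort("`fit` and `null_fit` were not fitted to the same rows.")
  }
  n <- fit$n_obs
  k <- length(fit$beta) + 1
  ll1 <- fit$loglik
  ll0 <- null_fit$loglik
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll1))
  nagelkerke <- cox_snell / (1 - exp((2 / n) * ll0))
  tibble::tibble(
    aic = -2 * ll1 + 2 * k,
    bic = -2 * ll1 + k * log(n),
    nagelkerke_r2 = nagelkerke,
    deviance = -2 * ll1
  )
}

#' Likelihood-ratio test for nested injury models
#'
#' @param fit_small,fit_big Nested `ssndt_fit` objects on the same rows
#'   (every term of `fit_small` present in `fit_big`).
#' @return A one-row tibble: `statistic` = 2(ll_big − ll_small), `df` =
#'   difference in fixed-effect count, `p.value` from the upper χ²(df) tail.
#' @examples
#' feet <- simulate_feet(n_participants = 100, seed = 7)
#' lr_test(fit_injury_model(feet, degree = 1), fit_injury_model(feet, degree = 2))
#' @export
lr_test <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "ssndt_fit"), inherits(fit_big, "ssndt_fit"))
  if (fit_small$n_obs != fit_big$n_obs ||
    fit_small$n_groups != fit_big$n_groups) {
    abort("Fits were not computed on the same rows.")
  }
  if (!all(names(fit_small$beta) %in% names(fit_big$beta))) {
    abort("`fit_small` is not nested in `fit_big`.")
  }
  df <- length(fit_big$beta) - length(fit_small$beta)
  statistic <- 2 * (fit_big$loglik - fit_small$loglik)
  p <- if (df == 0) 1 else stats::pchisq(max(statistic, 0), df, lower.tail = FALSE)
  tibble::tibble(statistic = statistic, df = df, p.value = p)
}

#' Predicted injury probability at given SSNDT values
#'
#' Applies the stored centering constants and returns the inverse-logit of
#' the linear predictor at random intercept `conditional_u` (default 0, the
#' median participant). Covariates default to their stored sample means, so
#' their centered terms vanish — the convention used for all threshold and
#' zone computations.
#'
#' @param fit An `ssndt_fit`.
#' @param ssndt_mm Vector of raw-scale SSNDT values (mm).
#' @param load,experience Covariate values (raw scale); default the sample
#'   means stored in the fit.
#' @param conditional_u Random-intercept value on the logit scale (default 0).
#' @return Numeric vector of probabilities, one per `ssndt_mm` value.
#' @examples
#' feet <- simulate_feet(n_participants = 137, seed = 1)
#' fit <- fit_injury_model(feet)
#' predict_risk(fit, c(2, 5.5, 9))
#' @export
predict_risk <- function(fit, ssndt_mm, load = NULL, experience = NULL,
                         conditional_u = 0) {
  stopifnot(inherits(fit, "ssndt_fit"))
  if (any(!is.finite(ssndt_mm))) abort("`ssndt_mm` must be finite.")
  x_c <- ssndt_mm - fit$centering[["ssndt_mean"]]
  eta <- rep(fit$beta[["(Intercept)"]], length(x_c)) + conditional_u
  if (fit$degree >= 1) eta <- eta + fit$beta[["ssndt_c"]] * x_c
  if (fit$degree >= 2) eta <- eta + fit$beta[["ssndt_c^2"]] * x_c^2
  if (fit$degree >= 3) eta <- eta + fit$beta[["ssndt_c^3"]] * x_c^3
  if (fit$adjust) {
    load_c <- (load %||% fit$centering[["load_mean"]]) - fit$centering[["load_mean"]]
    exp_c <- (experience %||% fit$centering[["exp_mean"]]) - fit$centering[["exp_mean"]]
    eta <- eta + fit$beta[["load_c"]] * load_c + fit$beta[["experience_c"]] * exp_c
  }
  plogis(eta)
}

#' Compare linear, quadratic and cubic SSNDT specifications
#'
#' Fits the three polynomial specifications (all adjusted, all with the
#' participant random intercept) plus the null model, and tabulates AIC,
#' BIC, Nagelkerke R² and the likelihood-ratio test of each model against
#' the previous degree.
#'
#' @param data Foot-level data frame.
#' @param nagq Quadrature nodes per fit (default 15).
#' @param adjust Adjust for load and experience (default `TRUE`).
#' @return A tibble with one row per degree: fit indices and sequential LRT.
#' @examples
#' feet <- simulate_feet(n_participants = 137, seed = 1)
#' compare_functional_forms(feet)
#' @export
compare_functional_forms <- function(data, nagq = 15, adjust = TRUE) {
  null_fit <- fit_injury_model(data, degree = 0, adjust = FALSE, nagq = nagq)
  fits <- lapply(1:3, function(d) {
    fit_injury_model(data, degree = d, adjust = adjust, nagq = nagq)
  })
  rows <- purrr::map2_dfr(fits, 1:3, function(f, d) {
    idx <- fit_indices(f, null_fit)
    lrt <- if (d == 1) {
      tibble::tibble(statistic = NA_real_, df = NA_integer_, p.value = NA_real_)
    } else {
      lr_test(fits[[d - 1]], f)
    }
    tibble::tibble(
      model = c("linear", "quadratic", "cubic")[d],
      degree = d,
      aic = idx$aic, bic = idx$bic, nagelkerke_r2 = idx$nagelkerke_r2,
      deviance = idx$deviance,
      lrt_statistic = lrt$statistic, lrt_df = lrt$df, lrt_p = lrt$p.value
    )
  })
  rows
}
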