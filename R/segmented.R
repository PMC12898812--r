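# Segmented (breakpoint) logistic regression within the random-intercept
# framework, fitted by profile maximum likelihood over a breakpoint grid,
# plus a Davies-type existence test with parametric-bootstrap calibration.

hinge <- function(x, psi) pmax(x - psi, 0)

# design for a broken-line logit with breakpoints psi (continuous at psi)
segmented_design <- function(data, psi, adjust, centering) {
  x <- data$ssndt_mm
  cols <- list(
    "(Intercept)" = rep(1, nrow(data)),
    ssndt = x
  )
  for (i in seq_along(psi)) {
    cols[[paste0("hinge_", i)]] <- hinge(x, psi[i])
  }
  if (adjust) {
    cols[["load_c"]] <- data$load_h_per_week - centering[["load_mean"]]
    cols[["experience_c"]] <- data$experience_years - centering[["exp_mean"]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# profile log-likelihood at fixed breakpoints; warm-startable
segmented_ll <- function(data, psi, grp, adjust, centering, nagq, start = NULL) {
  X <- segmented_design(data, psi, adjust, centering)
  core <- ri_logit_core(X, data$injured, grp,
    nagq = nagq, start = start, hessian = FALSE
  )
  list(ll = core$loglik, core = core)
}

#' Fit a segmented (breakpoint) logistic injury model
#'
#' Broken-line logit, continuous at each breakpoint, fitted within the
#' adjusted random-intercept framework by profile maximum likelihood: the
#' mixed logistic with hinge terms \eqn{(x - \psi)_+} is refitted at each
#' candidate breakpoint (or breakpoint pair) on a grid spanning the 5th to
#' 95th SSNDT percentiles, the grid maximiser is refined by local search,
#' and the breakpoint standard error is taken from the profile curvature.
#' A flat profile — no distinct maximum at the grid resolution — raises an
#' instability flag, the typical outcome for two breakpoints at study-size
#' samples.
#'
#' @param data Foot-level data frame.
#' @param n_breakpoints 1 or 2.
#' @param grid_size Number of breakpoint candidates (default 50 for one
#'   breakpoint, reduced to at most 20 per dimension for two).
#' @param adjust Adjust for load and experience (default `TRUE`).
#' @param nagq Quadrature nodes (default 1, Laplace).
#' @return An object of class `segmented_fit`: `psi` (mm), `psi_se`,
#'   per-segment slopes on the logit scale, `loglik`, `aic`, `bic`,
#'   `converged` and `unstable` flags.
#' @examples
#' feet <- simulate_feet(n_participants = 80, seed = 11)
#' fit_segmented(feet, grid_size = 15)
#' @export
fit_segmented <- function(data, n_breakpoints = 1, grid_size = NULL,
                          adjust = TRUE, nagq = 1) {
  check_foot_data(data)
  if (!n_breakpoints %in% 1:2) abort("`n_breakpoints` must be 1 or 2.")
  grid_size <- grid_size %||% if (n_breakpoints == 1) 50L else 15L
  qs <- quantile(data$ssndt_mm, c(0.05, 0.95), names = FALSE)
  cand <- seq(qs[1], qs[2], length.out = grid_size)
  grp <- as.integer(factor(data$participant_id))
  centering <- c(
    load_mean = mean(data$load_h_per_week),
    exp_mean = mean(data$experience_years)
  )

  warm <- NULL
  if (n_breakpoints == 1) {
    prof <- vapply(cand, function(ps) {
      fit <- segmented_ll(data, ps, grp, adjust, centering, nagq, start = warm)
      fit$ll
    }, numeric(1))
    best <- which.max(prof)
    # refine the grid maximiser by local search over the bracketing interval
    lo <- cand[max(best - 1, 1)]
    hi <- cand[min(best + 1, length(cand))]
    opt <- optimize(
      function(ps) segmented_ll(data, ps, grp, adjust, centering, nagq)$ll,
      interval = c(lo, hi), maximum = TRUE, tol = 1e-4
    )
    psi <- opt$maximum
    ll <- opt$objective
    # profile curvature from a symmetric second difference
    h <- max(diff(cand)[1] / 2, 1e-3)
    ll_m <- segmented_ll(data, psi - h, grp, adjust, centering, nagq)$ll
    ll_p <- segmented_ll(data, psi + h, grp, adjust, centering, nagq)$ll
    d2 <- (ll_p - 2 * ll + ll_m) / h^2
    psi_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
    # flat profile: a wide stretch of candidates statistically tied with
    # the maximum (within the chi-square(1)/2 half-width)
    near <- prof >= max(prof) - qchisq(0.95, 1) / 2
    unstable <- mean(near) > 0.5 || !is.finite(psi_se)
    final <- segmented_ll(data, psi, grp, adjust, centering, nagq)
    b <- final$core$beta
    slopes <- c(segment1 = unname(b[2]), segment2 = unname(b[2] + b[3]))
  } else {
    pairs <- utils::combn(cand, 2)
    prof <- apply(pairs, 2, function(ps) {
      tryCatch(
        segmented_ll(data, ps, grp, adjust, centering, nagq)$ll,
        error = function(e) -Inf
      )
    })
    best <- which.max(prof)
    psi <- pairs[, best]
    ll <- prof[best]
    psi_se <- c(NA_real_, NA_real_)
    near <- prof >= max(prof) - qchisq(0.95, 2) / 2
    unstable <- mean(near) > 0.5
    final <- segmented_ll(data, psi, grp, adjust, centering, nagq)
    b <- final$core$beta
    slopes <- c(
      segment1 = unname(b[2]),
      segment2 = unname(b[2] + b[3]),
      segment3 = unname(b[2] + b[3] + b[4])
    )
  }

  k <- length(final$core$beta) + 1 + n_breakpoints # + sigma + breakpoints
  n <- nrow(data)
  structure(
    list(
      psi = psi, psi_se = psi_se, slopes = slopes,
      loglik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
      n_breakpoints = n_breakpoints,
      converged = final$core$converged,
      unstable = unstable,
      grid = cand
    ),
    class = "segmented_fit"
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("Segmented random-intercept logistic fit (",
    x$n_breakpoints, " breakpoint", if (x$n_breakpoints > 1) "s", ")\n",
    sep = ""
  )
  cat(
    "  psi =", paste(fmt_num(x$psi, 2), collapse = ", "), "mm",
    " (SE", paste(fmt_num(x$psi_se, 2), collapse = ", "), ")\n"
  )
  cat("  slopes (logit/mm):", paste(fmt_num(x$slopes, 3), collapse = ", "), "\n")
  cat("  logLik =", fmt_num(x$loglik, 2), " AIC =", fmt_num(x$aic, 2), "\n")
  if (x$unstable) cat("  WARNING: flat profile - breakpoint location unstable\n")
  invisible(x)
}

#' Tidy a segmented fit
#'
#' @param x A `segmented_fit`.
#' @param ... Unused.
#' @return A tibble with one row per breakpoint: `term`, `psi_mm`,
#'   `psi_se`, plus per-segment slopes as attributes of the fit.
#' @method tidy segmented_fit
#' @export
tidy.segmented_fit <- function(x, ...) {
  tibble::tibble(
    term = paste0("psi_", seq_along(x$psi)),
    psi_mm = unname(x$psi),
    psi_se = unname(x$psi_se)
  )
}

#' Davies-type test for the existence of a breakpoint
#'
#' Tests the linear (no-breakpoint) adjusted mixed logistic against the
#' best single-hinge alternative: the statistic is the maximal
#' likelihood-ratio statistic over the candidate grid, and its null
#' distribution — which accounts for the search over candidates by
#' construction — is obtained by parametric bootstrap: `B` datasets are
#' simulated from the fitted no-breakpoint null (fixed effects plus fresh
#' participant intercepts) and the maximal statistic recomputed for each.
#'
#' @param data Foot-level data frame.
#' @param grid_size Number of breakpoint candidates between the 5th and
#'   95th SSNDT percentiles (default 20).
#' @param B Bootstrap replicates (default 199, minimum 99).
#' @param seed Integer seed (required).
#' @param adjust Adjust for load and experience (default `TRUE`).
#' @param nagq Quadrature nodes (default 1, Laplace).
#' @return A one-row tibble: `statistic` (maximal LRT over the grid),
#'   `p.value` = (1 + #\{boot >= observed\}) / (B + 1), `B`.
#' @examples
#' feet <- simulate_feet(n_participants = 40, seed = 2)
#' breakpoint_test(feet, grid_size = 6, B = 99, seed = 3)
#' @export
breakpoint_test <- function(data, grid_size = 20, B = 199, seed,
                            adjust = TRUE, nagq = 1) {
  check_foot_data(data)
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  if (B < 99) abort("`B` must be >= 99.")
  if (grid_size < 2) abort("`grid_size` must be >= 2.")
  grp <- as.integer(factor(data$participant_id))
  centering <- c(
    load_mean = mean(data$load_h_per_week),
    exp_mean = mean(data$experience_years)
  )
  qs <- quantile(data$ssndt_mm, c(0.05, 0.95), names = FALSE)
  cand <- seq(qs[1], qs[2], length.out = grid_size)

  null_design <- function(d) segmented_design(d, numeric(0), adjust, centering)

  max_lrt <- function(d, null_start = NULL) {
    Xn <- null_design(d)
    null_core <- ri_logit_core(Xn, d$injured, grp,
      nagq = nagq, start = null_start, hessian = FALSE
    )
    warm <- c(
      null_core$beta[1:2], 0,
      if (adjust) null_core$beta[3:4], null_core$par[length(null_core$par)]
    )
    lls <- numeric(length(cand))
    for (ci in seq_along(cand)) {
      X <- segmented_design(d, cand[ci], adjust, centering)
      hinge_core <- ri_logit_core(X, d$injured, grp,
        nagq = nagq, start = warm, hessian = FALSE
      )
      lls[ci] <- hinge_core$loglik
      warm <- hinge_core$par # adjacent candidates have nearby optima
    }
    list(
      stat = max(0, 2 * (max(lls) - null_core$loglik)),
      core = null_core
    )
  }

  obs <- tryCatch(max_lrt(data), error = function(e) {
    abort(paste0("Null-model fit failed: ", conditionMessage(e)))
  })

  # simulate from the fitted null: fixed effects + fresh random intercepts
  Xn <- null_design(data)
  beta0 <- obs$core$beta
  sigma0 <- obs$core$sigma
  eta_fix <- drop(Xn %*% beta0)
  np <- max(grp)

  set.seed(as.integer(seed))
  boot_stats <- numeric(B)
  null_start <- obs$core$par
  for (b in seq_len(B)) {
    u <- rnorm(np, 0, sigma0)
    yb <- rbinom(nrow(data), 1, plogis(eta_fix + u[grp]))
    db <- data
    db$injured <- yb
    boot_stats[b] <- tryCatch(
      max_lrt(db, null_start = null_start)$stat,
      error = function(e) NA_real_
    )
  }
  boot_stats <- boot_stats[is.finite(boot_stats)]
  p <- (1 + sum(boot_stats >= obs$stat)) / (length(boot_stats) + 1)
  tibble::tibble(statistic = obs$stat, p.value = p, B = length(boot_stats))
}
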