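# Estimation core: marginal-likelihood fit, model comparison, prediction.

test_that("with no clustering the marginal fit collapses to plain logistic", {
  # structural limit: for any data, the marginal likelihood evaluated at
  # sigma -> 0 equals the ordinary Bernoulli likelihood
  feet0 <- simulate_feet(n_participants = 100, seed = 41)
  fit0 <- fit_injury_model(feet0, nagq = 15)
  X0 <- ssndtrisk:::build_design(feet0, 2, TRUE, fit0$centering)
  grp0 <- as.integer(factor(feet0$participant_id))
  core0 <- ssndtrisk:::ri_logit_core(X0, feet0$injured, grp0,
    nagq = 15, start = c(fit0$beta, -10), hessian = FALSE
  )
  ll_bern <- -ssndtrisk:::logistic_nll(core0$beta, X0, feet0$injured)
  expect_lt(abs(core0$loglik - ll_bern) / abs(ll_bern), 1e-6)

  # boundary replicate: generated without clustering and whose MLE sits at
  # sigma ~ 0, the mixed fit matches the ordinary-logistic (IRLS) oracle
  cfg <- sim_config(n_participants = 300, sigma_u = 0)
  feet <- simulate_feet(config = cfg, seed = 32)
  fit <- suppressWarnings(fit_injury_model(feet, nagq = 15))
  X <- ssndtrisk:::build_design(feet, 2, TRUE, fit$centering)
  oracle <- suppressWarnings(
    stats::glm.fit(X, feet$injured, family = stats::binomial())
  )
  expect_lt(fit$sigma_u, 0.05)
  expect_lt(max(abs(fit$beta - oracle$coefficients) /
    pmax(abs(oracle$coefficients), 1e-8)), 1e-4)
  ll_glm <- -ssndtrisk:::logistic_nll(oracle$coefficients, X, feet$injured)
  expect_lt(abs(fit$loglik - ll_glm) / abs(ll_glm), 1e-6)
})

test_that("the fit agrees with an independent mixed-model implementation", {
  feet <- simulate_feet(
    n_participants = 137, config = sim_config(sigma_u = 1.5), seed = 7
  )
  fit <- fit_injury_model(feet, nagq = 15)
  df <- as.data.frame(feet)
  df$x_c <- df$ssndt_mm - mean(df$ssndt_mm)
  df$load_c <- df$load_h_per_week - mean(df$load_h_per_week)
  df$exp_c <- df$experience_years - mean(df$experience_years)
  ref <- lme4::glmer(
    injured ~ x_c + I(x_c^2) + load_c + exp_c + (1 | participant_id),
    data = df, family = stats::binomial, nAGQ = 15
  )
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$sigma_u, sqrt(unlist(lme4::VarCorr(ref)))[[1]],
    tolerance = 1e-3
  )
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(stats::vcov(ref))))),
    tolerance = 1e-2
  )
})

test_that("quadrature is stable in the node count", {
  feet <- simulate_feet(n_participants = 137, seed = 12)
  f15 <- fit_injury_model(feet, nagq = 15)
  f25 <- fit_injury_model(feet, nagq = 25)
  expect_lt(abs(f15$loglik - f25$loglik) / abs(f15$loglik), 1e-6)
})

test_that("AIC and BIC satisfy their definitional identities", {
  feet <- simulate_feet(n_participants = 80, seed = 13)
  fit <- fit_injury_model(feet)
  g <- glance(fit)
  k <- length(fit$beta) + 1
  expect_equal(g$AIC, -2 * fit$loglik + 2 * k)
  expect_equal(g$BIC, -2 * fit$loglik + k * log(fit$n_obs))
  expect_equal(g$deviance, -2 * fit$loglik)
  null <- fit_injury_model(feet, degree = 0, adjust = FALSE)
  idx <- fit_indices(fit, null)
  expect_equal(idx$aic, g$AIC)
  expect_equal(idx$bic, g$BIC)
})

test_that("shifting SSNDT by a constant leaves the centered fit unchanged", {
  feet <- simulate_feet(n_participants = 100, seed = 14)
  f1 <- fit_injury_model(feet, nagq = 7)
  shifted <- dplyr::mutate(feet, ssndt_mm = ssndt_mm + 5)
  f2 <- fit_injury_model(shifted, nagq = 7)
  expect_lt(abs(f1$beta[["ssndt_c"]] - f2$beta[["ssndt_c"]]), 1e-8)
  expect_lt(abs(f1$beta[["ssndt_c^2"]] - f2$beta[["ssndt_c^2"]]), 1e-8)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-8)
})

test_that("degenerate inputs raise explicit errors", {
  feet <- simulate_feet(n_participants = 20, seed = 15)
  allzero <- dplyr::mutate(feet, injured = 0)
  expect_error(fit_injury_model(allzero), "both outcome classes")
  expect_error(fit_injury_model(feet, degree = 4), "degree")
  expect_error(fit_injury_model(feet[0, ]), "no rows")
})

test_that("Nagelkerke R2 matches the closed formula and its edge case", {
  feet <- simulate_feet(n_participants = 60, seed = 16)
  fit <- fit_injury_model(feet)
  null <- fit_injury_model(feet, degree = 0, adjust = FALSE)
  idx <- fit_indices(fit, null)
  n <- fit$n_obs
  cs <- 1 - exp((2 / n) * (null$loglik - fit$loglik))
  expect_equal(idx$nagelkerke_r2, cs / (1 - exp((2 / n) * null$loglik)))
  # no improvement over the null -> exactly zero
  idx0 <- fit_indices(null, null)
  expect_equal(idx0$nagelkerke_r2, 0)
  expect_error(
    fit_indices(fit, fit_injury_model(feet[-1, ], degree = 0, adjust = FALSE)),
    "same rows"
  )
})

test_that("the likelihood-ratio test behaves definitionally and under the U", {
  feet <- simulate_feet(n_participants = 60, seed = 17)
  fit <- fit_injury_model(feet)
  self <- lr_test(fit, fit)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)

  lin <- fit_injury_model(feet, degree = 1)
  lrt <- lr_test(lin, fit)
  expect_equal(lrt$statistic, 2 * (fit$loglik - lin$loglik))
  expect_equal(lrt$df, 1)
  expect_error(lr_test(fit, lin), "not nested")
})

test_that("a strong U is detected by model comparison and the LRT", {
  cfg <- sim_config(n_participants = 500, beta2 = 0.08, sigma_u = 1)
  reject <- logical(20)
  aic_wins <- logical(20)
  for (r in 1:20) {
    feet <- simulate_feet(config = cfg, seed = 600 + r)
    lin <- fit_injury_model(feet, degree = 1, nagq = 7)
    quad <- fit_injury_model(feet, degree = 2, nagq = 7)
    reject[r] <- lr_test(lin, quad)$p.value < 0.05
    null <- fit_injury_model(feet, degree = 0, adjust = FALSE, nagq = 7)
    aic_wins[r] <- fit_indices(quad, null)$aic < fit_indices(lin, null)$aic
  }
  expect_gte(mean(reject), 0.95)
  expect_gte(mean(aic_wins), 0.95)
})

test_that("predictions honour centering and the U shape", {
  feet <- simulate_feet(n_participants = 137, seed = 18)
  fit <- fit_injury_model(feet)
  xbar <- fit$centering[["ssndt_mean"]]
  expect_equal(
    predict_risk(fit, xbar),
    unname(plogis(fit$beta[["(Intercept)"]]))
  )
  curve <- risk_curve(fit)
  xs_right <- seq(curve$x_min_mm, curve$x_min_mm + 6, by = 0.5)
  xs_left <- seq(curve$x_min_mm, curve$x_min_mm - 6, by = -0.5)
  expect_true(all(diff(predict_risk(fit, xs_right)) > 0))
  expect_true(all(diff(predict_risk(fit, xs_left)) > 0))
})

test_that("parameter recovery holds at large n", {
  cfg <- sim_config(n_participants = 500, sigma_u = 1)
  true_xmin <- cfg$ssndt_mean - cfg$beta1 / (2 * cfg$beta2)
  est <- t(vapply(1:60, function(r) {
    feet <- simulate_feet(config = cfg, seed = 2000 + r)
    fit <- fit_injury_model(feet, nagq = 7)
    c(fit$beta[["ssndt_c^2"]], risk_curve(fit)$x_min_mm)
  }, numeric(2)))
  mc_se_b2 <- sd(est[, 1]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - cfg$beta2), 3 * mc_se_b2)
  expect_lt(abs(mean(est[, 2]) - true_xmin), 0.3)
})
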