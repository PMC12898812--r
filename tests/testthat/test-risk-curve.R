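# Geometry of the quadratic logit: minimum, OR function, thresholds,
# local gradient.

test_that("the minimum-risk point follows the closed form", {
  curve <- published_curve()
  expect_equal(curve$x_min_mm, 7.8 - 0.238 / (2 * 0.051))
  expect_equal(round(curve$x_min_mm, 1), 5.5)

  # symmetric U: no linear term puts the minimum at the centering mean
  sym <- risk_curve(beta1 = 0, beta2 = 0.05, ssndt_mean = 7.8)
  expect_equal(sym$x_min_mm, 7.8)

  # brute-force oracle: dense grid search over the logit attains the same
  # minimiser
  xs <- seq(0, 25, by = 1e-4)
  eta <- 0.238 * (xs - 7.8) + 0.051 * (xs - 7.8)^2
  expect_lt(abs(xs[which.min(eta)] - curve$x_min_mm), 1e-3)
})

test_that("construction fails without positive curvature", {
  expect_error(risk_curve(beta1 = 0.2, beta2 = 0, ssndt_mean = 7.8), "positive")
  expect_error(risk_curve(beta1 = 0.2, beta2 = -0.05, ssndt_mean = 7.8), "positive")
  feet <- simulate_feet(n_participants = 40, seed = 3)
  cubic <- fit_injury_model(feet, degree = 3)
  expect_error(risk_curve(cubic), "quadratic")
})

test_that("the OR function is 1 at the minimum and exactly symmetric", {
  curve <- published_curve()
  expect_equal(odds_ratio_at(curve, curve$x_min_mm), 1)
  d <- c(0.1, 0.5, 1, 2.5, 7)
  expect_equal(
    odds_ratio_at(curve, curve$x_min_mm + d),
    odds_ratio_at(curve, curve$x_min_mm - d)
  )
  expect_true(all(odds_ratio_at(curve, seq(-5, 30, by = 0.5)) >= 1))
})

test_that("closed-form thresholds agree with root finding on random curves", {
  set.seed(99)
  for (i in 1:200) {
    curve <- risk_curve(
      beta1 = runif(1, -0.5, 0.5),
      beta2 = runif(1, 0.005, 0.3),
      ssndt_mean = runif(1, 4, 12)
    )
    target <- runif(1, 1.01, 3)
    pair <- thresholds_for_or(curve, target) # internally cross-checked <= 1e-6
    root_l <- ssndtrisk:::or_root(curve, target, "lower")
    root_u <- ssndtrisk:::or_root(curve, target, "upper")
    expect_lt(abs(pair$lower_mm - root_l), 1e-6)
    expect_lt(abs(pair$upper_mm - root_u), 1e-6)
    # reconstruction: evaluating the OR at the thresholds returns the target
    expect_equal(odds_ratio_at(curve, pair$lower_mm), target, tolerance = 1e-9)
    expect_equal(odds_ratio_at(curve, pair$upper_mm), target, tolerance = 1e-9)
  }
})

test_that("thresholds collapse onto the minimum as the target approaches 1", {
  curve <- published_curve()
  pair <- thresholds_for_or(curve, 1 + 1e-9)
  expect_equal(pair$lower_mm, curve$x_min_mm, tolerance = 1e-3)
  expect_equal(pair$upper_mm, curve$x_min_mm, tolerance = 1e-3)
  expect_error(thresholds_for_or(curve, 1), "> 1")
  expect_error(thresholds_for_or(curve, 0.9), "> 1")
})

test_that("the threshold grid is monotone with widening bands", {
  curve <- published_curve()
  grid <- threshold_grid(curve)
  expect_equal(nrow(grid), 10)
  expect_true(all(diff(grid$lower_mm) < 0))
  expect_true(all(diff(grid$upper_mm) > 0))
  widths <- grid$upper_mm - grid$lower_mm
  expect_true(all(diff(widths) > 0))
  # pairs are equidistant from the minimum
  expect_equal(
    grid$upper_mm - curve$x_min_mm,
    curve$x_min_mm - grid$lower_mm
  )
  one <- threshold_grid(curve, targets = 1.5)
  expect_equal(nrow(one), 1)
})

test_that("the local gradient matches a direct evaluation of the logit", {
  curve <- published_curve()
  eta <- function(x) 0.238 * (x - 7.8) + 0.051 * (x - 7.8)^2
  xs <- seq(0, 14, by = 0.25)
  expect_equal(
    local_or_per_mm(curve, xs),
    exp(eta(xs + 1) - eta(xs)),
    tolerance = 1e-12
  )
  # a symmetric 1 mm step across the minimum leaves the odds unchanged
  expect_equal(local_or_per_mm(curve, curve$x_min_mm - 0.5), 1)
  expect_true(all(diff(local_or_per_mm(curve, xs)) > 0))
  # instantaneous variant is exactly 1 at the minimum itself
  expect_equal(
    local_or_per_mm(curve, curve$x_min_mm, method = "derivative"), 1
  )
})

test_that("plot methods return ggplot objects", {
  curve <- published_curve()
  expect_s3_class(autoplot(curve), "ggplot")
  expect_s3_class(autoplot(curve, scheme = build_zone_scheme(curve)), "ggplot")
  expect_s3_class(plot_local_gradient(curve), "ggplot")
})
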