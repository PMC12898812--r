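# Risk zones, per-zone prevalence and screening metrics.

test_that("default anchors build nested bands with five ordered zones", {
  scheme <- build_zone_scheme(published_curve())
  b <- scheme$bands
  expect_equal(scheme$labels, c("Safe", "Mild", "Moderate", "High", "Extreme"))
  expect_true(all(diff(b$lower_mm) < 0))
  expect_true(all(diff(b$upper_mm) > 0))
  # published band boundaries, coefficient-rounding tolerance
  expect_equal(b$lower_mm, c(3.60, 2.67, 2.10, 1.80), tolerance = 0.05 / 1.8)
  expect_equal(b$upper_mm, c(7.37, 8.30, 8.87, 9.17), tolerance = 0.05 / 7)
})

test_that("anchor validation and minimal schemes work", {
  curve <- published_curve()
  expect_error(build_zone_scheme(curve, c(1.2, 1.2)), "strictly increasing")
  expect_error(build_zone_scheme(curve, c(1.5, 1.2)), "strictly increasing")
  expect_error(build_zone_scheme(curve, c(0.9, 1.5)), "> 1")
  two <- build_zone_scheme(curve, anchor_ors = 1.5)
  expect_equal(two$labels, c("Safe", "Extreme"))
  expect_equal(assign_zone(two, curve$x_min_mm), factor("Safe",
    levels = c("Safe", "Extreme"), ordered = TRUE
  ))
})

test_that("zone assignment is a partition with a safer-zone boundary rule", {
  scheme <- build_zone_scheme(published_curve())
  b <- scheme$bands
  expect_equal(as.character(assign_zone(scheme, 5.5)), "Safe")
  expect_equal(as.character(assign_zone(scheme, 9.5)), "Extreme")
  # boundary values map inward
  expect_equal(as.character(assign_zone(scheme, b$upper_mm[1])), "Safe")
  expect_equal(as.character(assign_zone(scheme, b$lower_mm[4])), "High")
  expect_error(assign_zone(scheme, NA_real_), "finite")
  # every finite value lands in exactly one zone; counts conserve n
  xs <- seq(-2, 20, by = 0.05)
  z <- assign_zone(scheme, xs)
  expect_false(anyNA(z))
  expect_equal(sum(table(z)), length(xs))
})

test_that("model risk is monotone across zones on each arm of the U", {
  curve <- published_curve()
  scheme <- build_zone_scheme(curve)
  b <- scheme$bands
  # right arm: representative points of successive zones have increasing OR
  pts_right <- c(
    curve$x_min_mm,
    mean(c(b$upper_mm[1], b$upper_mm[2])),
    mean(c(b$upper_mm[2], b$upper_mm[3])),
    mean(c(b$upper_mm[3], b$upper_mm[4])),
    b$upper_mm[4] + 2
  )
  expect_true(all(diff(odds_ratio_at(curve, pts_right)) > 0))
  pts_left <- c(
    curve$x_min_mm,
    mean(c(b$lower_mm[1], b$lower_mm[2])),
    mean(c(b$lower_mm[2], b$lower_mm[3])),
    mean(c(b$lower_mm[3], b$lower_mm[4])),
    b$lower_mm[4] - 0.5
  )
  expect_true(all(diff(odds_ratio_at(curve, pts_left)) > 0))
})

test_that("the zone report reproduces published counts and prevalences", {
  scheme <- build_zone_scheme(published_curve())
  feet <- feet_from_zone_counts()
  report <- zone_report(scheme, feet)
  counts <- published_zone_counts()
  got <- report[match(counts$zone, report$zone), ]
  expect_equal(got$n_feet, counts$n_feet)
  expect_equal(got$n_injured, counts$n_injured)
  expect_equal(
    round(got$prevalence_pct, 1),
    c(4.2, 16.0, 0.0, 25.0, 52.4)
  )
  total <- report[report$zone == "Total", ]
  expect_equal(total$n_feet, 274)
  expect_equal(total$n_injured, 58)
  expect_equal(round(total$prevalence_pct, 1), 21.2)
  # empty-zone flag: Moderate has feet here, so fabricate a concentrated set
  allsafe <- dplyr::mutate(feet, ssndt_mm = 5.5)
  rep2 <- zone_report(scheme, allsafe)
  expect_equal(rep2$n_feet[rep2$zone == "Safe"], nrow(feet))
  expect_true(all(rep2$empty[rep2$zone %in% c("Mild", "Moderate", "High", "Extreme")]))
  expect_equal(rep2$prevalence_pct[rep2$zone == "Extreme"], 0)
})

test_that("screening metrics match a brute-force confusion recount", {
  scheme <- build_zone_scheme(published_curve())
  feet <- feet_from_zone_counts()
  m <- screening_metrics(feet, scheme)
  # brute force from per-row labels
  z <- as.character(assign_zone(scheme, feet$ssndt_mm))
  pos <- z %in% c("High", "Extreme")
  expect_equal(m$tp, sum(pos & feet$injured == 1))
  expect_equal(m$fp, sum(pos & feet$injured == 0))
  expect_equal(m$tn, sum(!pos & feet$injured == 0))
  expect_equal(m$fn, sum(!pos & feet$injured == 1))
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, m$tn / (m$tn + m$fp))
  expect_equal(m$ppv, m$tp / (m$tp + m$fp))
  expect_equal(m$npv, m$tn / (m$tn + m$fn))
  expect_equal(m$accuracy, (m$tp + m$tn) / nrow(feet))
})

test_that("degenerate classifications flag undefined margins", {
  scheme <- build_zone_scheme(published_curve())
  feet <- feet_from_zone_counts()
  all_pos <- dplyr::mutate(feet, ssndt_mm = 12)
  m <- screening_metrics(all_pos, scheme)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_true(is.na(m$npv))
})

test_that("the proportion sample-size formula evaluates correctly", {
  expect_equal(sample_size_proportion(0.25, 0.05), (1.96 / 0.05)^2 * 0.25 * 0.75)
  expect_equal(round(sample_size_proportion(0.25, 0.05), 2), 288.12)
  expect_equal(round(sample_size_proportion(0.50, 0.05), 2), 384.16)
  expect_equal(sample_size_proportion(1e-12, 0.05), 0, tolerance = 1e-6)
  expect_equal(sample_size_proportion(0.25, 0.05, ceiling = TRUE), 289)
  expect_error(sample_size_proportion(1.2, 0.05), "p")
  expect_error(sample_size_proportion(0.2, 0), "delta")
})
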