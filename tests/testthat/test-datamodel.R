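test_that("a well-formed CSV reads back with the expected dimensions", {
  feet <- simulate_feet(n_participants = 137, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_result(feet, path)
  got <- read_feet(path)
  expect_equal(nrow(got), 274)
  expect_equal(length(unique(got$participant_id)), 137)
  expect_equal(nrow(attr(got, "validation")), 0)
})

test_that("result tables round-trip through CSV field-for-field", {
  curve <- published_curve()
  grid <- threshold_grid(curve)
  path <- withr::local_tempfile(fileext = ".csv")
  write_result(grid, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(grid), tolerance = 1e-12)

  scheme <- build_zone_scheme(curve)
  report <- zone_report(scheme, feet_from_zone_counts())
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_result(report, path2)
  back2 <- readr::read_csv(path2, show_col_types = FALSE)
  expect_equal(nrow(back2), 6) # 5 zones + total
  expect_equal(back2$n_feet, report$n_feet)
  expect_equal(back2$prevalence_pct, report$prevalence_pct, tolerance = 1e-12)
})

test_that("unicode participant ids survive a round-trip", {
  feet <- simulate_feet(n_participants = 4, seed = 2)
  feet$participant_id <- rep(c("ƒoo-1", "zażółć-2", "Αθλητής-3", "p4"), each = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_result(feet, path)
  got <- read_feet(path)
  expect_setequal(unique(got$participant_id), unique(feet$participant_id))
})

test_that("schema violations are errors, not silent repairs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path)
  expect_error(read_feet(path), "empty")

  feet <- simulate_feet(n_participants = 5, seed = 3)
  # a third foot for one participant necessarily repeats a side
  tri <- dplyr::bind_rows(feet, feet[1, ])
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tri, path2)
  expect_error(read_feet(path2), "duplicate")
  # and more than two rows per participant is rejected at validation
  tri2 <- dplyr::bind_rows(feet, dplyr::mutate(feet[1:2, ], ssndt_mm = 9))
  expect_error(fit_injury_model(tri2), "more than 2 feet")

  # missing required column
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(feet, -ssndt_mm), path3)
  expect_error(read_feet(path3), "missing required column")

  # non-binary outcome without an explicit mapping
  bad <- dplyr::mutate(feet, injured = ifelse(injured == 1, "yes", "no"))
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path4)
  expect_error(read_feet(path4), "0/1")
  # ... and the same file is accepted with the mapping made explicit
  ok <- read_feet(path4, injured_values = c(yes = 1, no = 0))
  expect_equal(sort(unique(ok$injured)), unique(sort(feet$injured)))

  # duplicate (participant, side)
  dup <- feet
  dup$foot_side <- "left"
  path5 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, path5)
  expect_error(read_feet(path5), "duplicate")
})

test_that("implausible or incomplete rows are rejected with reasons", {
  feet <- simulate_feet(n_participants = 10, seed = 4)
  feet$ssndt_mm[1] <- 40 # outside the plausibility window
  feet$load_h_per_week[3] <- NA # missing covariate -> listwise rejection
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(feet, path)
  expect_message(got <- read_feet(path), "rejected")
  rep <- attr(got, "validation")
  expect_equal(nrow(rep), 2)
  expect_match(rep$reason[rep$row == 1], "outside")
  expect_match(rep$reason[rep$row == 3], "covariate")
  expect_equal(nrow(got), nrow(feet) - 2)
})

test_that("comma-decimal input is refused rather than misread", {
  feet <- simulate_feet(n_participants = 5, seed = 5)
  lines <- c(
    paste(names(feet), collapse = ";"),
    apply(feet, 1, function(r) {
      r["ssndt_mm"] <- sub(".", ",", r["ssndt_mm"], fixed = TRUE)
      paste(r, collapse = ";")
    })
  )
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path)
  expect_error(read_feet(path), "comma decimal")
})

test_that("schema_map renames file columns to canonical names", {
  feet <- simulate_feet(n_participants = 6, seed = 6)
  renamed <- dplyr::rename(feet, id = participant_id, navdrop = ssndt_mm)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(renamed, path)
  expect_error(read_feet(path), "missing required column")
  got <- read_feet(path, schema_map = c(participant_id = "id", ssndt_mm = "navdrop"))
  expect_equal(got$ssndt_mm, feet$ssndt_mm, tolerance = 1e-9)
})
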