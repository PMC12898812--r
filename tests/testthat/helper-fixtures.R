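# Shared fixtures, all built in code.

# Published quadratic coefficients (centered scale) and the sample SSNDT
# mean they were centered at; the reference curve used throughout.
published_curve <- function() {
  risk_curve(beta1 = 0.238, beta2 = 0.051, ssndt_mean = 7.8)
}

# Printed two-sided thresholds for OR targets 1.1..2.0 (mm).
published_threshold_table <- function() {
  tibble::tibble(
    or_target = seq(1.1, 2.0, by = 0.1),
    lower_mm = c(4.12, 3.60, 3.22, 2.92, 2.67, 2.45, 2.26, 2.10, 1.94, 1.80),
    upper_mm = c(6.85, 7.37, 7.75, 8.05, 8.30, 8.52, 8.71, 8.87, 9.03, 9.17)
  )
}

# Printed bootstrap 95% CIs for the same grid (mm).
published_bootstrap_cis <- function() {
  tibble::tibble(
    or_target = seq(1.1, 2.0, by = 0.1),
    lower_mm = c(4.12, 3.60, 3.22, 2.92, 2.67, 2.45, 2.26, 2.10, 1.94, 1.80),
    lower_lo = c(1.49, 1.37, 1.30, 1.21, 1.18, 1.12, 1.14, 1.12, 1.11, 1.09),
    lower_hi = c(5.78, 5.36, 5.06, 4.84, 4.65, 4.48, 4.34, 4.20, 4.08, 3.98),
    upper_mm = c(6.85, 7.37, 7.75, 8.05, 8.30, 8.52, 8.71, 8.87, 9.03, 9.17),
    upper_lo = c(3.66, 4.43, 5.02, 5.48, 5.85, 6.17, 6.42, 6.66, 6.89, 7.06),
    upper_hi = c(8.06, 8.53, 8.87, 9.13, 9.36, 9.59, 9.76, 9.93, 10.08, 10.21)
  )
}

# Published per-zone counts (feet, injured) for the five-zone scheme.
published_zone_counts <- function() {
  tibble::tibble(
    zone = c("Safe", "Mild", "Moderate", "High", "Extreme"),
    n_feet = c(118, 50, 16, 8, 82),
    n_injured = c(5, 8, 0, 2, 43)
  )
}

# Foot-level rows realising given per-zone counts: feet are placed at
# representative SSNDT values inside each zone of the published scheme.
feet_from_zone_counts <- function(counts = published_zone_counts()) {
  scheme <- build_zone_scheme(published_curve())
  b <- scheme$bands
  # representative interior points: Safe centre; ring midpoints (upper arm);
  # Extreme beyond the widest band
  rep_x <- c(
    Safe = mean(c(b$lower_mm[1], b$upper_mm[1])),
    Mild = mean(c(b$upper_mm[1], b$upper_mm[2])),
    Moderate = mean(c(b$upper_mm[2], b$upper_mm[3])),
    High = mean(c(b$upper_mm[3], b$upper_mm[4])),
    Extreme = b$upper_mm[4] + 1
  )
  rows <- purrr::pmap_dfr(counts, function(zone, n_feet, n_injured) {
    tibble::tibble(
      ssndt_mm = rep(rep_x[[zone]], n_feet),
      injured = c(rep(1, n_injured), rep(0, n_feet - n_injured))
    )
  })
  n <- nrow(rows)
  rows$participant_id <- sprintf("Z%03d", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)])
  rows$foot_side <- rep(c("left", "right"), length.out = n)
  rows$load_h_per_week <- 7.7
  rows$experience_years <- 4.3
  rows
}

# Small deterministic ratings table for ICC tests.
ratings_fixture <- function(n = 18, k = 2, noise_sd = 1, seed = 42) {
  set.seed(seed)
  truth <- rnorm(n, 8, 3)
  sapply(seq_len(k), function(j) truth + rnorm(n, 0, noise_sd))
}
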