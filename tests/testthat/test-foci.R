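# Focus-count summaries, repair kinetics, expected-vs-observed hits.

foci_df <- function(counts_by_group) {
  do.call(rbind, lapply(counts_by_group, function(g) {
    data.frame(condition = g$condition, dose_Gy = g$dose_Gy,
               timepoint_h = g$timepoint_h,
               nucleus_id = seq_along(g$counts), foci_count = g$counts)
  }))
}

test_that("group summaries are exact for degenerate and Poisson data", {
  const <- foci_df(list(
    list(condition = "irr", dose_Gy = 2, timepoint_h = 1, counts = rep(7, 30)),
    list(condition = "ctrl", dose_Gy = 0, timepoint_h = 1, counts = rep(2, 30))))
  kin <- summarize_foci(const)
  expect_equal(kin$mean_foci, 7)
  expect_equal(kin$se_foci, 0)
  expect_equal(kin$background, 2)
  expect_equal(kin$excess, 5)
  expect_equal(kin$fraction_remaining, 1)

  set.seed(55)
  pois <- foci_df(list(
    list(condition = "irr", dose_Gy = 2, timepoint_h = 1,
         counts = stats::rpois(200, 22)),
    list(condition = "ctrl", dose_Gy = 0, timepoint_h = 1,
         counts = stats::rpois(200, 2))))
  kin <- summarize_foci(pois)
  expect_lt(abs(kin$mean_foci - 22), 3 * sqrt(22 / 200))
  expect_lt(abs(kin$excess - 20), 3 * sqrt(22 / 200) + 3 * sqrt(2 / 200))
})

test_that("background falls back to the pooled control mean and warns without controls", {
  d <- foci_df(list(
    list(condition = "irr", dose_Gy = 2, timepoint_h = 6, counts = rep(10, 25)),
    list(condition = "ctrl", dose_Gy = 0, timepoint_h = 1, counts = rep(3, 25))))
  kin <- summarize_foci(d)  # 6 h has no time-matched control
  expect_equal(kin$background, 3)

  no_ctrl <- foci_df(list(
    list(condition = "irr", dose_Gy = 2, timepoint_h = 1, counts = rep(10, 25))))
  expect_warning(kin2 <- summarize_foci(no_ctrl), "control")
  expect_equal(kin2$excess, 10)

  expect_warning(
    summarize_foci(foci_df(list(
      list(condition = "irr", dose_Gy = 2, timepoint_h = 1, counts = rep(4, 5)),
      list(condition = "c", dose_Gy = 0, timepoint_h = 1, counts = rep(1, 5))))),
    "nuclei")
})

test_that("SE scales as 1/sqrt(n) on Poisson counts", {
  set.seed(66)
  ses <- vapply(c(50, 200, 800), function(n) {
    d <- foci_df(list(
      list(condition = "irr", dose_Gy = 2, timepoint_h = 1,
           counts = stats::rpois(n, 20)),
      list(condition = "ctrl", dose_Gy = 0, timepoint_h = 1,
           counts = stats::rpois(n, 2))))
    summarize_foci(d)$se_foci[1]
  }, numeric(1))
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.35)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.35)
})

test_that("exact halving gives a one-hour half-time", {
  kin <- data.frame(timepoint_h = c(1, 2, 3), excess = c(18, 9, 4.5))
  dec <- fit_decay(kin, plateau = FALSE)
  expect_equal(dec$k_per_h, log(2), tolerance = 1e-6)
  expect_equal(dec$half_time_h, 1, tolerance = 1e-6)
  expect_equal(dec$plateau, 0)
})

test_that("noise-free exponential-plus-plateau input is recovered exactly", {
  t <- c(1, 2, 6, 12, 18, 24)
  kin <- data.frame(timepoint_h = t, excess = 20 * exp(-0.3 * t) + 1)
  dec <- fit_decay(kin)
  expect_equal(dec$k_per_h, 0.3, tolerance = 1e-6)
  expect_equal(dec$e0, 20, tolerance = 1e-6)
  expect_equal(dec$plateau, 1, tolerance = 1e-6)
})

test_that("repair rate is recovered within 10% from synthetic nuclei", {
  truth <- simulation_truth(foci_k_per_h = 0.3, foci_nuclei = 200)
  dat <- simulate_foci(truth, seed = 12)
  kin <- summarize_foci(dat)
  dec <- fit_decay(kin[kin$dose_Gy > 0, ])
  expect_equal(dec$k_per_h, 0.3, tolerance = 0.1)
  # the published qualitative claim: most damage resolved by 6 h
  fr6 <- kin$fraction_remaining[kin$dose_Gy > 0 & kin$timepoint_h == 6]
  expect_lt(fr6, 0.5)
})

test_that("a flat timecourse is flagged non-identifiable", {
  kin <- data.frame(timepoint_h = c(1, 2, 6, 12), excess = rep(8, 4))
  expect_warning(dec <- fit_decay(kin), "identifiable")
  expect_false(dec$identifiable)
  expect_error(fit_decay(data.frame(timepoint_h = 1:4, excess = rep(0, 4))),
               "positive excess")
})

test_that("observed initial excess is compared to the Poisson expectation", {
  stats2gy <- mean_traversals(2, std_beam(), std_geometry())
  expect_equal(stats2gy$mean_hits, 20.3, tolerance = 1e-2)

  set.seed(77)
  d <- foci_df(list(
    list(condition = "irr", dose_Gy = 2, timepoint_h = 1,
         counts = stats::rpois(400, 20.3)),
    list(condition = "ctrl", dose_Gy = 0, timepoint_h = 1,
         counts = rep(0, 400))))
  cmp <- expected_vs_observed(summarize_foci(d), stats2gy)
  expect_equal(cmp$expected_hits_int, 20)
  expect_equal(cmp$ratio_observed_expected, 1, tolerance = 0.05)

  zero <- mean_traversals(0, std_beam(), std_geometry())
  cmp0 <- suppressWarnings(expected_vs_observed(summarize_foci(d), zero))
  expect_true(is.na(cmp0$ratio_observed_expected))
})
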