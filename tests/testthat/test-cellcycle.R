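# DNA-content histogram deconvolution and timecourse summaries.

make_hist <- function(fractions, events = 1e5, seed = 1, truth = NULL, ...) {
  if (is.null(truth)) truth <- simulation_truth()
  simulate_dna_histogram(truth, seed = seed, fractions = fractions,
                         events = events, ...)
}

test_that("histogram constructor enforces its invariants", {
  expect_error(dna_histogram(c(1, 2, 1.5), c(1, 1, 1)), "increasing")
  expect_error(dna_histogram(c(1, 2, 4), c(1, 1, 1)), "uniform")
  expect_error(dna_histogram(1:3, c(-1, 1, 1)), "non-negative")
  expect_error(dna_histogram(1:3, c(0, 0, 0)), "no events")
})

test_that("a pure-G1 histogram is fit as nearly all G1", {
  h <- make_hist(c(1, 0, 0), seed = 21)
  fit <- suppressWarnings(fit_djf(h))
  expect_gte(fit$f_g1, 0.98)
  expect_lte(fit$f_s + fit$f_g2, 0.02)
})

test_that("generator/fitter round trip recovers phase fractions", {
  truth <- c(0.60, 0.17, 0.23)
  for (s in 1:3) {
    fit <- fit_djf(make_hist(truth, seed = 30 + s))
    expect_equal(fit$f_g1, truth[1], tolerance = 0.03 / truth[1])
    expect_lt(abs(fit$f_s - truth[2]), 0.03)
    expect_lt(abs(fit$f_g2 - truth[3]), 0.03)
    expect_equal(fit$f_g1 + fit$f_s + fit$f_g2, 1, tolerance = 1e-6)
  }
})

test_that("fractions are invariant to count scaling and x-axis gain", {
  h <- make_hist(c(0.5, 0.25, 0.25), seed = 44)
  base <- fit_djf(h)

  scaled <- dna_histogram(h$bin_centers, h$counts * 4)
  fs <- fit_djf(scaled)
  expect_equal(fs$f_g1, base$f_g1, tolerance = 1e-6)
  expect_equal(fs$f_s, base$f_s, tolerance = 1e-6)

  gained <- dna_histogram(h$bin_centers * 1.3, h$counts)
  fg <- fit_djf(gained)
  expect_equal(fg$mu_g1, base$mu_g1 * 1.3, tolerance = 0.01)
  expect_lt(abs(fg$f_g1 - base$f_g1), 0.01)
  expect_lt(abs(fg$f_g2 - base$f_g2), 0.01)
})

test_that("unstable inputs are refused", {
  small <- suppressWarnings(make_hist(c(0.6, 0.2, 0.2), events = 500,
                                      seed = 5))
  expect_error(suppressWarnings(fit_djf(small)), "events")
  few_bins <- make_hist(c(0.6, 0.2, 0.2), seed = 6, n_bins = 30)
  expect_error(fit_djf(few_bins), "50 bins")
})

test_that("recovery improves as events grow", {
  truth <- c(0.55, 0.20, 0.25)
  err_at <- function(events, seed) {
    f <- fit_djf(make_hist(truth, events = events, seed = seed))
    mean(abs(c(f$f_g1, f$f_s, f$f_g2) - truth))
  }
  e5 <- mean(vapply(1:5, function(s) err_at(1e5, 50 + s), numeric(1)))
  expect_lt(e5, 0.03)
  e6 <- err_at(1e6, 60)
  expect_lt(e6, 0.01)
})

test_that("timecourse summaries reproduce hand-computed means and SEs", {
  df <- data.frame(
    condition = "normoxia",
    timepoint_h = rep(c(2, 6, 12), each = 2),
    f_g1 = c(0.60, 0.62, 0.58, 0.60, 0.61, 0.63),
    f_s = c(0.17, 0.15, 0.19, 0.17, 0.16, 0.14),
    f_g2 = c(0.23, 0.23, 0.23, 0.23, 0.23, 0.23))
  out <- summarize_timecourse(df)
  g1_2h <- out$timecourse[out$timecourse$timepoint_h == 2 &
                            out$timecourse$phase == "G1", ]
  expect_equal(g1_2h$mean_pct, 61)
  expect_equal(g1_2h$se_pct, stats::sd(c(60, 62)) / sqrt(2))
  grand_g1 <- out$grand[out$grand$phase == "G1", ]
  expect_equal(grand_g1$mean_pct, mean(df$f_g1) * 100)
  expect_equal(grand_g1$se_pct, stats::sd(df$f_g1 * 100) / sqrt(6))
  # per-sample percentages sum to 100
  sums <- tapply(out$grand$mean_pct, out$grand$condition, sum)
  expect_equal(as.numeric(sums), 100)

  # constant fractions: grand mean equals the constant, SE = 0
  const <- df; const$f_g1 <- 0.6; const$f_s <- 0.2; const$f_g2 <- 0.2
  gc <- summarize_timecourse(const)$grand
  expect_equal(gc$mean_pct[gc$phase == "G1"], 60)
  expect_equal(gc$se_pct[gc$phase == "G1"], 0)
})

test_that("a known G1 offset between conditions shows up in grand means", {
  base <- c(0.55, 0.22, 0.23)
  shift <- c(0.63, 0.18, 0.19)  # G1 +0.08
  fits <- list()
  for (s in 1:4) {
    fits[[length(fits) + 1L]] <- fit_djf(make_hist(
      base, seed = 70 + s, condition = "normoxia", timepoint_h = s))
    fits[[length(fits) + 1L]] <- fit_djf(make_hist(
      shift, seed = 80 + s, condition = "hypoxia", timepoint_h = s))
  }
  grand <- summarize_timecourse(fits)$grand
  g1 <- grand[grand$phase == "G1", ]
  diff_g1 <- g1$mean_pct[g1$condition == "hypoxia"] -
    g1$mean_pct[g1$condition == "normoxia"]
  expect_equal(diff_g1, 8, tolerance = 0.25)
})
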