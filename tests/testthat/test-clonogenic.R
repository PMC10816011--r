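# Plating efficiency, surviving fractions, SHMT fitting, RBE/OER.

test_that("plating efficiency is the mean colony fraction with its SE", {
  const <- data.frame(dose_Gy = 0, seeded = 100, colonies = c(35, 35, 35))
  pe <- plating_efficiency(const)
  expect_equal(pe$pe, 0.35)
  expect_equal(pe$se, 0)

  spread <- data.frame(dose_Gy = 0, seeded = 100, colonies = c(32, 35, 38))
  pe <- plating_efficiency(spread)
  expect_equal(pe$pe, 0.35)
  expect_equal(pe$se, 0.03 / sqrt(3), tolerance = 1e-9)

  single <- data.frame(dose_Gy = 0, seeded = 100, colonies = 25)
  pe <- plating_efficiency(single)
  expect_equal(pe$pe, 0.25)
  expect_true(is.na(pe$se))

  none <- data.frame(dose_Gy = 0, seeded = 100, colonies = c(0, 0))
  expect_error(plating_efficiency(none), "zero colonies")
  expect_error(plating_efficiency(data.frame(dose_Gy = 2, seeded = 100,
                                             colonies = 10)),
               "0 Gy")
})

test_that("surviving fractions normalise by PE and flag zero-colony dishes", {
  d <- data.frame(dose_Gy = c(0, 0, 2, 2, 4),
                  seeded = 100,
                  colonies = c(35, 35, 7, 7, 0))
  out <- surviving_fractions(d, 0.35)
  expect_equal(out$sf_table$sf[out$sf_table$dose_Gy == 2], 0.2)
  expect_equal(out$sf_table$sf[out$sf_table$dose_Gy == 0], 1)
  # the zero-colony 4 Gy dish is excluded and reported
  expect_false(4 %in% out$sf_table$dose_Gy)
  expect_equal(nrow(out$excluded), 1L)
  expect_equal(out$excluded$dose_Gy, 4)
})

test_that("SHMT survival has the closed-form special values", {
  expect_equal(shmt_survival(0, 2.5, 3.2), 1)
  expect_equal(shmt_survival(2, 2, 1), exp(-1))
  expect_equal(shmt_survival(2.98, 2.98, 1.07), 0.3878, tolerance = 2e-4)
  expect_error(shmt_survival(-1, 2, 1), "dose")
  expect_error(shmt_survival(1, -2, 1), "d0")
})

test_that("SHMT survival is strictly decreasing with S(0) = 1", {
  set.seed(303)
  for (i in 1:25) {
    d0 <- stats::runif(1, 0.3, 5)
    n <- stats::runif(1, 0.3, 4)
    doses <- sort(stats::runif(8, 0.01, 12))
    s <- shmt_survival(doses, d0, n)
    expect_true(all(diff(s) < 0))
    expect_equal(shmt_survival(0, d0, n), 1)
  }
})

test_that("log-survival approaches the final-slope line defined by d0 and n", {
  d0 <- 1.7; n <- 2.3
  d <- c(20, 24)  # far beyond the shoulder
  y <- log10(shmt_survival(d, d0, n))
  slope <- diff(y) / diff(d)
  expect_equal(slope, -1 / (d0 * log(10)), tolerance = 1e-5)
  intercept <- y[1] - slope * d[1]
  expect_equal(intercept, log10(n), tolerance = 1e-4)
})

test_that("fitting noise-free model data recovers the parameters exactly", {
  fit <- fit_shmt(sf_noise_free(c(0.5, 1, 2, 4, 8), 2, 1.5))
  expect_equal(fit$d0_Gy, 2, tolerance = 1e-6)
  expect_equal(fit$n, 1.5, tolerance = 1e-6)

  # pure exponential special case
  fit1 <- fit_shmt(sf_noise_free(c(0.5, 1, 2, 4, 8), 1, 1))
  expect_equal(fit1$d0_Gy, 1, tolerance = 1e-6)
  expect_equal(fit1$n, 1, tolerance = 1e-6)

  # sub-unity extrapolation numbers (high-LET curves) are allowed
  fitc <- fit_shmt(sf_noise_free(c(0.5, 1, 2, 4), 1.10, 0.34))
  expect_equal(fitc$d0_Gy, 1.10, tolerance = 1e-6)
  expect_equal(fitc$n, 0.34, tolerance = 1e-6)

  expect_error(fit_shmt(sf_noise_free(c(1, 2), 2, 1.5)), "3 distinct")
})

test_that("RBE and OER reproduce the published ratio structure", {
  xr_ip <- shmt_fit(2.98, 1.07, se_d0 = 0.20)
  c_ip <- shmt_fit(1.11, 0.64, se_d0 = 0.07)
  expect_equal(round(rbe(xr_ip, c_ip)$estimate, 2), 2.68)

  xr_lp <- shmt_fit(2.29, 0.94, se_d0 = 0.13)
  c_lp <- shmt_fit(0.90, 0.76, se_d0 = 0.03)
  expect_equal(round(rbe(xr_lp, c_lp)$estimate, 2), 2.54)

  hyp <- shmt_fit(1.68, 1.20, se_d0 = 0.08)
  expect_equal(oer(hyp, xr_ip)$estimate, 0.564, tolerance = 1e-3)
  xr_lp_hyp <- shmt_fit(2.50, 1.19, se_d0 = 0.16)
  expect_equal(oer(xr_lp_hyp, xr_lp)$estimate, 1.092, tolerance = 1e-3)

  # a metric of a fit against itself is 1; OER reciprocals multiply to 1
  expect_equal(rbe(xr_ip, xr_ip)$estimate, 1)
  expect_equal(oer(xr_ip, xr_ip)$estimate, 1)
  expect_equal(oer(hyp, xr_ip)$estimate * oer(xr_ip, hyp)$estimate, 1,
               tolerance = 1e-12)

  # first-order error propagation for the ratio
  m <- rbe(xr_ip, c_ip)
  expect_equal(m$se,
               (2.98 / 1.11) * sqrt((0.20 / 2.98)^2 + (0.07 / 1.11)^2),
               tolerance = 1e-12)
})

test_that("dose_at_survival inverts the survival curve", {
  f <- shmt_fit(2.4, 1)
  expect_equal(dose_at_survival(f, exp(-1)), 2.4, tolerance = 1e-9)

  set.seed(404)
  for (i in 1:20) {
    f <- shmt_fit(stats::runif(1, 0.5, 4), stats::runif(1, 0.3, 3))
    target <- stats::runif(1, 0.001, 0.999)
    d <- dose_at_survival(f, target)
    expect_equal(shmt_survival(d, f$d0_Gy, f$n), target, tolerance = 1e-9)
  }
  # target -> 1 gives dose -> 0
  expect_lt(dose_at_survival(shmt_fit(2, 1.5), 1 - 1e-9), 1e-4)
  expect_error(dose_at_survival(shmt_fit(2, 1.5), 1.2), "target")
  expect_error(dose_at_survival(shmt_fit(2, 1.5), 0), "target")
})

test_that("D0 recovery: median within 5%, log-t interval coverage in band", {
  set.seed(11)
  n_sim <- 500
  d0_hat <- numeric(n_sim)
  covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    rec <- draw_colony_dataset(2.98, 1.07, 0.35)
    fit <- fit_shmt(replicate_sf(rec))
    d0_hat[i] <- fit$d0_Gy
    ci <- confint(fit, "d0_Gy")
    covered[i] <- ci[1, "lower"] <= 2.98 && 2.98 <= ci[1, "upper"]
  }
  expect_lt(abs(stats::median(d0_hat) / 2.98 - 1), 0.05)
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 0.99)
})

test_that("analyze_survival fits every condition of a full dataset", {
  truth <- simulation_truth()
  counts <- simulate_colonies(truth, seed = 9)
  res <- analyze_survival(counts)
  expect_length(res, 8L)
  for (r in res) {
    expect_gt(r$fit$d0_Gy, 0)
    expect_gt(r$fit$n, 0)
    expect_true(r$pe$pe > 0 && r$pe$pe <= 1)
  }
})
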