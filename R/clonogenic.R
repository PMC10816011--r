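# Clonogenic assay statistics: plating efficiency, surviving fractions,
# single-hit multi-target (SHMT) regression, RBE and OER.

condition_cols <- c("oxygen", "quality", "plating")

condition_label <- function(df) {
  paste(df$quality[1], df$oxygen[1], df$plating[1], sep = "/")
}

#' Plating efficiency from unirradiated dishes
#'
#' PE is the fraction of seeded, unirradiated cells that grow into colonies:
#' the mean of colonies/seeded over replicate dishes, with the standard error
#' of that mean. With a single replicate the SE is `NA`.
#'
#' @param records data frame of colony records with columns `dose_Gy`,
#'   `seeded`, `colonies` (and optionally condition columns); only rows at
#'   0 Gy are used.
#' @return A list with elements `pe`, `se` and `n_replicates`.
#' @examples
#' d <- data.frame(dose_Gy = 0, seeded = 100, colonies = c(32, 35, 38))
#' plating_efficiency(d)
#' @export
plating_efficiency <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("dose_Gy", "seeded", "colonies") %in% names(records)))
  ctrl <- records[records$dose_Gy == 0, , drop = FALSE]
  if (nrow(ctrl) == 0L) {
    stop("no unirradiated (0 Gy) records: plating efficiency undefined",
         call. = FALSE)
  }
  if (any(ctrl$colonies > ctrl$seeded)) {
    stop("colonies exceed seeded cells in a 0 Gy record", call. = FALSE)
  }
  frac <- ctrl$colonies / ctrl$seeded
  if (all(ctrl$colonies == 0)) {
    stop("all unirradiated dishes have zero colonies: plating efficiency ",
         "is zero and surviving fractions are undefined", call. = FALSE)
  }
  n <- length(frac)
  list(pe = mean(frac),
       se = if (n > 1L) stats::sd(frac) / sqrt(n) else NA_real_,
       n_replicates = n)
}

#' Surviving fractions from colony counts
#'
#' SF(D) = (colonies/seeded) / PE per dish, aggregated to mean ± SE per dose.
#' Dishes with zero colonies at positive dose cannot enter a log-domain fit;
#' they are excluded from the aggregate and returned in `$excluded` for QC.
#'
#' @param records data frame with columns `dose_Gy`, `seeded`, `colonies`
#'   (one row per replicate dish).
#' @param pe plating efficiency, either the list returned by
#'   [plating_efficiency()] or a single number in (0, 1].
#' @return A list with `sf_replicates` (per-dish SF), `sf_table` (per dose:
#'   `dose_Gy`, `sf`, `se_sf`, `n`) and `excluded` (zero-colony dishes).
#' @examples
#' d <- data.frame(dose_Gy = c(0, 2), seeded = 100, colonies = c(35, 7))
#' surviving_fractions(d, 0.35)$sf_table
#' @export
surviving_fractions <- function(records, pe) {
  stopifnot(is.data.frame(records),
            all(c("dose_Gy", "seeded", "colonies") %in% names(records)))
  if (is.list(pe)) pe <- pe$pe
  if (!is.numeric(pe) || length(pe) != 1L || !is.finite(pe) ||
      pe <= 0 || pe > 1) {
    stop("`pe` must be a single number in (0, 1]", call. = FALSE)
  }
  rec <- records
  rec$sf <- (rec$colonies / rec$seeded) / pe
  bad <- rec$colonies == 0 & rec$dose_Gy > 0
  excluded <- rec[bad, , drop = FALSE]
  kept <- rec[!bad, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(kept, kept$dose_Gy), function(g) {
    n <- nrow(g)
    data.frame(dose_Gy = g$dose_Gy[1],
               sf = mean(g$sf),
               se_sf = if (n > 1L) stats::sd(g$sf) / sqrt(n) else NA_real_,
               n = n)
  }))
  agg <- agg[order(agg$dose_Gy), , drop = FALSE]
  rownames(agg) <- NULL
  list(sf_replicates = kept, sf_table = agg, excluded = excluded)
}

#' Single-hit multi-target survival
#'
#' S(D) = 1 - (1 - exp(-D/D0))^n. D0 is the final-slope 37% dose and n the
#' extrapolation number (the y-intercept of the back-extrapolated exponential
#' tail). S(0) = 1 for all parameters and S is strictly decreasing in dose.
#'
#' @param dose_Gy dose in Gy (vectorised, >= 0).
#' @param d0_Gy final-slope 37% dose, Gy (> 0).
#' @param n extrapolation number (> 0); n = 1 gives pure exponential
#'   survival.
#' @return Surviving fraction in (0, 1].
#' @examples
#' shmt_survival(2.98, d0_Gy = 2.98, n = 1.07)
#' @export
shmt_survival <- function(dose_Gy, d0_Gy, n) {
  if (any(dose_Gy < 0)) stop("dose must be >= 0", call. = FALSE)
  if (d0_Gy <= 0 || n <= 0) stop("d0 and n must be > 0", call. = FALSE)
  1 - (1 - exp(-dose_Gy / d0_Gy))^n
}

#' Construct an SHMT fit object from known parameters
#'
#' Wraps externally obtained (e.g. published) survival-curve parameters in
#' the same container [fit_shmt()] returns, so RBE/OER can be computed from
#' them.
#'
#' @param d0_Gy final-slope 37% dose, Gy.
#' @param n extrapolation number.
#' @param se_d0,se_n standard errors (optional).
#' @param condition label for the condition the curve describes.
#' @param covariance 2x2 parameter covariance matrix (optional).
#' @param rss residual sum of squares of the fit (optional).
#' @param fit_domain domain the parameters were estimated in.
#' @param df residual degrees of freedom (optional; used by `confint`).
#' @return An object of class `shmt_fit`.
#' @export
shmt_fit <- function(d0_Gy, n, se_d0 = NA_real_, se_n = NA_real_,
                     condition = "", covariance = NULL, rss = NA_real_,
                     fit_domain = NA_character_, df = NA_real_) {
  if (d0_Gy <= 0 || n <= 0) stop("d0 and n must be > 0", call. = FALSE)
  structure(list(d0_Gy = d0_Gy, n = n, se_d0 = se_d0, se_n = se_n,
                 covariance = covariance, rss = rss,
                 condition = condition, fit_domain = fit_domain, df = df),
            class = "shmt_fit")
}

#' Confidence intervals for SHMT parameters
#'
#' Intervals are computed on the log scale (both parameters are positive
#' and their sampling distributions right-skewed) with a t quantile at the
#' fit's residual degrees of freedom, then back-transformed:
#' exp(log(est) +/- t * se/est).
#'
#' @param object an `shmt_fit`.
#' @param parm parameters to include (`"d0_Gy"`, `"n"`).
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix with `lower`/`upper` columns.
#' @export
confint.shmt_fit <- function(object, parm = c("d0_Gy", "n"), level = 0.95,
                             ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  tq <- if (is.finite(object$df) && object$df > 0) {
    stats::qt(1 - (1 - level) / 2, object$df)
  } else {
    stats::qnorm(1 - (1 - level) / 2)
  }
  se <- c(d0_Gy = object$se_d0, n = object$se_n)
  est <- c(d0_Gy = object$d0_Gy, n = object$n)
  out <- t(vapply(parm, function(p) {
    rel <- se[[p]] / est[[p]]
    c(lower = est[[p]] * exp(-tq * rel), upper = est[[p]] * exp(tq * rel))
  }, numeric(2)))
  out
}

#' @export
print.shmt_fit <- function(x, ...) {
  cat("Single-hit multi-target fit",
      if (nzchar(x$condition)) paste0(" [", x$condition, "]"), "\n", sep = "")
  cat(sprintf("  D0 = %.3f Gy (SE %.3f)\n", x$d0_Gy, x$se_d0))
  cat(sprintf("  n  = %.3f    (SE %.3f)\n", x$n, x$se_n))
  invisible(x)
}

# Straight-line init from the two highest doses in log10 space:
# log10 S ~ log10(n) - D / (d0 ln 10) on the exponential tail.
shmt_init <- function(dose, log10_sf) {
  ord <- order(dose, decreasing = TRUE)
  d <- dose[ord][1:2]
  y <- log10_sf[ord][1:2]
  slope <- (y[1] - y[2]) / (d[1] - d[2])
  d0 <- -1 / (slope * log(10))
  n <- 10^(y[1] - slope * d[1])
  if (!is.finite(d0) || !is.finite(n) || d0 <= 0 || n <= 0) {
    c(d0 = 1.5, n = 1)
  } else {
    c(d0 = min(max(d0, 1e-3), 1e3), n = min(max(n, 1e-3), 1e3))
  }
}

#' Fit the single-hit multi-target model to surviving fractions
#'
#' Performs least squares on log10(SF), matching the convention of plotting
#' survival on a logarithmic scale and reading n from the straight-line
#' extrapolation. The fit is unweighted by default: with few replicate
#' dishes, empirical per-dose standard errors are themselves so noisy that
#' delta-method weights (se_log10 = se_sf / (sf ln 10)) destabilise the
#' D0 estimate; pass `weighted = TRUE` to use them anyway (doses with
#' missing or zero SE then fall back to the median weight). Replicate-level
#' SF points (e.g. `surviving_fractions()$sf_replicates`) are accepted and
#' preferred over per-dose aggregates. Linear-domain fitting is available
#' via `domain = "linear"`.
#'
#' Unirradiated (0 Gy) points anchor the plating efficiency only and are
#' excluded from the regression: SF there is 1 by construction.
#'
#' @param sf_table data frame with columns `dose_Gy`, `sf` and optionally
#'   `se_sf` (as produced by [surviving_fractions()]).
#' @param condition label stored in the returned fit.
#' @param domain `"log10"` (default) or `"linear"`.
#' @param weighted use SE-derived weights when available (default `FALSE`).
#' @param start optional named vector `c(d0, n)` overriding the automatic
#'   initialisation.
#' @return An object of class `shmt_fit` with elements `d0_Gy`, `n`, `se_d0`,
#'   `se_n`, `covariance`, `rss`, `condition`, `fit_domain`.
#' @examples
#' doses <- c(0.5, 1, 2, 4, 8)
#' tab <- data.frame(dose_Gy = doses, sf = shmt_survival(doses, 2, 1.5))
#' fit_shmt(tab)
#' @export
fit_shmt <- function(sf_table, condition = "", domain = c("log10", "linear"),
                     weighted = FALSE, start = NULL) {
  domain <- match.arg(domain)
  stopifnot(is.data.frame(sf_table),
            all(c("dose_Gy", "sf") %in% names(sf_table)))
  tab <- sf_table[sf_table$dose_Gy > 0 & is.finite(sf_table$sf) &
                    sf_table$sf > 0, , drop = FALSE]
  if (length(unique(tab$dose_Gy)) < 3L) {
    stop("need >= 3 distinct positive doses with positive SF to fit",
         call. = FALSE)
  }
  dose <- tab$dose_Gy
  sf <- tab$sf
  se <- if ("se_sf" %in% names(tab)) tab$se_sf else rep(NA_real_, nrow(tab))

  if (is.null(start)) start <- shmt_init(dose, log10(sf))
  start <- list(d0 = unname(start[["d0"]]), n = unname(start[["n"]]))
  lower <- c(d0 = 1e-3, n = 1e-3)
  upper <- c(d0 = 1e3, n = 1e3)

  if (domain == "log10") {
    y <- log10(sf)
    w <- rep(1, length(y))
    if (weighted && any(is.finite(se) & se > 0)) {
      se_log <- se / (sf * log(10))
      w <- 1 / se_log^2
      w[!is.finite(w)] <- stats::median(w[is.finite(w)])
    }
    fit <- minpack.lm::nlsLM(
      y ~ log10(1 - (1 - exp(-dose / d0))^n),
      start = start, lower = lower, upper = upper, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12))
  } else {
    y <- sf
    w <- rep(1, length(y))
    if (weighted && any(is.finite(se) & se > 0)) {
      w <- 1 / se^2
      w[!is.finite(w)] <- stats::median(w[is.finite(w)])
    }
    fit <- minpack.lm::nlsLM(
      y ~ 1 - (1 - exp(-dose / d0))^n,
      start = start, lower = lower, upper = upper, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12))
  }
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, 2, 2, dimnames = list(names(est), names(est)))
  })
  shmt_fit(d0_Gy = est[["d0"]], n = est[["n"]],
           se_d0 = sqrt(vc["d0", "d0"]), se_n = sqrt(vc["n", "n"]),
           condition = condition, covariance = vc,
           rss = sum(stats::resid(fit)^2), fit_domain = domain,
           df = length(y) - 2)
}

# ratio of two independent estimates with first-order (delta-method) SE
ratio_with_se <- function(a, se_a, b, se_b) {
  r <- a / b
  se <- if (is.finite(se_a) && is.finite(se_b)) {
    abs(r) * sqrt((se_a / a)^2 + (se_b / b)^2)
  } else {
    NA_real_
  }
  list(estimate = r, se = se)
}

#' Relative biological effectiveness from two survival fits
#'
#' RBE = D0(reference X-rays) / D0(test radiation): doses producing equal
#' final-slope cell kill. The SE is propagated to first order assuming
#' independent fits. Comparing fits from different oxygen or plating
#' conditions triggers a warning.
#'
#' @param fit_xray `shmt_fit` for the reference X-ray curve.
#' @param fit_test `shmt_fit` for the test radiation curve.
#' @return A list of class `quality_metric` with `metric = "rbe"`,
#'   `estimate`, `se`, and the two input fits.
#' @examples
#' rbe(shmt_fit(2.98, 1.07, 0.20), shmt_fit(1.11, 0.64, 0.07))
#' @export
rbe <- function(fit_xray, fit_test) {
  stopifnot(inherits(fit_xray, "shmt_fit"), inherits(fit_test, "shmt_fit"))
  r <- ratio_with_se(fit_xray$d0_Gy, fit_xray$se_d0,
                     fit_test$d0_Gy, fit_test$se_d0)
  structure(list(metric = "rbe", estimate = r$estimate, se = r$se,
                 numerator = fit_xray, denominator = fit_test),
            class = "quality_metric")
}

#' Oxygen enhancement ratio from two survival fits
#'
#' OER = D0(hypoxia) / D0(normoxia): values above 1 mean hypoxic cells
#' tolerate more dose for the same kill (radioresistance). The SE is
#' propagated to first order.
#'
#' @param fit_hypoxia `shmt_fit` under hypoxia.
#' @param fit_normoxia `shmt_fit` under normoxia.
#' @return A list of class `quality_metric` with `metric = "oer"`.
#' @examples
#' oer(shmt_fit(1.68, 1.20, 0.08), shmt_fit(2.98, 1.07, 0.20))
#' @export
oer <- function(fit_hypoxia, fit_normoxia) {
  stopifnot(inherits(fit_hypoxia, "shmt_fit"),
            inherits(fit_normoxia, "shmt_fit"))
  r <- ratio_with_se(fit_hypoxia$d0_Gy, fit_hypoxia$se_d0,
                     fit_normoxia$d0_Gy, fit_normoxia$se_d0)
  structure(list(metric = "oer", estimate = r$estimate, se = r$se,
                 numerator = fit_hypoxia, denominator = fit_normoxia),
            class = "quality_metric")
}

#' @export
print.quality_metric <- function(x, ...) {
  cat(sprintf("%s = %.3f (SE %.3f)\n", toupper(x$metric), x$estimate, x$se))
  invisible(x)
}

#' Dose at a target surviving fraction
#'
#' Inverts S(D) = 1 - (1 - exp(-D/D0))^n in closed form:
#' D = -D0 * ln(1 - (1 - S)^(1/n)).
#'
#' @param fit an `shmt_fit` (or list with `d0_Gy` and `n`).
#' @param target_sf surviving fraction in (0, 1).
#' @return Dose in Gy; `shmt_survival(result)` returns `target_sf` to within
#'   1e-9.
#' @examples
#' dose_at_survival(shmt_fit(2, 1.5), 0.1)
#' @export
dose_at_survival <- function(fit, target_sf) {
  if (any(target_sf <= 0) || any(target_sf >= 1)) {
    stop("target surviving fraction must lie strictly in (0, 1)",
         call. = FALSE)
  }
  -fit$d0_Gy * log(1 - (1 - target_sf)^(1 / fit$n))
}

#' Per-condition survival analysis of a colony-count table
#'
#' Splits records by (oxygen, quality, plating), computes plating efficiency
#' from the 0 Gy dishes, surviving fractions, and an SHMT fit per condition.
#' Fits use replicate-level SF points in log10 space.
#'
#' @param records colony-count data frame with condition columns `oxygen`,
#'   `quality`, `plating` plus `dose_Gy`, `seeded`, `colonies`.
#' @param ... passed to [fit_shmt()].
#' @return A list with one element per condition, each containing `pe`,
#'   `sf_table`, `excluded` and `fit`.
#' @export
analyze_survival <- function(records, ...) {
  stopifnot(all(condition_cols %in% names(records)))
  key <- interaction(records[condition_cols], drop = TRUE, sep = "/")
  out <- lapply(split(records, key), function(g) {
    pe <- plating_efficiency(g)
    sf <- surviving_fractions(g, pe)
    repl <- sf$sf_replicates[sf$sf_replicates$dose_Gy > 0,
                             c("dose_Gy", "sf")]
    fit <- fit_shmt(repl, condition = condition_label(g), ...)
    list(condition = condition_label(g), pe = pe,
         sf_table = sf$sf_table, excluded = sf$excluded, fit = fit)
  })
  names(out) <- vapply(out, `[[`, character(1), "condition")
  out
}
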