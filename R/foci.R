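# gamma-H2AX focus kinetics: per-nucleus count summaries, background
# subtraction, exponential repair fits, and comparison against the
# Poisson-expected number of ion traversals.

#' Summarise per-nucleus focus counts over time
#'
#' Computes mean foci per nucleus with standard errors per condition and
#' timepoint, subtracts the unirradiated background (time-matched control
#' where one exists at the same timepoint, otherwise the pooled control
#' mean), and reports the fraction of the initial excess remaining at each
#' later timepoint.
#'
#' Rows with `dose_Gy == 0` are the unirradiated controls.
#'
#' @param data data frame with columns `condition`, `dose_Gy`,
#'   `timepoint_h`, `foci_count` (one row per nucleus; a `nucleus_id`
#'   column is allowed and ignored).
#' @param min_nuclei warn when a group has fewer nuclei than this.
#' @return An object of class `foci_kinetics`: a data frame per condition/
#'   timepoint with `mean_foci`, `se_foci`, `n_nuclei`, `background`,
#'   `excess` (floored at 0) and `fraction_remaining` (relative to the
#'   earliest irradiated timepoint).
#' @export
summarize_foci <- function(data, min_nuclei = 20) {
  stopifnot(is.data.frame(data),
            all(c("condition", "dose_Gy", "timepoint_h", "foci_count")
                %in% names(data)))
  if (any(data$foci_count < 0) || any(data$foci_count != round(data$foci_count))) {
    stop("foci counts must be non-negative integers", call. = FALSE)
  }
  ctrl <- data[data$dose_Gy == 0, , drop = FALSE]
  if (nrow(ctrl) == 0L) {
    warning("no unirradiated control group: excess foci reported as raw ",
            "means", call. = FALSE)
  }
  pooled_bg <- if (nrow(ctrl)) mean(ctrl$foci_count) else 0
  bg_by_time <- if (nrow(ctrl)) {
    vapply(split(ctrl$foci_count, ctrl$timepoint_h), mean, numeric(1))
  } else {
    numeric(0)
  }
  irr <- data[data$dose_Gy > 0, , drop = FALSE]
  groups <- split(irr, list(irr$condition, irr$timepoint_h), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    if (n < min_nuclei) {
      warning(sprintf("only %d nuclei for %s at %g h (>= %d recommended)",
                      n, g$condition[1], g$timepoint_h[1], min_nuclei),
              call. = FALSE)
    }
    tp <- as.character(g$timepoint_h[1])
    bg <- if (tp %in% names(bg_by_time)) bg_by_time[[tp]] else pooled_bg
    m <- mean(g$foci_count)
    data.frame(condition = g$condition[1], dose_Gy = g$dose_Gy[1],
               timepoint_h = g$timepoint_h[1],
               mean_foci = m,
               se_foci = if (n > 1L) stats::sd(g$foci_count) / sqrt(n)
                         else NA_real_,
               n_nuclei = n, background = bg,
               excess = max(m - bg, 0))
  }))
  out <- out[order(out$condition, out$timepoint_h), , drop = FALSE]
  out$fraction_remaining <- NA_real_
  for (cond in unique(out$condition)) {
    idx <- out$condition == cond
    e1 <- out$excess[idx][1]  # earliest timepoint
    if (e1 > 0) out$fraction_remaining[idx] <- out$excess[idx] / e1
  }
  rownames(out) <- NULL
  class(out) <- c("foci_kinetics", "data.frame")
  out
}

#' Fit exponential repair kinetics to excess foci
#'
#' Least-squares fit of excess(t) = E0 * exp(-k t) + plateau, giving the
#' repair rate k (per hour), the repair half-time ln(2)/k, and a residual
#' plateau of unrepaired damage. Requires at least three timepoints with
#' positive excess. A flat timecourse makes k non-identifiable; the fit is
#' then flagged.
#'
#' @param kinetics a [summarize_foci()] result (or any data frame with
#'   `timepoint_h` and `excess`), typically for one condition.
#' @param plateau allow a non-zero plateau (default `TRUE`).
#' @return List of class `foci_decay` with `k_per_h`, `half_time_h`, `e0`,
#'   `plateau`, `identifiable`, `rss`.
#' @examples
#' kin <- data.frame(timepoint_h = c(1, 2, 4), excess = c(18, 9, 4.5))
#' fit_decay(kin)
#' @export
fit_decay <- function(kinetics, plateau = TRUE) {
  stopifnot(all(c("timepoint_h", "excess") %in% names(kinetics)))
  pos <- kinetics[is.finite(kinetics$excess) & kinetics$excess > 0, ,
                  drop = FALSE]
  if (nrow(pos) < 3L) {
    stop("need >= 3 timepoints with positive excess to fit decay",
         call. = FALSE)
  }
  t <- pos$timepoint_h
  y <- pos$excess
  if (diff(range(y)) <= 1e-10 * max(y)) {
    # perfectly flat excess: decay rate cannot be identified
    warning("decay rate is not identifiable (flat excess timecourse)",
            call. = FALSE)
    return(structure(list(k_per_h = 0, half_time_h = NA_real_,
                          e0 = if (plateau) 0 else mean(y),
                          plateau = if (plateau) mean(y) else 0,
                          identifiable = FALSE, rss = 0),
                     class = "foci_decay"))
  }
  k_init <- {
    sl <- stats::coef(stats::lm(log(y) ~ t))[2]
    if (is.finite(sl) && sl < 0) -sl else 0.1
  }
  if (plateau) {
    fit <- minpack.lm::nlsLM(
      y ~ e0 * exp(-k * t) + p0,
      start = list(e0 = max(y), k = unname(k_init), p0 = min(y) / 2),
      lower = c(e0 = 0, k = 0, p0 = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ e0 * exp(-k * t),
      start = list(e0 = max(y), k = unname(k_init)),
      lower = c(e0 = 0, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
  }
  cf <- as.list(stats::coef(fit))
  k <- cf$k
  identifiable <- is.finite(k) && k > 1e-6
  if (!identifiable) {
    warning("decay rate is not identifiable (flat excess timecourse)",
            call. = FALSE)
  }
  structure(list(k_per_h = k,
                 half_time_h = if (identifiable) log(2) / k else NA_real_,
                 e0 = cf$e0,
                 plateau = if (plateau) cf$p0 else 0,
                 identifiable = identifiable,
                 rss = sum(stats::resid(fit)^2)),
            class = "foci_decay")
}

#' @export
print.foci_decay <- function(x, ...) {
  cat(sprintf("Focus repair: k = %.3f /h (t1/2 = %.2f h), E0 = %.1f, plateau = %.2f\n",
              x$k_per_h, x$half_time_h, x$e0, x$plateau))
  invisible(x)
}

#' Compare observed initial foci to Poisson-expected ion traversals
#'
#' Puts the background-subtracted initial excess of foci next to the
#' expected number of ion hits per nucleus for the matching beam and dose.
#' The expected count is also rounded to the nearest integer for a headline
#' figure. The ratio is `NA` when the expectation is zero.
#'
#' @param kinetics a [summarize_foci()] result for one condition; the
#'   earliest timepoint supplies the observed initial excess.
#' @param stats_row a [mean_traversals()] result (or one row of
#'   [traversal_table()]) at the same dose.
#' @return Data frame with `observed_excess`, `expected_hits`,
#'   `expected_hits_int` and `ratio_observed_expected`.
#' @export
expected_vs_observed <- function(kinetics, stats_row) {
  stopifnot(all(c("timepoint_h", "excess") %in% names(kinetics)),
            all(c("dose_Gy", "mean_hits") %in% names(stats_row)))
  if (nrow(stats_row) != 1L) {
    stop("`stats_row` must contain exactly one dose", call. = FALSE)
  }
  if ("dose_Gy" %in% names(kinetics) &&
      !isTRUE(all.equal(unique(kinetics$dose_Gy), stats_row$dose_Gy))) {
    warning("kinetics and traversal statistics are at different doses",
            call. = FALSE)
  }
  first <- kinetics[which.min(kinetics$timepoint_h), , drop = FALSE]
  lam <- stats_row$mean_hits
  data.frame(observed_excess = first$excess,
             expected_hits = lam,
             expected_hits_int = round(lam),
             ratio_observed_expected = if (lam > 0) first$excess / lam
                                       else NA_real_)
}
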