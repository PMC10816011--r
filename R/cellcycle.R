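# DNA-content histogram deconvolution: a Dean-Jett-Fox-style mixture of a
# Gaussian G1 peak, a Gaussian G2/M peak at roughly twice the G1 position,
# and a Gaussian-broadened rectangular S-phase bridge between them.

#' Construct a DNA-content histogram
#'
#' @param bin_centers strictly increasing, uniformly spaced fluorescence
#'   values (arbitrary units).
#' @param counts non-negative event counts per bin.
#' @param condition,timepoint_h,replicate optional sample metadata.
#' @return An object of class `dna_histogram`.
#' @export
dna_histogram <- function(bin_centers, counts, condition = NA_character_,
                          timepoint_h = NA_real_, replicate = NA_character_) {
  stopifnot(is.numeric(bin_centers), is.numeric(counts),
            length(bin_centers) == length(counts))
  if (any(diff(bin_centers) <= 0)) {
    stop("bin centers must be strictly increasing", call. = FALSE)
  }
  w <- diff(bin_centers)
  if (max(w) - min(w) > 1e-6 * stats::median(w)) {
    stop("bins must be uniform width", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) <= 0) stop("histogram has no events", call. = FALSE)
  structure(list(bin_centers = bin_centers, counts = counts,
                 condition = condition, timepoint_h = timepoint_h,
                 replicate = replicate),
            class = "dna_histogram")
}

# S-phase shape: unit-area rectangle on [mu1, mu2] convolved with a Gaussian
# of width sigma (measurement broadening).
broadened_rect <- function(x, mu1, mu2, sigma) {
  (stats::pnorm(x, mu1, sigma) - stats::pnorm(x, mu2, sigma)) / (mu2 - mu1)
}

djf_density <- function(x, a1, a2, as, mu1, r, cv1, cv2) {
  mu2 <- r * mu1
  a1 * stats::dnorm(x, mu1, cv1 * mu1) +
    a2 * stats::dnorm(x, mu2, cv2 * mu2) +
    as * broadened_rect(x, mu1, mu2, cv1 * mu1)
}

#' Fit a Dean-Jett-Fox-style cell-cycle model to a DNA histogram
#'
#' Least-squares fit of G1 Gaussian + G2/M Gaussian + Gaussian-broadened
#' rectangular S component to the binned counts. Each component has unit
#' area times a free amplitude, so phase fractions are the normalised
#' amplitudes and sum to 1 exactly. The G2/G1 position ratio is constrained
#' to [1.8, 2.05] (dye stoichiometry puts the G2/M peak near twice the G1
#' fluorescence); peak CVs are bounded by 0.2.
#'
#' Inputs are assumed debris- and doublet-gated upstream; histograms with
#' fewer than `min_events` events are refused because the fit is unstable.
#'
#' @param hist a [dna_histogram()].
#' @param ratio_init initial G2/G1 position ratio.
#' @param cv_init initial peak coefficient of variation.
#' @param min_events minimum total event count accepted.
#' @return An object of class `djf_fit` with phase fractions `f_g1`, `f_s`,
#'   `f_g2`, peak position `mu_g1`, `ratio_g2g1`, CVs, and `rss`.
#' @examples
#' set.seed(1)
#' x <- seq(10, 160, by = 1)
#' n <- hist(rnorm(5000, 50, 2.5), breaks = c(x - 0.5, max(x) + 0.5),
#'           plot = FALSE)$counts
#' fit_djf(dna_histogram(x, n))
#' @export
fit_djf <- function(hist, ratio_init = 1.95, cv_init = 0.05,
                    min_events = 1000) {
  stopifnot(inherits(hist, "dna_histogram"))
  x <- hist$bin_centers
  counts <- hist$counts
  if (length(x) < 50L) {
    stop("histogram must have at least 50 bins", call. = FALSE)
  }
  total <- sum(counts)
  if (total < min_events) {
    stop(sprintf("histogram has %d events; at least %d required for a ",
                 total, min_events), "stable fit", call. = FALSE)
  }
  width <- x[2] - x[1]
  mu1_init <- x[which.max(counts)]
  # amplitudes in event units: each component integrates to its amplitude
  scale <- total * width
  start <- list(a1 = 0.5 * scale, a2 = 0.2 * scale, as = 0.3 * scale,
                mu1 = mu1_init, r = ratio_init, cv1 = cv_init, cv2 = cv_init)
  lower <- c(a1 = 0, a2 = 0, as = 0,
             mu1 = min(x), r = 1.8, cv1 = 0.005, cv2 = 0.005)
  upper <- c(a1 = Inf, a2 = Inf, as = Inf,
             mu1 = max(x), r = 2.05, cv1 = 0.2, cv2 = 0.2)
  fit <- minpack.lm::nlsLM(
    counts ~ width * djf_density(x, a1, a2, as, mu1, r, cv1, cv2),
    start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- as.list(stats::coef(fit))
  amp <- c(g1 = p$a1, s = p$as, g2 = p$a2)
  frac <- amp / sum(amp)
  if (frac[["g2"]] < 1e-3 || frac[["g1"]] < 1e-3) {
    warning("a peak fraction collapsed to the boundary; histogram may be ",
            "single-peaked", call. = FALSE)
  }
  structure(list(f_g1 = frac[["g1"]], f_s = frac[["s"]], f_g2 = frac[["g2"]],
                 mu_g1 = p$mu1, ratio_g2g1 = p$r,
                 cv_g1 = p$cv1, cv_g2 = p$cv2,
                 rss = sum(stats::resid(fit)^2),
                 n_events = total,
                 condition = hist$condition, timepoint_h = hist$timepoint_h,
                 replicate = hist$replicate),
            class = "djf_fit")
}

#' @export
print.djf_fit <- function(x, ...) {
  cat("Cell-cycle fit: ",
      sprintf("G1 %.1f%%  S %.1f%%  G2 %.1f%%", 100 * x$f_g1, 100 * x$f_s,
              100 * x$f_g2),
      sprintf("  (G1 peak %.1f, G2/G1 %.3f)\n", x$mu_g1, x$ratio_g2g1),
      sep = "")
  invisible(x)
}

#' Convert a list of cell-cycle fits to a data frame
#'
#' @param fits list of `djf_fit` objects.
#' @return One row per fit with fractions, peak parameters and metadata.
#' @export
djf_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(condition = f$condition, timepoint_h = f$timepoint_h,
               replicate = f$replicate, f_g1 = f$f_g1, f_s = f$f_s,
               f_g2 = f$f_g2, mu_g1 = f$mu_g1, ratio_g2g1 = f$ratio_g2g1,
               rss = f$rss, n_events = f$n_events)
  }))
}

#' Summarise phase fractions over a timecourse
#'
#' Per condition and timepoint, the mean phase percentage and its standard
#' error over replicate samples; plus a per-condition grand mean over all
#' samples (all timepoints pooled), as used to report the average
#' distribution over an observation window.
#'
#' @param fits either a list of `djf_fit` objects or a data frame with
#'   columns `condition`, `timepoint_h`, `f_g1`, `f_s`, `f_g2`.
#' @return A list with `timecourse` (condition, timepoint_h, phase,
#'   mean_pct, se_pct, n) and `grand` (condition, phase, mean_pct, se_pct,
#'   n).
#' @export
summarize_timecourse <- function(fits) {
  df <- if (is.data.frame(fits)) fits else djf_fits_table(fits)
  stopifnot(all(c("condition", "timepoint_h", "f_g1", "f_s", "f_g2")
                %in% names(df)))
  long <- do.call(rbind, lapply(c("g1", "s", "g2"), function(ph) {
    data.frame(condition = df$condition, timepoint_h = df$timepoint_h,
               phase = toupper(ph), pct = 100 * df[[paste0("f_", ph)]])
  }))
  agg <- function(g) {
    n <- nrow(g)
    data.frame(mean_pct = mean(g$pct),
               se_pct = if (n > 1L) stats::sd(g$pct) / sqrt(n) else NA_real_,
               n = n)
  }
  tc <- do.call(rbind, lapply(
    split(long, list(long$condition, long$timepoint_h, long$phase),
          drop = TRUE),
    function(g) cbind(g[1, c("condition", "timepoint_h", "phase")], agg(g))))
  grand <- do.call(rbind, lapply(
    split(long, list(long$condition, long$phase), drop = TRUE),
    function(g) cbind(g[1, c("condition", "phase")], agg(g))))
  tc <- tc[order(tc$condition, tc$timepoint_h, tc$phase), ]
  grand <- grand[order(grand$condition, grand$phase), ]
  rownames(tc) <- rownames(grand) <- NULL
  list(timecourse = tc, grand = grand)
}
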