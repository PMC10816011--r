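# Synthetic-data generators emulating A549-style radiobiology experiments:
# binomial colony counts on SHMT survival curves, trimodal DNA-content
# histograms, and Poisson focus counts with exponential repair.

# Substream offsets: one global seed drives all generators, each via its own
# offset, so adding a generator never perturbs the draws of another.
SEED_OFFSET <- c(colonies = 101L, histogram = 202L, foci = 303L)

#' Published survival-curve parameters shipped with the package
#'
#' Reads the packaged table of published single-hit multi-target parameters
#' (D0, n with SDs) for A549 cells under the four radiation-quality /
#' oxygenation combinations and both plating protocols, together with the
#' published plating efficiencies.
#'
#' @return Data frame with columns `quality`, `plating`, `oxygen`, `d0_Gy`,
#'   `sd_d0`, `n`, `sd_n`, `pe`, `sd_pe`.
#' @export
published_shmt_params <- function() {
  path <- system.file("extdata", "a549_shmt_params.csv", package = "ionsurv",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default simulation truth
#'
#' Ground-truth configuration for the synthetic generators. Defaults follow
#' the published study conditions: plating efficiencies 0.35 (normoxia) and
#' 0.25 (hypoxia); SHMT parameters per condition from
#' [published_shmt_params()]; colony doses 0.5-4 Gy with 3 replicate dishes
#' of 200 seeded cells; a carbon beam of LET 73 keV/µm against nuclei of
#' 118.8 ± 52.5 µm²; cell-cycle fractions near the published unirradiated
#' normoxia distribution (59.6/17.3/23.6% G1/S/G2); and focus kinetics whose
#' initial excess defaults to the Poisson traversal mean at the configured
#' beam and dose.
#'
#' @param conditions data frame of conditions with SHMT truth; defaults to
#'   the published parameter table.
#' @param doses_Gy colony-assay dose points (0 Gy dishes are always added).
#' @param seeded cells seeded per dish.
#' @param replicates replicate dishes per dose.
#' @param let_keV_um beam LET in water.
#' @param mean_area_um2,sd_area_um2 nucleus-area geometry.
#' @param cc_fractions named or ordered length-3 vector of G1/S/G2
#'   fractions.
#' @param cc_mu1 G1 peak position (fluorescence a.u.).
#' @param cc_cv peak coefficient of variation.
#' @param cc_ratio G2/G1 position ratio.
#' @param cc_events events per histogram.
#' @param foci_background mean background foci per nucleus.
#' @param foci_excess initial radiation-induced excess; `NULL` uses the
#'   Poisson traversal mean for `foci_dose_Gy` at the configured beam.
#' @param foci_k_per_h repair rate (per hour).
#' @param foci_plateau residual unrepaired foci.
#' @param foci_dose_Gy dose of the focus experiment.
#' @param foci_nuclei nuclei scored per condition and timepoint.
#' @param foci_timepoints_h fixation times after irradiation.
#' @param cc_timepoints_h cell-cycle fixation times.
#' @return List of class `simulation_truth`.
#' @export
simulation_truth <- function(conditions = published_shmt_params(),
                             doses_Gy = c(0.5, 1, 2, 4),
                             seeded = 200,
                             replicates = 3,
                             let_keV_um = 73,
                             mean_area_um2 = 118.8,
                             sd_area_um2 = 52.5,
                             cc_fractions = c(g1 = 0.60, s = 0.17, g2 = 0.23),
                             cc_mu1 = 50,
                             cc_cv = 0.05,
                             cc_ratio = 1.95,
                             cc_events = 1e5,
                             foci_background = 2,
                             foci_excess = NULL,
                             foci_k_per_h = 0.3,
                             foci_plateau = 1,
                             foci_dose_Gy = 2,
                             foci_nuclei = 100,
                             foci_timepoints_h = c(1, 2, 6, 12, 18, 24),
                             cc_timepoints_h = c(2, 6, 12, 18, 24)) {
  cc_fractions <- as.numeric(cc_fractions)
  if (abs(sum(cc_fractions) - 1) > 1e-6) {
    stop("cell-cycle fractions must sum to 1", call. = FALSE)
  }
  beam <- beam_spec(let_keV_um, "simulation truth")
  geom <- nucleus_geometry(mean_area_um2, sd_area_um2)
  if (is.null(foci_excess)) {
    foci_excess <- mean_traversals(foci_dose_Gy, beam, geom)$mean_hits
  }
  stopifnot(foci_background >= 0, foci_excess >= 0, foci_k_per_h >= 0,
            foci_plateau >= 0, all(doses_Gy >= 0), seeded >= 1,
            replicates >= 1)
  structure(list(conditions = conditions, doses_Gy = doses_Gy,
                 seeded = seeded, replicates = replicates,
                 beam = beam, geometry = geom,
                 cc_fractions = cc_fractions, cc_mu1 = cc_mu1,
                 cc_cv = cc_cv, cc_ratio = cc_ratio, cc_events = cc_events,
                 cc_timepoints_h = cc_timepoints_h,
                 foci_background = foci_background,
                 foci_excess = foci_excess,
                 foci_k_per_h = foci_k_per_h, foci_plateau = foci_plateau,
                 foci_dose_Gy = foci_dose_Gy, foci_nuclei = foci_nuclei,
                 foci_timepoints_h = foci_timepoints_h),
            class = "simulation_truth")
}

#' Simulate a colony-count table
#'
#' For every condition, dose (including 0 Gy) and replicate dish, draws
#' colonies ~ Binomial(seeded, PE * S(dose)) where S is the SHMT survival
#' curve of the condition's true parameters. Colonies can never exceed
#' seeded cells, which a Poisson model would not guarantee.
#'
#' @param truth a [simulation_truth()].
#' @param seed integer seed; draws use substream `seed + 101`. `NULL`
#'   continues the current RNG stream without reseeding, so repeated calls
#'   under one `set.seed()` yield independent datasets.
#' @return Colony-record data frame: `oxygen`, `quality`, `plating`,
#'   `dose_Gy`, `seeded`, `colonies`, `replicate`.
#' @export
simulate_colonies <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!is.null(seed)) set.seed(as.integer(seed) + SEED_OFFSET[["colonies"]])
  cond <- truth$conditions
  doses <- c(0, truth$doses_Gy)
  rows <- vector("list", nrow(cond) * length(doses))
  k <- 0L
  for (i in seq_len(nrow(cond))) {
    for (d in doses) {
      surv <- shmt_survival(d, cond$d0_Gy[i], cond$n[i])
      p <- cond$pe[i] * surv
      if (p > 1) stop("pe * survival exceeds 1: invalid truth", call. = FALSE)
      k <- k + 1L
      rows[[k]] <- data.frame(
        oxygen = cond$oxygen[i], quality = cond$quality[i],
        plating = cond$plating[i], dose_Gy = d, seeded = truth$seeded,
        colonies = stats::rbinom(truth$replicates, truth$seeded, p),
        replicate = paste0("r", seq_len(truth$replicates)))
    }
  }
  do.call(rbind, rows)
}

#' Simulate a DNA-content histogram
#'
#' Draws each event's phase from the true fractions, places G1 events at
#' Gauss(mu1, cv*mu1), G2/M events at Gauss(r*mu1, cv*r*mu1) and S events
#' uniformly on (mu1, r*mu1) plus Gaussian measurement noise of width
#' cv*mu1, then bins onto a uniform grid.
#'
#' @param truth a [simulation_truth()].
#' @param seed integer seed; draws use substream `seed + 202`; `NULL`
#'   continues the current RNG stream.
#' @param fractions optional length-3 G1/S/G2 override.
#' @param events optional event-count override.
#' @param n_bins number of histogram bins.
#' @param condition,timepoint_h,replicate metadata stamped on the result.
#' @return A [dna_histogram()].
#' @export
simulate_dna_histogram <- function(truth, seed = 1L, fractions = NULL,
                                   events = NULL, n_bins = 150,
                                   condition = NA_character_,
                                   timepoint_h = NA_real_,
                                   replicate = NA_character_) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!is.null(seed)) set.seed(as.integer(seed) + SEED_OFFSET[["histogram"]])
  f <- if (is.null(fractions)) truth$cc_fractions else as.numeric(fractions)
  if (abs(sum(f) - 1) > 1e-6) stop("fractions must sum to 1", call. = FALSE)
  n <- if (is.null(events)) truth$cc_events else events
  if (n < 1000) {
    warning("fewer than 1000 events; the cell-cycle fitter will refuse ",
            "this histogram", call. = FALSE)
  }
  mu1 <- truth$cc_mu1
  mu2 <- truth$cc_ratio * mu1
  sig <- truth$cc_cv * mu1
  phase <- sample.int(3L, n, replace = TRUE, prob = f)
  x <- numeric(n)
  x[phase == 1L] <- stats::rnorm(sum(phase == 1L), mu1, sig)
  x[phase == 3L] <- stats::rnorm(sum(phase == 3L), mu2, truth$cc_cv * mu2)
  ns <- sum(phase == 2L)
  x[phase == 2L] <- stats::runif(ns, mu1, mu2) + stats::rnorm(ns, 0, sig)
  breaks <- seq(0, ceiling(1.5 * mu2), length.out = n_bins + 1L)
  x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dna_histogram(centers, counts, condition = condition,
                timepoint_h = timepoint_h, replicate = replicate)
}

#' Simulate per-nucleus focus counts over a repair timecourse
#'
#' Counts are Poisson with rate background + excess * exp(-k t) + plateau
#' for irradiated nuclei and rate background for time-matched unirradiated
#' controls.
#'
#' @param truth a [simulation_truth()].
#' @param seed integer seed; draws use substream `seed + 303`; `NULL`
#'   continues the current RNG stream.
#' @param condition condition label for the irradiated arm.
#' @return Focus data frame: `condition`, `dose_Gy`, `timepoint_h`,
#'   `nucleus_id`, `foci_count`, including dose-0 controls.
#' @export
simulate_foci <- function(truth, seed = 1L, condition = "carbon/normoxia") {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!is.null(seed)) set.seed(as.integer(seed) + SEED_OFFSET[["foci"]])
  rows <- lapply(truth$foci_timepoints_h, function(t) {
    rate <- truth$foci_background +
      truth$foci_excess * exp(-truth$foci_k_per_h * t) + truth$foci_plateau
    rbind(
      data.frame(condition = condition, dose_Gy = truth$foci_dose_Gy,
                 timepoint_h = t,
                 nucleus_id = seq_len(truth$foci_nuclei),
                 foci_count = stats::rpois(truth$foci_nuclei, rate)),
      data.frame(condition = paste0(condition, "/control"), dose_Gy = 0,
                 timepoint_h = t,
                 nucleus_id = seq_len(truth$foci_nuclei),
                 foci_count = stats::rpois(truth$foci_nuclei,
                                           truth$foci_background)))
  })
  do.call(rbind, rows)
}
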