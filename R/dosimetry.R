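# Fluence/dose conversion and Poisson traversal statistics for ion beams.

# Gy * cm^2 / (keV/um) for water at unit density: 1 keV/um = 1.602e-9 Gy cm^2
DOSE_FLUENCE_CONST <- 1.602e-9

#' Beam specification
#'
#' Describes an ion beam by its unrestricted LET in water. The label is
#' informational only (e.g. the energy per nucleon on target).
#'
#' @param let_keV_um linear energy transfer in water, keV/µm; must be > 0.
#' @param label free-text beam description.
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec(73, "12C 25.7 MeV/n")
#' @export
beam_spec <- function(let_keV_um, label = "") {
  if (!is.numeric(let_keV_um) || length(let_keV_um) != 1L ||
      !is.finite(let_keV_um) || let_keV_um <= 0) {
    stop("`let_keV_um` must be a single positive number", call. = FALSE)
  }
  structure(list(let_keV_um = let_keV_um, label = as.character(label)),
            class = "beam_spec")
}

#' Cell-nucleus geometry
#'
#' Mean and standard deviation of the projected nucleus area, used to turn
#' fluence into a Poisson traversal rate per nucleus.
#'
#' @param mean_area_um2 mean nucleus area in µm²; must be > 0.
#' @param sd_area_um2 standard deviation of the nucleus area in µm²; >= 0.
#' @return An object of class `nucleus_geometry`.
#' @examples
#' nucleus_geometry(118.8, 52.5)
#' @export
nucleus_geometry <- function(mean_area_um2, sd_area_um2 = 0) {
  if (!is.numeric(mean_area_um2) || length(mean_area_um2) != 1L ||
      !is.finite(mean_area_um2) || mean_area_um2 <= 0) {
    stop("`mean_area_um2` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sd_area_um2) || length(sd_area_um2) != 1L ||
      !is.finite(sd_area_um2) || sd_area_um2 < 0) {
    stop("`sd_area_um2` must be a single non-negative number", call. = FALSE)
  }
  structure(list(mean_area_um2 = mean_area_um2, sd_area_um2 = sd_area_um2),
            class = "nucleus_geometry")
}

#' Convert particle fluence to absorbed dose
#'
#' D[Gy] = 1.602e-9 * F[cm^-2] * LET[keV/µm], for water at density 1 g/cm³.
#'
#' @param fluence_per_cm2 particle fluence, cm⁻²; vectorised, must be >= 0.
#' @param let_keV_um LET in water, keV/µm; > 0.
#' @return Absorbed dose in Gy.
#' @examples
#' dose_from_fluence(1.7102e7, 73) # ~2 Gy
#' @export
dose_from_fluence <- function(fluence_per_cm2, let_keV_um) {
  stopifnot(is.numeric(fluence_per_cm2), is.numeric(let_keV_um))
  if (any(!is.finite(fluence_per_cm2)) || any(fluence_per_cm2 < 0)) {
    stop("fluence must be finite and >= 0", call. = FALSE)
  }
  if (length(let_keV_um) != 1L || !is.finite(let_keV_um) || let_keV_um <= 0) {
    stop("LET must be a single positive number", call. = FALSE)
  }
  DOSE_FLUENCE_CONST * fluence_per_cm2 * let_keV_um
}

#' Convert absorbed dose to particle fluence
#'
#' Exact inverse of [dose_from_fluence()].
#'
#' @param dose_Gy absorbed dose, Gy; vectorised, must be >= 0.
#' @param let_keV_um LET in water, keV/µm; > 0.
#' @return Fluence in cm⁻².
#' @examples
#' fluence_from_dose(2, 73) # ~1.71e7 / cm^2
#' @export
fluence_from_dose <- function(dose_Gy, let_keV_um) {
  stopifnot(is.numeric(dose_Gy), is.numeric(let_keV_um))
  if (any(!is.finite(dose_Gy)) || any(dose_Gy < 0)) {
    stop("dose must be finite and >= 0", call. = FALSE)
  }
  if (length(let_keV_um) != 1L || !is.finite(let_keV_um) || let_keV_um <= 0) {
    stop("LET must be a single positive number", call. = FALSE)
  }
  dose_Gy / (DOSE_FLUENCE_CONST * let_keV_um)
}

#' Poisson traversal statistics for one dose
#'
#' The mean number of ion traversals through a nucleus of area A (cm²) at
#' fluence F is lambda = F * A; the fraction of unhit nuclei is exp(-lambda).
#' Bounds use nuclei one standard deviation smaller/larger than the mean; the
#' lower bound is `NA` when mean - SD <= 0.
#'
#' @param dose_Gy absorbed dose, Gy; >= 0.
#' @param beam a [beam_spec()].
#' @param geometry a [nucleus_geometry()].
#' @return A one-row data frame of class `traversal_stats` with columns
#'   `dose_Gy`, `fluence_per_cm2`, `unhit_fraction`, `hit_fraction`,
#'   `mean_hits`, `mean_hits_lo`, `mean_hits_hi`.
#' @examples
#' mean_traversals(2, beam_spec(73), nucleus_geometry(118.8, 52.5))
#' @export
mean_traversals <- function(dose_Gy, beam, geometry) {
  stopifnot(inherits(beam, "beam_spec"), inherits(geometry, "nucleus_geometry"))
  if (length(dose_Gy) != 1L || !is.finite(dose_Gy) || dose_Gy < 0) {
    stop("dose must be a single non-negative number", call. = FALSE)
  }
  fluence <- fluence_from_dose(dose_Gy, beam$let_keV_um)
  um2_to_cm2 <- 1e-8
  lam <- fluence * geometry$mean_area_um2 * um2_to_cm2
  area_lo <- geometry$mean_area_um2 - geometry$sd_area_um2
  area_hi <- geometry$mean_area_um2 + geometry$sd_area_um2
  lam_lo <- if (area_lo > 0) fluence * area_lo * um2_to_cm2 else NA_real_
  lam_hi <- fluence * area_hi * um2_to_cm2
  out <- data.frame(
    dose_Gy = dose_Gy,
    fluence_per_cm2 = fluence,
    unhit_fraction = exp(-lam),
    hit_fraction = 1 - exp(-lam),
    mean_hits = lam,
    mean_hits_lo = lam_lo,
    mean_hits_hi = lam_hi
  )
  class(out) <- c("traversal_stats", "data.frame")
  out
}

#' Traversal table over a dose series
#'
#' One row of Poisson traversal statistics per dose; the layout of the classic
#' fluence / dose / unhit / hit / average-hits table.
#'
#' @param doses_Gy numeric vector of doses, Gy; all >= 0.
#' @inheritParams mean_traversals
#' @param rounded if `TRUE`, round for presentation: hits to 1 decimal,
#'   fractions to 2 decimals, fluence to 3 significant digits.
#' @return A data frame with one row per dose (class `traversal_stats`).
#' @examples
#' traversal_table(c(0.5, 1, 2, 4, 8), beam_spec(73), nucleus_geometry(118.8, 52.5))
#' @export
traversal_table <- function(doses_Gy, beam, geometry, rounded = FALSE) {
  if (length(doses_Gy) == 0L) {
    out <- mean_traversals(0, beam, geometry)[0, , drop = FALSE]
    class(out) <- c("traversal_stats", "data.frame")
    return(out)
  }
  rows <- lapply(doses_Gy, mean_traversals, beam = beam, geometry = geometry)
  out <- do.call(rbind, rows)
  if (rounded) {
    out$fluence_per_cm2 <- signif(out$fluence_per_cm2, 3)
    out$unhit_fraction <- round(out$unhit_fraction, 2)
    out$hit_fraction <- round(out$hit_fraction, 2)
    for (col in c("mean_hits", "mean_hits_lo", "mean_hits_hi")) {
      out[[col]] <- round(out[[col]], 1)
    }
  }
  class(out) <- c("traversal_stats", "data.frame")
  out
}

#' Poisson distribution of traversal counts
#'
#' Probability mass P(k) = exp(-lambda) lambda^k / k! for k = 0..K, with K
#' chosen so the truncated tail mass is below `tail_tol`.
#'
#' @param lambda_mean Poisson mean number of traversals; >= 0.
#' @param tail_tol maximum probability mass allowed beyond the truncation
#'   point.
#' @return Data frame with columns `hits` and `prob`.
#' @examples
#' hit_distribution(5.08)
#' @export
hit_distribution <- function(lambda_mean, tail_tol = 1e-9) {
  if (length(lambda_mean) != 1L || !is.finite(lambda_mean) || lambda_mean < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  if (lambda_mean == 0) {
    return(data.frame(hits = 0L, prob = 1))
  }
  k_max <- stats::qpois(tail_tol, lambda_mean, lower.tail = FALSE)
  while (stats::ppois(k_max, lambda_mean, lower.tail = FALSE) >= tail_tol) {
    k_max <- k_max + 1L
  }
  k <- 0:k_max
  data.frame(hits = k, prob = stats::dpois(k, lambda_mean))
}
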