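# Shared fixtures built in code.

# Noise-free SHMT surviving fractions at the given doses.
sf_noise_free <- function(doses, d0, n) {
  data.frame(dose_Gy = doses, sf = shmt_survival(doses, d0, n))
}

# One synthetic colony dataset for a single condition, drawn from the
# current RNG stream (no internal reseeding).
draw_colony_dataset <- function(d0, n, pe, doses = c(0, 0.5, 1, 2, 4),
                                seeded = 200, replicates = 3) {
  do.call(rbind, lapply(doses, function(d) {
    p <- pe * shmt_survival(d, d0, n)
    data.frame(dose_Gy = d, seeded = seeded,
               colonies = stats::rbinom(replicates, seeded, p))
  }))
}

# Replicate-level SF points ready for fit_shmt().
replicate_sf <- function(records) {
  sf <- surviving_fractions(records, plating_efficiency(records))
  sf$sf_replicates[sf$sf_replicates$dose_Gy > 0, c("dose_Gy", "sf")]
}

# Truth restricted to the X-ray / normoxia / immediate-plating condition.
xray_normoxia_truth <- function(...) {
  simulation_truth(
    conditions = data.frame(quality = "xray", plating = "immediate",
                            oxygen = "normoxia", d0_Gy = 2.98, sd_d0 = 0.20,
                            n = 1.07, sd_n = 0.05, pe = 0.35, sd_pe = 0.03),
    ...)
}

std_beam <- function() beam_spec(73, "12C 25.7 MeV/n")
std_geometry <- function() nucleus_geometry(118.8, 52.5)
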