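#!/usr/bin/env Rscript
# Generate the synthetic study dataset: colony counts for all eight
# radiation/oxygen/plating conditions, DNA-content histograms over the
# cell-cycle timecourse, and per-nucleus focus counts with repair.
# Everything downstream (02-05) reads from results/synthetic/.

suppressPackageStartupMessages(library(ionsurv))

seed <- 20240101L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- simulation_truth()
message("Simulation truth: LET ", truth$beam$let_keV_um, " keV/um, nucleus ",
        truth$geometry$mean_area_um2, " +/- ", truth$geometry$sd_area_um2,
        " um2, ", nrow(truth$conditions), " conditions, doses ",
        paste(truth$doses_Gy, collapse = "/"), " Gy")

counts <- simulate_colonies(truth, seed = seed)
write_table(counts, file.path(out, "colony_counts.csv"))
message("Colony counts: ", nrow(counts), " dishes -> colony_counts.csv")

dir.create(file.path(out, "histograms"), showWarnings = FALSE)
manifest <- NULL
for (tp in truth$cc_timepoints_h) {
  for (rep in 1:2) {
    h <- simulate_dna_histogram(truth, seed = seed + 10L * tp + rep,
                                condition = "normoxia", timepoint_h = tp,
                                replicate = paste0("r", rep))
    f <- sprintf("histograms/normoxia_t%02d_r%d.csv", tp, rep)
    write_table(data.frame(bin_center = h$bin_centers, count = h$counts),
                file.path(out, f))
    manifest <- rbind(manifest,
                      data.frame(file = f, condition = "normoxia",
                                 timepoint_h = tp,
                                 replicate = paste0("r", rep)))
  }
}
write_table(manifest, file.path(out, "histogram_manifest.csv"))
message("DNA histograms: ", nrow(manifest), " samples -> histograms/")

foci <- simulate_foci(truth, seed = seed)
write_table(foci, file.path(out, "foci_counts.csv"))
message("Focus counts: ", nrow(foci), " nuclei -> foci_counts.csv")

# provenance record for the whole synthetic dataset
jsonlite::write_json(
  list(seed = seed,
       truth = list(conditions = truth$conditions,
                    doses_Gy = truth$doses_Gy, seeded = truth$seeded,
                    replicates = truth$replicates,
                    let_keV_um = truth$beam$let_keV_um,
                    mean_area_um2 = truth$geometry$mean_area_um2,
                    sd_area_um2 = truth$geometry$sd_area_um2,
                    cc_fractions = truth$cc_fractions,
                    foci_excess = truth$foci_excess,
                    foci_k_per_h = truth$foci_k_per_h)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("Provenance -> truth.json")
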