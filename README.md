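# ionsurv

Quantitative analysis of cell-based ion-beam radiobiology experiments:
clonogenic survival, particle dosimetry, cell-cycle distributions and
DNA-damage kinetics. The package is aimed at radiobiologists and medical
physicists comparing high-LET particle beams (e.g. carbon ions) against
reference X-rays in vitro, under differing oxygenation — the setting of
hypoxia-induced radioresistance studies in tumour cell lines such as A549
lung adenocarcinoma.

## What it computes

**Clonogenic survival.** From colony-count tables (dose, seeded cells,
colonies per dish) it derives plating efficiencies and surviving
fractions, and fits the single-hit multi-target model

    S(D) = 1 − (1 − exp(−D/D0))^n

by least squares on log10(SF), yielding the final-slope dose `D0` (Gy) and
extrapolation number `n` with asymptotic uncertainties. Fitted (or
published) parameter pairs combine into the standard quality and oxygen
ratios with delta-method errors:

    RBE = D0(X-rays) / D0(test radiation)
    OER = D0(hypoxia) / D0(normoxia)

**Particle dosimetry.** Fluence ↔ dose conversion at a given LET
(`D = 1.602e-9 · F · LET`, water at unit density) and Poisson statistics of
ion traversals through cell nuclei: mean hits `λ = F·A` for the mean
nucleus area and ±1 SD bounds, unhit/hit fractions, and the full hit-count
distribution.

**Cell cycle.** Dean-Jett-Fox-style deconvolution of DNA-content
histograms into G1/S/G2 fractions (Gaussian peaks plus a broadened
S-phase bridge), with timecourse summaries.

**Focus kinetics.** Per-nucleus γH2AX focus summaries over time,
background subtraction against unirradiated controls, exponential repair
fits (rate, half-time, plateau), and comparison of the observed initial
excess with the Poisson-expected number of ion hits.

**Synthetic data.** Generators with the statistical structure the
analyses assume (binomial colonies, trimodal histograms, Poisson foci),
parameterised by default with the published study conditions, so the whole
pipeline is testable without laboratory data.

## Worked example

```r
library(ionsurv)

beam <- beam_spec(73, "12C 25.7 MeV/n")     # LET in water, keV/um
geom <- nucleus_geometry(118.8, 52.5)       # nucleus area mean / SD, um^2
traversal_table(c(0.5, 1, 2, 4, 8), beam, geom, rounded = TRUE)
#>   dose_Gy fluence_per_cm2 unhit_fraction hit_fraction mean_hits mean_hits_lo mean_hits_hi
#> 1     0.5         4280000           0.01         0.99       5.1          2.8          7.3
#> 2     1.0         8550000           0.00         1.00      10.2          5.7         14.6
#> 3     2.0        17100000           0.00         1.00      20.3         11.3         29.3
#> 4     4.0        34200000           0.00         1.00      40.6         22.7         58.6
#> 5     8.0        68400000           0.00         1.00      81.3         45.4        117.2
```

At 2 Gy a carbon beam of LET 73 keV/µm puts on average 20.3 ions (about
20) through an average A549 nucleus, and essentially no nucleus escapes
unhit beyond 1 Gy — the quantitative reason γH2AX focus counts at 2 Gy are
compared against "~20 hits per nucleus".

```r
# RBE from published survival-curve parameters (normoxia, immediate plating)
p <- published_shmt_params()
xr <- subset(p, quality == "xray"   & plating == "immediate" & oxygen == "normoxia")
ci <- subset(p, quality == "carbon" & plating == "immediate" & oxygen == "normoxia")
rbe(shmt_fit(xr$d0_Gy, xr$n, se_d0 = xr$sd_d0),
    shmt_fit(ci$d0_Gy, ci$n, se_d0 = ci$sd_d0))
#> RBE = 2.685 (SE 0.247)
```

Carbon ions are ~2.7× as effective as X-rays per Gray on the final slope
under these conditions.

```r
# Fit synthetic colony data and recover the generating curve
truth <- simulation_truth()
counts <- simulate_colonies(truth, seed = 1)
res <- analyze_survival(counts)
res[["xray/normoxia/immediate"]]$fit
#> Single-hit multi-target fit [xray/normoxia/immediate]
#>   D0 = 2.700 Gy (SE 0.670)
#>   n  = 1.149    (SE 0.384)
```

The fitted `D0` scatters around the generating 2.98 Gy; the recovery
statistics (median error, interval coverage) are exercised in the test
suite.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study flow on synthetic data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # colony counts, DNA histograms, foci
Rscript analysis/02_survival.R    # PE, SF, SHMT fits, RBE/OER tables
Rscript analysis/03_dosimetry.R   # traversal table, hit distribution
Rscript analysis/04_cellcycle.R   # DJF fits, phase timecourse
Rscript analysis/05_foci.R        # kinetics, repair fit, hits comparison
```

`run_pipeline(run_config(...))` performs the same stages programmatically
and writes a provenance-carrying `results.json`.

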