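---
title: "Models and methods in ionsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ionsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsurv)
```

ionsurv implements the quantitative backbone of a cell-based ion-beam
radiobiology study: clonogenic survival modelling with RBE and OER
derivation, fluence/dose/Poisson-traversal dosimetry, DNA-content histogram
deconvolution, and γH2AX focus kinetics. This vignette explains each model,
its assumptions, the tunable parameters, and the numerical and design
choices behind the implementation.

## Clonogenic survival: the single-hit multi-target model

The colony-forming-ability assay seeds a known number of single cells and
counts the colonies (by convention, more than 50 cells) they grow into.
Unirradiated dishes give the plating efficiency (PE), the fraction of
seeded cells that form colonies at all; the surviving fraction at dose $D$
is the colony fraction normalised by PE.

Survival is modelled with the single-hit multi-target (SHMT) form

$$S(D) = 1 - \left(1 - e^{-D/D_0}\right)^n,$$

where $D_0$ (Gy) is the dose that reduces survival to 37% along the
exponential final slope and $n$ is the extrapolation number — the
y-intercept obtained by extrapolating the straight part of the
log-survival curve back to zero dose. The model assumes $n$ equivalent
targets per cell, each inactivated by single hits at rate $1/D_0$; it
produces the classic low-dose shoulder for $n > 1$ and allows $n < 1$,
which high-LET curves empirically require. At high dose
$\log_{10} S \to \log_{10} n - D/(D_0 \ln 10)$, which is exactly how the
parameters are read off a plotted curve, and `fit_shmt()` verifies this
asymptote in its tests.

### Fitting choices

`fit_shmt()` minimises squared residuals of $\log_{10} S$ because survival
curves are interpreted on a logarithmic scale and the extrapolation number
is defined there; a linear-domain option exists. Three choices deserve
explanation:

* **Unweighted by default.** Delta-method weights from empirical per-dose
  standard errors are supported (`weighted = TRUE`), but with the study's
  three replicate dishes per dose those SEs are estimated from three
  values and are extremely noisy; in simulation they produce a
  heavy-tailed $D_0$ estimator whose mean over repeated experiments drifts
  upward. Unweighted fitting of replicate-level points proved markedly
  more stable, so it is the default and what `analyze_survival()` uses.
* **Replicate-level points.** Fitting each dish's SF rather than per-dose
  means uses the same information but avoids compounding the aggregation
  with noisy weights.
* **0 Gy points are excluded.** They define PE, so their SF is 1 by
  construction; including them would double-count PE noise.

Initialisation regresses $\log_{10} S$ on the two highest doses (slope
gives $1/D_0$, intercept gives $n$), falling back to $(D_0, n) = (1.5, 1)$
when degenerate. Parameters are bounded in $(10^{-3}, 10^3)$; optimisation
uses Levenberg–Marquardt (`minpack.lm::nlsLM`) with tight (`1e-12`)
convergence tolerances so that noise-free inputs are recovered to at least
six significant digits.

Dishes with zero colonies at positive dose have no defined log-survival;
they are excluded from the fit and reported in a QC table. With doses up
to 4 Gy and ~200 seeded cells this is rare.

### Uncertainty

Standard errors come from the asymptotic covariance of the least-squares
fit. Because $D_0$ and $n$ are positive with right-skewed sampling
distributions over a strongly correlated ridge, `confint()` intervals are
computed on the log scale with a $t$ quantile at the residual degrees of
freedom and back-transformed; in the package's simulation tests this
brings 95% interval coverage for $D_0$ into the low 90s, where plain Wald
intervals undercover.

### RBE and OER

Relative biological effectiveness is the ratio of reference to test dose
at equal effect, here taken on the final slope:
$\mathrm{RBE} = D_0(\text{X-rays}) / D_0(\text{test radiation})$. The
oxygen enhancement ratio compares oxygenation states:
$\mathrm{OER} = D_0(\text{hypoxia}) / D_0(\text{normoxia})$, so values
above 1 indicate hypoxia-induced radioresistance. Both carry first-order
(delta-method) standard errors assuming independent fits,
$\mathrm{SE}(a/b) = (a/b)\sqrt{(s_a/a)^2 + (s_b/b)^2}$. Published ± values
for such ratios are often derived replicate-wise and need not match
propagated SEs; ionsurv reports the propagated ones as its own.

The packaged table `published_shmt_params()` carries the published A549
parameter estimates for the four radiation × oxygenation combinations
under both plating protocols, so ratio structures can be recomputed from
printed estimates as well as from fresh fits. Two caveats are documented
rather than hidden: for the carbon-ion hypoxia rows the published OER
column contains entries that are not the ratio of the published $D_0$
values, and the package reports only the defined $D_0$ ratio.

## Particle dosimetry and Poisson traversals

For water at unit density the absorbed dose from fluence $F$ (cm⁻²) at
linear energy transfer $L$ (keV/µm) is

$$D[\mathrm{Gy}] = 1.602\times 10^{-9} \cdot F \cdot L,$$

the constant being the keV-to-joule conversion over a 1 g/cm³ mass
element. `dose_from_fluence()` / `fluence_from_dose()` are exact inverses.

The number of ion traversals through a nucleus of projected area $A$ is
Poisson with mean $\lambda = F A$. `mean_traversals()` evaluates $\lambda$
at the mean nucleus area and at mean ± 1 SD (the default geometry is
118.8 ± 52.5 µm², a measured A549 value), giving an average-hits figure
with a plausible range, the unhit fraction $e^{-\lambda}$ and its
complement. At the reference carbon beam (LET 73 keV/µm) and 2 Gy this
yields $\lambda \approx 20.3$, i.e. about 20 traversals per nucleus — the
yardstick against which observed focus counts are compared. One
discrepancy is worth noting: the published fluence column that accompanies
these hit numbers is internally consistent with an LET near 71 keV/µm,
while the hits column matches 73 exactly; ionsurv computes fluence from
dose at the configured LET and reproduces the hits and fraction columns.

Presentation rounding follows the published layout (hits to 1 decimal,
fractions to 2 decimals, fluence to 3 significant digits) and is opt-in
via `rounded = TRUE`. Nucleus-area variation is handled only at ±1 SD;
full mixing of Poisson rates over an area distribution would be a model
extension and is deliberately not on by default. `hit_distribution()`
returns the pmf truncated where the tail mass falls below $10^{-9}$.

## DNA-content deconvolution

Flow-cytometric DNA histograms of cycling cells are trimodal: a G1 peak at
fluorescence $\mu_1$, a G2/M peak near $2\mu_1$, and an S-phase plateau in
between. `fit_djf()` fits a Dean-Jett-Fox-style mixture:
Gaussian G1 ($\mu_1$, width $cv_1\mu_1$), Gaussian G2/M ($r\mu_1$, width
$cv_2 r\mu_1$), and an S component modelled as a rectangle on
$[\mu_1, r\mu_1]$ convolved with a Gaussian of the G1 width. Each
component has unit area times a free amplitude, so phase fractions are the
normalised amplitudes and sum to 1 exactly.

The S-phase rectangle is a simplification of the original second-degree
polynomial S model; it is identifiable with few parameters and recovers
fractions well in the generator/fitter round trip. The G2/G1 position
ratio is constrained to $[1.8, 2.05]$ (initial 1.95) reflecting dye
stoichiometry — doubled DNA should roughly double the signal, with small
dye- and instrument-dependent deviations. CVs are bounded by 0.2 and
initialised at 0.05; $\mu_1$ starts at the tallest histogram bin.
Histograms need at least 50 bins and 1000 events (below that the fit is
refused as unstable). Debris and doublet modelling is intentionally
omitted: inputs are assumed pre-gated upstream, a documented limitation
for raw cytometry exports.

`summarize_timecourse()` reports per-timepoint means ± SE over replicates
and a per-condition grand mean over all samples of the observation window,
mirroring how average phase distributions over 24 h are tabulated.

## Focus kinetics

γH2AX foci mark double-strand breaks. `summarize_foci()` averages
per-nucleus counts per condition and timepoint (warning below 20 nuclei),
subtracts the unirradiated background — time-matched control means where
available, else the pooled control mean — and floors the excess at zero.
Whether published focus figures average per nucleus or per image is often
unstated; ionsurv works per nucleus and says so in its outputs.

`fit_decay()` fits $E(t) = E_0 e^{-kt} + \text{plateau}$ to the excess,
reporting the repair rate $k$ (h⁻¹) and half-time $\ln 2 / k$. The
exponential-plus-plateau form is a deliberate quantitative addition: the
underlying biology is usually described only qualitatively ("most foci
resolved within 6 h"), which maps onto the derived statistic
`fraction_remaining(6 h) < 0.5`. A perfectly flat timecourse makes $k$
non-identifiable and is flagged rather than fitted. Counting foci from
micrographs is upstream image analysis and out of scope.

`expected_vs_observed()` closes the loop with dosimetry: the initial
background-subtracted excess is set against the Poisson traversal mean at
the same dose and beam, with the expectation also rounded to an integer
headline figure.

## The synthetic-data generator

Real per-dish, per-nucleus and list-mode data for this kind of study are
rarely deposited, so the package ships generators that emulate the
experiment's statistical structure and make every pipeline stage testable:

* **Colonies**: Binomial(seeded, PE·S(D)) per dish. Binomial rather than
  Poisson because colonies can never exceed seeded cells.
* **DNA histograms**: events drawn per phase (Gaussian G1 and G2/M,
  uniform S between the peaks plus Gaussian measurement noise), binned on
  a uniform grid.
* **Foci**: Poisson counts at rate background + excess·e^{−kt} + plateau,
  with time-matched controls at the background rate.

Defaults in `simulation_truth()` are the study conditions themselves:
PE 0.35 (normoxia) and 0.25 (hypoxia); published SHMT parameters per
condition; doses 0.5–4 Gy with three dishes of 200 cells; LET 73 keV/µm
against 118.8 ± 52.5 µm² nuclei; G1/S/G2 fractions (0.60, 0.17, 0.23)
matching the published unirradiated normoxia distribution; 10⁵ events per
histogram with $\mu_1 = 50$ (arbitrary fluorescence units), CV 0.05 and
G2/G1 ratio 1.95; focus background 2 and plateau 1 focus per nucleus with
repair rate 0.3 h⁻¹ and 100 nuclei per timepoint — background, plateau,
rate and nucleus counts are the package's own realistic choices where the
study reports only figures, and the initial excess defaults to the
dosimetry traversal mean at 2 Gy so the two modules agree by
construction.

A single global seed drives all generators through fixed per-generator
offsets, so adding one generator never perturbs another's draws;
`seed = NULL` lets a surrounding `set.seed()` drive repeated independent
datasets. What the generators do *not* emulate: plate-to-plate handling
effects, cytometry debris/doublets and instrument drift, focus overlap at
high dose, and any correlation between assays — passing recovery tests on
synthetic data therefore demonstrates correctness of the estimators under
the assumed noise model, not robustness to every artefact of real data.

## Problem sizes and test design

The test-suite simulations are sized to be statistically meaningful yet
quick: 500 synthetic survival datasets for the recovery/coverage
properties, 100 datasets for the mean-$D_0$ recovery check, 500 datasets
for plating-efficiency recovery, three to six histograms of 10⁵ events
(one of 10⁶) for fraction recovery, and 10⁵ Poisson draws for the
Monte-Carlo check of the hit distribution. Noise-free oracle tests demand
recovery to $10^{-6}$ relative; stochastic recovery tests assert the
bands the estimators were designed to meet (mean $D_0$ within 5%,
fractions within ±0.03 at 10⁵ events, repair rate within 10%).

## Known limitations

* The SHMT ridge between $D_0$ and $n$ is poorly identified from four
  dose points ending at 4 Gy; single-experiment estimates can land far
  along the ridge even though the fitted curve matches the data. More or
  higher doses are the only real cure.
* Linear-quadratic modelling is intentionally absent; the package fits
  SHMT only.
* The cell-cycle module assumes pre-gated singlet histograms and a single
  G1 population.
* RBE/OER uncertainties assume independent fits; shared calibration
  errors between curves are not propagated.
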