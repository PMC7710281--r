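# nadflim

Two-component NAD(P)H fluorescence-lifetime (FLIM) metabolic analysis in R.

## The problem

Fluorescence lifetime imaging microscopy (FLIM) of NAD(P)H gives a
label-free readout of cellular metabolism. Free (unbound) NAD(P)H is
self-quenched and decays fast, with a lifetime of roughly 0.4 ns; the
protein-bound cofactor is stretched open and decays slowly, in the 2–4 ns
range. Time-correlated single-photon counting (TCSPC) records, for every
pixel, a histogram of photon arrival times (256 time bins per pixel over
the laser repetition window). Fitting each histogram with a two-component
decay

&nbsp;&nbsp;&nbsp;&nbsp;*I(t) = α₁ e^(−t/τ₁) + α₂ e^(−t/τ₂)*&nbsp;&nbsp;(convolved with the instrument response)

and forming the **amplitude-weighted mean lifetime**

&nbsp;&nbsp;&nbsp;&nbsp;*τ_avg = (α₁τ₁ + α₂τ₂) / (α₁ + α₂)*

turns each pixel into a metabolic measurement: a larger free-component
amplitude share *α₁/(α₁+α₂)* (the **free fraction**) lowers τ_avg and
indicates a shift toward glycolysis; a smaller share indicates reliance on
oxidative phosphorylation. Comparing the per-cell mean τ_avg between two
matched cell populations (for example, two sorted B-cell subsets from the
same donors) with a paired Student's *t* test classifies the test
population as glycolytic-shifted, oxidative-shifted, or neither.

The package is aimed at microscopists and analysts who have pre-binned
TCSPC image cubes (or want to simulate them) and need a tested,
reproducible path from photon histograms to a population-level metabolic
call.

## What it provides

- **Forward model and derived quantities** — `model_curve()` (periodic
  biexponential with IRF convolution and wrap-around), `tau_avg()`,
  `free_fraction()`, `phasor_transform()` (fit-free cross-check on the
  universal semicircle).
- **Seeded synthetic data** — `simulate_pixel()`, `flim_scene()` +
  `simulate_scene()` (disc "cells" on a 64×64 grid), `simulate_cohort()`
  (paired donor cohorts with a known free-fraction shift and full ground
  truth).
- **Fitting** — `fit_decay()` (Poisson MLE by default, weighted least
  squares as cross-check; bounded L-BFGS-B; canonical τ₁ ≤ τ₂; returns a
  classed object with `coef`, `summary`, `predict`, `residuals`,
  `simulate`, `plot` methods) and `fit_image()` (per-pixel maps with a
  one-step spatial-pooling fallback for dim pixels).
- **Cell analysis** — `segment_cells()` (Otsu threshold, 8-connected
  labeling, area filter) and `aggregate_cells()` (per-cell means over
  valid pixels).
- **Group statistics** — `compare_paired()` (donor-level paired *t* test
  with a glycolytic/oxidative direction call).
- **IO and CLI** — TIFF cubes/maps/masks with JSON sidecars, CSV tables,
  and a four-stage pipeline (`simulate` → `fit` → `cells` → `compare`)
  via `cli_main()` or `inst/scripts/flim-pipeline.R`.

## Worked example

```r
library(nadflim)

acq <- flim_acquisition()               # 256 bins over 12.5 ns
irf <- irf_gaussian(fwhm_ns = 0.25)     # typical multiphoton IRF

# a mixed free/bound pixel: 50% free NAD(P)H at the canonical lifetimes
truth <- biexp_params(alpha1 = 0.5, tau1_ns = 0.4,
                      alpha2 = 0.5, tau2_ns = 2.0)
y <- simulate_pixel(truth, irf, acq, n_photons = 1e4, seed = 1)

fit <- fit_decay(y, irf, acq)
summary(fit)
#> Two-component TCSPC decay fit (poisson_mle)
#>
#> Coefficients:
#>       alpha1      tau1_ns       alpha2      tau2_ns   background
#> 4838.7640475    0.3823728 5180.2103465    1.8888616    0.1327119
#>
#> tau_avg = 1.161 ns, free fraction = 0.483
#> reduced chi-square = 0.842, log-likelihood = -586.88, photons = 10019
#> Converged after 20 objective evaluations
```

The fitted free lifetime (0.38 ns), bound lifetime (1.89 ns), free
fraction (0.48) and τ_avg (1.16 ns) recover the simulated truth (0.4 ns,
2.0 ns, 0.50, 1.20 ns) to within single-pixel photon noise; the reduced
chi-square near 1 says the two-component model explains the histogram at
the Poisson noise level. Averaged over 200 such pixels the fitted
lifetimes come back to 0.40 and 1.99 ns (see
`scripts/acceptance.R` below).

A full paired cohort from the shell (4 donors × 2 conditions, planted
+0.2 free-fraction shift):

```sh
Rscript inst/scripts/flim-pipeline.R simulate --config cfg.json --out run/
Rscript inst/scripts/flim-pipeline.R fit run/ --config cfg.json --out run/
Rscript inst/scripts/flim-pipeline.R cells run/ --min-area 15 --out run/
Rscript inst/scripts/flim-pipeline.R compare run/cells.csv --out run/
#> paired t: shifted vs reference, n = 4 donors, mean dtau_avg = -0.3208 ns,
#>   t = -28.073, df = 3, p = 9.922e-05 -> glycolytic_shift
```

The shifted arm's τ_avg drops by ≈0.32 ns — exactly −0.2 × (2.0 − 0.4),
the lifetime contrast times the planted free-fraction shift — and the
paired test calls the glycolytic direction.

## Limitations

Triple-exponential and lifetime-distribution models, the FAD channel /
optical redox ratio, vendor TCSPC container formats (PTU/SDT), global
(multi-pixel) fitting and detector artifacts (afterpulsing, pile-up) are
out of scope. See the methods vignette (`vignettes/nadflim-methods.Rmd`)
for model details, parameter defaults and numerical choices.
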