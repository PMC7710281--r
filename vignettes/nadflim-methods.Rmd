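---
title: "Methods: two-component NAD(P)H lifetime analysis"
author: "nadflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-component NAD(P)H lifetime analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadflim)
```

## The measurement and the model

TCSPC FLIM records, for each pixel, a histogram of photon arrival times
relative to the excitation pulse: `n_bins` bins spanning the laser
repetition window. NAD(P)H autofluorescence decays as a mixture of two
kinetic species — free cofactor with a short lifetime (canonically about
0.4 ns) and protein-bound cofactor with a long lifetime (2–4 ns). The
package models the expected per-bin counts as

$$\mu_i = b + \big[\mathrm{IRF} \circledast
  (\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2})\big]_i,$$

where $\circledast$ is *circular* convolution over the repetition period:
photons from decays slower than the window fold back into the start of
the next period (wrap-around), and the periodic steady state makes the
convolution exactly circular. Each exponential component is discretely
normalized over one period before scaling by its amplitude, so
$\sum_i \mu_i = \alpha_1 + \alpha_2 + b \cdot n_\mathrm{bins}$ holds to
machine precision and amplitudes are always in expected-photon units.
Because the infinite wrap-around series
$\sum_k e^{-(t + kT)/\tau}$ is proportional to $e^{-t/\tau}$, this
normalization includes wrap-around exactly (a brute-force truncated
series is the test oracle for this identity).

The metabolic summary statistics are the amplitude-weighted mean lifetime
$\tau_\mathrm{avg} = (\alpha_1\tau_1 + \alpha_2\tau_2) /
(\alpha_1 + \alpha_2)$ and the free fraction
$f = \alpha_1 / (\alpha_1 + \alpha_2)$. Amplitude weighting is used
deliberately — not the intensity ($\alpha\tau$) weighting that also
circulates in the FLIM literature — because the amplitude convention is
the one under which $\tau_\mathrm{avg}$ is linear in $f$:
$\tau_\mathrm{avg} = \tau_2 - f(\tau_2 - \tau_1)$, so a free-fraction
shift $\delta$ maps to a lifetime shift $-\delta(\tau_2-\tau_1)$ exactly.
More free NAD(P)H therefore always means lower $\tau_\mathrm{avg}$ and a
glycolytic interpretation.

### Time and IRF conventions

* Bins are indexed from 0 with centers $t_i = (i + 0.5)\,\Delta t$;
  defaults are 256 bins over 12.5 ns (the 80 MHz Ti:Sapphire repetition
  window), giving $\Delta t \approx 48.8$ ps.
* The default instrument response is a Gaussian of FWHM 0.25 ns centered
  1.0 ns into the window — typical of multiphoton TCSPC detection chains.
  An ideal impulse (`irf_delta()`) and a measured histogram
  (`irf_measured()`, interpolated onto the acquisition grid) are also
  supported. Gaussian IRFs are integrated over bin edges with period
  wrapping, so their discrete profile sums to 1 exactly. As the FWHM
  shrinks toward zero a Gaussian centered on the first bin center
  converges to the delta IRF (the delta is defined as an impulse at bin
  0); this limit is asserted in the tests at FWHM $10^{-4}$ ns.

### Phasor cross-check

`phasor_transform()` computes the first-harmonic Fourier coordinates
$g = \sum_i c_i\cos\omega t_i / \sum_i c_i$,
$s = \sum_i c_i\sin\omega t_i / \sum_i c_i$ with
$\omega = 2\pi/T$. Monoexponential decays fall on the universal
semicircle $g^2 + s^2 = g$; mixtures fall on the chord between their
component phasors with photon-weighted position. The phasor never enters
the fit — it is an independent linear functional of the data used to
cross-check fitted models (fit and data phasors must agree within 0.02 at
$10^4$ photons). One numerical caveat: with bin-center sampling the
discrete $s$ of a near-$\omega\tau = 1$ decay exceeds the continuous cap
of 0.5 by a few $10^{-5}$; invariant checks therefore allow a
$10^{-3}$ discretization tolerance rather than machine precision.

## Fitting

`fit_decay()` minimizes either the Poisson negative log-likelihood
$\sum_i (\mu_i - c_i\log\mu_i)$ (default) or the Neyman weighted
least-squares objective $\sum_i (c_i-\mu_i)^2/\max(c_i,1)$ over
$(\tau_1, \tau_2, f, A, b)$ with L-BFGS-B under box constraints
$\tau_1 \in [0.05, 1]$ ns, $\tau_2 \in [1, 6]$ ns, $f \in [0,1]$,
$A, b \ge 0$. Poisson MLE is the default because TCSPC bins at realistic
budgets hold few counts and Gaussian approximations bias lifetime
estimates there; WLS is retained as a cross-check whose correctly
specified reduced chi-square should average 1 (asserted within
$[0.8, 1.2]$ over 200 replicates at $10^4$ photons).

Numerical choices, in the order they act:

* **Start values and multistart.** Initialization
  $(\tau_1, \tau_2, f) = (0.4, 2.5, 0.5)$ — the canonical free lifetime,
  the middle of the bound range, equal amplitudes. Before the gradient
  run, the objective is evaluated on a small deterministic grid
  ($\tau_2 \in \{1.5, 2.5, 4\}$, $f \in \{0.25, 0.5, 0.75\}$) and the
  best point seeds the optimizer; this costs nine cheap function
  evaluations and removes the local-minimum failures that a single start
  occasionally hits. The full optimum is verified in tests against an
  exhaustive grid search (steps of 0.05 ns / 0.05 fraction over the
  whole box) on 64-bin curves: the optimizer's objective must never
  exceed the brute-force minimum.
* **Bounds disjointness.** The boxes enforce
  $\tau_{1,\max} \le \tau_{2,\min}$, so the optimizer cannot cross
  components; the constructor still performs a canonical swap
  ($\tau_1 \le \tau_2$, amplitudes following their lifetimes) as a
  safety net for boundary solutions.
* **Background.** Fitted as a free constant by default (started at half
  the minimum bin count); optionally fixed, in which case it is removed
  from the parameter vector entirely rather than pinned with equal
  bounds.
* **Degeneracy.** A fit is flagged degenerate — effectively
  monoexponential — when $\tau_2 - \tau_1 < 0.1$ ns or the minority
  amplitude fraction is below 0.01. Degenerate fits still report
  $\tau_\mathrm{avg}$ (which remains well determined); only the
  two-component decomposition is unreliable.
* **Failure semantics.** Histograms under the photon threshold raise an
  error; optimizer non-convergence is a flag on the result, not an
  exception, so image-scale runs degrade to masked pixels instead of
  aborting.

`fit_image()` applies the fitter per pixel. Pixels under the photon
threshold (default 300 photons) get exactly one escalation: counts pooled
over the 3×3 neighborhood and refitted; still-insufficient pixels are
masked invalid. One escalation keeps the spatial resolution loss bounded
and the behavior deterministic; results are independent of pixel
processing order because each pixel's fit uses only its own (or its
fixed neighborhood's) counts.

## The synthetic-data generator

No imaging data accompanies the study design this package emulates, so
the generator is first-class, tested code that defines the conditions the
analysis is validated under:

* **Per-pixel decays** are Poisson draws around the forward model —
  per-bin sampling, statistically identical to photon-by-photon
  simulation at the histogram level and far cheaper.
* **Scenes** place non-overlapping discs of radius 4–8 px (stand-ins for
  sorted lymphocytes) on a 64×64 grid, each disc carrying its own decay
  composition and a photon budget of 5,000 expected photons per pixel —
  a typical NAD(P)H FLIM operating point; the emulated study reports
  neither photon counts nor image sizes, so these are the package's own
  stated assumptions.
* **Cohorts** emulate the paired sorted-population design: 4 donors by
  default, each contributing a reference and a shifted population whose
  free fractions differ by $\delta$ (default +0.2), with inter-donor SD
  0.05 around a reference free fraction of 0.5 and cell-level SD 0.05,
  lifetimes fixed at $\tau_1 = 0.4$ ns, $\tau_2 = 2.0$ ns. All free
  fractions are clamped to $[0,1]$. Ground truth is always emitted next
  to the data.
* **Determinism.** Every generator is a pure function of its arguments
  and an explicit seed; seeds are never global state, and generators
  restore the caller's RNG stream. The pipeline derives per-stage seeds
  from one master seed.

What the generator does *not* emulate — and what passing tests therefore
do not establish for real data: realistic cell morphology and contact,
detector afterpulsing/dead-time/pile-up, autofluorescence from other
fluorophores in the emission band, photobleaching and motion, and
spatial lifetime heterogeneity within a cell. Recovery results here
bound estimator behavior under correct model specification, not under
instrument artifacts.

## Cell analysis and group statistics

Segmentation thresholds the time-summed intensity image (Otsu by
default — a sensible choice for the strongly bimodal synthetic images; a
fixed threshold is available) and labels 8-connected components,
discarding those under 20 px. The per-cell summary is the unweighted mean
of $\tau_\mathrm{avg}$ and free fraction over the cell's *valid* pixels
(photon-weighted means are available as an option); cells with no valid
pixels are dropped with a warning.

`compare_paired()` treats the donor as the experimental unit: cells are
averaged within donor and condition first, and the classical paired
Student's $t$ test (via `stats::t.test`) runs on the $n$ donor-level
differences with $n-1$ degrees of freedom. Averaging first avoids
pseudo-replication — cells from one donor are not independent. The test
is two-sided at $\alpha = 0.05$ by default, and the metabolic direction
is applied post hoc: `glycolytic_shift` only when the difference is
significant *and* the test population's $\tau_\mathrm{avg}$ is lower.
Zero-variance differences (identical populations) are reported as a
degenerate result with `NA` statistics rather than an error.

## Problem sizes used by the test suite

The suite validates the statistical claims at sizes chosen to exercise
each property well:

* parameter recovery and chi-square calibration: 200 replicates of
  single-pixel fits at $10^4$ photons;
* grid-search oracle: 20 random truths on 64-bin curves against an
  exhaustive $20 \times 101 \times 21$ grid;
* type-I error of the paired test: 1,000 null cohorts through the
  table-level generator (no curve fitting — the property under test is
  the test's calibration given the generator's noise model);
* power: 200 shifted cohorts with 3 cells per condition measured through
  pooled per-cell decay fits at $10^4$ photons;
* end-to-end pipeline: one 4-donor cohort of 64×64, 256-bin cubes with
  4 cells per condition at 2,000 photons per pixel, run through the CLI
  stages and required to recover the planted glycolytic shift.

## Known limitations

Two decay components only (no triple-exponential or lifetime
distributions); single emission channel (no FAD / optical redox ratio);
no global multi-pixel fitting; no vendor raw formats (pre-binned cubes
only); segmentation does not split touching cells. The bound-lifetime
default of 2.0 ns sits at the short end of the physically reported
2–4 ns range; it is configurable wherever parameters enter.
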