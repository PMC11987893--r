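---
title: "Calibrating pig carcass grading equations: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating pig carcass grading equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmpcalib)
```

## The problem

EU pig carcass grading prices carcasses by lean meat percentage (LMP),
estimated on the slaughter line from two probe measurements — backfat
depth F2 and loin muscle depth M2 — through a device-specific linear
equation. Device testing is a statistical exercise with four stages:
stratified sampling of carcasses, reference dissection with bias
correction, regression fitting with cross-validated error, and a
population-level assessment of what a new equation changes. `lmpcalib`
implements all four, plus a synthetic carcass generator so the pipeline
can be exercised and validated end to end without dissection data.

## Dissection model and the scaling factor

Partial (reference-method) dissection of the tenderloin plus four main
cuts yields

$$\mathrm{YPD} = 100\,\frac{t + \sum_{c} \ell_c}{t + \sum_{c} j_c},$$

with $t$ the tenderloin weight and $\ell_c \le j_c$ the lean and joint
weights of shoulder, loin, ham and belly. Full dissection yields
$\mathrm{YTD} = 100\,L/W_{1/2}$ with $L$ the total lean and $W_{1/2}$ the
half-carcass weight. Partial dissection systematically overstates lean
meat (the four cuts are leaner than the whole carcass), so since 2018 a
**scaling factor** must be estimated at every device test from a
total-dissection subsample and applied as
$\mathrm{LMP}_{ref} = \mathrm{YPD}\times SF$.

Two conventions would be defensible for $SF$; the package uses the
**ratio of subsample means**, $SF = \overline{\mathrm{YTD}} /
\overline{\mathrm{YPD}}$, rather than the mean of per-carcass ratios,
because the factor is defined and reported through the two means and the
two conventions agree at the two-decimal precision at which it is
applied. $SF$ is **rounded half-up to two decimals before application**
(the form in which it circulates in regulation); `compute_sf(...,
round_to = NULL)` retains full precision for diagnostics, since whether
the official procedure rounds before applying is not fixed anywhere
authoritative. Rounding is half-*up* (`round_half_up()`) because report
tables are conventionally rounded that way, not half-to-even as in base
`round()`.

```{r}
sf <- compute_sf(59.62, 67.12)   # subsample means -> SF = 0.89
sf$value
apply_sf(67.12, sf)              # corrected mean partial-dissection LMP
```

## Sampling design

The test sample is stratified over a 3 x 3 grid: backfat groups bounded
at 10 and 18 mm and weight groups bounded at 84.4 and 105.5 kg within
the admissible 60–120 kg range, with a 1:2:1 allocation on both margins
(126 carcasses; 30/66/30 and 32/62/32) and a total-dissection subsample
of 12 in a 1/2/1 pattern per weight row. The published integer bin
labels ("0–10", "11–18") leave real-valued gaps; bins are encoded
half-open on the upper edge (group 1 is $f_2 \le 10$) so every positive
measurement is classifiable — the choice only matters for measurements
in $(10, 11)$ and $(84.4, 84.5)$, which the integer-labelled field
protocol never produces.

Within a cell, carcasses are drawn uniformly at random without
replacement (field practice selects "next suitable carcass on the line",
which has no reproducible rule; uniform sampling under a seed is the
neutral, reproducible stand-in). Cells with too few candidates are
recorded as *shortfalls* rather than errors, because real tests tolerate
deficits of a few carcasses per cell; `validate_plan()` reports — but
does not adjudicate — the 1:2:1 and 10%-subsample conventions.

## Equation fitting and cross-validation

The equation $\widehat{\mathrm{LMP}} = b_0 + b_1 F2 + b_2 M2$ is fitted
by PLS1 (NIPALS) on centered predictors, the regression family permitted
for device testing. With only two predictors, the full two-component PLS
solution equals ordinary least squares exactly; this identity is the
package's correctness anchor (tested against an independent
normal-equations oracle to 1e-8) and the reason `n_components = 2` is
the default. One component gives the shrunken fit that the PLS family
exists for; more than two is impossible here.

Prediction error is the RMSEP from the PRESS statistic,
$\sqrt{\sum_i (y_i - \hat y_{(-i)})^2 / n}$. The cross-validation
flavour behind PRESS is not standardized; the package uses
**leave-one-out** (the classical PRESS definition, deterministic and
exactly reproducible) with `folds = k` as an option. The leave-one-out
loop refits explicitly per fold; for the full-rank case this equals the
hat-matrix closed form $e_i/(1-h_{ii})$, which the test suite uses as an
independent oracle. Authorization is the strict inequality
$\mathrm{RMSEP} < 2.5$ pp.

## SEUROP classification and equation comparison

Classes are lower-inclusive half-open LMP intervals: S $\ge 60$, E
$[55,60)$, U $[50,55)$, R $[45,50)$, O $[40,45)$, P $< 40$. The
thresholds are an argument, not a constant, since the published class
shares never print them and national scales can differ at the margins.
Predictions outside $[0,100]$ are clamped with a warning rather than
rejected — commercial populations genuinely contain carcasses near 30%
lean. `compare_equations()` reports mean shift, class structures, the
6 x 6 migration matrix, and 1-pp histogram counts over 30–75% (counts
only; the smooth overlay seen in grading reports is just a Gaussian at
the sample mean/SD and is left to the user's plotting).

Because both equations are linear, the population mean shift equals the
coefficient differences evaluated at the population mean measurements —
the identity that lets the headline "+0.58 pp" be verified from summary
statistics alone:

```{r}
tab <- data.frame(f2_mm = c(12.86, 14.86), m2_mm = c(64.2, 60.2))
cmp <- compare_equations(tab, cgm_equation("2011"), cgm_equation("2023"))
round(cmp$mean_shift, 4)
```

## The synthetic population

`generate_population()` emulates the national slaughter population the
workflow is designed for: (weight, F2, M2) from a trivariate Gaussian
with means 95.0 kg / 13.86 mm / 62.20 mm and SDs 10.6 / 4.26 / 8.40,
truncated by rejection to the observed ranges (60–120 kg, 3–55 mm,
21–99 mm); 50% gilts; a latent total-dissection LMP that is linear in
(F2, M2) with the 2023 coefficients and residual SD 2.2 pp (matching the
device-test RMSEP scale); and an observable partial-dissection LMP
$\mathrm{YPD} = \mathrm{YTD}/s + \delta$ with $s = 0.89$ and
$\sigma_\delta = 0.5$ pp. Only the marginal moments are published, so
the correlation structure is a design choice: `corr_weight_f2 = 0.15`
(heavier carcasses are visibly fatter in the grouped summaries, but only
weakly), zero otherwise, all configurable. $\sigma_\delta$ is likewise
unpublished; 0.5 pp encodes the "very high" observed total–partial
correlation while leaving the scaling-factor estimate realistically
noisy at subsample size 12.

Two numerical points deserve note:

* **Truncation shifts moments.** Rejection to a box moves the means
  (F2 by about +0.07 mm, weight by about −0.2 kg) and shrinks the SDs.
  At $n \ge 50{,}000$ these shifts exceed a 3-standard-error band, so
  the moment-recovery tests compare sample moments against the truncated
  distribution's *exact* moments (closed-form conditional truncated
  normal plus one-dimensional quadrature), not the nominal parameters —
  the generator is exact, and the nominal-vs-truncated distortion is
  separately checked to be under 0.3 units.
* **Cut weights are generated backwards.** `generate_cut_weights()`
  draws joint weights as a Dirichlet perturbation (concentration 300)
  of fixed cut proportions — tenderloin/shoulder/loin/ham/belly =
  0.015/0.25/0.23/0.30/0.20 of a 0.75 cut-out fraction, plausible
  butchery values that are *not* published and affect nothing
  downstream — then allocates lean proportionally to joint weight so the
  dissection formulas reproduce the carcass's latent YPD and YTD to
  1e-9. The generator therefore guarantees internal consistency of the
  dissection stage, not anatomical realism.

What the generator does **not** emulate: breed/farm structure, butcher
effects on dissection (reported to vary by up to ~2 pp), non-Gaussian
tails (the real population's extreme carcasses at 30% LMP are
under-represented), or the exact published class shares. Passing tests
therefore demonstrate that the *procedures* are correct and that the
design recovers known truth under its stated noise model — not that any
particular real population would yield particular coefficients.

## Problem sizes and determinism

Simulation-based checks use populations of 2,000–50,000 carcasses, a
200-replicate parameter-recovery experiment at the design size
(n = 126 stratified from populations of 4,000), and a 200,000-carcass
population for class-share behaviour — sizes at which Monte Carlo error
is small relative to the tested tolerances while the whole suite runs in
seconds. All stochastic stages take explicit seeds; `run_pipeline()`
derives per-stage seeds from one master seed, so a fixed configuration
is byte-reproducible.

## Known limitations

* Exactly the two-predictor equation form is supported; weight terms or
  additional probe sites would need a generalization of
  `fit_pls_pcr()`.
* The pipeline models one device; multi-device harmonization is out of
  scope.
* Shortfall handling is report-only: no rule decides when a deficit
  invalidates a test, because no such rule is published.
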