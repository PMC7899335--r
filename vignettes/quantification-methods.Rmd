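---
title: "Quantification methods: puncta, surface fraction, FRAP, behavior"
author: "glrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: puncta, surface fraction, FRAP, behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glrquant)
```

## Scope

`glrquant` re-implements, as a tested pipeline, the four quantification
methods used to study surface levels of the *C. elegans* AMPA-type
glutamate receptor GLR-1 in command interneurons:

1. **puncta calling** on 1-D fluorescence line scans of the ventral nerve
   cord (VNC) — intensity, width and density of synaptic receptor
   clusters;
2. **dual SEP/mCherry quantification** of the receptor surface fraction —
   superecliptic pHluorin (SEP) is quenched in acidic endosomes, mCherry
   is not, so their ratio over a shared ROI reports the surface pool;
3. **dual-channel FRAP** — because quenched endosomal SEP absorbs no
   light, it is protected from the photobleach, and post-bleach SEP
   recovery reports exocytic delivery of receptor rather than lateral
   diffusion;
4. **behavioral assay scoring** — nose touch, optogenetic ASH activation,
   thrashing, spontaneous reversals and aldicarb paralysis — with the
   group statistics (t, one-/two-way ANOVA, Tukey, Dunnett, repeated
   measures) implemented from first principles.

No imaging data from the original study is publicly deposited, so the
package pairs every analysis with a synthetic-data generator that carries
a full ground-truth record. All benchmark numbers quoted below are the
quantities the test suite and `scripts/acceptance.R` compute; none are
taken from elsewhere.

## Puncta calling

A line scan is a uniform 1-D grid of intensities (default pixel size
0.1 um/px; typical high-NA oil objectives with CCD cameras land in the
0.06–0.13 um/px range, and the pixel size is always an explicit parameter,
never assumed downstream).

**Background.** `estimate_background()` uses iterative sigma clipping: a
median/MAD starting estimate, then repeated exclusion of pixels more than
3 SD from the current mean (at most 10 rounds or until stable), returning
the mean and SD of the survivors. The median/MAD start matters: puncta can
occupy 20–40% of a VNC scan, and a mean/SD start lets the bimodal upper
mode drag the clip limit upward so that nothing is ever excluded. Scans
where fewer than 10 pixels survive are rejected as degenerate.

**Detection.** The threshold is `bg_mean + 4 * bg_sd` and a punctum is a
maximal contiguous run of pixels strictly above it, at least 0.3 um wide
(run length x pixel size). One run is one punctum: no watershed splitting
of merged neighbors is attempted, because the source protocol defines no
splitting rule; closely spaced peaks whose valley stays above threshold
are deliberately reported as a single punctum. The punctum center is the
position of the run's maximum pixel, ties broken toward the run midpoint.
Runs touching a scan end are kept but flagged (`edge = TRUE`), since their
width is only a lower bound. `detect_puncta()` is property-tested for
exact equivalence with a brute-force enumeration of supra-threshold runs,
and for monotonicity: raising the SD multiple never adds puncta, lowering
the width floor never removes any.

**Width.** FWHM is measured at the half level
`bg_mean + 0.5 * (peak - bg_mean)` as the distance between the two
level-crossings bracketing the peak, linearly interpolated between pixels.
On noisy slopes the profile may wobble across the half level several
times; taking only the innermost crossing would bias widths low by about
one pixel, so each side uses the mean of the innermost and outermost
crossing within the noise band (half level minus 4 background SD). On
noiseless profiles exactly one crossing exists and the rule reduces to
plain interpolation (exact for triangles and plateaus, sub-pixel for
Gaussians, whose analytic FWHM is `2 sqrt(2 ln 2) sigma ~ 1.177 um` at
`sigma = 0.5 um`).

**Reported metrics.** Peak intensity is the run maximum (the protocol
reports "maximum puncta intensity"); a background-subtracted segment
integral is exposed as an extra column without any fidelity claim. Peaks
are normalized to the same-day fluorescent-bead mean to cancel lamp
fluctuations; density is `10 * n / length_um` (puncta per 10 um).

**Recovery benchmark.** `simulate_scan_cohort()` freezes the benchmark
conditions: 4–6 Gaussian puncta per 60+ um scan, widths
`sigma ~ U(0.3, 1.0) um`, adjacent centers at least `4 (sigma_i +
sigma_j)` apart plus a 2–5 um gap, amplitudes `U(12, 24)` background SDs
on `N(100, 5^2)` background. Amplitudes start at 12 SD rather than the
8 SD detectability floor because the FWHM half level inherits noise from
the run-maximum peak estimate; bright, well-separated puncta are the
regime in which calling is expected to be error-free at all. Under these
conditions 200 scans give recall = precision = 1.0 (a detection counts as
true when its center lies within 3 true sigma of a true center, so
precision measures freedom from background false positives) and FWHM mean
absolute error below 1 pixel.

## SEP/mCherry surface fraction

With quench efficiency `q` (fraction of SEP fluorescence lost in acidic
compartments) and surface fraction `f`, the visible SEP fraction of total
receptor is

```
SEP / mCherry = cal * (f + (1 - f) (1 - q))
```

where `cal` is the relative SEP-vs-mCherry brightness scale. Defaults are
`q = 1` (SEP detectable only at the surface, the standard reading of the
reporter) and `cal = 1` (exact for synthetic data; for real data `cal` is
unknown, which is why cross-genotype comparisons use control-normalized
ratios, where `cal` cancels).

* `calibrate_thresholds()` operationalizes the protocol's "average
  background threshold from a representative subset of wild-type image
  sets": per channel, per calibration image, the 2-D pixel population is
  sigma-clipped exactly as in the puncta module and a per-image threshold
  `bg_mean + 4 bg_sd` computed; the channel threshold is the mean over
  images (at least three pairs required). The original ImageJ procedure is
  not recoverable, so the same background rule is reused to keep a single
  background concept in the package.
* `integrated_density()` is the thresholded integrated density with
  ImageJ "limit to threshold" semantics: the sum over ROI pixels strictly
  above the threshold (equivalently count x mean). `soma_total()` is the
  un-thresholded sum plus area, for max-projected soma images.
* `quantify_pair()` computes both integrated densities over the *same*
  ROI and their ratio; a zero mCherry density yields a flagged undefined
  ratio, not an error.
* `normalize_to_control()` divides each ratio by the mean control ratio
  of its batch. When acquisition-day labels are present the normalization
  is within-day (mirroring the per-day bead normalization); otherwise it
  falls back to the global control mean. Whether the original VNC ratios
  were day- or globally normalized is not stated, so both modes exist.
* `estimate_surface_fraction()` inverts the forward model:
  `f_hat = (ratio / cal - (1 - q)) / q`, clamped to `[0, 1]` with a flag
  rather than an error because noise can push the raw estimate slightly
  outside the simplex. `q = 0` makes `f` non-identifiable and errors.
  The inversion assumes a background-free (or background-subtracted)
  ROI; with an additive background pedestal inside the ROI the raw ratio
  is a relative proxy only, which is how the control-normalized ratios
  are used.

Benchmarks: the noiseless forward model with `q = 1` returns
`ratio = f_surf` to 1e-6 across `f in {0, 0.1, ..., 1}`; with 2% image
noise and 25 images per condition the mean `|f_hat - f|` stays below
0.02.

## Dual-channel FRAP

**Geometry.** The bleached region is the central half of the imaged
segment and the quantification ROI the central half of the bleached
region (central quarter of the image) — for a 32 um image, a 16 um bleach
interval inset 8 um from each image edge and an 8 um quantification
interval inset 4 um from each bleach edge. The inner inset minimizes the
contribution of receptors diffusing laterally into the bleached area.
Intervals are half-open in um with 0-based pixel conversion by flooring —
unambiguous and directly testable. One threshold per channel is fixed
from the pre-bleach image and applied to every timepoint, avoiding
bleach-dependent threshold drift (per-timepoint thresholds are not
described in the protocol). Pre- and post-bleach images are assumed to
share exposure settings.

**Forward model.** Receptor in the ROI is split into surface `S` and
internal `I` pools; each pool carries unbleached/bleached label fractions
per channel. Initial composition is `(f_surf, 1 - f_surf)`. The bleach
multiplies mCherry unbleached pools by `1 - beta` in both compartments
but the SEP unbleached pool only at the surface (quenched endosomal SEP
is protected). Kinetics per label: exocytosis `k_exo * I`, endocytosis
`k_endo * S`, and exchange with the unbleached reservoir outside the ROI
at rate `k_ext`, modeled as relaxation toward the reservoir composition
(unbleached pools toward `f_surf` and `1 - f_surf`, bleached pools toward
0). Relaxation, rather than a constant source term, keeps signals bounded
and conserves total receptor exactly when `k_ext = 0`. Signals are
`SEP = S_u + (1 - q) I_u` and `mCherry = S_u + I_u`, each normalized to
its pre-bleach value. Defaults (`k_exo = k_endo = 0.2/min`,
`f_surf = 0.5`) sit at the kinetic steady state
`f = k_exo / (k_exo + k_endo)`, so the bleach-free signal is stationary.

The model reproduces two closed forms used as tests: the immediate
post-bleach SEP floor `1 - beta f / (f + (1 - f)(1 - q))`, and, in the
pure-recycling design (`beta = 1, q = 1, k_endo = k_ext = 0`), the exact
single-exponential recovery `1 - exp(-k_exo t)`. It also reproduces the
qualitative signature motivating the dual design: with influx dominating
and no recycling, mCherry recovers while SEP stays near its floor,
because arriving surface SEP is subsequently endocytosed into the
quenched pool. The linear ODEs are integrated with `deSolve::lsoda` at
relative tolerance 1e-8 (they are stiffness-free) and cross-checked
against a fixed-step midpoint integrator in the tests.

**Fitting.** `fit_recovery()` fits `n0 + A (1 - exp(-k t))` with `n0`
pinned to the observed t = 0 value — the minimal identifiable model for a
4-timepoint design. `A` enters linearly, so the fit profiles the residual
sum of squares over `k` with a closed-form amplitude at each candidate
rate and minimizes by golden-section search on `k in [0, 10]/min`:
deterministic, with no convergence failures on sparse designs. Flat or
zero-amplitude curves are returned with `A = 0`, `k = NA` and
`fit_ok = FALSE` instead of an exception. Note the fitted `k` equals the
generative `k_exo` only in the pure-recycling design; under mixed
kinetics it is an effective rate.

**Comparison.** `compare_recovery()` runs a two-way repeated-measures
ANOVA (genotype between worms, time within) plus per-timepoint Tukey
contrasts. No sphericity correction is applied by default (none is named
in the source protocol); a Greenhouse–Geisser epsilon is available behind
`gg = TRUE`. An optional unbleached-reference correction for acquisition
photofading exists in `recovery_fraction()` and is off by default, since
the protocol applies none.

## Behavior

The worm is the experimental unit: per-worm fractions (10 nose-touch
trials; light pulses for optoASH, default 5 per worm — the per-worm trial
count is not stated in the protocol and is configurable) or per-worm
counts (thrashes per 30 s, spontaneous reversals per 5 min, never
re-scaled across assays), then group mean ± SEM over worms. The plate is
the unit only for aldicarb (20 worms per plate, paralysis checked at
15-min intervals); `paralysis_curve()` pools plates within genotype,
attaches binomial standard errors, and treats a decreasing per-plate
count as a data-integrity error naming the plate. Missing trials are
excluded, never imputed.

The generator draws Bernoulli trial outcomes, Poisson counts, and
exponential paralysis times right-censored at the assay end — the
memoryless hazard as the minimal model, with a Weibull shape parameter
available for accelerating hazards. The optogenetic stimulus is treated
as a per-genotype response probability; no dose–response model is
attempted since only a single stimulus intensity is described.

## Statistics from first principles

Implemented directly from sums of squares so that every figure-style
comparison is reproducible outside a statistics GUI; base R supplies only
distribution functions (`pt`, `pf`, `ptukey`). Each test is cross-checked
in the suite against an independent implementation (`t.test`, `aov`,
`TukeyHSD`, `multcomp::glht`) and calibrated by null simulation.

* `t_test2()` — pooled-variance Student's t by default (the protocol
  says "Student's t test"); Welch behind a flag. Two zero-variance groups
  with equal means return `t = 0, p = 1` by convention.
* `anova_oneway()` — standard between/within decomposition; with two
  groups `F = t^2` exactly.
* `tukey_hsd()` — studentized-range comparisons with Tukey–Kramer
  standard errors for unequal group sizes.
* `dunnett()` — many-to-one comparisons whose family-wise adjustment
  uses the Monte-Carlo null distribution of the maximum absolute Dunnett
  t (group means and a shared chi-squared error variance drawn under the
  null; 100,000 draws under a fixed internal seed, cached per design).
  Monte-Carlo rather than table lookup keeps the procedure
  dimension-general and directly testable; the fixed seed never touches
  the caller's RNG stream.
* `rm_anova_two_way()` — univariate mixed-design ANOVA; the between
  effect is tested against the unit-within-group mean square, within and
  interaction effects against the unit-by-time residual. Complete
  within-unit grids are required (missing cells error out).

Null simulations in the suite hold the family-wise error of Tukey and
Dunnett and the type-I error of the repeated-measures genotype test
within [0.03, 0.07] at alpha = 0.05 (2,000 and 1,000 replicates).

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure* the analyses assume:
Gaussian peaks on Gaussian read noise (a Poisson shot-noise option exists
for the line scans), two receptor pools with pH quenching, label-resolved
bleach kinetics at the ROI-aggregate level, and standard trial/count/
time-to-event behavioral outcomes. They deliberately omit optics (no PSF,
no Z-stacks — projections are assumed already made), spatially resolved
diffusion (lateral exchange is the single `k_ext` term, matching the fact
that only ROI totals are quantified), non-uniform backgrounds,
autofluorescence, motion artifacts, and any worm locomotion model.
Passing benchmarks therefore demonstrate correctness of the *computation*
under the model's assumptions — calling, ratios, kinetics and statistics
— not robustness to every pathology of real microscope data.

## Problem sizes and numerical choices

Benchmarks run at: 500 scans (oracle equivalence), 200 scans (parameter
recovery), 25 images x 9 surface fractions, 100 FRAP curves (rate
recovery), 400–500 replicates (repeated-measures calibration/power),
2,000 replicates (Tukey/Dunnett family-wise error), 500–1,000 worms
(behavioral consistency) — sizes chosen so each Monte-Carlo check has
narrow error bands while the whole suite stays quick on a laptop. ODE
tolerance 1e-8 relative / 1e-10 absolute; fit search `k <= 10/min`;
sigma clipping at 3 SD, at most 10 iterations; all RNG flows through
per-object seeds via `withr::with_seed`, so identical truth records give
byte-identical data and generators never perturb the caller's RNG.

## Known limitations

* Merged puncta are counted once; densities underestimate truth when
  spacing approaches the resolution of the threshold rule.
* FWHM of edge-flagged puncta is a lower bound, not an estimate.
* The surface-fraction inversion assumes background-free ROIs and a known
  quench efficiency; with `q` unknown, only control-normalized ratios are
  comparable across genotypes.
* The single-exponential FRAP fit reports an effective rate under mixed
  kinetics; mechanistic rates are identifiable only in designed regimes.
* The repeated-measures ANOVA handles complete grids only, matching the
  fixed imaging schedule.
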