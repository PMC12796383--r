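---
title: "Models and conventions behind discgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind discgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discgrowth)
```

This vignette documents the models, assumptions and numerical
conventions the package commits to. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The logistic growth model

Wing-disc volume over the third larval instar is described by the
three-parameter logistic law

$$V(t) = \frac{Asym}{1 + e^{(t_{mid} - t)/scal}},$$

where `Asym` is the asymptotic maximum volume (carrying capacity),
`tmid` (h AEL) the time at which `V = Asym/2`, and `scal` (h) the
steepness scale. The model assumes a single saturating growth phase with
no regression or oscillation, and volumes measured with positive,
roughly proportional error — which is why `normalize_volumes()`
(division by the mean volume at the earliest timepoint) changes only
`Asym` and leaves `tmid`, `scal` and the whole rate curve untouched.

`fit_logistic()` minimises the raw sum of squared volume residuals. The
self-start takes `Asym0 = 1.05 × max(V)` (any factor > 1 works; it is
exposed as `asym_factor`) and obtains `tmid0`, `scal0` by regressing
`logit(V/Asym0)` on time, followed by Gauss–Newton refinement
(`stats::nls`) with a Levenberg–Marquardt fallback
(`minpack.lm::nlsLM`) for resamples on which Gauss–Newton steps fail.
Non-convergence raises an error rather than returning a silent result;
constant-volume data are rejected as degenerate.

The relative growth rate is the time derivative of the fitted volume
divided by the instantaneous volume. For the logistic law this has the
closed form

$$\frac{dV/dt}{V(t)} = \frac{1}{scal}\Bigl(1 - \frac{V(t)}{Asym}\Bigr),$$

which the package uses directly instead of numeric differentiation: it
is exact, noise-free, strictly positive and strictly decreasing, with an
early-time plateau of `1/scal` and the value `1/(2·scal)` at `tmid`.
The default evaluation grid is 0.5 h steps over the observed time range.

### Bootstrap ribbon

`bootstrap_growth_rate()` draws case resamples with replacement
*within each timepoint* (stratified resampling). The resampling unit is
the individual disc measurement; stratification preserves the design,
including unequal cohort sizes per timepoint. Each resample is refit and
the rate evaluated on the grid; the ribbon is the per-time SD across
successful refits, with the failure count surfaced and an error if more
than 20 % of refits fail. Because resampling *n*-from-*n* within a
stratum deflates the bootstrap variance by `(n−1)/n` — material with the
5–6 discs per timepoint typical of volumetry — the SD carries the
standard finite-sample rescaling `sqrt(n̄/(n̄−1))` with `n̄` the mean
stratum size. The number of resamples (`n_boot`, default 500) and the
resampling unit are conventions of this package: the ribbon is
convention-dependent and should be read as such.

## The growth-rate correlation screen

Each gene contributes one expression profile per timepoint; replicates
are collapsed by the arithmetic mean (`summarise_replicates()`) before
correlating. Correlating on the 7 replicate means, rather than on all
replicate columns, reflects the notion of a per-gene "time-course
profile"; the profile matrix interface leaves the alternative open to
the user. The growth rate entering the correlation is evaluated at the
matrix's timepoints from the continuous fitted curve, not read off a
plot.

Selection uses strict inequalities at the threshold (default 0.8):
`r > 0.8` is `positive`, `r < −0.8` is `negative`, `r = 0.8` exactly is
`unselected`. Zero-variance profiles have no defined correlation; they
are flagged `undefined` and excluded from classification and clustering
rather than propagating `NaN`. The four classes partition the gene list.

For heatmap display each profile is divided by its own maximum
(`max_normalize()`, row maximum exactly 1, idempotent), then clustered
on Euclidean distances under Ward's minimum-variance criterion in its D2
form (`ward.D2`: the Lance–Williams recurrence applied to unsquared
Euclidean distances). Clustering is delegated to `stats::hclust`, whose
deterministic tie-handling and leaf ordering we adopt as the
reproducibility convention; the test suite verifies the merge-height
sequence against an independent hand-coded Lance–Williams recursion.

Gene-set over-representation replaces web-service pathway analysis with
an explicit one-sided hypergeometric tail `P(X ≥ overlap)` over
user-supplied GMT gene sets, intersected with the universe before
testing. The plain tail is the default; the conservative EASE variant
(overlap decremented by one, so sets overlapping in ≤ 1 gene get
`p = 1`) is provided because some enrichment services default to it.
Benjamini–Hochberg values are reported alongside, while the retention
flag follows the raw `p < 0.05` rule used for pathway screening.

## Sensor calibration

A functioning hypoxia reporter brightens as oxygen falls. Its
calibration curve is modelled as two regimes of normalised intensity
*I* against environmental O₂ (%):

- responsive: $I = m\,O_2 + k$ with $m < 0$, fitted by ordinary least
  squares over the responsive range (default 5.0–18.0 % O₂);
- plateau: $I = c$, the plain mean over the upper range (default
  18.0–20.9 %), i.e. a zero-slope regression.

Intensities are first normalised to the normoxia (20.9 %) group mean,
per batch when a batch column is present, which also absorbs any overall
intensity rescaling. The regression runs on per-level mean intensities
by default (`per_level_mean = TRUE`), matching calibration on average
intensities; per-replicate regression is a switch away, and the two
coincide on balanced designs. The boundary level 18.0 % belongs to both
regimes by default (`boundary_shared`), mirroring the overlapping
protocol ranges.

Derived quantities: the **sensitivity breakpoint** `(c − k)/m`, the O₂
level where the regimes intersect (the mildest hypoxia the sensor
resolves — the line and plateau meet there by construction), and the
**dynamic range** `(m·O₂_floor + k)/c` (default floor 5.0 % O₂), the
fold-increase over the plateau. A fit with `m ≥ 0` is flagged
non-responsive and withholds both. `bootstrap_breakpoint()` adds a
percentile CI by within-level resampling; it is an extension beyond the
plain calibration protocol.

One subtlety on synthetic data: the generator plants a *hard*
breakpoint at 17.09 % O₂, so its 18 % level lies on the plateau. The
default 5–18 % responsive window — sensible for real calibrations, where
the measurement at 18 % is consistent with both regimes — would
therefore drag one plateau point into the line fit and bias recovery.
Tests and the acceptance script calibrate synthetic tables with
`responsive_range = c(5, 15)`, i.e. the levels genuinely below the
planted breakpoint.

## Quantification rules

All image quantification operates on a single 2-D plane (one optimal
confocal plane); z-stack reduction is a pre-processing step left to the
user. Compartment masks are inputs — anterior/posterior outlines are
drawn from lineage markers by the experimenter, and the package does no
boundary inference. Masks are binary matrices congruent with the image.

- `roi_mean_intensity()` thresholds within the ROI to exclude
  background (automatic Otsu on the ROI's own histogram by default, a
  fixed value for reproducibility) and averages intensity over the
  signal pixels. Otsu presumes a bimodal ROI histogram: pass an ROI
  containing both signal and background, or use a fixed threshold. A
  constant ROI is treated as all-signal; an ROI with no pixel above the
  threshold is flagged with an undefined mean.
- `pa_ratio()` divides the P-compartment mean by the A-compartment mean
  of the same disc (internal control).
- `area_fraction()` is the percentage of compartment pixels above
  threshold.
- `red_green_ratio()` isolates nuclei as connected components of the
  thresholded nuclear mask and reports per-nucleus mean-red over
  mean-green; touching nuclei are not split (a documented limitation),
  and zero-green nuclei are excluded with a flag.
- `trichome_density()` enforces the four-inter-vein-ROI protocol
  (deviations require an explicit override) and reports mean count per
  unit area.
- `t50_pupariation()` returns the observation time if the cumulative
  fraction hits 0.5 exactly, linear interpolation between the
  bracketing observations otherwise, and a censored `NA` if 50 % is
  never reached. It shifts exactly with any time translation of the
  data.

## The synthetic-data module

Every generator is seeded, byte-reproducible, and attaches the planted
truth from which its noiseless output is exactly predictable. Noise is
multiplicative log-normal throughout — volumes and fluorescence are
positive with roughly proportional error — parameterised by a
coefficient of variation: the factor is `exp(ε)`,
`ε ~ N(0, sqrt(log(1+cv²)))`, so its CV is exactly `noise_cv`. The CV
defaults (5 % for volumes and calibration intensities, 10 % for
expression) are conventions chosen as typical biological replicate
scatter; real replicate noise distributions are unknown.

Defaults encode the study conditions: `volume_sim_config()` samples
every 4 h from 72 to 116 h AEL plus 118 h with 6 discs per timepoint (5
at 84 h); `sim_config()` is the RNA-seq design (80, 88, 96, 104, 112,
116, 118 h AEL; 3 replicates, 2 at 80 h). The planted growth curve
(`Asym = 21.5` fold, `tmid = 104` h, `scal = 10.6` h) decelerates from
9 %/h at 72 h to 2 %/h at 118 h; the planted sensor
(`m = −3/12.09`, `k = 4 − 5m`, `c = 1`) has its breakpoint at 17.09 % O₂
and a 4-fold dynamic range at 5 % O₂. Oxygen levels
{5, 8, 11, 14, 18, 20.9} % span both regimes with ≥ 2 levels each.
Pupariation times are logistic-distributed (any sigmoid would serve;
the logistic has closed-form quantiles) around `t50 = 120` h with a 3 h
scale, scored 4-hourly for a 210-larva cohort.

Expression generation plants positive/negative affine transforms of the
growth-rate profile (tracking / anti-tracking) mapped into
`[0.5, 1.5] ×` a log-normal per-gene level, and null genes drawn
independently of the rate. Null profiles are redrawn while their
noiseless correlation with the rate reaches 0.8 in absolute value: this
guard makes the planted labels unambiguous (a "null" gene whose profile
accidentally tracks the rate is not a labelling error one can test
against) at the cost of truncating ~2 % of the null correlation tail —
the test suite's Monte-Carlo oracle replays exactly this guarded
process.

What the generators do *not* emulate: sequencing counts or library-size
effects (expression values are post-normalisation abundances),
confocal optics and point-spread functions, reporter maturation
kinetics, disc anatomy beyond a two-compartment ellipse, and
between-replicate batch structure. Passing the planted-truth tests
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to every artefact of real data.

## Problem sizes and tolerances

The test suite runs on cohorts of the default designs: 50 seeds for
parameter-recovery checks (median tolerances: 10 % on `Asym`, 2 h on
`tmid`, 15 % on `scal`, 0.5 % O₂ on the breakpoint), 100 simulations ×
500 resamples for ribbon coverage (± 2 SD covering the true rate at
≥ 90 % of grid times), and 10 seeds for the grid-search oracle
comparison (fitted SSE within 0.1 %). Exact identities (rate at `tmid`,
regime intersection, hypergeometric enumeration, Ward heights) are
checked at 1e-10–1e-12. These sizes were chosen to make the checks
statistically meaningful while keeping the suite comfortably fast on a
single CPU.

## Known limitations

- Alternative growth laws (Gompertz, von Bertalanffy) are out of scope;
  if a tissue's trajectory is asymmetric around its inflection, the
  logistic rate curve will be biased.
- The screen is threshold-based, not inferential: no p-values attach to
  individual gene correlations, mirroring the |r| > 0.8 selection rule.
- The piecewise calibration is linear-plus-plateau by design; Hill-type
  saturation below 5 % O₂ is not modelled.
- Nucleus separation is connected-components only; clumped nuclei
  merge.
- Numeric reproduction of wet-lab intensity values is not attempted:
  manual threshold settings of the original imaging workflow are
  unknowable, so only the quantification *rules* are reproduced.
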