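---
title: "Models and methods behind septrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind septrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(septrack)
```

`septrack` quantifies the subcellular dynamics of bacterial division
proteins — prototypically the DNA translocase FtsK in *C. glutamicum* — from
single-molecule localization microscopy. This vignette explains the models
the package fits, the assumptions behind them, the defaults and why they
were chosen, and what the synthetic-data validation does and does not
demonstrate.

## The measurement model

A single-particle tracking movie is a stack of short-exposure frames
(default frame interval `dt = 0.013` s, i.e. 10 ms exposure plus transfer
time) in which individual fluorophores appear as diffraction-limited spots
(pixel size 0.0968 µm on the reference instrument). The package's spot
detector filters each frame with a negated Laplacian-of-Gaussian kernel at
scale `sigma = diameter / (2 * sqrt(2))` — with the default 0.5 µm estimated
spot diameter this matches the LoG response maximum to the spot size — and
keeps strict local maxima of the response. Sub-pixel positions come from a
2D quadratic fit on the 3×3 response neighborhood, refined by an iterative
Gaussian-weighted centroid on the raw image; on rendered test spots at high
signal this localizes to ~0.1 px RMS. The signal-to-noise ratio of a
candidate is `(peak − local median) / (1.4826 × local MAD)` in a window
around the spot, a robust estimate that ignores the spot's own tail pixels;
candidates below `snr_min = 5` are discarded. Both the LoG scale convention
and the SNR estimator are package choices (configurable), since common
tracking tools leave them implicit.

Linking is frame-to-frame optimal assignment: between consecutive frames the
minimum-total-squared-distance bipartite matching is computed (a
Jonker–Volgenant-style solver on the connected components of the "allowed
link" graph), with links longer than `max_link = 0.3` µm forbidden and no
frame gaps permitted; among maximum-cardinality matchings the cheapest is
chosen. Unmatched spots open new tracks; tracks shorter than
`min_len = 5` frames are dropped. Within a frame, spots are ordered by x
then y, making the result invariant to input order. A track is assigned to
a cell only if every localization falls inside that cell's outline polygon
(boundary inclusive); tracks touching two cells are conservatively dropped.

## Diffusion mixtures from jump distances

Under 2D Brownian motion with coefficient D, the squared frame-to-frame
displacement r² is exponential with mean 4·D·dt, so a k-population ensemble
has CDF `F(x) = 1 − Σ f_i exp(−x/(4 D_i dt))`. Three estimators are
provided:

* `method = "cdf"` (default): nonlinear least squares of the model CDF
  against the empirical CDF over all sorted data points — the convention of
  jump-distance analysis tools, and the package default for comparability.
  Optimization runs on log-D / softmax-fraction transformed parameters with
  Levenberg–Marquardt and 10 quantile-spread multi-starts from a fixed,
  recorded seed.
* `method = "mle"`: EM for the exponential mixture of pooled jumps.
* `method = "track_mle"`: EM in which all jumps of one track share one
  population label — the correct likelihood for single-molecule data, since
  a molecule does not change identity between frames. This is substantially
  more efficient than the pooled estimators (population fractions to ~1
  point at 3,000 tracks versus ~3 points pooled) and is the default in the
  end-to-end pipeline. An optional fixed-probability uniform "outlier"
  component per jump (`outlier_frac`, default 0.05 in the pipeline) makes
  track classification robust to occasional mislinked jumps, which otherwise
  eject a whole confined track from its population.

Localization error adds 4σ² to every component's mean. By default the
package fits and reports *apparent* D (the convention of the reference
analyses); `sigma > 0` switches to the corrected scale 4·D·dt + 4σ². The
ensemble MSD's linear fit over lags 1–4 (`compute_msd`) exposes the 4σ²
intercept for diagnostic use. Model order is chosen by `select_mixture_order`:
the smallest k whose residual sum of squares is within 5% (configurable) of
the k+1 fit.

Default mixture parameters are the fitted FtsK constants — D = 0.017
(confined, divisome/DNA-engaged), 0.0509 (slow-mobile), 0.394 µm²/s
(fast-mobile) — so simulations run at the documented scale of the system.

## Dwell times

A dwell event is a maximal run of consecutive frames staying within
`r_dwell = 0.1` µm of the run's first position; runs shorter than two frames
are discarded and an n-frame run lasts (n−1)·dt seconds. This operational
definition (radius, anchoring at the run start, minimum length) is a package
choice; published analyses leave it implicit, so fitted values are
comparable only within a definition. Durations are fitted by maximum
likelihood as a left-truncated exponential (closed form `tau = mean(d) −
t_min`) or a two-component truncated exponential mixture via EM with
moment-based multi-starts. Callers should know that at the tau ratios
typical for these data (~0.14 s vs ~0.33 s) the two-component likelihood is
intrinsically flat: at n = 5,000 events the maximum-likelihood estimates
scatter by roughly 10–15% in tau and ~10 points in the percentages across
datasets, which the reported uncertainty reflects. The validation suite
therefore checks recovery as a median over replicate datasets rather than on
a single draw.

## Standardized-cell statistics

Localizations of each cell are projected onto the pole-to-pole axis
(straight-rod assumption; curved centerlines are out of scope) and rescaled
so the poles map to u = ±1.5 µm and the local half-width of the outline maps
to v = ±0.5 µm — the standardized 3 × 1 µm cell. Orientation follows the
lesser-pole convention: the pole with fewer localizations maps to negative
u, applied before any pole-resolved statistic. Heatmaps bin standardized
points at 0.1 µm (30 × 10) and normalize to proportions; difference heatmaps
subtract two such grids. Demographs bin along the *actual* cell axis at
0.1 µm, normalize each row to maximum 1, and sort rows by cell length —
cell length serving as the cell-cycle proxy throughout.

Per-cell statistics use the central 20% of the cell length as the midcell
region and the terminal 20% at each end as polar regions: `midcell_prop`
and `polar_prop` are the corresponding localization fractions, `polar_ratio`
is lesser/greater pole count (0 when only one pole is occupied, NA when
both are empty), and `max_location` is the center of the most-populated
0.1 µm axial bin, ties broken toward midcell. Note that for a
spherocylinder the *area* of the polar regions is less than 20% of the cell
per pole (the caps narrow), so under uniform occupancy `polar_prop`
converges to the exact area fraction (~0.35 for a 3 × 1 µm cell) rather
than the naive length fraction 0.4; the tests compare against the exact
geometry. Trends of any statistic against cell length use degree-1 LOESS
(tricube weights, default span 0.75) with pointwise standard errors from the
local fit.

## Cell profiles

Morphometrics come from multi-channel line profiles sampled at 0.0645 µm
(a 5-pixel, 322.5 nm line width). Peaks are local maxima with topographic
prominence of at least 20% of the channel's dynamic range (configurable),
found after Gaussian smoothing (1.5 samples). Cell length is the distance
between the outermost membrane peaks; septa are interior membrane peaks
outside a 15% pole-exclusion margin; nucleoids are DNA-channel peaks
separated by troughs dropping below 50% of the lower adjacent peak. The
trough rule is noise-limited on raw samples and broadening-limited on
smoothed ones, so each adjacent peak pair is locally refit as two Gaussians
on the unsmoothed channel and the rule is evaluated on the fitted curve
(falling back to a lightly smoothed signal if the local fit fails). Time-lapse septal traces
(5-minute intervals) are reduced to the fraction of cell-cycle frames at or
above an intensity threshold (default 1,800 au — an instrument-specific
convention, not a transferable constant).

## The synthetic-data generator

Cells are 2D spherocylinders (default length ~Normal(2.5, 0.4) µm truncated
at the 1 µm width) with Bernoulli septum flags at midcell. Molecules evolve
by per-axis Gaussian steps of variance 2·D·dt with specular reflection at
the wall (up to 10 reflections, then clamped), which preserves the uniform
stationary distribution of free diffusion. Track lengths are
1 + Geometric(1 − p_survive) with p_survive = 0.85 (memoryless bleaching;
mean ≈ 6.7 frames), localization error is Gaussian with default
σ = 0.02 µm, and confined molecules are placed at the septum plane of
septum-bearing cells (else at a pole) with probability `septal_bias`. Image
stacks render each localization as an integrated-Gaussian PSF
(σ = 0.13 µm) plus Poisson noise on signal and background. Profiles are
sums of Gaussian pole/septum peaks and nucleoid blobs with additive Gaussian
noise; feature counts that cannot be resolved geometrically (septa closer
than 4 peak-SD; nucleoids closer than 3.5 blob-SD, the analytic bound of the
50%-trough rule) are rejected as parameter errors.

The generator emulates the features the pipeline measures — population
structure, septal/polar enrichment, bleaching-limited tracks, shot noise —
but not blinking photophysics, 3D diffusion, anisotropic PSFs, membrane
curvature effects or chromosome polymer structure. Passing the validation
suite therefore demonstrates that the estimators recover known truth under
the stated model, not that the model captures every property of real data.

## The end-to-end validation experiment

`compare_conditions()` builds a two-condition experiment: condition A
("late recruitment", wild-type-like) gives septa only to cells of at least
median length and a confined fraction of 32.5%; condition B ("early
recruitment") gives septa to all cells and a confined fraction of 39.9% —
the documented wild-type and *smc*-deletion values. Each condition simulates
3,000 molecules across 100 cells (above the ~1,000-track minimum used per
condition in comparable experiments; 100 cells keeps the per-cell spot
density low enough that co-localized septal molecules rarely merge into one
detected spot), renders movies, and runs the complete pipeline: detect,
link, assign, fit the 3-component mixture (track-level likelihood, 5%
outlier component), project into the standardized cell, and compare
early-cycle (below-median-length) per-cell midcell proportions with the
Wilcoxon rank-sum test. The expected outcome — a higher fitted confined
fraction and a strongly higher early-cycle midcell proportion in condition
B — is checked across 20 seeds in the acceptance suite. Problem sizes were
chosen for statistical power at realistic effect sizes: the planted
confined-fraction difference is 7.4 points and the track-level estimator
resolves ~1–2 points at this scale.

## Numerical choices and degenerate inputs

Mixture EM stops at a 1e-10 relative log-likelihood change (1,000–2,000
iteration cap); CDF least squares uses `nls.lm` with ftol = ptol = 1e-12 and
10 multi-starts from seed 20260101 (fixed and recorded). Fractions are kept
on the simplex by a softmax parametrization, D positive by a log transform;
components are always reported sorted by ascending D. Degenerate cases are
defined: empty stacks, zero-variance samples, single-peak profiles, poles
that coincide, and overlapping outlines raise errors; all-equal dwell
durations fall back from order 2 to order 1 with a warning; a two-group
Dunn test warns and suggests the rank-sum test. Ties in the max-location
bin break toward midcell; boundary points count as inside a cell.

## Known limitations

Straight-axis cells only; 2D only; no gap closing, track splitting/merging
or drift correction; dwell definitions are not portable across tools; the
Kruskal–Wallis effect size is reported as (H − k + 1)/(N − k) (called
epsilon-squared here; naming varies across sources, and a rank-based
alternative is available); and apparent-D fits deliberately leave the 4σ²
localization-error term in the reported coefficients unless `sigma` is
supplied.
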