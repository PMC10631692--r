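---
title: "Landscape ecological security assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape ecological security assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsecr)
```

## The assessment model

`landsecr` quantifies landscape ecological security — the capacity of a
regional land-use mosaic to keep its structure and function under
disturbance — from categorical land-use maps observed at several epochs.
Risk and security are treated as inverse: everything is computed on a risk
scale and the five security grades are ordered so that grade I is the
safest (lowest risk).

**Per-class structure and loss.** For each land-use class $i$ with $n_i$
patches (rook-connected components), class area $A_i$ and study area $A$:

* fragmentation $C_i = n_i / A_i$,
* separation $S_i = \tfrac12 \sqrt{n_i / A}\,(A / A_i)$,
* fractal dimension $D_i$, the patch mean of $2\ln(P/4)/\ln(a)$ with
  perimeter $P$ and area $a$ in cell units (a single-cell patch is assigned
  $D = 1$, the dimension of a square, because $\ln a = 0$).

The disturbance index is the weighted sum
$E_i = aC_i + bS_i + cD_i$ with $a + b + c = 1$; defaults $(0.5, 0.3, 0.2)$
rank fragmentation as the dominant symptom of disturbance, then
separation. The loss index is $R_i = E_i F_i$, where $F_i \in [0,1]$ is an
expert-scored vulnerability: built-up 0.05, forest 0.10, cultivated 0.14,
water 0.19, tea garden 0.24, rubber 0.28. The ordering encodes that
monoculture plantations (rubber, tea) are the most fragile landscapes under
further disturbance while built-up land has little ecological structure
left to lose. The vulnerability table is a configuration constant; a
factor-analytic vulnerability needing vegetation-coverage and soil-erosion
covariates is deliberately out of scope because those inputs are not part
of this pipeline.

The structure-index formulations are pluggable: they are the conventional
companions of the disturbance index in the landscape-ecological-risk
literature, but no single canonical definition exists, so
`class_structure_metrics()` is a separate step whose output feeds
`disturbance_index()` unchanged.

**Grid risk.** A fishnet of square cells (default 10 km) is laid over the
study boundary, anchored at the lower-left corner of its bounding box;
cells keep their in-boundary clipped area (Sutherland–Hodgman clipping
against each cell rectangle) and cells with under 1% of their area inside
the boundary are dropped. Per cell $k$, the ecological risk index is the
area-weighted mean of class losses,
$\mathrm{ERI}_k = \sum_i (A_{ki}/A_k) R_i$, a convex combination — it can
never leave the range of the class $R_i$ values. Grades use fixed
breakpoints $0.042, 0.049, 0.056, 0.06$ (upper bound 1), left-closed
right-open intervals (a value exactly on a break takes the higher grade);
an exact dynamic-programming Jenks natural-breaks alternative
(`jenks_scheme()`) is available when epoch-specific breaks are wanted, but
the fixed table is the default because it is what makes epochs comparable.

**Geostatistics.** The empirical semivariogram
$\gamma(h) = \frac{1}{2N(h)} \sum (Z(x_i) - Z(x_j))^2$ is binned into 12
equal-width lags up to half the maximum pairwise distance by default; each
bin reports the mean pair distance rather than the bin midpoint, which
removes most within-bin bias. Spherical and exponential models are fitted
by weighted least squares (weights = pair counts) with box constraints from
five deterministic starting points; the exponential range is reported as
the practical range (95% of the sill), the convention of common GIS
software. Ordinary kriging solves the standard semivariance system with a
Lagrange multiplier and a global neighborhood — a few hundred support
points do not justify search-radius heuristics. With a zero nugget the
predictor honors the data exactly.

**Spatial autocorrelation.** Global Moran's I uses contiguity weights
(rook by default, row-standardized; queen available). Inference is
reported both from the normality approximation (z-score) and from seeded
permutations (999 by default, pseudo p one-sided toward the observed
statistic). Local Moran's I follows the standard LISA construction with
conditional permutations; significant units are labeled HH, LL, LH or HL
by the quadrant of (value, spatial lag) about the mean, others `ns`. Under
row standardization the local statistics sum to $S_0 I$, which the tests
verify numerically. The contiguity scheme, standardization and permutation
count are declared assumptions — typical interactive-GIS practice — since
none is intrinsic to the statistic.

**Gravity migration.** Each grade's center of gravity is the area-weighted
mean of its cell centers; epoch-to-epoch shifts are summarized by the
displacement components, the Euclidean distance (degree inputs are
converted at 111.11 km/degree, a crude equirectangular constant kept as a
named configuration value), and a compass bearing. The bearing is an
`atan2` bearing measured clockwise from north mapped to the 8-wind rose by
45° sectors; the quadrant-free $\arctan(\Delta y/\Delta x)$ term is also
reported for transparency but is sign-ambiguous and not used for labeling.

**Grey forecasting.** GM(1,1) accumulates the positive series once,
forms the background $z^{(1)}(k) = \alpha x^{(1)}(k) + (1-\alpha)
x^{(1)}(k-1)$ with $\alpha = 0.5$ (the universal adjacent-mean convention;
configurable), solves $x^{(0)}(k) + a z^{(1)}(k) = b$ by least squares,
and forecasts through the exponential time-response function, anchoring
the first fitted value at the first observation. When $|a| < 10^{-12}$
the exponential form is numerically meaningless and the linear-accumulation
limit is used instead, which makes a constant series an exact fixed point.
Forecasting is applied independently per fishnet cell — the only choice
that yields forecast *maps* — with per-cell $R^2$/RMSE recorded;
per-grade-area series can be forecast with the same functions when only
grade shares are of interest. Forecast epochs are abstract steps; mapping
steps to calendar years belongs to the run configuration.

## The synthetic generator

`generate_landuse_raster()` synthesizes categorical maps by seeded
multi-source region growing over a fixed uniform random priority field.
Each class receives an exact cell quota (largest-remainder apportionment
of its target fraction) and roughly `quota / (1 + clumping)` seed cells,
so clumping directly controls patch counts — the quantity the
fragmentation metrics consume. Growth is competitive and quota-bounded;
enclosed unassigned pockets are resolved by dropping a fresh seed for a
class with remaining quota. Rook connectivity is the single connectivity
convention package-wide. All randomness flows from one integer seed
(`withr::local_seed`); no global state is left behind.

`evolve_landuse()` converts cells class-to-class with a per-epoch
probability, multiplied (and clipped at 1) for cells adjacent to the
target class — a minimal contagion model of plantation expansion.
`generate_autocorrelated_points()` draws exact Gaussian-random-field values
by direct Cholesky factorization of the point covariance (desk-scale by
design, $n \lesssim 2000$), so simulated fields carry *exactly* the
variogram the geostatistics tests assume.

The demo dataset (`make_demo_dataset()`) is a 120×120 grid of 1-km cells
over an irregular hexagonal boundary with six classes at area shares
0.70/0.15/0.03/0.07/0.03/0.02 (forest, rubber, tea, cultivated, built-up,
water) — loosely the area ordering of the published class table — with
high forest clumping and adjacency-biased forest→rubber, forest→tea and
cultivated→built-up conversion across four epochs, so the forest share
declines monotonically and risk drifts upward. What the generator does
*not* emulate: classification error, georeferencing noise, rasters whose
class textures follow real patch-size distributions, and topography-driven
anisotropy. Passing tests therefore demonstrate the correctness of the
computations, not the realism of any particular landscape.

## Numerical choices

* Patch labeling runs on an adjacency graph (igraph components); an
  independent queue-based flood fill is kept in the test suite as the
  oracle, and the two are required to agree exactly on rasters up to
  64×64.
* Variogram fitting tolerates the non-convexity of the WLS surface with
  five fixed starts; ties resolve to the lowest objective value. A fit on
  noiseless model-generated curves must recover parameters to $10^{-6}$.
* Duplicate kriging locations are averaged (with a warning) before the
  system is solved; kriging variances are clipped at zero against roundoff.
* Grade classification rejects values outside $[0, \text{upper}]$ rather
  than silently clamping; the forecasting stage clamps its *own*
  extrapolations into the gradable range before classification, because a
  grey forecast of a bounded index can leave the bound.
* Areas are carried in cell counts internally and converted once
  ($10^4\,\mathrm{hm}^2$ for the class table, km² for transition
  matrices); all grid math assumes a projected CRS in meters.

### The variogram recovery experiment

A single 400-point realization of a Gaussian field with range comparable
to the window supports only weak inference on the variogram parameters:
across a wide sweep of windows and binnings, single-realization WLS fits
show mean errors near 100% of a nugget worth 10% of the sill and 25–45%
of the range, for both families — this is ergodic fluctuation, not an
estimation bug. The recovery experiment therefore averages the empirical
variograms of 10 independent realizations (common binning, pair-count
weights; `pool_empirical_variograms()`), fits once, and judges the nugget
and sill on the variance (sill) scale and the range on the range scale,
requiring all errors below 25%. The design — a 150×150 window (five
practical ranges), 400 uniform points per realization, 12 lags to
distance 105 — passes with a wide margin for both families across disjoint
seed decades.

## Problem sizes

The test suite exercises rasters up to 64×64 against exhaustive oracles,
lattices up to 8×8 for spatial statistics, 400-point fields for
geostatistics, and the full 120×120 four-epoch demo for the end-to-end
run; the complete suite runs in well under five minutes on one CPU, the
demo pipeline itself in a few seconds.

## Known limitations

* The structure indices assume a single raster resolution per run; mixing
  resolutions across epochs is rejected rather than resampled.
* Kriging is isotropic ordinary kriging only — no anisotropy, trend, or
  co-variables.
* The grey model is the plain GM(1,1); series with strong oscillation or
  sign changes are outside its domain (non-positive series are rejected).
* Compass labels from centroid shifts are convention-dependent; the
  bearing convention here is stated explicitly and the raw arctangent is
  reported alongside so other conventions can be reconstructed.
* The fishnet drops cells with under 1% in-boundary area; with very coarse
  cells over a narrow study area this can leave grades supported by few
  cells, and grade-level centroids are then noisy.
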