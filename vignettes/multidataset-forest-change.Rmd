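---
title: "Comparing forest cover change across heterogeneous satellite-style products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing forest cover change across heterogeneous satellite-style products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestflux)
```

## The problem

Estimates of forest cover change diverge across observing systems because
the systems measure different things: a spectral trajectory detector reacts
to any sustained change in reflectance, a post-classification comparison
only sees changes that flip a discrete class between two dates, a
fractional-cover difference sees sub-pixel change but averages away
short-lived events, and a fine-resolution binary product counts small
patches the coarse products cannot resolve. On top of that sit three purely
methodological levers — detector parameters, the spatial resolution at
which change is extracted, and the definition of "forest" itself — each of
which can move the headline numbers by more than the real signal.

`forestflux` packages all four extraction recipes, the accounting that
turns labels into km² and coverage percent, the agreement and correlation
statistics used to compare products, and the three sensitivity experiments,
around a synthetic scene generator with exact ground truth. Every claim the
package makes about its own behaviour is checked against that ground truth
or against an independent oracle in the test suite.

## The trajectory detector

Each pixel carries an annual index series (an NBR-like quantity in
[−1, 1]; high over closed canopy, low over bare ground). Processing is:

1. **Gap fill.** Runs of at most two consecutive missing years are linearly
   interpolated; longer gaps exclude the pixel, which is reported as
   `none` with `qa = TRUE` rather than silently labelled unchanged.
2. **Despike.** An interior year is replaced by the mean of its neighbours
   when it is a local extremum and even its *smaller* deviation from a
   neighbour exceeds `despike_threshold` (default 0.5) times the local
   three-point range. Requiring the smaller deviation — not the deviation
   from the neighbour mean — is deliberate: at the corner year of a genuine
   step the deviation from the neighbour mean is half the step height, so a
   mean-based rule deletes the last pre-event observation whenever noise
   makes the corner a marginal extremum, and the fitted drop then straddles
   the event. A spike must stand away from *both* neighbours.
3. **Segmentation.** A continuous piecewise-linear least-squares fit on a
   hinge basis. Vertices are selected greedily: starting from the single
   best-fit segment, the interior year whose insertion most reduces the SSE
   is added, then a coordinate-descent relocation pass lets each current
   vertex move to any better position. Insertion stops at `max_segments`
   (default 4) or when the best insertion improves the SSE by less than
   `mse_improvement_min` (default 0.01) of the *single-segment* SSE. Two
   design points matter here:
   - The improvement is judged against the single-segment SSE — the
     trajectory's own variance scale — not against the current model's
     residual. A current-residual criterion accepts essentially every late
     vertex (any reduction is a large fraction of a near-zero residual) and
     splits clean steps into two sub-threshold half-steps.
   - An insertion that drives the residual to numerical zero is always
     accepted, so exactly-representable piecewise-linear input is recovered
     exactly even when its smallest kink falls below the relative gate.
   The relocation pass is what makes the greedy search exact on noiseless
   piecewise-linear input: pure insertion can place its first vertex
   between two true vertices and never recover. The test suite verifies
   equality with an exhaustive enumeration of all vertex subsets over a
   300-series family (length 14, up to 3 segments).
4. **Classification.** Segments whose absolute fitted change reaches
   `change_threshold` (default 0.15 index units) are candidates; the
   largest-magnitude candidate decides, ties going to the earliest segment.
   A negative decisive segment is **loss** only if it starts at or above
   `forest_threshold` (default 0.4 — it was forest before losing); a
   positive one is **gain** only if it ends there (it became forest). The
   change year is the decisive segment's end for loss and start for gain;
   the magnitude is the absolute fitted change.
5. **Masking.** A forest-domain mask suppresses loss labels outside it.
   Gain is kept everywhere by default — afforestation happens on previously
   non-forest land, which is exactly where a forest mask is false — but
   `mask_filters_gain = TRUE` applies the mask symmetrically, since the
   masking convention differs between operational products.

The defaults are mid-range values exposed through `detector_params()`; the
package treats them as experimental variables (see the sweeps below), not
as constants, because detection outcomes are demonstrably sensitive to
them.

## The three comparison recipes

- **Stable-map categorical change** (`stable_class_map()`,
  `categorical_change()`): the modal class over each of two windows
  (defaults 2001–2003 and 2010–2012), compared under a class-set forest
  definition (IGBP codes 1–5; woody savanna, code 8, joins under the
  extended definition). The mode suppresses year-to-year classification
  flicker; with a 10% independent flip rate, a 3-year mode is wrong only
  when at least two of three labels flip (probability ≈ 2.8%), which the
  tests check stochastically. Mode ties break to the class seen latest in
  the window (configurable to lowest-code).
- **Fractional change** (`period_mean_cover()`, `fractional_change()`):
  difference of period-mean percent tree cover; any strictly non-zero
  delta counts toward the corresponding direction (no minimum-delta
  epsilon by default).
- **Loss accumulation** (`accumulate_annual_loss()`): logical OR of annual
  binary loss layers — a pixel lost once is lost, with no double counting —
  paired with a single whole-period gain layer.

## Accounting

On an equal-area grid, binary products are accounted by whole-pixel
counting and fractional products by sub-pixel summation
(`binary_change_area()`, `fractional_change_area()`). The two meet exactly
where they should: aggregating a fine binary map to coarse percent with
`aggregate_fraction()` and then accounting fractionally reproduces the fine
binary accounting identically (same summands regrouped), which the suite
asserts with `expect_identical()`. Provincial aggregation partitions the
same summands, so provincial rows sum to national totals exactly; pixels
with no province ID go to an explicit `unassigned` row rather than being
dropped. `coverage_percent()` uses a configurable land-area denominator
(default 9.6 × 10⁶ km²) because published coverage percentages are only
interpretable relative to their denominator — and published sources are not
always internally consistent about it.

## Agreement and correlation

`agreement_count()` counts, per pixel, the datasets flagging change in one
direction; counts are banded 0 / 1–2 / 3–4 as none / low / high agreement,
with 4 marking full agreement. On a zero-noise scene whose events fall
between the comparison windows, all four recipes flag identical pixels and
the count map contains only 0 and 4 — the end-to-end consistency check of
the whole generator-plus-recipes stack. Events outside that window (for
example a disturbance during the first stable-map window) are visible to
the trajectory detector but invisible to the period comparisons; that is a
real property of the recipes, not an artefact, and it is why the
consistency check constrains `event_years`.

Provincial correlations use the sample Pearson r with a two-sided t-test at
the 90% level (`t = r√((n−2)/(1−r²))`; two-sided is the conservative
reading when sidedness is unspecified, and the level is configurable). The
weighted variant computes r from weighted moments (weights normalised to
sum 1; provincial forest areas in the intended use) and judges significance
with the Kish effective sample size `n_eff = (Σw)²/Σw²` — a pragmatic
choice, made explicit here because no standard procedure exists for
weighted-correlation significance in this setting. With equal weights the
weighted r reduces to the plain r to machine precision, which is tested.

## Scaling and resampling

All scaling is block-aligned with integer factors — the products being
emulated share pixel boundaries by construction, and sub-pixel registration
is a separate problem the package deliberately avoids. `resample()`
provides the five standard kernels: nearest (coarse-cell-centre sample),
average (block mean, mass-preserving to 1e-9), mode (block majority, ties
to the smallest code), bilinear, and cubic (separable Catmull-Rom,
a = −0.5, clipped to the input range; any interpolating cubic would do —
the tests pin the implementation to an independently coded tensor-product
oracle rather than to one canonical kernel). Interpolating kernels are
rejected for categorical input with an explicit error.

`run_scaling_experiment()` reproduces the two orderings used in practice:
resampling an existing change map (products that ship change) versus
resampling the period maps and re-extracting change (products whose change
is derived). On scenes with sub-block minority change the second ordering
is far more method-sensitive — modal reclassification can flip entire
blocks from a two-pixel conversion — and the tests derive the exact
expected areas from the constructed block geometry.

## The synthetic generator

`make_truth()` draws per-pixel event kinds i.i.d. from a mix over five
classes: stable forest (cover 1), stable non-forest (cover 0), abrupt loss
(step down by `magnitude`, default 0.8, at an interior event year),
gradual gain (ramp at `ramp_rate`, default 0.1 yr⁻¹, saturating at
`magnitude`), and loss-then-recovery (step down, then ramp back, capped at
the pre-event cover). The default mix (40/25/15/12/8%) describes a
forest-dominated landscape with a realistic surplus of stable land over
changed land; event years are uniform on the interior of the span so every
event has observations on both sides. Renderers map cover to each sensor:
an affine index map (`0.05 + 0.55 × cover` by default — contrast chosen for
clear forest/bare separation, not to mimic any instrument), thresholded
class codes with independent label flips, replicated-to-children percent
cover with Gaussian noise, and fine binary loss/gain layers keyed to a
cover threshold. Noise is i.i.d. Gaussian per pixel-year with no spatial
autocorrelation, no clouds, no gaps unless injected — sufficient for the
statistics the package exercises, and a deliberate simplification: passing
tests demonstrate algorithmic correctness on this model, not performance on
real imagery with correlated noise, phenology, or registration error.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in a few minutes: the oracle-equivalence family is 300
series of length 14; parameter recovery uses a 100×100 scene (10,000
trajectory fits) at σ = 0.02 with 20% abrupt-loss pixels; sweeps use 25×25
scenes; conservation checks 30×30 with refinement factor 8. Tolerances are
dictated by the property: conservation identities are exact or 1e-9;
oracle equivalence 1e-9; the equal-weights correlation reduction 1e-12;
stochastic recovery rates use fixed seeds with margins (recall ≥ 0.95,
false-positive rate ≤ 1%) that the detector clears comfortably at the
stated noise level. Degenerate inputs are defined, not accidental:
constant series fit as one zero-slope segment with zero SSE; zero-variance
correlation inputs return undefined r flagged not-significant; empty masks
yield zero loss; all-missing pixels land in the QA layer.

## Interfaces

Rasters serialise as long-form CSV plus a JSON sidecar carrying the grid,
years, kind and nodata sentinel (−9999 numeric, 255 categorical/binary) —
a plain-text format chosen so fixtures and outputs are diffable and
dependency-free; integer data round-trips bit-exactly. `run_config()`
bundles every setting, rejects unknown keys by name, and round-trips
through JSON. `run_report()` is the end-to-end entry point: one scene, four
products, four change maps, national and provincial tables, agreement maps
and correlation matrices, written as CSVs that are byte-identical across
runs with the same seed.

## Known limitations

- The generator's noise model is white; real interannual reflectance noise
  is autocorrelated and spatially structured, so real-data recall will be
  lower than the synthetic figures at equal σ.
- The fitter is greedy. Exactness is demonstrated on noiseless
  piecewise-linear input and near-optimality on the tested noisy cases,
  but no global-optimality guarantee exists off those families.
- Resampling is restricted to integer block factors; arbitrary-CRS warping
  is out of scope.
- The mask convention (loss-only by default) is one of two defensible
  readings of operational practice; both are implemented and the choice is
  a flag.
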