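---
title: "Methods: quantification models and design choices in nemaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification models and design choices in nemaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

nemaquant implements three quantification procedures used when delivering
reporter mRNAs (eGFP, luciferase) to plant-parasitic nematode juveniles,
plus statistics for male gonad morphometry. This vignette documents the
models, their assumptions, the tunable parameters, and the design choices
made where the procedures left genuine freedom.

## 1. Fluorescence pixel scoring

### Model

Each worm is scored on a single 8-bit grayscale micrograph (one most
in-focus 2D section per animal; Z-stack handling is out of scope). The
statistic is:

1. **crop** the worm's bounding box (0-based, half-open coordinates);
2. **invert**: `p -> 255 - p`;
3. **adjust** brightness, contrast, intensity, in that order:
   * brightness: `p' = p + 255 B/100` (additive, scaled to the full 8-bit
     range),
   * contrast: `p'' = 127.5 + (p' - 127.5)(1 + C/100)` (linear about
     mid-gray),
   * intensity: `p''' = p''(1 + I/100)` (multiplicative gain);
   each stage **rounds half away from zero and clamps to [0, 255]**
   before the next, so every result is bit-exact and machine independent;
4. **count** pixels whose absolute deviation from a reference background
   gray *strictly exceeds* an integer shade-variance threshold
   `v` in [0, 255] (strict, because a pixel must *exceed* the tolerance
   to count).

The default adjustment is B = -17, C = +71, I = -27 and the default
background reference is gray 209 (hex D1). Image editors do not agree on
B/C/I transfer functions and the original ones are not recoverable; the
three formulas above are this package's fixed, documented semantics. All
results are reproducible bit-exactly *within* this pipeline, which is the
property the tests enforce (an independent single-pass scalar
reimplementation must agree to exact integer equality).

### Background and threshold

The 209 reference describes externally processed micrographs. When
images are processed by this package the post-adjustment background
depends on the B/C/I semantics, so `estimate_background()` (modal gray,
ties broken toward the lighter value) should be preferred; the pipeline
runner does this by default. Under the default adjustment the synthetic
dark background (gray 10) maps to 186.

The shade-variance threshold was "empirically derived" in the original
assay and never printed. `calibrate_variance()` is this package's
operational substitute, not a reconstruction: it returns the smallest
`v` such that a chosen quantile (default: median) of the control images'
bright-pixel fractions is at most a target (default 1%). Note a trade-off:
on worms with genuine gut autofluorescence a 1% target also silences the
gut signal, which would make control counts near zero. Since control
worms are expected to score non-zero (autofluorescence restricted to the
digestive tract, with treated worms brighter throughout the body), the
pipeline default is a fixed `v = 60` for the synthetic scenario: above
the processed noise floor and the body-wall deviation, below the gut and
reporter deviations. Calibration remains available (`variance = NULL`).

The fold change between treated and control is the ratio of arithmetic
means (a ratio of medians is also emitted); whether the original
statistic used means or medians is not stated, so the package reports
both and defaults to means.

## 2. Luminescence decay kinetics

### Model

Each well's time series is fitted with

    Intensity = a + b * 2^(c * time)

`a` is a non-decaying background (luminescence units), `b` the decaying
amplitude, `c` a rate per second (negative for decay). The half-life of
the decaying component is `-1/c` exactly. Times are seconds from the
first read; the plate protocol reads every 176 s for 48.84 h, i.e. 1000
time points per well. The time unit inside the original fit was never
stated; the 176-second sampling clock is the only stated unit, so this
package fixes seconds and reports half-lives in seconds (hours in the
print method). Half-lives are invariant to that choice (tested: fitting
in minutes rescales `c` by 60 and leaves `-1/c` equal in absolute time).

### Optimisation

`fit_decay()` minimises the residual sum of squares with a
Levenberg-Marquardt optimiser (`minpack.lm::nlsLM`), from the
conventional starts `a = 1000, b = 1000, c = -0.0001`. Tolerances are
`ftol = 1e-10` (relative RSS change) and `ptol = 1e-12` (parameter
step). A single-start fit occasionally fails on flat series, so
non-converged fits are restarted with `c` one decade up and down.
Degenerate series (e.g. constant) return a *flagged* non-converged fit
rather than an error; a fitted amplitude indistinguishable from zero
(|b| below 1e-8 of the data scale) leaves `c` unidentifiable and is
flagged the same way. Flagged or non-decaying (`c >= 0`) wells are
excluded from the half-life comparison with a warning, and the excluded
counts are reported — whether the original analysis excluded such wells
is unknown, so the report makes the bookkeeping explicit.

### Detection window

"How long does the treated signal stay above background?" has no stated
rule, so the package operationalises it with two endpoints. At every
time point a one-sided Mann-Whitney test (treated > control, across
wells) is run at level alpha: `conservative_end` is the end of the
contiguous significant run starting at t = 0, `liberal_end` the last
significant time anywhere. Both are 0 when nothing is significant. Under
the null (both groups generated identically) the per-time-point
rejection rate equals the achievable level of the discrete exact test
(0.0415 at 8 vs 8 wells, alpha = 0.05), which the acceptance suite
checks over 200 simulated plates.

## 3. Mann-Whitney U, letters, boxes

* **U statistic**: number of rank wins of the first sample (ties count
  1/2), computed from midranks.
* **Exact p**: full enumeration of all rank arrangements whenever
  `n1 + n2 <= 20` (arrangement counts stay below 10^6 there). The
  tie-free null distribution depends only on the group sizes and is
  cached. Two-sided p is `min(1, 2 * min(lower tail, upper tail))`.
* **Approximate p** (larger samples): normal approximation with the tie
  correction `sigma^2 = n1 n2 / 12 [(N+1) - sum(t^3 - t)/(N(N-1))]` and a
  0.5 continuity correction. The exact/approximate boundary matters
  because the assays straddle it (group sizes 7-9 and 8 are exact,
  21-32 approximate).
* **Compact letter display**: insert-and-absorb. Two groups share a
  letter *iff* their pairwise p >= alpha; letters are consecutive
  lowercase from "a"; absorbed (subset) columns are removed. The iff
  property is asserted on every analysis run in the test suite.
* **Box summaries**: quartiles by linear interpolation of order
  statistics (`quantile` type 7, the common plotting default — the
  convention is otherwise unstated, so it is fixed and documented);
  whiskers extend to the most extreme data points within 1.5 x IQR of
  the quartiles; everything outside is listed as an outlier.
* **Multiple testing**: pairwise morphometry letters use raw p-values at
  alpha = 0.05 by default, matching the reporting convention of the
  original analysis; a Bonferroni flag is available and off by default.

## 4. Synthetic data: what it emulates, and what it does not

The generators are pure functions of (parameters, seed). Per-entity
substreams are derived from (master seed, entity index), so adding wells
or worms never perturbs entities already generated.

* **Worm images**: a dark canvas (gray 10) with a stylised worm — a tube
  of width 12 px around a sinusoidal midline with random phase; the tube
  interior is body gray 40 plus an optional diffuse, body-wide
  `reporter_extra` (0 for controls), and a central stripe of half the
  tube width carries an additional `gut_extra = 60` emulating intestinal
  autofluorescence. Per-pixel Gaussian noise (sd 2 by default) is
  rounded and clamped. The geometry is deliberately not anatomical: the
  scoring statistic is geometry-agnostic, so a tube suffices to test it.
  Poisson photon noise, optics, bleed-through and motion are not
  simulated — the score uses a hard threshold, so distribution shape is
  secondary. Consequently, passing tests show the *statistic* behaves as
  specified, not that real micrographs would score identically.
* **Plate series**: intensities on the model curve plus Gaussian noise,
  clamped at 0, on the 176 s / 48.84 h grid; 8 treated and 8 control
  wells by default, with controls generated at `b = 0` (background
  only).
* **Morphometry**: body length ~ Normal, truncated positive; gonad
  proportion ~ Normal, truncated to (0, 100]; gonad length is their
  product, so the proportion statistic has exactly the specified
  distribution. Defaults: proportions 65 / 55 / 45 % (sd 5) at 0-1,
  2-3 and 5-6 days post-emergence, n = 8 per group. The middle value
  (55%) is an interpolation — no reference central value exists for that
  group. Body lengths 1150 / 1190 / 1230 um with sd 150 um encode a
  modest ageing increase that is small against between-worm variation,
  so individual body-length comparisons are usually not significant at
  these group sizes while the proportion contrast is — the qualitative
  pattern the morphometry analysis is meant to recover.

## 5. Problem sizes and numerical choices in the test suite

The suite freezes every derived expectation from an independent oracle
(scalar pixel loops, per-arrangement enumeration, a second rasterizer)
and runs: 200 random-image scoring comparisons at exact integer
equality; 500 random Mann-Whitney instances with ties at 1e-12; 200
simulated null plates on a 41-point grid for the detection-window
calibration (the per-time-point null rate is grid-length independent, so
the short grid loses nothing); 200 morphometry seeds for the letter
separation power check; and noiseless decay refits at 1e-6 relative
error on the full 1000-point grid. The whole suite runs in well under a
minute on one CPU.

## 6. Known limitations

* The B/C/I semantics are *a* reasonable fixed choice, not the original
  editor's; absolute pixel counts are comparable only within this
  pipeline.
* `calibrate_variance()` pins a false-positive rate on controls; it does
  not reconstruct the original threshold, which was never published.
* The decay model assumes a single exponential component over the whole
  span; substrate depletion kinetics and well-position effects are not
  modelled.
* Exact Mann-Whitney p-values are enumerated, so samples beyond
  `n1 + n2 = 20` always take the approximate path.
* Worm segmentation is out of scope: bounding boxes are inputs.
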