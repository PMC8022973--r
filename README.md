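# nemaquant

Quantification pipelines for reporter-gene assays in plant-parasitic
nematodes, written for researchers measuring transient expression of
delivered mRNAs (eGFP, luciferase) in *Heterodera*-type juveniles and
characterising male gonad morphometry.

The package implements three procedures as tested, reusable code:

1. **Fluorescence pixel scoring** — each worm's micrograph is cropped,
   inverted, adjusted (brightness −17%, contrast +71%, intensity −27% by
   default, with per-stage round-half-away-from-zero and clamping to
   [0, 255]), and scored as the number of pixels whose deviation from a
   reference background gray (209 = hex D1 by default) strictly exceeds an
   integer shade-variance threshold *v* ∈ [0, 255]. Treated and control
   groups are compared with a Mann–Whitney *U* test and a fold change of
   mean counts.
2. **Luminescence decay kinetics** — each well's time series (one read
   every 176 s for 48.84 h) is fitted by Levenberg–Marquardt least squares
   with

       Intensity = a + b · 2^(c·t),   half-life = −1/c

   from starts (a, b, c) = (1000, 1000, −0.0001); treated and control
   half-lives are compared with Mann–Whitney, and a per-time-point
   one-sided test yields a detection window (contiguous and last
   significant time above background).
3. **Gonad morphometry** — gonad length as a percentage of body length per
   age group (days post-emergence), pairwise exact Mann–Whitney tests,
   compact letter displays (groups share a letter iff p ≥ α), and box
   summaries with 1.5 × IQR whiskers.

Mann–Whitney p-values are exact by full enumeration of rank arrangements
(midranks for ties) whenever n₁+n₂ ≤ 20, otherwise normal approximation
with tie and continuity corrections.

Synthetic generators emulate all three readouts with known ground truth
(worm images with intestinal autofluorescence masks, plate series, and
morphometry tables), so the whole pipeline runs and is testable without
any microscope or plate-reader files.

## Worked example

```r
library(nemaquant)

## fluorescence: 20 treated vs 20 control synthetic worms
treated <- generate_worm_batch(20, image_sim_params(reporter_extra = 50),
                               seed = 7, offset = 0)
control <- generate_worm_batch(20, image_sim_params(), seed = 7, offset = 20)
cfg <- quant_config(variance = 60)
proc <- lapply(control, function(w) adjust_bci(invert(w$image), cfg))
cfg$background_gray <- estimate_background(
  gray_image(do.call(rbind, lapply(proc, unclass))))
box <- bounding_box(0, 0, 200, 80)
ts <- lapply(treated, function(w) score_worm(w$image, box, cfg))
cs <- lapply(control, function(w) score_worm(w$image, box, cfg))
compare_fluorescence(ts, cs)
#> Mann-Whitney U comparison (normal_approximation)
#>   U = 400, p = 4.683e-10 (n1 = 20, n2 = 20)
#>   fold change (mean ratio) = 2

## luminescence: noiseless series on the 176 s grid refits its generator
fit_decay(generate_luminescence(n_wells = 1, noise_sd = 0)[[1]])
#> decay fit [well treated_01]: a = 1000, b = 1000, c = -0.0001 /s (converged)
#>   half-life = 10000 s (2.778 h), rss = 0

## morphometry: ageing decline in gonad/body percentage
analyze_groups(generate_morphometry(seed = 7), "proportion")
#> Morphometry analysis of proportion by age group
#>   0-1 dpe (n = 8, letter a): median 67.58 [Q1 61.38, Q3 73.23]
#>   2-3 dpe (n = 8, letter b): median 56.28 [Q1 55.35, Q3 59.08]
#>   5-6 dpe (n = 8, letter c): median 45.96 [Q1 42.9, Q3 48.12]
#> pairwise two-sided Mann-Whitney p-values:
#>           0-1       2-3       5-6
#> 0-1 1.0000000 0.0006216 0.0001554
#> 2-3 0.0006216 1.0000000 0.0029530
#> 5-6 0.0001554 0.0029530 1.0000000
```

Reading the output: the treated worms' bright-pixel counts are twice the
controls' on average (the controls' counts come from gut
autofluorescence alone), with all 400 treated/control pairs won (U = 400)
and p ≪ 0.05; the noiseless decay refit recovers its generating
parameters exactly, giving a 10 000 s half-life; and the three age groups
carry distinct letters a/b/c because every pairwise p is below 0.05, with
group medians declining from ~65% to ~45%.

A multi-stage runner (`run_pipeline(run_config(seed, outdir))`) simulates
images, plate and morphometry table, analyses all three, and archives the
resolved configuration (`run_config.json`) beside its outputs so every
file is reproducible from the seed. A thin command-line wrapper with the
same subcommands (`simulate-images`, `simulate-plate`,
`simulate-morphometry`, `quantify`, `fit-decay`, `morphometry`,
`run-all`) is installed at `inst/cli/nemaquant`.

CSV schemas (fixed column orders, RFC-4180 quoting):

| file | columns |
| --- | --- |
| manifest.csv | worm_id, file, group, x0, y0, x1, y1 (0-based, half-open) |
| plate.csv | well, group, time_s, intensity |
| morphometry.csv | worm_id, dpe_group, body_length_um, gonad_length_um |
| scores.csv | worm_id, group, bright_pixel_count, total_pixels, variance, background_gray |
| fits.csv | well, group, a, b, c, half_life_s, rss, converged |

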