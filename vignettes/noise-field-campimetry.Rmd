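---
title: "Noise-field campimetry: stimulus generation, quality control and paired detection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-field campimetry: stimulus generation, quality control and paired detection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisefield)
```

## The method

Noise-field (snow-field) campimetry shows a patient a full-screen field of
dynamic random noise. In regions of visual-field loss the flicker looks
absent, cloudy or dark, so a *negative* scotoma — one the patient has never
noticed — becomes a *positive* one they can point to and draw. The test takes
seconds, needs no thresholding hardware, and is used to make glaucoma
patients aware of defects already documented by standard automated perimetry
(and thereby to support adherence and earlier presentation), not to replace
perimetry.

This package implements the computational side of such a screening study,
end to end:

1. **Stimulus generation** (`stimulus_config()`, `render_sequence()`):
   gray random-dot frames, tiled in square dots, driven by a seeded
   pseudorandom generator.
2. **Noise quality control** (`sequence_summary()`, `stripe_score()`):
   luminance histograms, tone balance, and a permutation test for the
   stripe artifacts that betray a defective generator.
3. **Visual-field classification** (`anderson_patella()`,
   `stage_classify()`): Humphrey 30-2 pattern-deviation cluster criteria,
   staging by mean deviation, reliability filtering.
4. **Agreement scoring** (`categorize_agreement()`): hemifield-level
   comparison of patient-drawn shadows with the instrument's abnormal
   areas, with physiological blind-spot exclusion.
5. **Exact statistics** (`detection_table()`, `mcnemar_exact()`,
   `clopper_pearson()`, `chi2_adjusted_residuals()`): the paired
   detection-rate analysis of a two-noise study.
6. **Cohorts without patients** (`expand_from_counts()`,
   `simulate_cohort()`, `synth_vf_and_shadow()`): deterministic expansion
   of published count tables, and seeded simulation for testing.

## The stimulus and its parameters

The default configuration reproduces the reference study profile:

| parameter | default | meaning |
|---|---|---|
| `width_px`, `height_px` | 1920 × 1200 | full screen of the test display |
| `dot_px` | 7 | dot edge in pixels; 1.89 mm at 0.27 mm dot pitch, about 2 mm |
| palette | 255, 191, 127, 64, 0 | five equiprobable gray tones (density ratios 1, 0.75, 0.5, 0.25, 0) |
| `fps` | 60 | frame rate; frame interval treated as exactly 1/60 s |
| `n_frames` | 60 | one second of stimulus, matching the analysed still count |
| `dot_pitch_mm_per_px` | 0.27 mm | converts pixel sizes to physical sizes |

Dots are tiled from the top-left corner; when the frame is not a multiple of
the dot size the last row/column of cells is clipped (1920 = 274·7 + 2,
1200 = 171·7 + 3). Each cell consumes exactly one uniform index from the
generator, drawn in row-major order, so a frame of `ceiling(1920/7) ×
ceiling(1200/7) = 275 × 172` cells consumes 47,300 draws and the whole
sequence is a pure function of the seed.

The palette stores its 8-bit levels explicitly rather than deriving them
from the density ratios, because no single rounding rule maps
(0.75, 0.5, 0.25) to all of (191, 127, 64); the measured level set is taken
as canonical. `predict_luminance()` maps levels to screen luminance with a
bare gamma model (`white · (level/255)^2.2`); it ignores the black-level
offset and is documented as a 10–15% approximation for mid and dark tones.

Two analytic facts anchor the quality-control checks. With five
equiprobable tones the pixel-level mean is 127.4 and the population SD is
90.09. A frame mean averages 47,300 independent cells, each covering up to
49 pixels, so its standard error is `90.09 × 7 / sqrt(2,304,000) ≈ 0.415`.
The packaged checks therefore expect a 60-frame mean-of-means within
127.4 ± 0.30 and an SD-of-means in [0.30, 0.55]; both are properties of the
renderer, not tuned numbers.

```{r stimulus, eval = FALSE}
cfg <- stimulus_config(rng = rng_state("xorshift32", 1))
frames <- render_sequence(cfg)
s <- sequence_summary(frames)
c(mean_of_means = s$mean_of_means, sd_of_means = s$sd_of_means)
#>  mean_of_means   sd_of_means
#>      127.4272       0.3895
```

## Generator choice and the stripe demonstration

The production generator is 32-bit Marsaglia xorshift with shift triple
(13, 17, 5) — the canonical parameterization of the cited family; the exact
variant used by any particular implementation is unknowable from published
output, so only distributional properties are matched. Seed 0 (the one
state xorshift cannot hold) is remapped to a documented constant. Uniform
indices are produced by rejection sampling (accept raw values below
`floor(range/k)·k`), eliminating modulo bias.

Linear congruential generators carry two structural defects: the lattice
structure of successive tuples, and very short periods in the low-order
bits when the modulus is a power of two. Either can imprint visible
structure on the *time-averaged* stimulus even though single frames look
random — which is exactly why a noise-field stimulus must be checked
temporally, not frame by frame. `temporal_average()` simulates a long
camera exposure (`exposure_frames(0.2, 60)` = 12 frames), and
`stripe_score()` tests the dot-cell column and row means of the averaged
image against a permutation null, reporting the orientation with the
larger |z|.

Whether the artifact is visible depends on the interaction of the
generator's structure with dot count and tone count; at the default
five-tone, 275-cells-per-row profile the RANDU-style preset (a = 65539,
c = 0, m = 2^31) projects only weakly onto columns and may pass. The
packaged demonstration, `stripe_demo_config()`, therefore uses conditions
under which the defect is structural rather than incidental: four tones
(tone selection then depends on the two lowest state bits, which alternate
with period 2 under RANDU) and 8-pixel dots (an even number of dot columns,
aligning the alternation into vertical stripes in every frame). Under
those conditions the LCG scores |z| in the thousands while xorshift stays
inside ±4 on the same seeds. Even seeds would collapse the multiplicative
LCG onto a short cycle, so demonstration seeds are mapped to odd values.

## The 30-2 model and the abnormality criteria

The canonical Humphrey 30-2 layout (76 points on the 6° lattice offset 3°)
ships as a JSON resource with three auditable point sets: the outer rim
("edge" points), the nasal-edge column (the rim points at the nasal
extreme), and the two blind-spot points at 15° temporal, y = ±3.
Coordinates are stored eye-neutrally (+x temporal, +y superior); the JSON
interchange schema uses chart coordinates and mirrors on read for left
eyes, so mirroring a chart and swapping laterality is an exact symmetry of
the classification.

A field is called glaucomatous when any of three criteria fires:

1. a cluster of ≥3 points at p < 5% on the pattern-deviation plot within
   one hemifield, at least one of them at p < 1%, where only non-edge
   points count toward the size except that up to two nasal-edge points
   may count;
2. pattern standard deviation significant at p < 5%;
3. glaucoma hemifield test outside normal limits.

Design choices where the criterion text is silent: adjacency is the
8-neighbourhood (diagonal contiguity counts, as in clinical usage);
clusters never span the horizontal meridian (the criterion is evaluated
per hemifield); non-nasal edge points keep a component connected but add
nothing to its counted size; blind-spot points are excluded outright.
Probability categories are modelled as the instrument's four significance
levels plus not-significant, with all comparisons phrased as "this
category or stricter", which absorbs the difference between a 5/2/1/0.5%
printout and criteria phrased in terms of 5% and 1%.

Staging uses mean deviation: M1 above −6 dB, M2 in [−12, −6] (both
boundaries belong to M2), M3 below −12 dB, and M4 whenever the instrument
printed no pattern-deviation map at all (fields so depressed the map is
suppressed, typically below about −20 dB). M4 is therefore decided by the
absent map, not by MD.

## Agreement scoring

Patient drawings are reduced to hemifield flags (any region touching a
superior quadrant flags the superior hemifield, and likewise inferior).
Scoring against the instrument's hemifield flags:

* **Agreement** — identical flags, at least one hemifield abnormal in both;
* **Partial agreement** — coincidence in one hemifield, mismatch in the
  other, *in either direction*: a drawing that adds a hemifield the
  instrument calls normal is partial, not full, agreement;
* **No agreement** — no hemifield coincides;
* **No response** — nothing reported or reproducible, or nothing left
  after blind-spot exclusion.

Agreement and partial agreement together define "detection". A region is
excluded as the physiological blind spot when it is isolated, temporal,
straddles the horizontal meridian and sits within 5° of 15° eccentricity
(the tolerance is a parameter; the location is only ever described as
approximate). Eyes with normal fields are not scored on this scale — a
reproducible drawing there counts against specificity and a no-response as
a correct negative — so `categorize_agreement()` signals a dedicated
condition for them rather than guessing.

## Statistics

All headline statistics are exact:

* `mcnemar_exact(b, c)` — exact binomial McNemar on the discordant pairs,
  `min(1, 2·P(X ≤ min(b,c)))`, `X ~ Bin(b+c, ½)`; this, not the
  chi-square approximation, reproduces printed values like 0.0156 and
  0.5000 exactly.
* `binom_two_sided(k, n)` — equal-tails exact binomial p at p₀ = ½.
* `clopper_pearson(x, n)` — exact Beta-quantile interval. This choice is
  verifiable from the reference tables: 31/33 gives 79.8%–99.3% under
  Clopper–Pearson, which Wald and Wilson intervals do not reproduce.
* `chi2_adjusted_residuals(table)` — Pearson chi-square without continuity
  correction plus adjusted standardized residuals
  `(O−E)/sqrt(E(1−row/N)(1−col/N))` for cellwise post-hoc comparison.

`detection_table()` assembles the per-stage analysis (rates, exact CIs,
McNemar per stage, a pooled M3+M4 row for the advanced group, chi-square
of detection × stage per noise, sensitivity over glaucoma eyes and
specificity over normal eyes), and `preference_table()` analyses
ease-of-recognition among eyes detected by both noises. One knowingly
"wrong" number: where the reference total row prints a preference rate of
70.9%, the counts give 94/134 = 70.1% and the computed value is emitted.

## Synthetic cohorts and what the tests do and do not show

`expand_from_counts()` deterministically expands the packaged per-stage
count fixture into 259 per-eye records (205 glaucoma, 19 preperimetric,
35 normal). The fixture encodes the paired structure explicitly; in this
cohort every analog-detected eye was also CG-detected, and the expander
verifies all marginal constraints at run time instead of assuming them.
Expansion order is stable, so eye IDs are reproducible.

`simulate_cohort()` draws paired outcomes from per-stage probabilities
(defaults: the empirical rates of the fixture via
`reference_stage_probs()`); a recovery test at 10⁴ eyes per stage checks
the analysis returns the generating rates within 3 binomial SEs.
`synth_vf_and_shadow()` builds a field/drawing pair that scores as any
requested category, placing clusters of 3 / 6 / 10 non-edge points for
M1 / M2 / M3 and drawing MD uniformly inside the stage interval
(depth-of-defect realism is out of scope); M4 pairs can only be generated
as no-response, since an absent pattern-deviation map yields no hemifield
flags.

These generators emulate the *structure* of the data — paired outcomes,
cluster geometry, blind-spot drawings — not patient behaviour: there is no
model of attention, drawing sloppiness, media opacity or learning effects.
Green tests demonstrate that the pipeline's arithmetic and logic are
right, and that the published tables follow from the published counts;
they cannot re-measure the human detection rates themselves.

## Numerical and scale choices

* Within-frame SD uses the population (n) convention, matching
  image-analysis tools; spread across frames uses the sample (n−1)
  convention, matching "mean ± SD over 60 images".
* The stripe permutation test uses 199 permutations by default (p
  resolution 1/200) and its two-sided p is
  `(1 + #{|z_perm| ≥ |z_obs|}) / (n_perm + 1)`, so a maximal stripe
  reaches the attainable minimum `1/(n_perm+1)`.
* Test and demonstration problem sizes — 60 full-resolution frames for the
  QC profile, 12-frame averages for the stripe score, 10⁶ draws for
  generator uniformity, 10⁴ eyes per stage for recovery — are the sizes at
  which the corresponding analytic expectations are sharp while a full
  suite run stays comfortably in the minutes range on a laptop core.
* Degenerate inputs are decided, not left to chance: a perfectly flat
  count table has F = 0 and p = 1; `mcnemar_exact(0, 0)` is 1; a
  Clopper–Pearson bound at x = 0 (or x = n) is exactly 0 (or 1); an empty
  palette, a zero xorshift state, or a field without a pattern-deviation
  map raise typed errors.

## Limitations

Beyond the synthetic-data caveats above: the luminance model is a gamma
curve without black-level offset; analog-noise ingestion is supported only
as "any stack of grayscale frames" (no video decoding); histogram *shape*
classification (bell vs trapezoid) is a visual judgement in the source
material, with no quantitative rule to implement, and is deliberately
absent; and the generator match to any particular historical
implementation is distributional, not bit-exact, since published stimuli
do not pin down the generator's parameterization or seeds.
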