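---
title: "lewyquant: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lewyquant: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lewyquant)
```

## The problem

Multiplex immunofluorescence of α-synuclein (α-Syn) pathology co-labels a
tissue section with antibodies against distinct epitopes — here an
N-terminus epitope (residues 34–45), phosphorylated S129, and a C-terminus
epitope (residues 118–123). Because misfolded α-Syn buries or exposes
epitopes depending on its conformation and truncation state, the three
channels do not simply replicate each other: substantial aggregate
populations (perinuclear threads, glial inclusions, neuronal lysosomal
puncta) are visible to the N-terminus antibody alone. `lewyquant`
quantifies this: per-region decomposition of total immunolabelling into
epitope-unique and overlapping areas, pathology load, Lewy body (LB) vs
Lewy neurite (LN) morphology distributions, and proteinase-K (PK)
digestion time courses.

## Segmentation model

Each channel is processed as

1. **Background subtraction** — `channel - GaussianBlur(channel, sigma)`,
   clipped at zero. The blur is a *background estimate*, so
   `blur_sigma_px` (default **20 px**) must be large relative to the
   objects to preserve; at the default 0.5 µm/px it is 10 µm, comfortably
   above the 1–2 µm neurite half-widths and large enough that 7–21 µm
   Lewy bodies lose at most ~40% of their interior intensity, far from
   the threshold. The blur uses a truncated discrete Gaussian (radius
   `4*sigma`) with symmetric boundary reflection.
2. **Otsu thresholding** — 256 equal-width bins over the observed range;
   the threshold is the bin edge maximising between-class variance,
   foreground is *strictly greater*, ties resolve to the smallest
   qualifying edge. A channel that is constant after background
   subtraction (pure monomer background, noise-free) yields an empty mask
   rather than an error; `otsu_threshold()` itself refuses constants
   because the statistic is undefined there.
3. **Monomer exclusion floor** — the C-terminus antibody also labels
   diffuse non-pathological (monomeric) α-Syn, so the Otsu threshold is
   raised to a floor. Default mode `quantile_of_background` uses the
   99.9th percentile of background-subtracted intensities *outside* the
   Otsu foreground; an `absolute` intensity mode is available. The source
   workflow states the intent (exclude monomer) but no value; the
   quantile default is the package's choice and is recorded per image in
   the segmentation log.
4. **Small-object filter** — components below `min_object_px`
   (default 5) are removed. This substitutes an automated rule for the
   original study's manual confirmation of segmentation; removals are
   logged.

Raising the floor can only shrink the mask (monotonicity is
property-tested), and on noise-free reference scenes the per-channel
Jaccard overlap with ground truth exceeds 0.99.

## Epitope area algebra

With per-epitope masks the package computes `total` (union area),
`unique(e) = total − area(union of the others)` and
`overlap = total − Σ unique` — the subtraction forms used in the field's
image-analysis workflows. These equal the per-pixel set definitions
(pixels labelled by exactly one antibody; pixels with coverage ≥ 2), and
both routes are asserted against each other in the tests. The algebra is
generalised to k ≥ 2 channels with "overlap" kept as coverage ≥ 2 (not
coverage = k), matching the subtraction definition. Percentages are
normalised to the total aggregate area; pathology load is the total
aggregate area as a percentage of the region quantified. Per-aggregate
composition applies the same report to one object's footprint.

Whether multi-section studies should average per-section percentages or
pool areas per case is ambiguous in published workflows; `lewyquant`
computes per image and leaves aggregation to the caller (both are one
`aggregate()` away from the per-case table).

## Morphometry

Aggregates are 8-connected components of the union mask. Perimeter uses
the 4-direction Crofton estimator (as in standard toolkits) because naive
edge counting overestimates the perimeter of digitised discs by up to
4/π, destabilising circularity for small objects; circularity is capped
at 1.1 since digitisation can push tiny discs slightly above 1. Aspect
ratio comes from second central moments with the 1/12 pixel-extent
correction (a 1-px-wide line stays finite; a 3×60 bar measures exactly
20). Feret diameter is the maximum pairwise distance over the convex hull
of pixel corners.

Classification rules (no numeric criteria exist in the source
literature; these are declared package defaults, all configurable via
`morphology_rules()`):

| class        | rule                                                   |
|--------------|--------------------------------------------------------|
| punctate     | equivalent diameter < 2.5 µm and aspect < 2            |
| lewy_body    | circularity ≥ 0.6 and aspect ≤ 2                       |
| lewy_neurite | aspect ≥ 3 or elongation (Feret²/area) ≥ 6             |
| unclassified | otherwise                                              |

The elongation clause is a skeleton length/width proxy that catches
strongly curved neurites whose moment aspect ratio is modest. Punctate
lysosomal aggregates are reported as their own class rather than forced
into LB/LN.

## The synthetic-scene simulator

The simulator emulates the morphological and epitope structure described
for human Lewy pathology, and is the ground-truth provider for every
test:

- **Lewy bodies**: discs, 7–21 µm diameter by default (the typical
  intracellular range; 40–55 µm extracellular "ghost" bodies are
  drawable by explicit `aggregate_spec`), uniform N-terminus fill and
  peripheral pS129/C-terminus rings — the classical halo. The ring is the
  outer 25% of the radius; no quantitative core/halo intensity ratio is
  published, so ring width and peak intensities are stated simulator
  defaults, not derived values.
- **Lewy neurites**: constant-curvature arc polylines thickened to 1–2 µm,
  8–25 µm long, optionally club-ended (one inflated tip). An arc rather
  than a literal smoothed random walk keeps the shape fully parameterised
  by orientation + total turn and deterministic from the spec alone.
  Populations are mixed: triple-labelled, N-terminus-exclusive and
  pS129-exclusive neurites all occur.
- **Glial aggregates**: thin (1.2 µm) neuritic threads, N-terminus only.
- **Lysosomal puncta**: 1–2 µm discs, N-terminus only.
- **Monomer background**: constant per-epitope low level,
  C-terminus-dominant (default 12 vs 1 arbitrary units) — the monomer
  pool is what the C-terminus antibody sees in normal tissue.
- **Noise**: additive Gaussian (default sd 2) plus an optional
  signal-dependent term (`poisson_scale * sqrt(I)`); intensities are
  floating point and only quantised to 16 bits on OME-TIFF export.
  Aggregate peaks (≈130–230) sit far above background so that, per the
  design intent, Otsu separates aggregates from monomer in reference
  scenes.

Determinism: a scene's seed fixes output bit-exactly. PK series render
geometry from the scene seed and noise from `seed XOR timepoint-index`,
so timepoints stay co-registered yet carry independent noise, and
timepoint 0 reproduces `render_scene()` exactly.

What a green test does *not* establish: the simulator has no optical PSF,
no 3-D structure, no autofluorescence or neuromelanin, no cell-context
channels, and its backgrounds are spatially flat. Recovery results
therefore validate the *algebra, segmentation logic and statistics*, not
performance on real tissue with uneven illumination or antibody
penetration artefacts.

## Proteinase-K time course

`pk_model` specifies multiplicative retention factors per (epitope,
timepoint) on the cumulative digestion schedule {0, 15, 30, 40, 50, 60}
min (analyses here default to the {0, 15, 30, 60} endpoints). Factors may
exceed 1 — brief digestion unmasks epitopes before degrading them.
Quantities are internally normalised to the pre-treatment value, so t = 0
is exactly 100%.

Measurement mode is a genuine design fork: published area-based
quantification ("thresholded immunolabelling area") and intensity-based
quantification are both defensible, and the source workflow does not say
which was used for the single-aggregate panels. Under a multiplicative
intensity-decay model, thresholded area is a *step function* of the
retention factor (the aggregate stays above threshold until it suddenly
does not), so area cannot recover graded retention; integrated
background-subtracted intensity within the pre-treatment union footprint
tracks it almost unbiasedly. `measure_timepoint()` documents `area` as
its default per the stated workflow, while the pipeline level
(`analysis_config(pk_mode=)`, `run_pk_analysis`) defaults to
`intensity`. The PK cohort simulator applies the N-terminus retention
schedule to the whole measured footprint (all aggregate kinds) for the
same reason: a co-located undigested population would dilute the pooled
estimate; `pk_model()` itself defaults its `affected_kinds` to the
protease-susceptible glial/lysosomal populations.

`fit_retention` reads retention as `normalized_pct/100` and fits
`log(retention) ~ time` by least squares over timepoints strictly beyond
15 min, excluding the unmasking window; a noiseless halving per 30 min
yields `log(2)/30` per minute exactly.

## Statistics

All tests are implemented from the defining formulas (two-sided where
sidedness applies) and checked against brute-force oracles: one-way
ANOVA sums of squares (equal to t² for two groups), Tukey–Kramer q with
adjusted p from a studentized-range CDF computed by 96-node
Gauss–Legendre quadrature of the double integral (agrees with reference
implementations to ~3e-6; documented tolerance 1e-6 at moderate df),
repeated-measures ANOVA with the subject effect removed, Pearson r with
slope/intercept attached (correlation and simple regression are reported
together because users of such cohort plots expect both), and
Shapiro–Wilk W via Royston's coefficient algorithm with his p-value
approximations (exact for n = 3). Normality results are reported
alongside ANOVA rather than gating an automatic nonparametric fallback —
no fallback is specified in the source workflow, so the decision is left
to the analyst.

Calibration is part of the acceptance suite: the null rejection rate of
the ANOVA over 10,000 simulations must sit in 5% ± 1.5 points, and the
repeated-measures test must keep ≤ 10% false positives on all-ones PK
null cohorts (measured ~4%).

## Numerical and degenerate-input choices

- Coordinates are row-major, origin top-left, 1-based in R; masks clip to
  the image; an aggregate entirely outside the image rejects the spec.
- Areas are primary in pixels; µm² = px · (pixel size)² — the squared
  conversion is stated explicitly because the linear-vs-area slip is a
  classic bug.
- Zero total immunolabelling flags percentages as undefined (`NA`) and
  reports load 0; empty masks yield empty object lists, not errors.
- Report CSVs round percentages to 2 decimals; in-memory objects keep
  full precision.
- TIFF support is a minimal in-package baseline codec (uncompressed,
  8/16-bit grayscale, either endianness on read) with OME-XML channel
  names and physical pixel size; this keeps the package free of binary
  dependencies and is cross-validated against an independent external
  reader in the tests.

## Known limitations

- Area-based colocalization only; no intensity-correlation (Manders /
  pixel-Pearson) measures, by design.
- No cell-type context: perinuclear/glial/lysosomal localisation *calls*
  require nuclei and cell-marker channels that are out of scope; the
  simulator kinds stand in as ground truth.
- The LN/LB classification thresholds are package defaults tuned on the
  simulator's shape families; real curvilinear pathology may need
  adjusted `morphology_rules()`.
- PK retention is modelled as spatially uniform multiplicative decay;
  real digestion also erodes aggregates spatially.
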