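# lewyquant

Quantification of multiplex α-synuclein immunofluorescence for Lewy-body
disorders.

Most antibodies against α-synuclein (α-Syn) target its C-terminus and can
miss aggregate populations that only expose other epitopes. When a tissue
section is co-labelled with a panel covering the N-terminus (residues
34–45), phosphorylated serine 129 (pS129), and the C-terminus (residues
118–123), the interesting quantities are how much of the total aggregate
immunolabelling is *epitope-specific* — detected by exactly one antibody —
versus shared, how pathology is partitioned between Lewy-body (LB) and
Lewy-neurite (LN) morphologies, and how each epitope withstands
time-dependent proteinase-K (PK) digestion. `lewyquant` implements that
whole analysis as a tested, reusable pipeline, together with a synthetic
multiplex-scene simulator that provides exact ground truth for every stage
(real post-mortem images from such studies are not publicly deposited).

## The core quantities

For per-epitope binary masks \(M_1, \dots, M_k\) obtained by Gaussian-blur
background subtraction, per-channel Otsu thresholding, and a monomer
exclusion floor:

- **total area** \(T = |\bigcup_i M_i|\)
- **epitope-unique area** \(U_e = T - |\bigcup_{i \ne e} M_i|\)
  (equivalently the pixels labelled by `e` and no other antibody)
- **overlap area** \(V = T - \sum_e U_e\) (pixels with coverage ≥ 2)
- **pathology load** \(= 100\,T / |\text{region}|\)

so \(T = \sum_e U_e + V\) holds exactly in pixel counts. Aggregates are
8-connected components of the union mask, with circularity \(4\pi A/P^2\)
(Crofton perimeter), moment aspect ratio, equivalent-circle and Feret
diameters; LB/LN/punctate classes follow explicit, configurable rules. PK
series are internally normalised to the pre-treatment value
(\(100 \cdot q_t/q_0\), values above 100 = epitope unmasking) and retention
is estimated per timepoint with an exponential decay rate over the
post-unmasking window. The statistics layer (one-way ANOVA, Tukey HSD via
a numerically integrated studentized-range distribution, repeated-measures
ANOVA, Pearson correlation with regression, Shapiro–Wilk) is implemented
from the defining formulas with brute-force oracles in the tests.

## Worked example

```r
library(lewyquant)

spec  <- random_scene_spec(seed = 42)        # mixed LB/LN/punctate/glial scene
scene <- render_scene(spec)                  # image + exact ground truth
masks <- segment_image(scene$image, analysis_config())
epitope_report(masks, pixel_size_um = scene$image$pixel_size_um)
```

```
<epitope_area_report> total 4195 px (1049 um2), load 6.4%
  unique Nterm   51.16%
  unique pS129    4.98%
  unique Cterm    0.00%
  overlap        43.86%
```

Half the simulated pathology is detected *only* by the N-terminus antibody
(the scene contains N-exclusive neurites plus glial and lysosomal puncta),
none is C-terminus-exclusive, and 6.4% of the region is covered by
aggregates. The exact ground-truth oracle for the same scene reports
51.28 / 4.97 / 0.00 / 43.75 — the pipeline recovers the composition to a
fraction of a percentage point. Morphology on the same union mask:

```r
um   <- Reduce(`|`, lapply(masks, function(m) m$mask))
objs <- lapply(label_aggregates(um, 0.5), classify_morphology)
morphology_distribution(objs)
#>   lewy_body     82.00%  (n=3)
#>   lewy_neurite  17.43%  (n=8)
#>   punctate       0.57%  (n=2)
```

A PK digestion cohort (8 subjects, cumulative 0/15/30/60 min, N-terminus
retention 1 / 1.1 / 0.7 / 0.45, other epitopes spared):

```r
cohort <- simulate_pk_cohort(n_subjects = 8, seed = 42)
res    <- run_pk_analysis(cohort, analysis_config())
aggregate(normalized_pct ~ epitope + timepoint_min, res$series, mean)
#> Nterm: 100 -> 110.1 -> 69.9 -> 44.9   (pS129, Cterm stay within 0.2 of 100)
```

The 15-min unmasking (signal above pre-treatment) and the graded
N-terminus digestion are recovered to ~0.1 of a percentage point, and the
repeated-measures ANOVA flags the N-terminus time effect (p < 1e-50)
while leaving the spared epitopes non-significant.

A command-line wrapper with `simulate`, `quantify`, `pk` and `all`
subcommands is installed at `inst/cli/lewyquant.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","lewyquant.R",package="lewyquant"))') simulate --out out/ --seed 1`).

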