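# bondmap

Statistical pipeline for brain-wide immediate-early-gene (c-Fos) activity
mapping in pair-bonding studies of prairie voles. Whole-brain imaging of
mate pairs and same-sex sibling controls across a cohabitation time course
(0, 2.5, 6, 22 h) yields per-animal c-Fos+ cell counts for hundreds of
atlas regions; `bondmap` provides the analysis chain that turns those
counts, the behavioral record, and a structural connectome into a
characterized bonding network — together with a synthetic-data generator
that emulates the study design with planted effects, so every stage is
testable end to end.

## The statistics at the core

**Region screen.** For each region (or voxel) with counts
*Y<sub>i</sub>*, two nested quasi-Poisson GLMs (log link, dispersion φ
estimated by Pearson χ²/df) are compared:

- null: sex *S* + timepoint polynomial (*T*, *T*²) + block *B*
- bonding: the same + partner type *P* + *P*×*S* + *P*×*T* + *P*×*T*²

with the quasi-likelihood ANOVA statistic
*F* = (ΔDeviance/Δdf)/φ. Because counts, dispersion and design are far
from textbook assumptions, *F* is calibrated against a Monte Carlo
permutation null: mate/sibling labels are re-assigned at the pair level
within timepoint × block exchangeability strata, the whole screen is
re-run per shuffle, and *p* = (1 + #{F<sub>perm</sub> ≥
F<sub>obs</sub>})/(1 + N) — so 10,000 shuffles give a floor of p = 0.0001.
False discovery rate is controlled by Benjamini–Hochberg (q < 0.1 by
convention; Storey's q-value is available).

**Network characterization.** Significant regions are reduced to an
anatomically exclusive set over the atlas hierarchy (an ancestor and its
descendant never co-occur; the higher-*F*, more localized region wins),
then grouped by Ward (D2) clustering of z-scored counts, embedded by
non-metric MDS, and validated against a structural connectome with a
row-shuffling permutation test of mean within-cluster connection density.

**Brain–behavior coupling.** Canonical correlation analysis links region
counts to behavioral measures (Wilks' Λ = Π(1−ρ²) with Rao's F for factor
significance), and within-pair coordination is quantified by female–male
Pearson correlations per region — plain, and partial, controlling a shared
behavioral driver such as ejaculation count.

## Worked example

```r
library(bondmap)

design <- simulate_design(12)                          # 192 animals, 96 F / 96 M
design <- apply_exclusions(design, study_exclusions(design))
sum(design$ieg_included)                               # 189

units <- sprintf("R%03d", 1:40)
cfg <- sim_config(effect_units = units[1:5], effect_size = 0.7,
                  coupling_units = units[1:5], gamma = 0.3, dispersion = 2)
counts <- simulate_counts(design, units, cfg, seed = 1)

screen <- fos_screen(counts, design, n_perm = 500, seed = 2)
summary(screen, n = 5)
#> Permutation-calibrated GLM screen (bonding contrast)
#>   40 units, 189 animals, 500 permutations (pair scheme)
#>   6 units significant at q < 0.1 (BH)
#>
#> Top units by F:
#>  unit     F df1 df2        p       q significant direction
#>  R002 66.62   4 176 0.001996 0.01331        TRUE         1
#>  R005 56.36   4 176 0.001996 0.01331        TRUE         1
#>  R001 54.76   4 176 0.001996 0.01331        TRUE         1
#>  R003 52.87   4 176 0.001996 0.01331        TRUE         1
#>  R004 50.89   4 176 0.001996 0.01331        TRUE         1
```

All five planted regions hit the permutation floor p = 1/501 ≈ 0.002 and
survive FDR at q < 0.1; `direction = 1` marks higher counts in mates. The
hierarchy-aware reduction then removes anatomically overlapping survivors:

```r
atlas <- simulate_atlas(40, depth = 3, seed = 3)
sig   <- screen$table[screen$table$significant, ]
sel   <- select_exclusive(atlas, sig$unit, sig$F)
sum(sel$chosen)
#> 6
```

`run_pipeline(pipeline_config(seed = 1), outdir = "out")` executes the full
chain — simulation, screen, exclusive selection, clustering/MDS/time
courses, connectome test, CCA, pair coordination, behavior tests, outlier
screen — and writes every stage product (CSV/JSON) plus a reproducibility
manifest.

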