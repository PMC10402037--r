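---
title: "Methods: permutation-calibrated mapping of pair-bonding networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-calibrated mapping of pair-bonding networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondmap)
```

`bondmap` implements the statistical side of a brain-wide c-Fos mapping
study of pair-bond formation: mate pairs versus same-sex sibling controls,
observed at four cohabitation timepoints, with per-animal c-Fos+ cell
counts across a hierarchical brain atlas. This vignette is the package's
account of its models and the design choices behind them. It states no
empirical result that the test suite does not itself compute.

## The screening model

For each region, counts are modeled by a quasi-Poisson GLM (log link;
variance φ·mean, φ estimated as Pearson χ²/df). Two nested models are
compared:

* **null** — sex + orthogonal linear and quadratic polynomials of the
  ordinal timepoint codes 1–4 + block;
* **bonding** — the null terms plus partner type and its interactions with
  sex and with both time polynomials.

The quadratic time term matters because bonding-related induction is
expected to peak at the middle timepoints (2.5–6 h) and fade by 22 h: a
hump, not a trend. The sex-difference contrast compares the bonding model
to the same model without the partner×sex term. An intercept is always
included even though it is conventional to write the model without one;
count GLMs without an intercept are degenerate, and the model comparison
is unaffected because both models contain it.

The quasi-likelihood ANOVA statistic F = (ΔD/Δdf)/φ_full has no reliable
reference distribution at these sample sizes and dispersions, so inference
is by permutation (below), with the F statistic serving as the ranking and
test statistic only.

### Degenerate inputs and numerics

IRLS runs to a relative deviance change below 1e-8 (at most 100
iterations). An all-zero region is returned as a flagged zero-deviance fit
rather than an error, so voxel-scale screens keep running; its F is 0.
Negative F values, possible through dispersion noise in nearly saturated
comparisons, are clipped at zero. Rank-deficient design columns are
tolerated (R's pivoting IRLS drops them) and the rank difference, not the
column-count difference, sets the numerator df.

## Permutation scheme

Partner-type labels are shuffled at the pair level: each pair keeps its
two animals, their sexes, its timepoint and its block; only the
mate/sibling label moves. Shuffling is restricted to timepoint × block
exchangeability strata. One shuffle produces one relabeled design applied
to all regions (permutation indices are shared across regions, as when the
whole screen is re-run on relabeled data), and the p-value uses the
add-one estimator (1 + #{F_perm ≥ F_obs})/(1 + N), which is never zero and
floors at 0.0001 for N = 10,000.

Two aspects deserve the emphasis:

* **Why stratify on block as well as timepoint.** Block is a batch factor;
  there is no reason its effects should be linear in the block index. Any
  relabeling that moves labels across blocks lets residual (non-linear)
  block variation leak into the partner terms, and the leak cannot cancel:
  sex composition is structurally tied to partner type (mate pairs are
  always F+M, sibling pairs same-sex), so no relabeling preserves the
  partner×sex column's balance over blocks. Within-stratum shuffling keeps
  every relabeled design balanced over both nuisance factors.
* **Why the screen defaults to factor block coding.** For the same reason:
  a single linear block coefficient leaves categorical batch effects
  partially unabsorbed, and the unabsorbed part is not exchangeable under
  relabeling of partner×sex (above), which mis-calibrates the permutation
  null in a direction that depends on the realized batch draw. Absorbing
  block fully (5 dummies for 6 blocks, a cheap 4 extra df at n = 189)
  makes the within-stratum permutation test exact. The single-coefficient
  form of the published model is available via `block_factor = FALSE` in
  `fos_screen()` and is the default in `design_matrix()`.

An unrestricted response-row shuffle (`scheme = "row"`) is provided for
comparison; it tests the stronger null of no design structure at all.

FDR control is Benjamini–Hochberg by default, at q < 0.1 for the brain
screen and q < 0.05 for behavioral tests (both configurable). Storey's
q-value (BH scaled by a π₀ estimate at λ = 0.5) is available, since count
screens with many true effects can afford the extra power.

## Exclusive region selection

The atlas is a tree; a parent and its substructure both reaching
significance describe one signal twice. Significant regions are visited in
decreasing F order and accepted only if unrelated (neither ancestor nor
descendant) to every accepted region. Since a focal substructure usually
carries a sharper signal than the composite parent containing it, this
retains localized regions over large ones. Ties on F prefer the deeper
node — the more localized claim — and then alphabetical order, so the
output is deterministic. "Overlap" means hierarchy ancestry only; sibling
regions never overlap in a structure tree, and spatial partial overlaps
outside the hierarchy are out of scope.

## Clustering, MDS, time courses, connectome test

Distances between regions are Euclidean over per-animal counts z-scored
within region, so high-count structures do not dominate the geometry
(raw-count distances remain available by skipping `zscore_units()`).
Clustering is Ward D2; the number of clusters is a parameter (default 8,
matching the original anatomical judgment) — no automatic k selection is
attempted. The MDS is Kruskal's non-metric variant, initialized from the
classical (Torgerson) solution, reporting stress-1 on the 0–1 scale;
because the initialization is deterministic, so is the embedding. Zero
dissimilarities between distinct regions (exactly identical profiles) are
nudged to half the smallest positive dissimilarity, as isotonic MDS
requires strictly positive input.

Cluster time courses z-score each cluster's per-animal total count and
average within partner × sex × timepoint cells.

For connectome validation, regions absent from the connectivity matrix
(finer than its parcellation) are represented by their nearest ancestor
present in it; unresolvable regions are dropped with a report. Mean
connection density of a cluster averages all directed off-diagonal entries
among its member regions; the overall statistic is the unweighted mean
across clusters (cluster size is a property of the parcellation, not of
connection strength, so weighting by it would conflate the two). The
permutation test shuffles whole rows (origin regions) of the matrix,
excludes diagonal cells after shuffling, and uses the same add-one
p-value; the test accepts an explicit cluster subset so either all
clusters or only the major ones can be tested.

## Canonical correlation

Both variable sets are z-scored (required for comparable weights across
units of measure) and the solution is the SVD of the whitened
cross-covariance. Dimensions beyond a set's rank are dropped with a
warning; an optional ridge on the within-set correlations supports small
synthetic runs, with no regularization by default at study dimensions
(n = 189, ~68 regions, ~10 behaviors). Each factor is oriented so its
largest-magnitude behavior loading is positive, making score signs stable
across runs. Sequential factor significance uses Wilks' Λ_k = Π_{i≥k}
(1−ρᵢ²) with Rao's F approximation. Animals observed at the 0 h timepoint
have no interaction behaviors; their behavioral entries are zeros, not
missing — they were observed, and excluding them would delete the baseline
group.

## Within-pair coordination

Per-region female–male correlations are computed across mate pairs
retained in a timepoint window: "during bond formation" means timepoints
2–3 (2.5 and 6 h) pooled, "after bonding" timepoint 4, both configurable.
Complete-case handling is per analysis: a pair is dropped from a given
correlation only if a member is missing there, which is why degrees of
freedom can differ across analyses of the same data. The partial
correlation r_xy·z = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²)) with df =
n−3 controls a pair-level behavioral driver (ejaculation count by
default). Both a per-region mode and a full cross-region mode (female's
region a vs male's region b) are provided, with an edge list of entries
exceeding a threshold (default r > 0.75). Sibling-pair coordination uses
the same machinery with members ordered by animal id (Pearson correlation
is order-invariant).

## The synthetic-data generator

The generator reproduces the study design: `n_pairs_per_cell` mate pairs
and as many sibling pairs per timepoint (default 12, giving 192 animals,
96 of each sex), sibling pairs split evenly FF/MM (an odd count alternates
the extra pair's sex across timepoints), blocks 1–6 cycling within partner
type so every block mixes both pair types. The layout is fully
deterministic given the pair count. `study_exclusions()` reproduces the
published subject bookkeeping (three IEG exclusions, one behavioral camera
failure for a pair), leaving 189 of 192 animals for count analyses and 190
for behavior.

Counts are negative binomial — a gamma–Poisson mixture with variance φ·μ,
exactly the mean–variance law the quasi-Poisson screen assumes — because
quasi-likelihood itself has no sampling distribution to simulate from.
The log-scale linear predictor holds a baseline (default log 100 cells), a
small sex effect (0.05), mild time trends, i.i.d. normal block effects
(sd 0.1; the study adjusted for block but never quantified it), and on
designated regions a partner-type effect (default 0.7 on the log scale —
chosen for testability, as no region-scale effect sizes are published).

A pair-level latent z ~ log-normal(0, 1) ties the data streams together:
ejaculation counts are Poisson(λ·z) at timepoints 2–3 (none at 0 h, 5% of
the rate by 22 h — the hump-shaped mating time course), and coupled
regions' means are scaled by z^γ, i.e. log-linearly in the standard-normal
log-latent, like every other term of the log-link model. Two properties
follow: coupled regions of the two pair members correlate (increasingly in
γ), and because a coupled region's conditional mean is *linear* in the
activity-scale latent z^γ, partialling that latent out removes the
coordination — the generative twin of the observation that controlling
ejaculation rate abolishes pair correlations. A latent entering the rate
exponentially instead would leave residual rank dependence that a linear
partial correlation cannot remove, which is a caution worth remembering
when interpreting partial correlations on real data.

Two realism limits matter when reading test results. First, shared block
(and time-course) effects themselves induce within-pair correlation on
*every* region — pair members share a batch — so experiments that isolate
the latent-coupling mechanism switch those channels off (`block_sd = 0`,
flat time trend); on real data, within-pair correlations should likewise
be read net of batch structure. Second, the generator plants block-dense
connectivity and clean region effects; it does not emulate registration
error, segmentation noise, spatial autocorrelation between neighboring
regions, or atlas mis-parcellation, so passing tests certify the
statistics, not the imaging pipeline upstream.

## Behavioral tests and outlier screen

Welch t-tests compare mates to siblings; paired t-tests compare female to
male mates within dyads. Dyadic measures (huddling, vocalizations, mating
counts — identical within a pair by construction) are tested at one value
per dyad, individual measures at one per animal, which reproduces the
study's mixed n's (e.g. 94 + 96 animals but 47 + 48 dyads once a pair is
excluded). All contrasts in a batch share one FDR correction at q < 0.05.

The whole-brain count quality screen is a generalized extreme studentized
deviate (Rosner) procedure with defaults k = 5 candidates at α = 0.05 (the
EnvStats-style convention; the study reports only that two samples were
flagged): candidates are removed most-extreme-first, R_i = max|x − x̄|/s
is compared with the t-based critical value λ_i, and the flagged set is
the prefix up to the last exceedance, per the ESD rule.

## Problem sizes and determinism

Default verification runs use 192 synthetic animals, hundreds of regions
and 150–500 permutations; study-grade runs use 10,000 permutations
(`n_perm` everywhere). Every random stage takes an explicit seed and each
pipeline stage derives its own seed from the master, so any stage can be
re-run standalone, bit-identically, from the previous stage's files; the
pipeline manifest records config and output checksums.

## Known limitations

* The permutation screen's validity leans on the timepoint × block strata
  being the right exchangeability structure; designs with pair-level
  confounders outside (sex composition aside, which is handled by
  absorbing block) would need additional stratification.
* Voxel mode is just a wide count matrix: no spatial smoothing or
  cluster-extent correction is applied.
* No mixed-model or Bayesian alternatives; no sparse/penalized CCA; no
  graph statistics beyond the thresholded coordination edge list.
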