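---
title: "Representational similarity analysis of grasp planning and execution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational similarity analysis of grasp planning and execution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasprsa)
```

# The scientific problem

When people grasp an object they must combine several visuomotor
computations: orienting the hand (the *grasp axis*), opening the fingers to
the right width (the *grasp size* or grip aperture), and anticipating how
heavy the object is (*object mass*, which determines grip and lift forces).
`grasprsa` implements a representational similarity analysis (RSA) pipeline
for a factorial grasping experiment designed to tease these three factors
apart: nine conditions (three L-shaped objects, one light wooden and two
heavy brass-loaded, times three pre-cued grasps), each performed during a
delayed *planning* phase and a subsequent *execution* phase, with
multivoxel activity patterns recorded in nine cortical regions of interest
spanning early visual cortex (V1), the ventral stream (LOC, pFS, PPA), the
dorsal stream (SPOC, aIPS, PMv, PMd) and primary sensorimotor cortex
(M1/S1).

The pipeline covers:

1. the factorial **design** and its three binary model RDMs, with an
   exhaustive search certifying their mutual orthogonality, plus
   constrained trial sequencing;
2. a **synthetic-data generator** that plants known representational
   structure into voxel patterns and comfort ratings, so that every stage
   can be validated against ground truth without the study's raw data;
3. the **RDM core**: correlation-distance RDMs, fixed upper-triangle
   vectorization, RDM comparison and averaging;
4. **first-order RSA**: per-subject model correlations, noise ceilings,
   one-tailed Wilcoxon signed-rank group tests, Benjamini–Hochberg FDR;
5. **second-order RSA**: region-by-region correlation of average RDMs
   within and across phases, Bonferroni thresholding, hierarchical
   clustering and classical MDS;
6. the **comfort analysis**: paired factor contrasts on 1–10 ratings,
   absolute-difference comfort RDMs, and comfort-to-model /
   comfort-to-neural correlations.

# The design and its model RDMs

Each condition carries one level of each factor: axis (45° clockwise vs
counterclockwise about vertical), size (2.5 cm vs 7.5 cm aperture) and mass
(67 g wood vs 557 g brass-loaded; mass is fixed by object, giving a 3
light / 6 heavy split). The model RDM of a factor is the 9 × 9 binary
matrix with 1 where two conditions differ on that factor. For the analysis
to attribute variance unambiguously, the three model RDMs must be
*uncorrelated* over their 36 upper-triangle entries.

The per-condition axis/size level chart of the original experiment is
published only as a figure, so the package reconstructs an assignment from
its stated defining property. `search_orthogonal_assignment()` enumerates
all 2^9 × 2^9 joint binary assignments (mass fixed) and reports those whose
three pairwise Pearson correlations are zero to a configurable tolerance
(default 1e-12; exact zeros exist — 2,960 of the 262,144 joint
assignments). `build_design()` ships the first exact-zero assignment in the
deterministic enumeration order (condition 1 is the least-significant bit
of the assignment key; axis key 9, size key 56). Any exact-zero assignment
carries the same inferential guarantees; the shipped one may differ from
the original chart by relabeling.

```{r design}
design <- build_design()
check_orthogonality(model_rdms(design))
```

Two structural facts about this design are worth stating plainly:

* **Exact RDM orthogonality forces unbalanced level splits.** The
  exhaustive search proves that no exact-zero assignment has factor-level
  indicators that are pairwise uncorrelated: with mass split 3/6, the
  axis and size *levels* are necessarily somewhat confounded with mass
  (the shipped assignment has a 2/7 axis split and a 3/6 size split).
  RDM-level analyses are immune — the model RDMs are exactly orthogonal —
  but *level-mean contrasts* (such as the comfort t tests) can inherit
  leakage from a strong effect of another factor. This is a property of
  any such design, not of the implementation.
* **Mixture symmetry holds only for equal splits.** The planted geometry
  `w_a·A + w_s·S` correlates equally with its two components only when
  both factors split the conditions equally (as size and mass do here,
  3/6), because a binary RDM's variance depends on its split.

## Trial sequencing

`generate_trial_sequence()` builds the 4-run session (each condition
exactly twice per run, 72 trials). The condition order is pseudorandomized
by a seeded greedy first-order counterbalancing: at each step the candidate
whose transition from the previous condition has been used least is chosen,
ties broken at random. The original report cites sequence-optimization
literature without stating an algorithm; greedy transition balancing is a
standard, transparent choice, and plain shuffling is available via
`method = "shuffle"`. Planning delays are drawn uniformly from
{6, 8, 10, 12} s, execution is fixed at 7 s, and the intertrial interval is
drawn uniformly from the integer choices {10, 11, 12} s (the experiment
states a 10–12 s range without a distribution). Every onset-to-onset
spacing therefore lies in [23, 31] s by construction.

# The synthetic-data generator

`generate_patterns()` emulates the quantity the analysis actually consumes:
condition-wise, ROI-wise voxel beta patterns. For each region × phase it
draws one unit-norm prototype pattern per factor level; a condition's mean
pattern is the weighted sum of its levels' prototypes, with non-negative
weights per (region, phase, factor) from the `planted_weights` table. Each
subject perturbs every prototype with Gaussian noise (`subject_sd`,
between-subject geometry variation), and independent Gaussian measurement
noise (`voxel_sd`) is added per condition and voxel. Under this
construction the expected neural RDM correlates positively with each
planted factor's model RDM, increasingly so in its weight — the basis of
the parameter-recovery tests.

Defaults are the study conditions where stated — 21 subjects, the nine
regions above, two phases, and 65 voxels per region (a 15-mm-diameter
sphere at 3-mm isotropic resolution is ≈ 1767 mm³ / 27 mm³ ≈ 65 voxels) —
and stated assumptions where not: the per-ROI signal-to-noise ratio is
unpublished, so the default noise levels (`subject_sd = 0.3`,
`voxel_sd = 1.2`, against unit-norm prototypes whose per-voxel scale is
≈ 1/√65 ≈ 0.12) were chosen to place per-subject model correlations near
0.25 and noise ceilings near [0.2, 0.35] at n = 21 — the magnitude range
typical of published ROI-level RSA — while keeping planted effects
detectable. The default `planted_weights` table encodes, with unit weights,
the qualitative significance map reported for the real data (axis in
dorsal/motor regions during planning; size in ventral then premotor
regions; mass only during execution).

What the generator deliberately does **not** model: BOLD time courses, HRF
convolution, GLM estimation, head motion, spatial autocorrelation between
voxels, or non-Gaussian beta distributions. RSA consumes only pattern
correlations, which are invariant to per-condition affine rescaling (a
tested property), so Gaussian noise at the beta level is an adequate test
bed for the *pipeline*; passing tests certify the statistical machinery and
its calibration, not biological realism of any particular simulated
dataset.

Comfort ratings are simulated as `baseline − Σ_f weight_f · costly(f) +
noise`, clipped to [1, 10]; the default weights (mass 3, axis 0.5, size 0,
noise SD 0.75, baseline 8) emulate the reported rating structure: a large
mass effect, a weak axis effect, no size effect. Ratings are real-valued by
default (the original granularity beyond the 1–10 scale is unstated);
`integer_ratings = TRUE` rounds them.

# The RDM core

Dissimilarity is `1 − r` (Pearson) between condition patterns, so entries
lie in [0, 2] and the diagonal is zero. All RDM-to-RDM comparisons use the
upper triangle only, in a single pinned row-major pair order
((1,2), (1,3), …, (8,9)) shared by every module — vectorization order is
the kind of silent convention that corrupts second-order analyses when two
code paths disagree, so it is centralized in `pair_index()` and tested.
Constant vectors raise errors rather than propagating `NaN`.

Whether the original RDM-to-RDM correlations were Pearson or Spearman is
unstated; Pearson is the default everywhere and Spearman a uniform option
(`method = "spearman"`). Group summaries average raw correlations (matching
the stated noise-ceiling definition, "the average correlation"); a Fisher-z
option exists in `run_first_order()`. Inputs are treated as
already-normalized betas; optional per-voxel z-scoring across conditions
(`zscore_voxels = TRUE`) is off by default.

# First-order inference

For each region × phase, each subject's neural RDM is correlated with each
model RDM; the per-subject correlations are tested against zero with a
one-tailed Wilcoxon signed-rank test. The implementation is exact wherever
tractable: full 2^n sign-pattern enumeration for small samples (n ≤ 14,
valid under ties), the closed-form signed-rank distribution for untied
samples up to n = 25, and the tie- and continuity-corrected normal
approximation beyond. Zeros are dropped by default (classic Wilcoxon);
`zero_method = "pratt"` keeps them in the ranking. The noise ceiling
follows the standard two-bound recipe: the upper bound averages each
subject's correlation with the grand-mean RDM, the lower bound with the
leave-one-out mean.

FDR correction uses Benjamini–Hochberg. The original report does not state
the family over which correction was applied; the default family is each
model × phase across the nine regions (matching the per-panel presentation
of the results figures), with `per_phase` and `global` as options — on null
data all three control the error rate; on structured data the family choice
trades power against stringency across panels.

# Second-order inference

Group-average RDMs per region are correlated between regions within each
phase (36 unique pairs) and across phases (the full 9 × 9 planning ×
execution matrix, 81 tests, diagonal self-pairs included), Bonferroni
thresholded at α/m. Two p-value routes are provided:

* **parametric** (default): the t transform with df = 34. The 36 RDM
  entries are not independent (entries sharing a condition covary), so
  this is approximate;
* **permutation**: condition labels of one RDM are permuted (default
  10,000, seeded), which respects the entry dependence and is the
  statistically safer route. Direct calibration on independent random RDMs
  shows the permutation test holds its level (≈ 0.04 rejection at nominal
  0.05), and with valid p-values the Bonferroni bound is inherited by
  construction; the null-calibration checks therefore use this mode.

Within-phase structure is summarized by agglomerative clustering on
distance `1 − r` (average linkage by default; the original linkage is
unstated, single/complete are options) with regions pre-sorted
alphabetically so merge order cannot depend on input order, and by
classical (Torgerson) MDS — chosen over stress-minimizing MDS for exact
reproducibility — with negative eigenvalues clipped, coordinates centered,
and a deterministic sign convention (the largest-magnitude coordinate on
each axis is positive).

# Comfort analysis

Per factor, each subject's ratings are averaged within level and the level
difference tested with a two-tailed paired t test (two-tailed because a
null-ish effect is a meaningful outcome here). The comfort RDM is the
matrix of absolute rating differences — "difference between ratings" must
be read as a dissimilarity, hence symmetric and non-negative; a signed
variant would not be an RDM. Comfort-to-model and comfort-to-neural
inference mirrors the first-order machinery (per-subject correlations,
one-tailed Wilcoxon, FDR across regions within phase). When every
subject's comfort RDM is *exactly* orthogonal to a model the signed-rank
test is undefined and that model's row reports `NA` rather than aborting
the analysis. The t statistics reported for the real ratings (e.g.
t(20) = 8.1 for mass) depend on the deposited data and are not recomputed
here; the synthetic defaults reproduce their qualitative pattern.

# Numerical and degenerate-input policy

* Constant pattern or RDM vectors are explicit errors naming the offending
  condition or region — never silent `NaN`.
* RDM symmetry is enforced to 1e-12 (1e-8 for computed correlation
  distances, where floating-point asymmetry of `cor()` is larger).
* A single-subject pattern set still produces first-order results, with
  ceilings marked unavailable (`NA`).
* All randomness flows through explicit seeds (`withr::with_seed`), so
  identical configurations give byte-identical outputs end to end.

# Problem sizes used in the shipped checks

The test-suite and `scripts/acceptance.R` simulations use the study-sized
configuration (21 subjects × 65 voxels) for parameter recovery (20 seeds ×
weights {0, 0.25, 0.5, 1}), 500 null analyses at 30 voxels for Wilcoxon
calibration, 200 datasets for noise-ceiling ordering, and 100 null datasets
× 5,000 permutations for cross-phase false-positive calibration. These
sizes give Monte-Carlo standard errors comfortably inside the asserted
bands while keeping a full run in a few minutes on one CPU.

# Known limitations

* The reconstructed axis/size assignment is relabeling-equivalent to the
  original, not pixel-identical to its figure.
* The generator's noise model is Gaussian and spatially unstructured;
  quantities that depend on voxel covariance structure (e.g. multivariate
  noise normalization, which the pipeline deliberately does not implement)
  cannot be studied with it.
* The parametric second-order p-values treat 36 dependent entries as 34
  degrees of freedom; use the permutation mode when calibration matters.
* Headline statistics of the original dataset (specific bar heights,
  significance maps, comfort t values) require the deposited data; the
  package reproduces the *procedures* and validates them on planted
  ground truth.
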