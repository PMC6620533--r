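---
title: "Multimodal MRI fusion classification with personalized diagnostic maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal MRI fusion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuse)
```

## The problem

Autism spectrum disorder (ASD) is diagnosed behaviourally — most often
with the Autism Diagnostic Observation Schedule (ADOS) — yet both
cortical anatomy and resting-state functional connectivity carry
diagnostic signal. `neurofuse` implements a two-stage classification
pipeline that consumes *feature-level* MRI derivatives on the 68-region
Desikan–Killiany (DK) parcellation (34 cortical labels per hemisphere)
and produces three things:

1. a **global diagnosis** (ASD vs typically developed, TD) per subject,
   from structural MRI (sMRI), resting-state functional MRI (fMRI), and
   their fusion;
2. a **personalized map**: per subject, the maximum autism-class
   probability each cortical area attains across all of its pairwise
   features — a per-area view of where the classifier sees atypicality;
3. an **ADOS severity screen**: which pairwise features correlate with
   the ADOS total score, and which areas participate in many such
   features.

Upstream image processing (surface reconstruction, parcellation, BOLD
preprocessing) is deliberately out of scope: the package starts from
region-level feature tables and region time courses.

## Feature construction

### Structural: the pairwise delta tensor

Eight morphometric features are used per region: surface area $A$
(mm²), volume $V$ (mm³), mean thickness $\bar{T}$ and its standard
deviation $T_{sd}$ (mm), and four curvature summaries derived from the
principal curvatures $k_1, k_2$ at each surface vertex:

$$\mathrm{MCI} = \tfrac{k_1 + k_2}{2}, \quad K = k_1 k_2, \quad
\mathrm{ICI} = \max(K, 0), \quad
\mathrm{FI} = |k_1|\,(|k_1| - |k_2|),$$

averaged (unweighted by default) over the region's vertices. For the
folding index the curvatures are first ordered by magnitude
($|k_1| \ge |k_2|$), which makes $\mathrm{FI} \ge 0$; this matches the
convention of the standard surface-analysis tools that produce these
features in practice. When region-level tables are supplied directly —
the common case — the vertex-level operations are bypassed; they exist
so the formulas are covered and testable.

Raw region values are confounded by subject-level factors (head size,
age, global thickness). Instead of the raw values, each subject is
represented by a signed pairwise-difference tensor,

$$\Delta_{i,j,f} = x_{i,f} - x_{j,f},$$

a $68 \times 68 \times 8$ array that is antisymmetric in $(i, j)$ with
a zero diagonal. Any constant added to a feature across all regions —
precisely the signature of a global confound — cancels exactly; this
is tested as a package invariant. The delta is kept *signed* and both
triangles are carried in the tensor, but the classification feature
universe uses only the strict upper triangle ($i < j$): the lower
triangle duplicates the information up to sign and the diagonal is
constant. That gives $68 \cdot 67 / 2 \cdot 8 = 18\,224$ structural
features.

### Functional: the connectivity matrix

Each region's mean BOLD time course (averaged over the voxels carrying
its atlas label; exact label equality, no partial-volume weighting) is
correlated with every other region's:

$$F_{i,j} = \rho\!\left(x_i(t),\, x_j(t)\right),$$

a symmetric $68 \times 68$ Pearson matrix with unit diagonal. The
strict upper triangle gives $2\,278$ functional features. A region
with a constant time course has no defined correlation; its entries
are set to 0 with a warning rather than aborting a cohort run — a
documented convention, chosen so one degenerate region cannot sink a
batch analysis.

## Two-stage classification

### Stage 1: one local KNN per feature

Every pairwise feature gets its own $k$-nearest-neighbour classifier
($k = 7$, absolute distance on the scalar value). Each feature's
cross-validated accuracy and each subject's out-of-fold autism
probability (the ASD fraction among the $k$ nearest training
neighbours, a multiple of $1/k$) are recorded, and features are ranked
by accuracy.

Design choices worth making explicit:

* **Out-of-fold local estimates.** The local accuracies and
  probabilities are computed under the same stratified fourfold
  assignment used by the global stage, shared by every feature and
  both modalities. Resubstitution (training-set) estimates are
  available via `resubstitution = TRUE` but are optimistic and not the
  default.
* **Determinism.** Distance ties are broken by a seeded shuffle of the
  subject order; exact 0.5 votes resolve to TD, the conservative
  default for a diagnostic tool. Reruns with one seed are
  bit-identical.
* **Tie-breaks in the ranking** are lexicographic in (feature slab,
  $i$, $j$), i.e. by canonical universe position.
* **Affine invariance, not monotone invariance.** KNN on absolute
  distance is invariant under positive affine rescaling of a feature,
  and this is asserted as a property test. It is *not* invariant under
  general monotone maps — a nonlinear order-preserving map can change
  which $k$ points are nearest — so no such claim is made or tested.
* The per-feature grid (~20k single-feature classifiers × subjects ×
  folds) is the pipeline's hot loop and is implemented in C++; an
  independent R implementation (`knn_local_classifier`) serves as the
  oracle it is tested against.

### Stage 2: ranked-prefix selection and fusion

Per modality, prefixes of the accuracy-ranked feature list are grown
one feature at a time (`incremental_selection`), each prefix evaluated
by stratified fourfold cross-validation of a random forest whose two
hyperparameters — number of trees and maximum depth — are grid-searched
by inner threefold cross-validation on each training split (default
grid: trees ∈ {10, 50, 100, 200}, depth ∈ {2, 4, 8, unbounded}; Gini
impurity). The chosen prefix length is the smallest one attaining the
maximum accuracy; the scan range defaults to 100. The chosen sMRI and
fMRI prefixes are then concatenated and the same protocol evaluates
the fused vector on the subjects that carry both modalities. Metrics
are accuracy, sensitivity (ASD positive), specificity, and AUC from
the *pooled* out-of-fold autism probabilities by trapezoidal ROC —
pooling is more stable than per-fold averaging at cohorts of a couple
of hundred subjects.

**Leakage, and the two modes.** Ranking features on the full cohort
before cross-validating the global classifier lets the feature
selection see the test folds; estimates in this default mode
(`mode = "pooled"`) reproduce the classical protocol of this pipeline
family but are optimistic. `mode = "nested"` additionally reports, for
the chosen prefix lengths, metrics in which the local ranking is
recomputed inside every outer training fold. Honest error estimation
should quote the nested numbers; both are reported so the difference
is visible rather than hidden.

`benchmark_classifiers` applies the identical folds and features to a
radial-kernel SVM, Gaussian naive Bayes, and a single-hidden-layer
feed-forward network (8 units, weight decay 0.01, standardized
inputs), for a like-for-like family comparison. The SVM is scored by
its decision values mapped through a logistic link rather than Platt
probabilities, because the Platt calibration in the underlying library
uses an internal RNG that would break bit-reproducibility.

## Personalized maps

From the stage-1 probability structures, each subject's map is

$$V_f(i) = \max_{j \ne i} P_F(i, j), \qquad
V_s(i) = \max_{j \ne i,\, f} P_S(i, j, f),$$

the highest autism probability any of the area's pairwise features
reached. The maximum runs over all partners $j \ne i$ symmetrically
for both modalities (a one-sided bound for the structural max would
break the symmetry of the underlying probability tensor for no
reason); the diagonal is excluded because $\Delta = 0$ and $\rho = 1$
are constants. Maps are exported as a long CSV and, optionally, a
schematic 68-cell colour grid per subject — a deliberate stand-in for
cortical-surface rendering, which is out of scope.

## ADOS severity screen

Every pairwise feature is correlated (Pearson) with the ADOS total
score over the scored subjects, with the two-sided p-value from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n - 2$ df. The default threshold
$|r| \ge 0.32$ corresponds to $p = 0.01$ at $n = 61$ scored subjects —
the screen's working point. No multiple-testing correction is applied
by default (the screen is a raw-correlation filter whose expected
false-positive rate, about 1.2% of tested features under the null, is
part of its definition); Benjamini–Hochberg adjusted p-values can be
reported alongside with `bh_fdr = TRUE`. Areas are then ranked by how
many significant features they participate in, ties broken by atlas
order.

The cohort demographic tests mirror standard cohort tables: a 2×2
chi-squared test of sex by diagnosis without continuity correction and
a pooled-variance two-sample t-test on age, either from raw data or
reconstructed exactly from per-subgroup (count, mean, SD) summaries.
The reference cohort summaries shipped in `inst/extdata/` reproduce a
pooled age t-statistic of 0.95 through this moment path.

## The synthetic cohort generator

The clinical cohort this pipeline family is designed around is
restricted-access, so the package ships a generator
(`generator_config`, `generate_cohort`) whose defaults emulate its
shape: 72 ASD / 113 TD, 61 ASD subjects with ADOS totals in [1, 24],
7 subjects with unusable fMRI, T = 180 time points (≈ 6 min at
TR = 2 s — the reference acquisition does not pin T exactly, so 180 is
a stated assumption), sex proportions 33M/39F vs 49M/64F, and subgroup
age Gaussians with means 13.07/13.53/13.04/12.81 years and SDs
2.75/2.58/2.68/3.17.

What it plants, and how:

* **Morphometry.** Region baselines are region-specific Gaussians
  shared by both classes (scales chosen to be anatomically plausible:
  areas ~1500–3500 mm², thickness ~2–3.2 mm, etc.); every subject gets
  a global per-feature offset — a head-size-like confound that the
  delta tensor must cancel, and a property test verifies it does.
  ASD subjects receive mean shifts of 1.5 within-region SD at five
  (region, feature-slab) elements spread across both hemispheres and
  five different slabs.
* **Connectivity.** Time courses are multivariate Gaussian draws whose
  correlation target is a fixed low-rank factor structure (three
  factors, loadings scaled to 0.3) plus, for ASD, ±0.4 deltas on five
  planted edges (three hyper-, two hypo-connected). The loading scale
  was set from the spectral constraint: the base matrix's smallest
  eigenvalue (≈ 0.47) must exceed the largest planted perturbation
  (0.4) for the ASD target to stay positive definite, which is
  verified (smallest eigenvalue > 1e−6) at configuration time so
  planted values are exact rather than projected.
* **Severity.** A designed feature–severity correlation (default 0.6)
  couples the ADOS-like score to one standardized delta feature per
  planted morphometric element and to the planted edges:
  $z_{sev} = \rho\,\tilde{s} + \sqrt{1-\rho^2}\,\varepsilon$, mapped
  affinely to integers in [1, 24]. Rounding and clipping attenuate the
  realized correlation slightly.

Everything is a deterministic function of the seed; a separate
`structure_seed` fixes the "anatomy" (baselines, base connectivity) so
different cohorts sample the same underlying population.

**What passing tests on synthetic data do and do not show.** The
generator produces Gaussian features, exactly planted effects,
stationary Gaussian time courses, and noise-free labels. Real cohorts
have heavy-tailed morphometry, site and motion artefacts, autocorrelated
BOLD noise, diagnostic label noise, and correlated (not planted-sparse)
group differences. Green tests therefore demonstrate that the
machinery is correct and well calibrated — that planted signal of a
stated size is recovered and null signal is not — not that any
particular accuracy will transfer to clinical data.

## Problem sizes and numerical choices

The test and acceptance suites run at sizes chosen as the package's
own desk-scale defaults: module tests use cohorts of 20–40 subjects
and T = 30–60; the recovery suite uses 200-subject cohorts (T = 180)
over 20 seeded runs for ranking recovery and 10 for fusion
complementarity, with the prefix scan capped at 8 and a reduced forest
grid, since complementarity is insensitive to the grid. The calibration
checks use 10 000 null features at n = 61 and a 200-subject permuted-
label cohort.

Recovery of a planted element is assessed directly on the feature
ranking: an fMRI element is a single edge, and an sMRI element — a
(region, slab) pair — counts as recovered when any of the 67 pairwise
delta features touching it reaches the top of the list. One structural
caveat matters for interpreting this: an sMRI element's 67 features
share the planted region's draws, so their accuracy estimates are
correlated and a strong element typically occupies several of the
highest ranks at once. A short top-of-the-list window can therefore be
crowded by two or three elements even when all five separate cleanly
from the null features (in these simulations every planted feature
outranks the best null feature, while simultaneous coverage of all
five elements by a 20-feature window occurs in well under half of
runs). Feature-level precision at the top and element separation from
the null are the robust recovery statements; exhaustive coverage of
all planted elements by a fixed short window is not.

Other numerical conventions collected in one place: sample (n−1)
standard deviations throughout; correlation matrices symmetrized by
$(C + C^\top)/2$ to remove floating-point asymmetry before use; ties
in the prefix-accuracy curve resolve to the shortest prefix; ties in
classifier votes resolve to TD; constant features in the severity
screen get $r = 0$ (never significant) rather than NA propagation;
seeds derived from a user seed stay below $2^{31}$.

## Known limitations

* The pooled-mode metrics are optimistic by construction (see above);
  nested mode is the honest estimate and is slower.
* Personalized maps are maxima over ~2 278 (fMRI) or ~18 224 (sMRI)
  out-of-fold probabilities; with $k = 7$ the probability scale is
  coarse (multiples of 1/7) and the maximum statistic is biased upward
  for every subject. Maps should be read comparatively (which areas,
  which subjects), not as calibrated posteriors.
* The severity screen's unadjusted threshold admits ≈ 1.2% of null
  features by design; interpret feature counts, not individual
  features, unless BH adjustment is enabled.
* The generator does not simulate raw 4-D volumes, hemodynamics, or
  preprocessing artefacts; the NIfTI extraction path is tested on
  synthetic arrays only.
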