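---
title: "Coordinate-based meta-analysis with aleMeta: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based meta-analysis with aleMeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aleMeta)
```

## The problem and the model

Functional neuroimaging studies report activation as lists of stereotactic
peak coordinates (foci). A coordinate-based meta-analysis asks whether foci
from many independent experiments converge in space more than expected if
the experiments were spatially unrelated. `aleMeta` implements the
activation likelihood estimation (ALE) family of methods for this question,
as applied to patient-versus-control motor-activation corpora in
Parkinson's disease, together with the follow-up analyses such corpora
invite: per-experiment cluster attribution, detection-probability
cross-tabulation, severity (UPDRS-III) correlation, and meta-analytic
connectivity modeling (MACM).

The model has three layers:

1. **Spatial uncertainty of a focus.** A reported focus is an uncertain
   estimate of a true activation location. Each focus is modeled as an
   isotropic 3-D Gaussian whose per-axis standard deviation,
   `sigma(n) = sqrt(sigmaSubj^2 / n + sigmaTemplate^2)`, shrinks with the
   experiment's sample size `n` (the lower group size when the two groups
   differ): between-subject anatomical variability averages out with more
   subjects, between-template (normalization) variability does not. The
   constants are not estimable from a foci corpus itself; the defaults are
   the standard empirical calibration used across the field's ALE tools
   (between-subject scale 11.6 mm and between-template scale 5.7 mm in
   Euclidean-distance units, converted to per-axis standard deviations by
   `2 * sqrt(2 / pi)`, i.e. `sigmaSubj` ≈ 7.27 mm, `sigmaTemplate` ≈
   3.57 mm; FWHM around 9–10 mm at n = 15). They are exposed in
   `kernelSpec()` rather than hard-coded, because they are a calibration
   choice, not a derived quantity.

2. **Modeled activation (MA).** For one experiment, the probability that
   its true activation lies at grid voxel v is the maximum over its foci of
   the Gaussian evaluated at the voxel center times a reference voxel
   volume (8 mm³, i.e. a 2-mm voxel), truncated at `3.5 * sigma` and
   clipped below 1. The maximum (rather than the sum) is the nonadditive
   combination rule of the revised algorithm: several foci of one
   experiment are alternative claims about the same underlying activation,
   so duplicated or adjacent foci must not inflate evidence. The legacy
   additive rule remains available (`combine = "sum"`) for comparisons.
   Using a *fixed reference volume* rather than the analysis voxel volume
   makes MA values independent of grid resolution — the value at a shared
   voxel center is identical on a 2-mm and an 8-mm grid — and keeps scores
   on the scale familiar from 2-mm analyses.

3. **ALE and its null.** The ALE score at a voxel is the union
   `ALE(v) = 1 - prod_e(1 - MA_e(v))`: the probability that at least one
   experiment truly activates there, under independence. The null
   hypothesis is *random spatial association*: each experiment's MA value
   at a voxel is an independent draw from that experiment's empirical MA
   histogram over the mask. The voxel-wise p-value is the null probability
   of an equal or higher ALE score (right-continuous survival function).

## Computing the null distribution

The union of independent draws becomes a sum under the transform
`L = -log(1 - MA)`, so the null distribution is the convolution of the
per-experiment L histograms. `aleNullModel()` computes it two ways:

* **exact** — full enumeration of the union over the experiments' distinct
  MA values, as value/probability pairs with no discretization. This is
  feasible for small problems and is used automatically when the
  enumerated support stays below `maxExact`; on toy problems the survival
  function then matches exhaustive enumeration of all voxel pairings
  *exactly*, which the test suite asserts.
* **binned** — histogram convolution on an L-lattice of step `binWidth`
  (default 1e-5, approximately ALE-score units at the relevant scores),
  via FFT. Query scores are snapped to the same lattice so "equal or
  higher" ties are counted consistently. The exact and binned routes are
  compared against each other in the tests.

## Cluster-level family-wise error control

`clusterFwe()` thresholds the voxel map at an uncorrected cluster-forming
p (default 0.001), labels connected components (26-neighborhood default;
6/18 selectable), and compares each cluster's extent against the
permutation distribution of the *maximum* cluster extent under the null:
in each of `nPerm` realizations every experiment's foci are relocated
uniformly at random within the mask (foci count and sample size preserved)
and the whole map is recomputed and rethresholded. The corrected cluster p
is `(1 + #{permutation maxima >= extent}) / (nPerm + 1)`; the add-one
convention makes the test valid at finite `nPerm`. A cluster-mass variant
(`statistic = "mass"`) is available; extent is the default.

Two details matter for calibration:

* Relocated foci are drawn as mask voxels *without replacement* per
  experiment, plus a uniform within-voxel jitter — so null foci are
  continuous-uniform over the masked volume exactly like observed foci,
  and observed and permuted corpora are exchangeable under the null.
* The cluster-forming cutoff is the ALE score whose analytic null survival
  first drops below the forming p, computed once from the observed MA
  histograms, and applied to observed and permuted maps alike. The
  analytic null *is* the random-relocation model, so recomputing it per
  permutation would be circular (and two orders of magnitude slower);
  relocation leaves each experiment's MA histogram essentially unchanged
  apart from mask-edge effects.

The package's own check of all this is `fweCalibration()`: on null corpora
with uniform foci, the fraction of analyses reporting any significant
cluster stays at or below the nominal alpha within binomial noise. The
shipped calibration study (also the acceptance script) uses 50 corpora of
25 experiments with 10 foci each, sample sizes 8–25, a 6-mm grid and 200
permutations — sizes chosen so the study completes in minutes while the
binomial standard error (±0.03 at alpha 0.05) is still informative.

## Attribution, detection counts and severity correlation

How much does each experiment drive a cluster? The published analyses
describe the quantity only as "how much individual studies contributed";
`attributeCluster()` makes the convention explicit as *leave-one-out ALE
mass*: the contribution of experiment e is the drop in the cluster's total
ALE when e is removed, normalized across experiments to sum to 1. Removing
a non-contributing experiment changes nothing; two identical experiments
split a cluster evenly. "Detected by" an experiment is likewise an
undefined phrase in the source literature; the package's declared
convention is a contribution fraction exceeding `relThreshold / n`
(default `relThreshold = 0.1`, i.e. a tenth of the uniform share), exposed
in configuration. Detection counts are reported as integer percentages
rounded half *away from zero* (`reportDetectionPercent()`), the convention
that reproduces all published percentage pairs (17/49 → 35%, 18/49 → 37%,
11/49 → 22%, 13/41 → 32%, 21/25 → 84%, 4/25 → 16%).

The severity correlation ranks per-*study* contributions (a study's
experiments are summed first, since severity scores are study-level means)
against study-mean UPDRS-III scores: Spearman's rho as the Pearson
correlation of mid-ranks, two-sided p from the t approximation, reported
uncorrected. OFF-state means are used when available, else ON-state
(configurable). The conditional detection analysis
(`detectionProbability()`) restricts to experiments whose control group
activated the putamen and cross-tabulates whether they also found a
patient decrease.

## MACM and the rostrocaudal gradient

`macmProfile()` retrieves every database experiment reporting a focus
inside a volume of interest (nearest-voxel membership), then runs the full
ALE chain on the retrieved set; the significant-coactivation mask is the
union of FWE-significant clusters. Retrieval below 21 experiments is
refused, reusing the corpus-eligibility convention (>20) — the real
threshold used with the proprietary coactivation database is not public,
so the package states its own and makes it configurable.
`macmConjunction()` intersects same-polarity masks (a minimum-statistic
variant is available), and `overlapSummary()` restricts the overlap to a
labeled atlas region and reports voxel count, centroid and mean y — the
rostrocaudal statistic (smaller y = more caudal). Any integer-labeled
NIfTI plus label table works as an atlas; `makeToyAtlas()` ships an
elongated bilateral "putamen" for tests. Since licensed coactivation
databases cannot be bundled, the database interface is simply the Sleuth
dialect: any corpus, including the synthetic one, plugs in.

## The synthetic-data generator

`generateCorpus()` emulates the statistical skeleton of the published
corpus: per-experiment sample sizes uniform in 6–26, foci counts uniform
in 1–34, study-mean UPDRS-III uniform in 9–41 (the ranges of the published
study table), all foci continuous-uniform over the mask except planted
convergence loci, where a chosen proportion of experiments each contribute
one focus drawn isotropic-normal around the locus center.
`generateCoactivationDb()` plants VOI-hitting experiments whose target
coupling is Bernoulli with stated probability; background foci avoid the
VOI voxel sets so retrieval counts equal the planted counts exactly. All
randomness flows through one seed, recorded in the ground-truth output.

What the generator does *not* emulate matters for interpreting green
tests: real foci concentrate in gray-matter hotspots rather than uniform
space, real studies share methodological biases, and real convergence is
multi-focal. Passing recovery tests show the inference chain detects
planted convergence against its own null model — not that any particular
real-data result is correct.

### A power boundary worth knowing

Under these corpus conditions a planted locus is detectable only if its
local focus density clearly exceeds the uniform background. A locus
claiming 35% of 49 experiments at dispersion (per-axis sd) 10 mm has peak
planted density `17 * (2*pi*100)^{-3/2}` ≈ 1.1e-3 foci/mm³ against a
background of `49 * 17.5 / 1.89e6` ≈ 4.5e-4 — an enrichment of ~2.4×,
while a voxel-level p < 0.001 cut under this null demands roughly 4–5×.
The same locus at dispersion 6 mm (enrichment ~11×) clears the voxel
threshold comfortably and is recovered in roughly three-quarters of seeds
at 6-mm map sampling, with the remainder lost to the granularity of small
cluster extents at that resolution rather than to the voxel-level signal.
This boundary is a property of the generative model and the ALE
statistic, not of implementation choices: neither the forming threshold
nor grid refinement moves it materially. The recovery study in the
acceptance tests runs at the dispersion-10 conditions regardless and
reports what it finds.

## Numerical and design choices

* **Grid.** Default 2-mm isotropic MNI bounding box with a shipped
  ellipsoidal analysis mask (center (0, −18, 8) mm, semi-axes
  (70, 86, 75) mm, ~1.9 L), so nothing needs downloading; any NIfTI mask
  is accepted (nonzero = analyzed). Simulation studies in the tests and
  the acceptance script run at 6 mm to keep runtimes in minutes; MA
  values are resolution-independent by construction, and the grid only
  affects spatial sampling density.
* **Talairach input.** Foci flagged Talairach are converted with the
  pooled Lancaster affine (stored as a named constant; the inverse of the
  published MNI→Talairach fit). Conversion happens at pipeline entry,
  never silently at parse time.
* **Cluster-forming threshold.** Not stated in the source analyses;
  default p < 0.001 uncorrected (the field standard), configurable.
* **Peaks.** The peak is the voxel with maximum z; ties break toward the
  smallest lexicographic (x, y, z). z values are capped at 10.
* **Degenerate inputs.** Empty experiment lists, pools at or below the
  gate (strictly more than 20 experiments required), fewer than 100
  permutations, empty clusters, all-negative detection tables and
  zero-variance correlations are all explicit errors, not silent results.
* **Determinism.** Every stochastic routine takes a seed; rerunning with
  the same seed and configuration reproduces cluster tables byte for
  byte, and `runAle()` writes its exact configuration and seed beside its
  outputs.

## Limitations

The package analyzes reported peak coordinates, not statistical maps;
image-based meta-analysis is out of scope, as are threshold-free cluster
enhancement, voxel-level FWE, anatomically informed (nonstationary)
kernels, publication-bias diagnostics and the proprietary coactivation
database itself. The study-selection module filters a metadata table
declaratively; it does not screen literature. White-matter masking of
peaks is not implemented; secondary peaks of a cluster are reported when
more than 8 mm apart so users can apply their own anatomical judgment.
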