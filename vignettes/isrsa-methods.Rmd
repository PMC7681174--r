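---
title: "Methods: searchlight intersubject RSA with trait-based dissimilarity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: searchlight intersubject RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isrsa)
```

## The question the method answers

Intersubject representational similarity analysis (IS-RSA) asks where in the
brain the *geometry of individual differences* in a trait maps onto the
geometry of individual differences in multivoxel activity. Instead of
correlating a trait score with activation voxel by voxel, it compares two
subject-by-subject dissimilarity matrices: one predicted from trait scores,
one measured from neural activity patterns. With `n` subjects both matrices
have `n(n-1)/2` informative entries (435 pairs at the package's reference
cohort size of 30).

This package implements the full workflow for a two-informant
callous-unemotional (CU) trait questionnaire and per-condition fMRI beta
maps: questionnaire scoring, intersubject model construction, searchlight
neural dissimilarity, Mantel permutation inference, and map thresholding,
plus a synthetic generator that produces every input the pipeline consumes.

## Trait scoring

Each subject is assessed by two informants (child and parent) on `K` ordinal
items (default 24 items, levels 0-3; both are configuration values, as is
the subscale-to-item map, for which `icu_subscales()` supplies the standard
published assignment). Scoring rules, in order:

1. **Combination**: the combined response per item is the *highest* response
   given by either informant. If only one informant answered, that answer is
   used. A multi-marked response (two adjacent boxes ticked, stored as
   `"a|b"`) contributes its highest marked value; the rule is implemented as
   the maximum over the marked set, which generalizes the usual
   two-adjacent-boxes case.
2. **Imputation**: an item answered by neither informant is replaced by the
   arithmetic mean of the subject's remaining combined items, kept as a real
   number (totals may therefore be non-integer).
3. **Scores**: the total is the sum over all items; each subscale is the sum
   over its configured item subset.

Exclusion flags (`motion_excluded`, `attention_excluded`) are honoured by
`score_cohort()`, which drops flagged subjects and attaches a manifest with
the accounting (enrolled − motion − attention = analyzed; 37 − 4 − 3 = 30
under the synthetic defaults).

## Intersubject dissimilarity models

Summary scores are first normalized to the in-sample maximum
(`normalize_scores()`), giving `s_i` in `[0, 1]` with `max(s) = 1`. Four
models predict pairwise neural dissimilarity `d_ij`:

| kind | formula | intuition |
|------|---------|-----------|
| `low_alike` | `max(s_i, s_j)` | all low scorers alike; each high scorer different |
| `high_alike` | `1 − min(s_i, s_j)` | all high scorers alike |
| `nn_abs` | `abs(s_i − s_j)` | similarity is relative (nearest neighbours) |
| `nn_euclid` | Euclidean distance of raw item vectors | item-level nearest neighbours |

`low_alike` and `high_alike` are the two Anna Karenina ("AnnaK") models.
`nn_euclid` deliberately uses *raw* item responses: normalization is applied
to summary scores before model construction, and item-wise rescaling is not
part of the procedure (a `normalize_items` flag exists for sensitivity
analysis). Downstream inference is rank-based, so any global rescaling of
`nn_euclid` distances would be inconsequential anyway.

Diagonals: the nearest-neighbour models have exact zero diagonals; the AnnaK
diagonals follow their own formula (`d_ii = s_i` or `1 − s_i`). No statistic
ever reads the diagonal — everything downstream uses the strictly-lower
triangle — so this choice is cosmetic and documented for exactness.

A property worth knowing (it matters for interpretation and for the
validation results below): the nearest-neighbours model is *positively
rank-correlated with both AnnaK models by construction*. Across simulated
cohorts, Spearman correlations between the lower triangles of `nn_abs` and
either AnnaK model are around 0.45-0.50, while the two AnnaK models
correlate around −0.47 with each other. The three models are not mutually
exclusive detectors; they are overlapping hypotheses about the same pair
space.

## Neural dissimilarity and searchlights

A searchlight is the set of the `V = 100` in-mask voxels nearest to a center
voxel in millimeter distance (`build_searchlights()`). Defining membership
by voxel count rather than a fixed radius keeps the pattern dimensionality
identical at every center; near mask edges the enclosing sphere simply
grows. A `radius_cap_mm` option drops centers whose enclosing radius
exceeds a bound, for users who prefer truncation. Distances are computed in
millimeters from the grid spacing (default 3 mm isotropic), so anisotropic
grids are handled; distance ties at the cutoff break deterministically by
ascending (x, y, z) index. All volumes in one analysis must share the grid
exactly — there is no resampling, because silent resampling would change
searchlight membership.

Within a voxel set, the neural RDM entry for a subject pair is
`1 − Spearman rho` between their beta vectors (average ranks for ties;
`pattern_rdm()`). Voxels non-finite in any subject are excluded listwise; a
constant pattern (zero rank variance) is an error naming the subject, and
inside the searchlight loop such centers are recorded as undefined with the
reason rather than aborting the map.

## Inference: the Mantel permutation test

At each searchlight the observed statistic is the Spearman correlation
between the lower triangles of the model and neural RDMs. The null is built
by shuffling subject labels — permuting rows and columns of the model matrix
*jointly* — and recomputing the correlation `B = 1000` times. The p-value is
the proportion of permuted statistics strictly exceeding the observed one.
Three deliberate choices:

* **Strict `>` with denominator `B`** implements the stated rule literally;
  p = 0 is attainable (reported as p < 1/B in text). The add-one smoothed
  estimator `(r+1)/(B+1)` is available but off by default.
* **One-sided by observed sign**: the exceedance rule is one-sided for
  positive correspondence, yet anticorrespondent (negative-rho) clusters are
  reportable. The default `alternative = "observed_sign"` computes the
  one-sided p in the direction of the observed sign and flags the sign in
  all outputs, which reproduces both sign classes without inventing a
  two-sided rule.
* **One shared permutation schedule per run**, derived from the seed and
  reused across searchlights and models, so p-values are comparable across
  the map; per-center schedules are available by flag.

Implementation note: after a joint row/column permutation, the multiset of
lower-triangle values of a symmetric matrix is unchanged — only *which*
pair lands where changes. The permuted Spearman statistic can therefore be
computed by indexing a precomputed rank matrix rather than re-ranking,
making `B = 1000` permutations across a few thousand searchlights cheap.
A unit test verifies the fast path against direct recomputation at
`1e-12` tolerance, and an exhaustive mode (all `n!` label permutations,
`n <= 8`) provides an enumeration oracle.

## Thresholding

`threshold_map()` binarizes at the cluster-forming threshold `p < .005`,
splits supra-threshold centers by the sign of rho, labels connected
components (18-connectivity by default, 6/26 configurable; the convention
is not dictated by the procedure and is recorded in the output), and applies
two survival rules: cluster extent `k >= 10` voxels, and voxel-level
Benjamini-Hochberg FDR at `q = .05` over all defined centers' p-values, a
cluster surviving FDR when any member voxel passes. FDR is applied per map
(per condition-model pair), not pooled across maps. Peak coordinates are
reported in millimeters from the grid spacing and origin.

With `B = 1000` and strict exceedance counting, `p < .005` means at most 4
of 1000 permutations exceeded the observed statistic; with the reduced
`B = 200` used in some validation runs it means zero exceedances, which is
slightly conservative.

`compare_maps()` computes the voxel-wise Spearman correlation of two maps'
rho values over centers defined in both, excluding centers undefined in
either — used to compare the summary-score and item-wise
nearest-neighbours maps per condition.

## ROI analysis

`roi_mean()` averages finite beta values over an anatomical mask per
subject. `partial_spearman()` then associates mean activation with a trait
score controlling for age, gender and IQ: all variables are
rank-transformed, the ranked x and y are residualized on the ranked
covariates plus intercept by least squares, residuals are correlated, and
the two-sided p uses the t approximation with `n − 2 − k` degrees of
freedom.

## The synthetic generator

`simulate_cohort()` emulates the cohort the pipeline expects: 37 enrolled
subjects, of whom 4 are motion-flagged and 3 attention-flagged, leaving 30;
ages uniform on 10-17; a balanced 0/1 gender indicator; IQ ~ N(100, 15),
independent of the trait by default so covariate-control tests are clean (a
`confounded` mode couples them). Item responses come from a latent-trait
ordinal model: subject trait + item offset + subject-item noise defines a
shared propensity observed by each informant with informant-specific noise
calibrated so the informant correlation equals `informant_r` (default 0.9;
at 1.0 the informants agree exactly). Thresholds were set once at the 25th,
60th and 85th percentiles of the propensity scale, giving right-skewed
item marginals and cohort totals in the 20-50 range typical of CU
questionnaires. Missing cells, both-informant-missing items and
multi-marked cells are injected at low configurable rates to exercise every
scoring rule.

`simulate_betas()` plants intersubject structure: within a planted region,
subject i's pattern is `w * loading_i * g + noise`, with `g` a unit-variance
shared pattern, noise standard deviation 1, and loadings

* `1 − s_i` for a `low_alike` plant (low scorers share the pattern),
* `s_i` for a `high_alike` plant,
* `(cos(pi s_i / 2), sin(pi s_i / 2))` on two orthogonal shared patterns
  for an `nn` plant, so pattern similarity decays smoothly with
  `|s_i − s_j|`.

The effect weight `w` in `[0, 1]` scales signal amplitude against
unit-scale noise; `w = 0` is exactly pure noise. Outside planted regions
voxels are independent noise (optionally Gaussian-smoothed to stress
cluster inference); outside the mask they are `NA`. The default mask is an
ellipsoid of ~1900 voxels in a 17 x 17 x 15 grid of 3 mm voxels — large
enough for meaningful cluster inference, small enough that a 20-replicate
recovery experiment with `B = 1000` finishes in about two minutes on one
CPU. Identical configuration and seed give bit-identical output.

What the generator does *not* emulate: spatial autocorrelation of real BOLD
signal and noise (off by default), inter-regional correlation, physiological
artifacts, or any hemodynamic time-series structure (beta maps are emitted
directly; first-level modelling is out of scope). Passing recovery tests on
this generator therefore demonstrates the *statistical machinery* is
correct and powered under idealized noise, not that effect sizes transfer
to real data.

## Validation results the package computes about itself

`validate_mantel_null()` confirms the permutation test's type-I error: over
500 independent null RDMs at n = 30, the rejection rate at alpha = .05 falls
in the 95% binomial interval around .05 (any single 500-replicate batch
fails such a check ~5% of the time by construction; the pooled rate over
several seeds sits at the nominal level).

`validate_recovery()` plants one region per model kind at `w = 0.8` and asks
each model's thresholded map whether it covers at least half of each planted
region. Each model recovers *its own* region in ~85-95% of replicates. Full
selectivity — recovering one's own region *and* neither of the others' —
holds in only ~30% of replicates, and the failures are informative: they are
almost entirely nearest-neighbours/AnnaK confusions, exactly as the model
correlations above predict. A region planted with AnnaK structure is
genuinely, partially detectable by the nearest-neighbours model and vice
versa. Users interpreting real maps should treat the three models as
correlated hypotheses and expect overlapping detections rather than
mutually exclusive ones.

## Numerical and design choices, collected

* Spearman everywhere with average ranks; ties are common in ordinal trait
  data and the tie rule is therefore stated rather than left to chance.
* Lower triangles are extracted in a fixed column-major order shared by all
  matrices of the same size, so vectors align pair-by-pair.
* Permutation schedules, cohort generation and beta generation are all
  seeded; every result object records the seed it was produced with, and
  `run_isrsa()` writes a provenance record with a configuration hash.
* Degenerate inputs fail loudly and specifically: all-zero scores, constant
  patterns (naming the subject), asymmetric matrices, mismatched grids
  (naming the file), subject-order mismatches.
* The searchlight loop's results are independent of how centers are chunked
  or ordered; maps from a joint multi-model call equal maps from separate
  calls with the same seed.
* Problem sizes used in the shipped validation suite — ~1900-voxel mask,
  V = 100, B = 1000 (recovery) or B = 200 (null calibration), 20 recovery
  replicates, 500 null replicates — were chosen as the smallest sizes at
  which the target quantities are stable, and are stated alongside each
  result.

## Known limitations

* The generator's noise is white by default; cluster-extent inference on
  smoothed noise is stressed by an option, not by the defaults.
* `nn_euclid` requires complete item data (it follows imputation in the
  pipeline); there is no pairwise-deletion distance.
* Exhaustive Mantel enumeration is limited to n <= 8 (40,320 permutations).
* The AnnaK/nearest-neighbours non-exclusivity described above is a
  property of the models themselves; no thresholding choice in this package
  can make them selective.
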