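---
title: "Random SVM clusters for functional-connectivity classification and region discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random SVM clusters for functional-connectivity classification and region discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvmcluster)
```

## The model

A subject's resting-state activity is summarized as one ROI-by-time
matrix; the feature vector is the Pearson correlation of every unordered
ROI pair. For `R` regions that is `E = R(R-1)/2` functional connections
(FCs) — 4,005 for the 90 cerebral parcels of the AAL atlas. Edges are
indexed 1-based in row-major order over the strict upper triangle
(edge 1 = (1,2), edge `E` = (R-1, R)); every frequency table, feature
subset and export in the package relies on this one fixed convention.

The classifier is an ensemble of `n` SVMs. Member `i` draws `M` subjects
from the training set S1 and a random `d`-of-`E` feature subspace, and
trains only on those. The validation set S2 screens the ensemble: members
with accuracy strictly below 0.5 — worse than guessing — are deleted,
leaving `k` members. Held-out subjects in S3 are classified by unweighted
majority vote, and the patient vote fraction doubles as a score for
precision-recall analysis.

Discovery inverts the ensemble: members whose validation accuracy exceeds
0.75 are "superior", and the number of superior subspaces containing each
edge is that edge's appearance frequency. A subspace that happens to hold
discriminative edges makes its member accurate, so discriminative edges
accumulate counts. The top-`k` edges by count are the optimal features;
each increments the weight of its two endpoint ROIs, and the
highest-weight ROIs are nominated as candidate pathogenic regions.

### Assumptions

* Labels are binary and reasonably balanced; stratified splitting keeps
  each of S1/S2/S3 balanced to within one subject per class.
* Correlation features make group differences approximately linearly
  separable; the default base learner is therefore a linear SVM with unit
  cost (an RBF kernel is available by configuration, but a linear margin
  keeps the subspace-frequency reading clean).
* Discovery assumes member accuracy is informative about the member's
  feature subspace — i.e. that enough members exist for each edge to be
  sampled many times (see the ensemble-size discussion below).

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `ratios` | S1:S2:S3 proportions | 4:1:5 | half the cohort held out for testing; sizes by largest-remainder rounding |
| `n` | ensemble size | 360 | plateau of the published accuracy curve; see sweep rule |
| `d` | features per member | 148 | argmax of the published dimensionality sweep |
| `M` | subjects per member | `ceiling(0.8 * |S1|)` | no published value; 80% subsampling without replacement keeps members diverse but trainable; bootstrap available |
| screen threshold | deletion bound on S2 accuracy | 0.5 | below-chance members harm the vote; deletion is strict (`< 0.5`), so exactly-0.5 members stay |
| superior threshold | discovery bound | 0.75 | strictly-greater; only clearly-informative members feed frequencies |
| `k` | optimal-feature count | 148 | equated with the tuned `d`, independently configurable |

A note on the 4:1:5 split: a 957-subject cohort (479 patients, 478
controls) allocates to 383/96/478 under largest-remainder rounding. The
published protocol prints 382/96/479, which no standard rounding of 957
reproduces; this implementation documents and follows the deterministic
largest-remainder allocation.

Two conventions are deliberate and bit-stable: vote ties (fraction
exactly 0.5) resolve to the patient label — deterministic and oriented
toward sensitivity in a screening context — and count ties at the
`top_features` boundary break by ascending edge index.

Per-member randomness derives from `(master seed, member index)` through
a fixed integer stream, so builds are reproducible and independent of
evaluation order.

## Sweep selection rules

The published tuning procedure reads "accuracy becomes stable" off a
curve; here that is formalized so it is a pure, testable function of the
curve. `select_stable()` returns the smallest grid value at which a
window of `w = 5` consecutive accuracies has range `< tol = 0.02`;
`select_argmax()` returns the accuracy argmax with ties to the smaller
(cheaper) dimensionality. Sweeps reuse one split across grid points so
curves are comparable, and repeats (default 5) re-randomize only member
construction.

## The synthetic cohort generator

`generate_cohort()` emulates exactly what the classifier consumes: a
two-group panel of ROI time series whose correlation structure differs
between groups on known edges. For a planted edge `(i, j)` with target
correlation `r`, both endpoint series mix a shared latent factor:

    x_i = sqrt(1 - a^2) * e_i + a * s,   a = sqrt(|r|)
    x_j = sqrt(1 - a^2) * e_j + sign(r) * a * s

with `s`, `e_i`, `e_j` independent unit-variance white noise, so the
population correlation of the pair is exactly `r`. Planted edges must be
vertex-disjoint, which keeps each edge's construction exact and all other
pairs at population correlation 0. This latent-factor route was chosen
over sampling from a full covariance matrix because it is exact, O(R·T)
per subject, and trivially verifiable against a Monte-Carlo oracle of the
same formula.

Site effects are affine (`x * scale^(site-1) + shift*(site-1)`); Pearson
correlation is affine-invariant, so sites perturb only what the z-scoring
step of `normalize_and_slice()` must undo — which is precisely the role
normalization plays for multi-site cohorts. "Slicing to a uniform length"
truncates from the start of the series to the panel minimum (or a
configured length); a constant series cannot be z-scored and maps to
zeros with a warning, and its edges receive correlation 0 rather than
`NaN` so downstream linear algebra stays total.

The generator does **not** emulate hemodynamics, autocorrelated BOLD
noise, head motion, or voxel-level structure. Passing tests therefore
demonstrate that the pipeline's logic is correct and that it recovers
planted correlation differences at realistic sample sizes — not that any
particular accuracy will be attained on real neuroimaging data, where
effect sizes are far smaller and confounds abound.

Demographics (`generate_metadata()`) are drawn independently of the time
series — they describe the cohort, they are never features. Default group
means/SDs for age and FIQ/PIQ/VIQ follow the printed summaries of the
ABIDE-I case-control cohort this workflow targets. The demographics
report uses a Welch two-sample t-test (the unequal-variance choice is
conservative; for the printed IQ summaries pooled and Welch agree to
three decimals) and a chi-square test on decade-binned age. One known
quirk: the printed PIQ p-value of 0.001 is not reproducible from its own
group summaries (summary-based t gives p ≈ 2e-4, which rounds to 0.000),
suggesting per-variable missing data upstream; the package reports what
it computes.

## Study conditions used by the test suite

Effect sizes for planted edges are calibration choices — no published
effect size exists for real patient/control edge differences. Two frozen
conditions cover the two regimes:

* **Null cohort** (calibration): `r_base = r_alt = 0.2`, 60 subjects per
  group, 90 ROIs, T = 120, `n = 100`, `d = 60`. Screened-cluster test
  accuracy must sit within `0.5 ± 3` binomial standard errors over 10
  seeds.
* **Strong-effect cohort** (recovery): 20 vertex-disjoint planted edges,
  `r_base = 0.1`, `r_alt = 0.5`, 100 subjects per group, T = 150,
  `n = 2000`, `d = 100`, superior threshold 0.75, top-20 edges. Floors:
  top-20 edge precision ≥ 0.8 and planted-ROI recall at rank 40 ≥ 0.8,
  averaged over 10 seeds.

The recovery ensemble is large on purpose. An edge is sampled into a
member with probability `d/E ≈ 0.025`, so the expected count of a planted
edge across all members is `n·d/E`, while a background edge's count grows
only with the superior subset. With `n = 200` those means are ≈ 5 versus
≈ 2 — and across ~4,000 background edges the upper tail of the background
distribution swamps a top-20 list. At `n = 2000` the separation is ≈ 50
versus ≈ 20 with standard deviation ≈ 4–7, and ranking is reliable. This
is worth remembering when applying frequency discovery to real data:
`n` must be large enough that each feature is sampled many times.

Problem sizes throughout the suite (tens of subjects, tens of ROIs for
unit tests; the two frozen cohorts above for end-to-end checks) were
chosen so the whole suite runs comfortably on a laptop while keeping every
statistical check meaningfully powered.

## Numerical and degenerate-input choices

* Zero-variance series: correlation 0 with a warning, never `NaN`.
* Precision with no predicted patients is reported as 0 with a
  `degenerate_precision` flag rather than `NaN`.
* A member whose subject draw contains one class is redrawn (bounded
  retries), then errors naming the member.
* An emptied cluster (screening) or empty superior set raises a dedicated
  error class; the command-line wrapper maps these to exit code 4
  (config errors 2, missing artifacts 3).
* Discovery uses validation (S2) accuracy for the 0.75 threshold so test
  labels never influence feature selection; a configuration switch
  (`accuracies =`) permits substituting another accuracy reading.

## Limitations

* The baseline harness replaces the product-based neural network of the
  published comparison with a generic feedforward net (`nnet`); PNNs have
  no canonical R implementation and the ensemble-versus-single-learner
  comparison does not depend on that choice.
* Vote fractions are not calibrated probabilities; members are unweighted
  by design.
* The generator's white-noise series make correlation estimates slightly
  cleaner than autocorrelated BOLD would; planted-recovery floors are
  therefore optimistic relative to real data.
* Atlas support is the shipped AAL table (116 parcels, cerebellum
  filter); other parcellations can be used by passing a compatible label
  table, but no registration or voxel-level processing is provided.
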