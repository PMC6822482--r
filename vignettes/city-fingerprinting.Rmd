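---
title: "Fingerprinting the city of origin of a metagenome from its enzyme-level functional profile"
author: "cityprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting the city of origin of a metagenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Urban subway surfaces carry microbial communities whose composition reflects
the local environment. When such a community is shotgun-sequenced and its
reads are mapped to molecular functions — Enzyme Commission (EC) numbers —
the resulting *functional profile* (relative abundance of reads annotated to
each of up to 1257 ECs) carries a city-specific signal. `cityprint`
implements a pipeline that learns this signal: it trains one classifier per
city to recognise "this city vs every other city", combines the classifiers
by ranking their standardized scores, and — because any ranking assigns
*some* city to *any* input — calibrates a score threshold below which a
sample is judged to come from none of the training cities.

The package consumes the per-sample two-column output of an upstream
read-to-function annotator (EC number, annotated read count) together with a
metadata table; it does not run read QC or annotation itself.

## Data model

Relative abundance of a function is its annotated read count divided by the
sample's **total** read count (annotated reads are a small subset, so
abundances sum to well below 1). The total is supplied in the metadata table
rather than inferred from the profile file: whether it refers to pre- or
post-QC reads is a choice the upstream pipeline made, and the package leaves
it to the user.

Profiles are assembled over the lexicographically sorted union of observed
ECs, with exact zeros where an EC was absent, into an `ECProfileSet` — a
`SummarizedExperiment` with ECs as rows and samples as columns, carrying
city labels, total read counts, and a set tag per sample. Model features are
frozen at training time: new samples are projected onto the training EC
universe (unseen ECs dropped, missing ECs zero).

## Feature selection: the DKM criterion

Each city's signature functions are found with the DKM impurity criterion
$g(q) = 2\sqrt{q(1-q)}$. A feature's score for a binary task is the impurity
decrease of its best binary split,

$$\mathrm{gain} = g(p) \;-\; \sum_{v \in \{L,R\}} \frac{n_v}{n}\, g(p_v),$$

maximised over thresholds at midpoints between consecutive distinct sorted
values ($p$ = positive fraction overall, $p_v$ in branch $v$). This
best-split formulation is deterministic and is verified in the test suite
against an exhaustive brute force over every threshold; it is invariant
under strictly monotone transformations of the feature and under positive
rescaling of all abundances. Ties in score are broken lexicographically by
EC identifier.

The default of `k = 20` selected ECs per city follows the original study's
empirical grid (5, 10, 20, 40); `k` is a parameter everywhere it appears.
During cross-validation each iteration selects its own top-*k*; the
*consensus signature* of a city is the *k* ECs most frequently selected
across iterations (frequency ties broken by higher mean DKM gain, then
lexicographically).

## Classification and score standardization

Each city model is a soft-margin SVM (`e1071`, the radial-basis defaults:
cost 1, kernel width $1/n_\mathrm{features}$) trained on city-vs-rest
labels. Features are z-scored by the training set's mean and standard
deviation and the same statistics are applied to any later test sample —
testing features standardized according to the training set. The scaling is
done explicitly (rather than through the SVM's internal scaler) so that
all-absent, zero-variance ECs are handled deterministically (scale 1). The
raw score of a sample is its signed kernel margin, oriented city-positive.

Raw margins of different city models are not comparable, so each is
standardized to that model's training score range:
$(\mathrm{raw} - \min)/(\max - \min)$, where min and max are taken over the
distinct training-cohort samples scored by the model. Scores are *not*
clamped — standardization must stay strictly monotone — and a degenerate
range maps to 0.5. The training range is the full cohort range; the
alternative reading in which each sample's own score is excluded from its
range was considered and rejected as immaterial at cohort sizes of interest.
Cities are ranked by standardized score (ties lexicographic); the top-ranked
city is the assignment, and an assignment is correct under the *top-2
criterion* when the true city holds either of the first two ranks.

## Class balancing

City sample counts are heavily imbalanced, and unbalanced training drives
assignments toward the dominant cities. The two-stage balancing resampler
first draws, with replacement, exactly `perCity` (default 150) samples from
every city, then resamples positives (the target city's stage-1 draw) and
negatives (the pooled other cities) with replacement to `perClass` (default
5000) each. Balancing changes sample multiplicities only, never the set of
distinct samples. In the `balance-select` and `final` variants, feature
selection runs on the balanced multiset and training uses the selected ECs,
matching the published ordering (balance, then select, then train); the
standardization range is still computed on the distinct cohort samples, so
that test-set scores refer to the actual training cohort.

## The five variants and cross-validation

* `raw-full` — all ECs, no balancing (leave-one-out).
* `raw-select` — per-iteration DKM top-*k*, no balancing (leave-one-out).
* `balance-select` — balancing, then DKM top-*k* on the balanced multiset
  (leave-one-out).
* `final` / `final-unbalanced` — one pass of the `balance-select` /
  `raw-select` procedure on the complete set, producing the deployable
  `ModelSuite`.

Leave-one-out cross-validation removes one sample, reruns the *entire*
training procedure — feature selection and balancing included — on the
remainder, and scores the held-out sample with every city model. The test
suite re-derives iteration artifacts from scratch to demonstrate that the
held-out sample can never leak into selection or training.

The random-label baseline permutes city labels. Two modes are exposed: the
default re-scores a fixed cross-validation result against permuted truth
(the published procedure — the model is applied to a random-label set), and
`retrain = TRUE` reruns the full leave-one-out per permutation. Accuracy
under either mode collapses to the chance level implied by the class priors.

## Novelty: the random-metagenome null

To decide that a sample is from *none* of the training cities, a null set of
artificial metagenomes is built: ten samples per city are pooled and each
output sample draws, for every EC independently, a value from the pool's
values for that EC. This preserves per-EC marginals while destroying the
inter-EC correlation that makes a profile city-like. The novelty threshold
is the nearest-rank 95% quantile of the null set's top-hit standardized
scores, so at most 5% of the calibration set exceeds it by construction; a
sample is judged novel when its top-hit score is at or below the threshold
(confidence of known origin applies strictly above it). The published
threshold value (0.65 on the study's data) is a calibration *output* and is
never hard-coded.

**Limitation — margin saturation.** A kernel margin is not a typicality
score. A sample far outside the training cloud (after feature z-scoring) has
near-zero kernel similarity to every support vector, so every city model
returns its intercept — a constant "plateau" score that can exceed the
random-null threshold, because the null's members are per-EC in-range
mixtures that earn confidently *negative* margins below the plateau. On
tightly clustered synthetic data with many cities, extremely alien profiles
can therefore evade the novelty flag even though mildly divergent ones are
caught. The original study's data happened to have the favourable geometry
(its real negative-control set scored entirely below the calibrated
threshold). Users screening for potentially alien inputs should inspect raw
scores (a sample scoring exactly at a model's far-field plateau is suspect)
rather than rely on the threshold alone.

## Evaluation conventions

ROC sweeps every distinct score as a threshold; FPR = FP/(TN+FP),
TPR = TP/(TP+FN); the AUC is the trapezoid area and, with tied scores
grouped per threshold, equals the rank-sum (pair-counting, ties ½)
statistic — asserted to 1e-12 in the tests. PR curves report precision
TP/(TP+FP) against recall; the AUC anchors the curve at its first attainable
recall point, extending that precision to recall zero, so perfect separation
scores exactly 1 and no optimistic interpolation is introduced. ROC is
insensitive to prevalence while PR degrades for rare cities — the pipeline
reports both per city.

Signature enrichment/depletion uses Welch's two-sample t-test (unequal group
sizes are the norm), two-sided, city vs rest. P-values are deliberately
reported without multiplicity adjustment, because the signature ECs are
selected by the DKM criterion and not by these tests; a Benjamini–Hochberg
column is available behind a flag.

## The synthetic-data generator

No public accession exists for the original study's data, so the package
ships a seeded generator that emulates its structure: all cities share one
log-normal baseline EC composition (`baselineSdLog = 1.25`); each city's
planted signature ECs (20 per city, disjoint across cities) are multiplied
or divided by `effectSize`; per-sample counts come from multinomial
sampling at `depth` reads (1e5) with per-sample log-normal composition
noise (`sampleNoiseSd = 0.3`) and Bernoulli dropout (`sparsity = 0.2`)
emulating annotation sparsity. The canonical condition is 8 cities with
deliberately imbalanced counts (5, 8, 100, 10, 60, 10, 15, 20 — dominated
by two large cities), a 200-EC universe, effect size 8, seed 42. Planted
ground truth (signature ECs and directions) is recorded in the container
metadata for recovery tests.

What the generator does *not* emulate: inter-EC correlation within the
baseline (real pathways co-vary), sequencing-depth variation between
samples, batch effects, and within-city substructure. Passing tests
therefore demonstrate correctness of the *procedure* (leakage-free
selection, calibrated thresholds, direction of balancing effects), not
field performance on real metagenomes. The effect size of 8 makes the
canonical fixture close to separable by design — the study-condition tests
assert direction and chance-level comparisons, not headline accuracies.

The outgroup generator emulates an unrelated negative-control microbiome:
an independent redraw of all EC means, additionally perturbed by the factor
`shift` on a random half of the ECs. The random-metagenome and label-shuffle
constructions follow the published procedures exactly (10 samples per city
pooled, per-EC independent uniform draws, 1000 outputs; uniform label
permutations preserving per-city counts).

## Problem sizes used by the tests

The test suite and acceptance script run entirely on generated data: the
canonical fixture above for the study-condition checks (two leave-one-out
runs, 228 iterations each), a 3-city set for unit-level checks, and a
harder 3-city, effect-3 condition where prevalence and balancing effects
are visible. Leave-one-out balancing uses 30/100 (stage-1/stage-2) — the
two-stage structure is what matters for the directional claims, and 228
refits at the published 150/5000 would be disproportionate — while the
single final suites are fit at the published 150/5000. Numerical
tolerances: oracle equalities at 1e-12; stochastic assertions use binomial
tests or permutation intervals at the sizes stated in the tests.

## Reproducing the headline calibration

`scripts/acceptance.R --seed <s> --out <path>` regenerates the canonical
known-like set, fits the `final` suite (150/5000), calibrates the threshold
at the 95% quantile of a fresh 1000-sample random null, and reports the
percentage of an *independent* 1000-sample null replicate exceeding the
threshold — the quantity the calibration claims to control at 5%.
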