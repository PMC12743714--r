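---
title: "Positive-unlabeled case ascertainment in hospital administrative data"
author: "puadmin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-unlabeled case ascertainment in hospital administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In hospital administrative and billing data, secondary diagnoses such as
sepsis are only *actively* coded when present: an uncoded case is not a
verified negative but an unlabeled one. Medical record review studies
repeatedly find that true sepsis rates are a multiple of the raw coded
rates, so treating uncoded cases as negatives biases reimbursement
grouping, quality indicators and epidemiological estimates. puadmin frames
case ascertainment from such data as positive-unlabeled (PU) learning:
binary classification from labeled positives and unlabeled examples only,
with no reliable negatives.

## Model and assumptions

A case is a triplet $(x, y, s)$: a feature vector $x$ (cost attributes and
aggregated procedure counts), a latent class $y \in \{0, 1\}$, and an
observed label $s \in \{0, 1\}$. Only $(x, s)$ are recorded. Two identities
define the PU setting and are enforced by the `pu_dataset` container:
$p(s = 1 \mid x, y = 0) = 0$ and $p(y = 1 \mid s = 1) = 1$. The class
prior is $\alpha = p(y = 1)$ and the label frequency is
$c = p(s = 1 \mid y = 1)$, so in a single-training-set scenario the
labeled fraction is $\alpha\,e(x)$ with propensity
$e(x) = p(s = 1 \mid x, y = 1)$. Under SCAR (selected completely at
random) $e(x) \equiv c$; under SAR the propensity depends on a subset of
attributes $x_e$. The package follows the reduction of SAR to SCAR that is
plausible when the labeler (a coding specialist) never sees the learning
attributes (cost data): recall computed on labeled positives then
estimates recall on all latent positives, which the synthetic-data tests
verify directly because the generator knows $y$.

Two further assumptions motivate learning from cost data: separability (a
classifier can split the classes at some threshold $\tau$) and smoothness
(similar cost patterns imply similar class probability). Both are
diagnosed with the prediction-probability CDF (`prediction_cdf()`): a
well-behaved PU model concentrates unlabeled mass near probability 0 and
labeled mass near 1.

## The two learners

**Spy technique (two-step heuristic).** A fraction (default 10%) of the
labeled positives is seeded into the unlabeled pool; a step-1 classifier
is fitted treating the remaining positives as class 1 and unlabeled cases
plus spies as class 0. The lowest predicted probability among the spies
bounds, from below, where genuine positives live; unlabeled cases strictly
below it are *reliable negatives*. Because one outlying spy can drive that
minimum to zero, step 1 is repeated (default 1,000 times) with a fresh spy
draw per repeat, and the threshold is the arithmetic mean of the
per-repeat minima. Redrawing spies each repeat is the reading under which
repetition actually averages away spy-selection noise; per-repeat minima
are retained in the fit object so the threshold is auditable. Each
unlabeled case's step-1 probability is likewise averaged across repeats
before the reliable-negative cut. Step 2 adds the spies back and fits a
supervised classifier on positives versus reliable negatives; unlabeled
cases that are neither spies nor reliable negatives are simply scored by
that model. Top-down threshold shares (fixed percentages of cases declared
reliable negatives) are deliberately not implemented; the repeat-averaged
minimum replaces them. The step-2 training label mean is recorded and used
as the classification threshold for binary decisions.

**Adaptive-resampling ensemble (robust approach).** Putative labels start
as observed (labeled = positive, unlabeled = negative) with mislabel
probability 0 for all. Each iteration resamples every putative class at
its original size, with replacement, with inclusion probability
proportional to $1 - $ mislabel probability; the base classifier (default:
radial-kernel SVM on min-max normalized features) is refitted and every
case's mislabel probability is updated to the predicted probability of the
class opposite to its putative label. We resample per class at fixed size
rather than excluding cases by independent Bernoulli draws: under
case-wise exclusion the labeled positive class shrinks faster than the
negative class purifies whenever the calibrated positive probability is
capped near the label frequency (it is, since the model initially
estimates $p(s = 1 \mid x) \approx c\,p(y = 1 \mid x)$), and the
iteration degrades instead of improving. Fixed-size per-class resampling
keeps class sizes stable while still progressively excluding
likely-mislabeled cases, and is how the reference adaptive-sampling
algorithm operates. After at most `n_iterations` (default 5, early stop
when the largest update falls below $10^{-3}$) the final model is an
ensemble (default 20 members) fitted on independent low-mislabel
resamples; the ensemble probability is the unweighted member mean, hence
invariant to member order. The PU training label mean is the
classification threshold.

**Base classifiers.** Any fit/predict pair returning class probabilities
plugs in. Built-ins: logistic regression (`stats::glm.fit`), Gaussian
naive Bayes (`e1071::naiveBayes`), gradient boosted trees (xgboost,
library defaults), and the radial-kernel SVM (`e1071::svm`, default cost
and gamma). SVM probabilities come from Platt scaling — a logistic sigmoid
fitted to decision values — with the sigmoid fitted on 3-fold
cross-validated decision values over deterministic interleaved folds.
In-sample decision values are overconfident and polarize borderline cases
during adaptive resampling; cross-validated calibration is the standard
remedy and, unlike the calibration built into the underlying SVM library,
is deterministic and seedable from R.

## Evaluation

False positives and true negatives are unobservable in PU data, so
evaluation uses recall $r = TP/(TP+FN)$, recall-at-$k$ (share of all truth
positives inside the top $k\%$ of probability-ranked cases) and
precision-at-$k$ (share of truth positives inside that top set), with
five-fold stratified cross-validation and out-of-fold predictions pooled
so every case is scored exactly once. Truth is counted under five
coding-strategy scenarios: A explicit, B explicit and implicit, C
implicit, D explicit or implicit, E implicit only — satisfying
$E \subseteq C \subseteq D$, $B \subseteq A \subseteq D$ and
$|D| = |A| + |C| - |B|$. Numerical conventions, chosen where the
published description is silent: ranking ties break by ascending case id
(deterministic and auditable); the top-$k$ set size is
$\lfloor kN/100 \rfloor$ (flooring never inflates precision);
classification uses $\ge$ at the threshold; the per-fold classification
threshold is the *training*-set label mean of the fold (the step-2 mean
for the spy learner), which avoids using any test-fold information. On
synthetic data, latent-truth "oracle" metrics are reported as a separate
scenario. Both per-fold and pooled metrics are emitted, since published
tables do not say which aggregation they use.

## External validity check

Relabeling unlabeled cases above a threshold implies a new disease rate.
For thresholds derived from the top 5–30% of predictions (per fold the
probability of the $\lfloor kN/100\rfloor$-th ranked case, averaged over
folds) and from the class-label mean, the relabel count $r_k$ among the
$u_t$ unlabeled learning-sample cases is transferred to the initial
sample of $l_i$ labeled and $u_i$ unlabeled cases:
$$s_k = \frac{l_i + u_i\, r_k / u_t}{l_i + u_i},$$
equivalently the new positive count over $n_i = l_i + u_i$. The ratio of
$s_k$ to the raw rate $l_i/n_i$ cancels $n_i$ — it equals the new
positive count over $l_i$ — and is judged against the closed interval
2.4–4.1 of rate inflations reported by medical record review.
Relabeling uses pooled out-of-fold predictions (one decision per case)
and the $\ge$ convention; transferred counts stay unrounded until report
formatting. $n_i$ must be supplied for real data; synthetic runs take it
from generator truth. Note one symbol collision in the published
formulation: $r_k$ denotes recall-at-$k$ in evaluation and the relabel
count in the transfer formula; the code names the latter
`relabel_count_t`.

## The synthetic-data generator

Real case-cost data are access-restricted, so `generate_pu_dataset()`
emulates their statistical structure with known truth: latent classes
drawn at prior $\alpha$ (default 0.2), labels at frequency $c$ (default
0.5, SCAR; SAR mode rescales a logistic propensity so the positive-class
mean equals $c$), and 17 cost attributes drawn from class-conditional
zero-inflated log-normal distributions plus Poisson procedure-chapter
counts. Defaults were set once to reproduce the qualitative facts of the
motivating dataset — total costs of labeled cases more than three times
those of unlabeled cases, many exact-zero cells (ICU, dialysis, operating
room), heavy right skew — and to realize the strong class separation the
recovery tests assume, via clear class-conditional zero-inflation
contrasts and log-location shifts of roughly 1–1.5 SD spread over many
attributes (high-dimensional joint elevation is exactly what makes real
sepsis cost profiles learnable). The explicit coding flag equals the
observed label, because labeling *is* explicit coding; implicit flags are
drawn directly (65% of latent positives, 5% of latent negatives) rather
than via diagnosis-code lists, which are configuration inputs for real
data. Cohort fields are generated clean; `inject_cohort_noise()` plants
exactly-one-violation cases so the filters are testable against a
mutation log.

What the generator does **not** emulate: the real attribute catalogue
(71 cost attributes) or its empirical moments, between-hospital coding
heterogeneity, feature correlation beyond class-conditional independence,
and age/length-of-stay effects on costs. Passing recovery tests therefore
show the pipeline's statistical machinery is sound under the stated
mechanism, not that any particular recall is attainable on real data.

## Reproducibility and problem sizes

A single master seed drives everything; stages derive child seeds with
`child_seed()`, so runs are byte-for-byte reproducible including CSV
artifacts and the run manifest. The recovery suite uses n = 5,000 cases
with five generator seeds for the adaptive learner, n = 50,000 for
label-frequency convergence, and 20 replicates of the spy threshold at
10 versus 1,000 repeats on an n = 300 sample with the logistic scorer —
sizes chosen as the smallest at which the binomial error bands make the
checks meaningful.

## Known limitations

* Min-max scaling of heavy-tailed costs compresses most of each feature's
  mass near zero; the radial SVM with default bandwidth then leans mainly
  on zero-pattern contrasts and summed evidence across attributes. This
  mirrors the published setup but is not optimal feature engineering.
* The mislabel probability of a *labeled* positive is taken as
  $p(y = 0 \mid x)$, the natural reading; labeled positives can therefore
  be down-weighted. At low label frequencies the early iterations
  under-rate positives (their calibrated probability is capped near $c$);
  the fixed-size resampling keeps this benign but cannot remove it.
* With heavy contamination of the unlabeled pool, the mean mislabel
  probability assigned to planted latent positives *decreases* as
  contamination grows (the negative class is partially absorbed); only
  the ordering — planted cases above true negatives — is a reliable
  invariant, and that is what the tests assert.
* Probability calibration beyond Platt scaling, base-classifier tuning,
  and model-comparison statistics are out of scope.
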