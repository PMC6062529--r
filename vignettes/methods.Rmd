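---
title: "Automated prognostic pipelines: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated prognostic pipelines: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements: the
models and procedures, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Lung-transplant referral for adults with cystic fibrosis is traditionally
triggered by a single spirometric criterion — FEV1% predicted dropping below
30%. A prognostic model supporting that decision must be *precise*: at ~9%
three-year event prevalence (death or transplant), a model can post a high
AUC-ROC purely on easy true negatives while flooding the waiting list with
premature referrals. The package therefore optimizes and reports
precision-recall behaviour first, and treats AUC-ROC as a secondary
descriptor.

## The clinical utility

For labels $y_i \in \{0,1\}$ and risk scores $s_i \in [0,1]$,

$$U = \tfrac12\,(\mathrm{AUCPR} + \mathrm{AP}).$$

The precision-recall curve has one point per distinct score threshold
(descending; tied scores form one threshold; a row is predicted positive at
or above the threshold). Two estimators of its area are deliberately kept:

* **AUC-PR** — trapezoidal, after keeping the maximum precision at each
  distinct recall and prepending the anchor (recall 0, first precision).
  The dedup-and-anchor convention is ours: the raw curve can zigzag at a
  fixed recall, which makes a trapezoid ill-defined; the reduced curve is
  monotone in recall and integrable. The trapezoid can be optimistic.
* **Average precision** — $\sum_k (R_k - R_{k-1})\,P_k$ over the
  non-interpolated curve, which cannot be optimistic in that way.

Their mean is the optimization objective; the two agree closely for
well-behaved curves (a property test checks agreement within 0.05 on smooth
simulated score sets). Both equal the prevalence for uninformative constant
scores. Youden's J breaks cutoff ties toward the *lower* cutoff, favouring
sensitivity — the referral use-case. Confusion-matrix ratios with empty
denominators are reported as missing, never as zero.

Utilities are estimated by stratified k-fold cross-validation (default 10
folds). Fold assignment is seeded and fixed for an entire optimizer run, so
every pipeline is scored on the same partitions and utilities are comparable.

## The pipeline space

A pipeline is $P = \{I(\theta_I), F(\theta_F), M(\theta_M), C\}$: imputation,
feature processing, classification, calibration. The default registry ships
7 imputers (mean, median, most-frequent, EM on a Gaussian model, iterative
soft-thresholded-SVD matrix completion, chained-equations regression,
iterative random forest), 5 processors (identity, standardization, PCA,
correlation-based feature agglomeration, univariate selection), 6 classifiers
(regularized logistic regression, random forest, two gradient-boosting
variants, bagged trees, Gaussian naive Bayes) and 3 calibrators (sigmoid,
isotonic, none — calibrators have no hyper-parameters). Registries are plain
lists: components can be added, removed, or re-declared with different
domains. At the full published menu sizes (7, 14, 20, 3) the space counts
$7 \cdot 14 \cdot 20 \cdot 3 = 5{,}880$ pipelines; the count is always derived
from the registry, never hard-coded.

Hyper-parameter domains are conventional choices (tree counts 10–1000
log-scaled, PCA components 2–100 capped at the data dimension, learning rates
0.01–0.5 log-scaled, etc.) declared next to each component so any run is
reproducible from its serialized configuration. `screening_registry()` is a
compact variant (mean/median, identity/standardization, logistic +
gradient boosting bounded at 150 rounds and depth 4, none/sigmoid) that keeps
a full search affordable on cohorts of several thousand patients on one CPU
while retaining one linear and one tree-based learner.

Calibration is fit on an internal stratified 80/20 split of the training
fold: the first three stages are fit on the 80% part, the calibration map on
the held-out 20%, because calibrating on the classifier's own training rows
overfits the Brier score.

## Decoupled Bayesian optimization

The utility is approximated as
$\tilde U_c(C) + \tilde U(M(\theta_M), F(\theta_F)) + \tilde U_I(I(\theta_I))$
— the performance of imputers and calibrators is assumed not to interact with
the classifier/processor choice — which splits the search into three
independent problems, each with a Gaussian-process prior over its space.

**Kernel.** Each input is encoded as a categorical block (component
identities) plus a continuous block (hyper-parameters normalized to [0,1],
log-scaled dimensions on the log scale, inactive dimensions at the
midpoint). The kernel is the product of a Matérn-5/2 on the continuous block
and an exponentiated-overlap kernel $\exp(-w\,\#\text{mismatches})$ on the
categorical block; it is positive semidefinite and $k(x,x)$ equals the signal
variance. Matérn-5/2 is the conventional BO choice (twice-differentiable
sample paths).

**Acquisition.** Upper confidence bound $\mu + \kappa\sigma$ with
$\kappa = 2$ by default. Because utility is being *maximized*, the optimistic
(+) bound is the correct exploration direction. Acquisition is maximized over
a random candidate pool (default 500) rather than by gradient ascent — the
space is mostly categorical.

**Numerics.** The GP is zero-mean on internally centered observations (the
running mean is restored on output): a strictly zero-mean surrogate makes
every unexplored region maximally pessimistic and measurably degrades search
on planted landscapes. Posteriors use a Cholesky solve with observation
noise plus 1e-8 jitter, escalated tenfold until the Gram factorizes. Kernel
parameters (signal variance, length-scale, overlap weight, noise) are refit
every 5 iterations by bounded L-BFGS on the marginal likelihood. The first 5
iterations are random probes. Failed pipeline fits score utility 0 and the
search continues. Evaluations are memoized by serialized configuration, so
the small categorical imputer/calibrator spaces are not re-evaluated every
iteration.

**Scoring the decoupled terms.** The decoupled objective does not itself
determine how an imputer or calibrator is scored in isolation; we score $\tilde U_I$ as the
cross-validated utility of (imputer + identity processor + a fixed reference
classifier), and $\tilde U_c$ as one minus the cross-validated Brier score of
the calibrated reference pipeline — the decoupling assumption licenses a
fixed reference. Whether the original system fit one joint GP or
per-classifier GPs is not documented; the single mixed-kernel GP used here is
one admissible reading.

## The ensemble

Each explored (classifier, processor) configuration receives the posterior
probability that it is the best of all explored configurations, estimated
from joint (correlated) draws of the GP posterior at the explored points —
the probability-of-best event is joint, so independent marginals would be
wrong. Argmax ties in a draw split its weight equally. Members below the 0.01
weight threshold are pruned and weights renormalized (if everything falls
below the threshold, the single best member is kept). Weights are computed
from the cross-validation-era posterior *before* refitting, since the
posterior describes cross-validated utility; the surviving members — each
completed with the decoupled optimal imputer and calibrator — are then refit
on the full dataset. Prediction is the weighted arithmetic mean of member
risks.

## The interpreter

Risk strata partition $[0,1]$ into half-open intervals (default breakpoints
0.05 / 0.33 / 0.5: low, moderate, high, very high; a boundary score belongs
to the upper group, 1.0 to the last). Covariates are discretized by recursive
Fayyad–Irani splitting: a binary cut is accepted only when its information
gain clears the MDL coding cost $\bigl(\log_2(N-1) + \Delta\bigr)/N$. The
FEV1%-predicted column is forced to the clinical 30% threshold rather than
discretized automatically. Discretization is fit on the same data being
explained — the interpreter is descriptive, not predictive, so a held-out
split would only add variance.

Rules are grown greedily per stratum: at each length $k \le 3$, the current
antecedent is extended by the single condition maximizing confidence (ties:
higher conventional support, then lexicographic — the growth order is our
choice; the procedure is otherwise the greedy k-ruleitem scheme), and the
shortest antecedent meeting confidence ≥ 0.8 and support ≥ 0.2 is emitted;
longer, antecedent-subsumed extensions are dropped. *Support* follows the
group-prevalence definition (the prevalence of the consequent risk group),
which is rule-independent within a group; because that definition is unusual,
the conventional antecedent-and-consequent support is reported alongside as
`standard_support`. The interpreter operates on predictions and never alters
them (a test checks byte-identity of predictions before and after).

## Cohort machinery

Filters run in flow-chart order — age at baseline, prior transplant, lost to
follow-up — and the counts are returned as an arithmetic-checked flow
object. The age comparator is configurable with default "≥ 18 years" (the
inclusive reading is the one consistent with the published flow counts; the
narrative text also uses "more than 18 years old"). The composite endpoint is
death OR transplant within the horizon, counted once; pulmonary decline is
baseline FEV1% > 30, horizon FEV1% < 30, and no transplant, with missing
horizon values excluded rather than imputed. Genotypes become 9 binary
features (homozygosity, F508del and G551D carriage, and one flag per CFTR
functional class I–VI from the bundled exemplary class map); unknown
mutations contribute no class flags and raise a warning.

Baseline-table statistics: Fisher's exact test uses the probability-mass
two-sided convention (the dominant convention, and the one that reproduces
reported baseline-table p-values); the Mann-Whitney U test enumerates all
arrangements exactly for small samples (which handles ties exactly) and
otherwise uses the tie-corrected normal approximation with continuity
correction. External scores can be recalibrated in the large (intercept-only
log-odds shift matched to a target prevalence by a 1-D root find; exactly
rank-preserving) or by logistic recalibration (slope + intercept on the score
log-odds; separation is flagged and the slope capped at 50). Single-variable
importance re-runs a reduced search on one column at a time and reports
cross-validated AUC-ROC or AUC-PR — the two rankings can disagree, which is
precisely the point of reporting both.

## The synthetic generator

One latent severity factor $Z \sim N(0,1)$ drives everything: a
monotone-trended autoregressive FEV1% trajectory (five annual values plus a
horizon value), anthropometrics, and Bernoulli comorbidity/treatment flags
with log-odds linear in $Z$. The outcome log-odds are
$b_0 + 2.4\,Z + 1.2\,\text{oxygen} + 1.0\,[\text{FEV1\%}<30]$, with $b_0$
root-found so the marginal prevalence matches the specification (default
9.4% at n = 4,064, the study scale). The effect sizes were fixed once so that
a well-specified model attains cross-validated AUC-PR/average-precision near
the published registry-scale level (≈0.58) — i.e. the generator emulates a
cohort with the study's detectable signal, not an arbitrary easy or
impossible one. Oxygen therapy carries an outcome effect beyond FEV1 so that
precision-oriented importance can diverge from discrimination-oriented
importance. Missingness defaults to the published spirometric-trajectory
rates (31.0 / 20.0 / 15.5 / 6.2 / 4.4% from oldest to baseline year) and
anthropometric rates (2.1 / 1.4 / 2.9%), MCAR by default with an optional
severity-dependent MAR coefficient. An exact-event mode plants a fixed event
count by weighted sampling without replacement, used to reproduce reference
flow-chart counts exactly.

What the generator does **not** emulate: real registries have multi-factor
correlation structure, informative visit patterns, center effects, and
longitudinal dynamics far richer than one latent factor; a passing test on
synthetic data shows the machinery is correct under the stated model, not
that any particular clinical conclusion transfers. Planted utility
landscapes and planted-rule datasets are test harnesses: they expose their
ground truth (argmax, rules) so search and mining can be scored against it.

## Problem sizes used by the tests

The test suite and acceptance script choose sizes that exercise the method
honestly while remaining single-CPU-friendly: the planted-landscape check
runs 18 combinations × budget 30 × 10 seeds; rule recovery runs n = 5,000 ×
10 seeds; the end-to-end check simulates n = 4,064 at 9.4% prevalence and
searches 50 iterations over the screening registry with 3-fold inner
cross-validation, then re-runs identically-seeded to confirm bit-identity.
Budget-200, 10-fold configurations (the study defaults) are the package
defaults for real use.

## Known limitations

* The decoupling assumption ignores imputer×classifier and
  calibrator×classifier interactions; it buys a dramatically smaller search
  space at the cost of missing such interactions.
* Probability-of-best weights are Monte-Carlo estimates; with many
  near-equivalent members they carry sampling noise of order
  $1/\sqrt{n_\text{draws}}$.
* The greedy rule miner emits at most one rule per stratum per growth path;
  distinct co-existing rules for the same stratum require planting distinct
  strata or re-mining on subsets.
* Isotonic calibration can be piecewise-constant and ties many scores;
  downstream cutoff searches then see fewer operating points.
* The EM and matrix-completion imputers summarize the completed training
  matrix as a Gaussian for transforming new rows; heavily non-Gaussian
  covariates are imputed only to second-order accuracy.
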