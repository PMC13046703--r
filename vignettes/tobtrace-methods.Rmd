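---
title: "Methods: origin traceability from tobacco leaf chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: origin traceability from tobacco leaf chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tobtrace` discriminates the geographical origin of flue-cured tobacco
leaves from a 70-component chemical composition table and ranks the
components that carry the discrimination. This vignette documents the
models, the assumptions behind them, and every place where the package had
to make a methodological choice.

## The study design and what the generator emulates

The design the package targets has 1,717 samples in 13 origin classes:
nine Chinese provinces (Yunnan 360, Sichuan 103, Guizhou 157, Chongqing
92, Henan 206, Hunan 103, Fujian 124, Shandong 24, Heilongjiang 100) and
four countries sampled without sub-regions (United States 64, Brazil 129,
Zimbabwe 154, Zambia 101). Each sample carries 70 components in seven
categories (routine constituents, ions, polyphenols, poly/fatty acids,
amino acids, Amadori compounds, others), with heterogeneous units — %,
mg/g and µg/g span roughly four orders of magnitude.

The underlying measured data are proprietary; what is public is the
per-country mean ± SD of every component, plus a handful of
province-level means. `generate_chem_table()` therefore draws each
component of each sample from a normal distribution with the country mean
(plus a province offset) and the country SD.

Design choices, made once:

* **Independent Gaussian marginals.** Only marginal means and SDs are
  published; no between-component covariance is available, and inventing
  one would manufacture structure the data may not have. A user-supplied
  correlation matrix hook exists (`correlation =`), defaulting to the
  identity.
* **Province offsets.** For the nine Chinese provinces only a few
  province means are published (total alkaloids, reducing sugar, total
  sugar, total nitrogen for Hunan/Heilongjiang/Sichuan; Fru-Asn for Henan
  and Hunan; succinic acid for Heilongjiang; rutin for Sichuan).
  `default_region_offsets()` sets each offset to the difference between
  the published province mean and the China-wide mean, and zero
  elsewhere. `separation_scale` multiplies the offsets so 13-class
  difficulty is tunable — it is a free parameter of the synthetic design,
  not an estimate of the real provinces' separation.
* **Truncation.** Negative draws are truncated to zero (rather than
  re-sampled, which would complicate the single-seed reproducibility
  contract), and pH is clamped to (0, 14). For any component whose mean
  is at least two SDs above zero the truncated mass is negligible; the
  test suite verifies the induced mean shift stays far below 0.5 SD.
* **Noise features.** `n_noise_features` appends standard-normal columns
  drawn independently of all labels, used to calibrate the importance
  analysis.

What passing tests on this generator do **not** show about real data:
real components are correlated (sugar/Amadori chemistry couples many of
them), real distributions are skewed and heteroscedastic within classes,
and real provinces differ in many more components than the published
handful. Consequently region-level (13-class) accuracy on the synthetic
default is *by construction* bounded: provinces with no published offsets
are distributionally identical to one another. Country-level (5-class)
discrimination is fully determined by the published profiles and is the
meaningful synthetic benchmark.

## Univariate screening

`one_way_anova()` is the classical fixed-effects decomposition
(`F = MSB/MSW`, p from the F distribution), delegated to `stats::aov` and
checked in the tests against a brute-force sum-of-squares oracle. If the
pooled within-group variance is exactly zero while means differ the test
is degenerate; the package reports `F = Inf`, `p = 0` and a `degenerate`
flag instead of failing.

Post hoc comparisons use `stats::TukeyHSD`, whose unbalanced-group
standard errors are the Tukey–Kramer extension — relevant here, with
group sizes from 24 to 1269. The compact letter display is the
insert-and-absorb algorithm: letters are assigned so that two groups
share at least one letter exactly when they are *not* significantly
different, with letter groups ordered by their earliest member for
deterministic output. The suite verifies this equivalence exhaustively
for all 3- and 4-group significance patterns.

Significance categories are right-closed: `***` for p ≤ 0.001, `**` for
0.001 < p ≤ 0.01, `*` for 0.01 < p ≤ 0.05, `ns` above. The published
table's footnote mixes strict and non-strict inequalities at the
boundaries; the package standardizes on the one explicitly non-strict
form (p ≤ 0.001) and applies it to every bin edge.

No multiplicity correction is applied across the 70 components; the
screening mirrors a per-component mean-comparison table, not a
familywise inference.

## Profile clustering

`mean_profiles()` averages each component within each region;
`pearson_distance()` computes `d(i, j) = 1 − r(i, j)` across the 70
components (range [0, 2]; constant profiles are rejected since their
correlation is undefined); `agglomerate()` wraps `stats::hclust`.

Choices: the linkage is **average** (UPGMA) by default — the common
default for correlation distances — with single and complete available;
Ward is excluded because it assumes squared Euclidean input. Components
are correlated **as-is**, without per-component standardization, because
correlation distance is already location/scale-invariant per profile
pair; an optional `scale_components` switch exists for users who want
large-magnitude components (µg/g Amadori compounds) not to dominate the
correlation. With profiles on means of hundreds of samples the topology
is stable, but the exact dendrogram of the real study is only
qualitatively reproducible since its linkage and scaling were not
recorded.

## Kernels

Five families, written for row vectors:

| family | form |
|---|---|
| linear | `x1 · x2` |
| polynomial | `(c1 · x1 · x2 + c2)^c3` |
| gaussian | `exp(−‖x1 − x2‖² / σ²)` |
| sigmoid | `tanh(a · x1 · x2 + c)` |
| hybrid | `m·linear + n·polynomial + q·gaussian`, `m + n + q = 1` |

Numerical choices:

* σ² divides the squared distance **directly** (no factor 2), following
  the printed kernel form rather than the common `2σ²` convention; the
  search range [10, 50] is interpreted on that scale.
* The sigmoid is not part of the hybrid mixture (the hybrid is defined
  over the three Mercer components only). `check_psd()` exists as a
  Mercer guard: the sigmoid Gram can be indefinite, which is reported as
  a flag, not an error.
* Fractional polynomial degrees (the search range allows any c3 in
  [2, 4]) floor the base at zero before exponentiation to stay real;
  integer degrees use the raw base, so the degree-1, `c1 = 1, c2 = 0`
  kernel is exactly the linear kernel.
* The hybrid weights must sit on the simplex to within 1e-9; the Gram is
  computed as the entrywise weighted sum, verified in tests to 1e-12.

## The SVM and its baselines

`train_svm()` solves soft-margin binary subproblems on the precomputed
Gram with the SMO solver in `kernlab`, under either pairwise one-vs-one
voting (default; ties broken by the aggregated signed decision score) or
one-vs-rest. The binary label factors keep default (alphabetical) level
order: `kernlab::ksvm` on a precomputed kernelMatrix converges to a wrong
solution when the factor's level order is customized, a behaviour the
test suite pinned down empirically; the decision sign of each machine is
therefore calibrated against the training decisions rather than assumed.

Unrecorded parameters, fixed as package defaults: the soft-margin cost
`C = 1` (exposed, and appendable to the tuning space by the user);
one-vs-one decomposition (the classical choice for kernel SVMs);
**z-score standardization fitted on the training split** — without it a
Gaussian width of 10–50 is meaningless when µg/g components have
variances 10⁶ larger than % components.

The BPNN is a fully connected ReLU network (1–5 hidden layers of 2–40
neurons, the tuned ranges), softmax output, cross-entropy loss, mini-batch
Adam at the tuned learning rate (0.001–0.1), with a stratified 10%
validation carve-out for early stopping and best-epoch weight restoration;
it is implemented in the package because no installed R package provides
multi-hidden-layer MLP classification. The RF baseline wraps
`randomForest` with the tuned ranges (50–200 trees, leaf size 2–10). Both
are deterministic under their `seed`.

## Particle swarm tuning

The swarm follows the canonical update
`v ← w·v + 1.5·r1⊙(pbest − x) + 1.5·r2⊙(gbest − x)` with `w` decaying
linearly from 0.9 to 0.4 across iterations and `r1, r2 ~ U[0, 1]`.
Positions are clamped to the box, integer dimensions rounded, and the
hybrid weights renormalized onto the simplex after every move (re-seeded
uniformly if their sum collapses below 1e-6) — the simplest projection
that preserves the per-coordinate [0, 1] boxes. Velocities are clamped at
half the box width per dimension, a standard stabilization.

The fitness is the mean accuracy of stratified five-fold cross-validation
on the training split. Folds are drawn **once** per tuning run and reused
for every candidate so fitness values are comparable across the swarm;
fitness evaluations are wrapped in an RNG shield (the global random state
is saved and restored) because seeded learners would otherwise freeze the
swarm's own random factors. Swarm budget is not part of the published
method; the defaults are 30 particles × 50 iterations, and the package's
own demonstrations and tests use reduced budgets (e.g. 10 × 10) chosen as
reasonable smoke-scale settings. The optional `fitness_tolerance` early
stop is off by default — the method mentions a satisfactory-fitness
termination without defining it, so none is invented.

## Evaluation metrics

`stratified_split()` rounds each class's test allocation half-up, then
adjusts the largest class so the global test count is exactly
`round(N × fraction)` — deterministic and within one sample per class of
the target share. `stratified_kfold()` deals shuffled class members
round-robin from a rotating start; a class smaller than `k` triggers a
warning since it cannot reach every fold.

From a confusion matrix, accuracy is trace/total; per-class recall,
precision and F1 are standard; **macro-F1 is the harmonic mean of
macro-recall and macro-precision** (not the mean of per-class F1 — the
two differ, and the package implements the former deliberately, matching
the reference formulation). A class with zero predicted positives gets
precision 0 with a warning rather than NaN; with a 24-sample class in a
13-class table, this is reachable in routine runs. The multiclass AUC is the
macro-averaged one-vs-rest rank-sum AUC with midrank ties, verified
against exhaustive pair counting.

## Permutation feature importance

The loss is `1 − macro one-vs-rest AUC` of the model's score matrix. For
each component and repeat (default 10), the component's column is
shuffled **within the evaluation split** and the loss recomputed; the
model is never refit, because the method measures the degradation of the
*trained* model's performance, not the component's refit value.
Importance is the mean loss increase over repeats (± SD), ranked
descending with name-ordered tie-breaks. The evaluation split is the
held-out test set of the interpreted model, avoiding training-set
optimism. On synthetic tables with planted informative components the
suite requires all five planted components inside the top 10 in at least
90% of 20 seeded runs.

## Pipeline and reproducibility

`run_pipeline()` chains generate → screen → cluster → split → tune →
train → evaluate → interpret, persisting every artifact and a JSON
report. All stage seeds derive from the single config seed by fixed
offsets and are echoed in the report; two runs with the same config are
bit-identical. Every default the method leaves open (C, swarm budget,
linkage, repeats) is printed into the report so the gaps stay auditable.

## Problem sizes used by the tests

The suite exercises the full 1,717-sample generator for the marginal
recovery and screening checks (seconds), and uses reduced designs
elsewhere as the package's own smoke-scale choices: 2–3% scale pipelines
with 2–3 particles × 2 iterations for bit-reproducibility, a 20-seed ×
70-component linear-SVM study for the importance property, and a 20 × 50
swarm on the sphere benchmark for convergence.

## Known limitations

* Independent-Gaussian synthesis cannot reproduce real covariance-driven
  phenomena (e.g. correlated permutation importance deflation).
* Province-level separation beyond the published offsets is a free
  parameter; 13-class accuracies on synthetic defaults are not estimates
  of real-data performance.
* The SVM score aggregation for one-vs-one is a heuristic (signed
  decision sums) — adequate for AUC-based importance, but not calibrated
  probabilities.
* The sigmoid kernel is non-Mercer for parts of its parameter range; the
  solver may still return a model, and `check_psd()` is the intended
  guard.
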