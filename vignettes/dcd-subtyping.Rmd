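---
title: "Multivariate subtyping of developmental coordination disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate subtyping of developmental coordination disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcdtype)
```

## The problem

Developmental coordination disorder (DCD, dyspraxia) is diagnosed from wide
batteries of neuro-psychological, neuro-psychomotor and neuro-visual tests.
Clinically, three subtypes are distinguished: ideomotor dyspraxia (IM),
visual-spatial and constructional dyspraxia (VSC), and a mixt form (MX) that
combines both profiles with additional coordination and dexterity deficits.
Each child's battery reduces to 49 binary items (0 = success, 1 = failure,
from percentile or SD cut-offs), so the data are a subjects × items 0/1
matrix with a 3-level diagnosis. Two questions drive the analysis:

1. **Feature extraction** — which of the 49 items actually discriminate the
   subtypes, so that a shorter battery could be used?
2. **Patient typology** — do children cluster into groups that agree with
   the clinical subtypes, and how tight and stable are those groups?

Cohorts of this kind are small (tens of children) while the item set is
large and correlated, which is why the pipeline leans on two multivariate
learners that tolerate `n < p`-style regimes: random forests and partial
least squares discriminant analysis (PLS-DA), plus a sparse PLS-DA variant
that performs item selection inside the fit.

`dcdtype` implements that pipeline end to end, driven by a synthetic cohort
generator, with tidyverse-style interfaces: cohorts are tibbles, fitted
objects have `tidy()`/`glance()` methods, and results plot with
`autoplot()`.

## The models

### Random forest

The forest is grown from scratch for binary predictors: each of `ntree`
unpruned trees is fit on an `n`-out-of-`n` bootstrap sample; at every node
`mtry` items are drawn without replacement and the split minimising the
weighted Gini impurity of the two children is taken (a binary item admits
exactly one split, 0 vs 1). Growth stops only at purity, when no sampled
split strictly reduces impurity, or when a child would be empty. Prediction
is majority voting; ties break by the fixed class order IM < VSC < MX so
results are reproducible (reference implementations break ties randomly —
a deliberate, documented divergence).

Because each tree ignores about a third of the subjects, the out-of-bag
(OOB) subjects give an honest error estimate, and permuting one item's
values among a tree's OOB subjects measures that item's contribution to
accuracy (*mean decrease in accuracy*, overall and per true class; items a
tree never uses contribute exactly zero). Subjects that happen to be in-bag
for every tree receive no OOB vote; they are skipped and counted rather
than silently imputed. The proximity of two subjects is the fraction of
trees in which they share a terminal node; `1 - proximity` feeds a
classical (Torgerson) metric MDS, with negative eigenvalues truncated at
zero and each coordinate's sign fixed so the largest-magnitude entry is
positive. Validation subjects are projected into the training MDS space
with Gower's add-a-point formula — the reason the MDS is implemented via an
explicit eigendecomposition rather than `cmdscale()` (which agrees with it
on embeddable inputs, and is used as an oracle in the tests).

### PLS-DA and sparse PLS-DA

The diagnosis is dummy-coded into an indicator matrix `Z` (one column per
class, rows summing to 1). NIPALS extracts components `k = 1..K`: a
unit-norm weight vector maximising the covariance between the deflated item
block and centered `Z`, a score vector, and deflation of the item block by
regression on the score, which makes the scores mutually orthogonal.
Iterations stop when the weight vector changes by less than `1e-12`
(capped at 500 iterations; hitting the cap flags the component as
non-converged but is not fatal). When deflation exhausts the item block
before `K` components, the model truncates and records the fact.

The sparse variant applies a soft-thresholding rule to the weight vector
*inside* every NIPALS iteration: with threshold `t = eta * max|w|`, each
entry is shrunk by `t` towards zero and the result renormalised. `eta = 0`
reproduces the unpenalised fit exactly; as `eta` grows, the support
shrinks monotonically down to a single item per component. The union of
items with a nonzero weight on any component is the *selected set* — the
model's feature extraction. An elastic-net formulation motivates this kind
of penalty, but the implemented sparsity is the NIPALS soft-thresholding
rule itself, parameterised directly by the fraction `eta` the tuning grid
uses.

Classification functions map raw item values to one score per class
(intercepts absorb the centering); the scores are pushed onto the unit
simplex with an exponential softmax and the predicted class is the argmax
(ties again break by class order). The softmax is one reading of
"rescaled to [0, 1] with unit sum"; a linear min–max rescaling is exposed
as `transform = "linear"` and picks the same class whenever the raw scores
are distinct, so the choice is immaterial for classification.

Items are centered but **not** scaled to unit variance by default: all
items live on the same 0/1 scale already, and dividing by the standard
deviation would inflate the influence of rare items. Because the original
toolchain's defaults differ on this point, scaling is exposed as
`scale = TRUE`.

Uncertainty for the sparse coefficients comes from `B` stratified
(per-class) bootstrap refits with percentile 2.5/97.5% bounds (the CI
flavour is a package choice; nothing in the method dictates one).
Non-converged refits are skipped and counted; more than 10% skips raises a
warning.

### Model selection and importance testing

Hyperparameters are tuned by stratified, repeated 10×5-fold
cross-validation ("10×5" read as 10 repeats of 5-fold, i.e. 50 held-out
evaluations — the idiom of the usual machine-learning toolchains; when the
smallest class has fewer members than the fold count, the folds shrink to
that size with a warning). The criterion is mean held-out accuracy; ties
resolve to the least complex setting. The grids are: 10 `mtry` values
evenly spaced over `[2, p]` with `ntree` fixed at 500; `K = 1..10` for
PLS-DA; and `K = 1..10` crossed with 10 uniformly spaced `eta` strictly
inside (0.3, 0.9) for sparse PLS-DA. Accuracies of two tuned models on the
same resampling plan are compared with a paired t-test,
Bonferroni-corrected over the number of model pairs; fold-level accuracies
are positively correlated, so the test is anti-conservative, which is
documented rather than corrected (no Nadeau–Bengio-style variance
adjustment).

The significance of variable importance is assessed by permutation: class
labels are exchanged `B = 999` times, the importance recomputed each time,
and `p = (1 + #{null >= observed}) / (B + 1)` — one-sided, since only large
importance is meaningful, and never zero by the add-one convention.

### Clustering fitness

The typology lives in a component-score space — the sparse PLS-DA scores
(Euclidean distance), or equivalently the first MDS coordinates of the
forest proximities. PAM (k-medoids, BUILD + SWAP via the `cluster`
package) partitions the training subjects; the number of clusters
maximises the average silhouette width (ASW) over `k = 2..7`, ties to the
smaller `k`. Singleton clusters take silhouette 0 by the standard
convention. Note that BUILD + SWAP is a local search: on rare tiny
configurations it terminates in a swap-local optimum above the global
best, which the tests exercise explicitly against an exhaustive oracle.

Stability is Hennig-style bootstrap reclustering: subjects are resampled
with replacement, PAM re-run with the *same* `k` (the question is the
stability of the original solution, not of `k` itself), and each original
cluster scored by its best Jaccard match among the new clusters, computed
on deduplicated subject identities after restricting the original cluster
to subjects present in the resample. Isolation follows the L/L*
definitions: a cluster is L* iff its diameter is smaller than its
separation, and L iff every member's farthest within-cluster neighbour is
nearer than any outside observation (L* implies L). Cluster affinity for
validation subjects is the Euclidean distance to each training medoid
after projecting them into the training score space (PLS: centered with
training means, multiplied by the training weights; RF: Gower projection),
reported per expected cluster with a flag for whether the own medoid is
nearest on average.

## The synthetic cohort generator

No patient-level data are distributed with studies of this kind, so the
generator is a first-class module that emulates the study conditions: 63
children with class priors 8% IM / 52% VSC / 40% MX (allocated by the
largest-remainder rule so the 5-child IM class never vanishes from a small
cohort), 49 items named by the clinical acronyms, and the class-conditional
impairment pattern reported clinically — IM children fail digital
perception (DIPE), imitation of gestures (IMOG), digital praxia (DIPR) and
synkinesis (SYNK); VSC children fail lego blocks (LEBL), puzzles (PUZL)
and the visuo-spatial/constructional items (VISS, VISC, VIMI); MX children
fail the union plus coordination between upper and lower limbs (CULL) and
manual dexterity (MAND). Those 11 items are the planted discriminative
set. Impaired-class failure probabilities default to 0.9 and
unimpaired-class ones to 0.1 — a strong, clean effect matching the
near-deterministic impairment patterns the conditional-frequency heatmaps
of real batteries show. The remaining 38 background items get
class-independent probabilities drawn once per spec uniformly from
[0.08, 0.92], anchored to the reported range of marginal failure rates
(7.9%–92.1%); no finer calibration exists to copy.

Dependence between items is a Gaussian copula with one shared latent
factor per subject mixed into every item's latent normal with weight
`sqrt(latent_correlation)`; thresholding at each item's normal quantile
gives correlated Bernoullis. The default `latent_correlation = 0.3`
produces within-class phi correlations centred near 0.1–0.2, consistent
with the reported inter-item correlation profile (range roughly −0.4 to
0.8 with median ≈ 0.09, once the between-class signal is added). A single
shared factor is the simplest mechanism that reproduces such a range; it
does **not** reproduce block-structured correlations between functionally
related tests, item difficulty gradients by age, or missingness — so
passing tests demonstrate that the pipeline recovers structure of this
planted form, not that it would behave identically on any real battery.

Generation is bit-for-bit reproducible from the spec's seed, and specs
serialize to JSON.

## Problem sizes used by the tests

The test-suite simulations run at sizes chosen to make their statistical
assertions sound at desk scale: parameter-recovery checks use 50
replicates of an `n = 200` cohort (sparse selection of the 11-item set
with at most 3 false positives; forest importance ranking all planted
items above all noise items; silhouette-selected `k = 3` on the sparse
scores); the permutation-test size check uses 200 replicates of a null
12-item cohort at `B = 199` with forest importance at `ntree = 100` —
super-uniformity holds for any statistic under label exchangeability, so
the smaller forest changes nothing but runtime; the Monte-Carlo χ²
validity check pools 500 random splits of a null 49-item cohort at
`n_mc = 199`. The end-to-end run mirrors the full analysis on one seeded
63-subject cohort: 0.7/0.3 stratified split, nested-CV tuning of all three
classifiers, importance screening with `B = 999` permutations, PAM
typology with 500-resample stability, and validation affinity.

## Worked pipeline

```{r pipeline, eval = FALSE}
library(dcdtype)

cohort <- generate_cohort(dcd_spec_paperlike(63, seed = 1))
split <- stratified_split(cohort, 0.7, seed = 2)
train <- cohort[split$training, ]
valid <- cohort[split$validation, ]

plan <- repeated_stratified_kfold(train$diagnosis, 5, 10, seed = 3)
tn <- tune_grid(train, fit_predict_spls(), grid_spls(10), plan)
spls <- fit_splsda(train, K = tn$best$K, eta = tn$best$eta)
spls$selected_items

mean(predict(spls, valid) == valid$diagnosis)

sol <- choose_k(pls_scores(spls), 2:7)$solution
bootstrap_stability(sol, B = 500, seed = 4)
isolation_classify(sol)
cross_classification(sol$assignments, train$diagnosis)
```

## Numerical choices and edge cases

* NIPALS: tolerance `1e-12` on the weight change, 500-iteration cap,
  non-convergence flagged, exhausted deflation truncates `K`.
* Constant items are harmless everywhere: they get zero PLS weight (and a
  degenerate [0, 0] bootstrap interval), are never chosen as splits, and
  take the undefined-correlation sentinel `NA` in the item summary,
  excluded from range and median summaries.
* Monte-Carlo χ² tests simulate the permutation null with fixed margins
  via the equivalent hypergeometric draw; constant items take `p = 1` by
  convention, and all permutation p-values use the add-one convention.
* All stochastic steps (generation, splitting, fold construction, forest
  growth, permutations, bootstraps) take explicit integer seeds and
  restore the caller's RNG state.
* A stratified split that would empty the validation set errors out
  instead of proceeding, since every downstream fitness measure needs
  validation data.

## Known limitations

* The generator's single-factor copula understates structured inter-item
  correlation; recovery rates on real batteries with block correlation may
  differ.
* The paired resampled t-test for model comparison is anti-conservative on
  correlated folds.
* Per-class importance averages over trees with at least one OOB subject
  of that class; with very small classes and few trees the estimate is
  noisy, which is also why OOB-unvoted subjects are reported rather than
  hidden.
* PAM inherits BUILD+SWAP's local-search character; for the tiny score
  spaces used here this matters only in adversarial configurations.
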