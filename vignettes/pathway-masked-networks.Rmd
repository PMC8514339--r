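---
title: "Pathway-masked sparse networks: model, training and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-masked sparse networks: model, training and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pnet` classifies tumour samples (primary versus metastatic/castration-
resistant) from gene-level somatic alterations, using a feed-forward
network whose connectivity is not learned but fixed by curated biology.
Nodes are biological entities — features, genes, pathways, biological
processes — and an edge exists only where the annotation databases assert
a relation. Each layer computes

y = f[(M * W)^T x + b],

where `W` is the trainable weight matrix, `M` the fixed binary mask, `*`
the Hadamard product, `b` the bias and `f = tanh`. Because `M` multiplies
`W` both in the forward pass and in the gradient, masked-out weights are
inert: the model has only as many effective parameters as there are
curated relations, orders of magnitude fewer than a dense network over
the same nodes (`count_params()` reports both, with dense weights
`w_l = n_l (n_{l-1} + 1)`).

The layer stack is: one feature layer (3 nodes per gene: mutation,
copy-number amplification, deletion, each wired one-to-one to its gene),
one gene layer, and `n_pathway_layers` pathway strata of increasing
abstraction (default 5). After every hidden layer a 1-unit sigmoid head
produces a layer-wise probability; the model's score is the arithmetic
mean of all head probabilities. The heads serve two purposes: every layer
is forced to be predictive on its own, and deep, narrow layers are kept
under direct supervision instead of relying on a long gradient path.

### Assumptions

* Inputs are binary or small counts; the mutation channel is binarized by
  default because tanh units saturate on raw counts.
* Only high-level copy-number events carry signal: amplification means a
  GISTIC call of exactly +2, deletion exactly −2; single-copy events map
  to zero. Mutations classified as silent, intronic, UTR, RNA or lincRNA
  are excluded before aggregation.
* The annotation hierarchy is a DAG over pathways; gene sets attach genes
  to pathways. Annotation quality bounds model quality: the masks are
  hard constraints.

## Compiling the hierarchy into layers

Pathways are stratified by their shortest child→parent distance to the
layering origin. When the relation table has a single root, that root is
the origin and is not itself a mask node; with several top-level
processes an implicit origin sits above them, so the top-level processes
occupy the last layer and feed the outcome heads directly — no artificial
super-root enters the masks. Choices made where the underlying databases
are messier than a strict layering:

* **Truncation.** Pathways deeper than the retained strata are collapsed
  onto their ancestor at the deepest retained stratum (walking parents,
  preferring the shallowest and then the lexicographically smallest), and
  their gene annotations travel with them, so truncation never removes
  gene coverage.
* **Copy nodes.** A gene annotated to a pathway above the gene-adjacent
  stratum reaches it through identity "copy" nodes (`id..copyD`), one per
  intermediate stratum, each wired one-to-one. This keeps every mask
  strictly layer-adjacent, which the forward equation requires.
* **Backward relations.** In a DAG a pathway's recorded parent can sit at
  the same or a greater depth than the pathway itself (the child also has
  a shorter route to a root). Such relations cannot be drawn in a
  stratified mask and are dropped with a warning; they are rare and never
  disconnect a node, because by construction every non-top pathway has a
  parent exactly one stratum up.
* **Determinism.** Node order within a layer is lexicographic, so two
  compilations of the same inputs are byte-identical — a requirement for
  seeded reproducibility downstream.

## Training protocol

The loss is class-weighted binary cross-entropy summed over heads with
per-head loss weights, minimized by Adam:

* `lr_init = 0.001`, reduced every 50 epochs by `lr_drop_factor`.
* Class weights `w_c = N / (2 n_c)` counter the class imbalance of the
  cohort (about 1:2 metastatic:primary).
* Head loss weights default to a geometric ramp `1, 2, 4, ...` so the
  deeper, narrower layers — which are harder to fit — weigh more.
* Probabilities are clipped at `1e-7` inside the loss; no dropout or L2
  by default (an optional L2 on masked-in weights is exposed).
* Weight initialization is uniform Glorot-style with the fan-in taken
  from the **mask**, not the dense shape: a unit with 3 biological inputs
  is initialized as a 3-input unit.

Two defaults were set by convergence experiments rather than convention:
`batch_size = 10` and `lr_drop_factor = 0.75`. With a few hundred
training samples, larger batches give so few Adam updates per epoch that
an aggressively halving schedule freezes the sparse model before its
training loss has converged (the dense comparator, with the same step
budget, converges easily — a bias in the comparison, not just a quality
loss). Small batches plus the gentler decay restore convergence at the
stated initial rate; on cohorts of a thousand samples the step budget is
generous either way. When validation data are supplied to `train_pnet()`
the weights of the best-validation-AUC epoch are restored at the end;
training is bit-reproducible given the config seed.

For external-style prediction on unseen cohorts,
`train_balanced_ensemble()` trains members on class-balanced subsamples
(all minority samples plus an equal-size majority draw, disjoint draws
when possible) and averages their scores.

## Interpretation

`deeplift_scores()` implements backward multiplier propagation with the
rescale rule: linear (masked) operations pass multipliers through
`M * W`; each nonlinearity contributes `(f(z) − f(z0)) / (z − z0)`,
falling back to `f'(z0)` when `|z − z0| < 1e-7`. The reference input `x0`
is the all-zeros profile — the natural "no alteration" baseline for
binary genomic features. The explained target is the averaged outcome.

One subtlety follows from the multi-head architecture: a head attached
below a given layer is not a function of that layer, so the full outcome
difference cannot decompose over that layer's nodes. Explaining a layer
therefore holds the bypassing heads fixed at their sample values, and the
decomposable difference for layer l is the summed probability change of
the heads at or above l. `delta_t` is returned per layer, the
completeness identity `sum_i C_i = delta_t` holds for every layer and
sample (to floating-point accuracy away from the fallback branch), and
for the feature layer `delta_t` is the full outcome difference.

Node importance aggregates sample scores as `C = |sum_s C_s|` — opposite
signs cancel, as intended for a population-level score. To counter
over-annotation bias, a node whose degree (mask fan-in + fan-out, heads
excluded) exceeds its layer's mean by more than five population standard
deviations has its score divided by its degree. Ranks are dense integers
by descending adjusted score, ties broken lexicographically by node id.
`node_activation_analysis()` complements attribution with per-node Welch
t statistics of activations by class; nodes with zero variance in both
classes (for example zero fan-in nodes, whose activation is the constant
`tanh(b)`) are flagged degenerate with statistic 0 rather than dropped.

## Evaluation and statistics

Splits are stratified 80/10/10 (per-class test counts `round(n_c/10)`;
the validation set matches the test size), cross-validation is stratified
k-fold, and metrics are AUC (rank statistic with midrank ties), AUPRC
(step-interpolated), and 0.5-threshold accuracy/F1/precision/recall, with
undefined precision reported as 0 and flagged. Model comparisons use the
hand-implemented DeLong test for paired AUCs (zero-variance differences
give p = 1) and a stratified bootstrap (default 2,000 resamples) for the
other metrics, two-sided with add-one smoothing, so the smallest
attainable p at 2,000 resamples is 1/2001. Families of p-values are
adjusted by Benjamini–Hochberg. Learning curves compare fold scores
between models with the equal-variance t-test; when both arms have zero
variance the p-value is reported as 1 if the means agree and 0 otherwise
(the self-comparison convention). The 2×2 chi-squared uses the Yates
correction clamped at zero, and the two-group log-rank test is delegated
to the survival package.

## The synthetic cohort generator

`sim_config()`/`generate_cohort()` emulate the study inputs end to end: a
rooted pathway hierarchy (default 18 leaf pathways, 6 and 2 above, one
origin root; branching cap 3), disjoint gene sets of 6 genes per leaf
(108 genes), cohorts of 1,000 samples at 33% class-1 — the real cohort's
metastatic fraction — and planted signal: `n_drivers = 3` leaf pathways
whose genes are altered with probability `p1 = 0.3` in class-1 samples
against a background `p0 = 0.05`. An altered gene-sample pair receives
exactly one channel drawn from `channel_mix = (0.5, 0.3, 0.2)`
(mutation/amplification/deletion), so amplification and deletion are
mutually exclusive as in real gene-level GISTIC calls.

What the generator deliberately does **not** emulate: real mutation
spectra and gene-length effects, co-occurrence and mutual-exclusivity
structure between drivers, overlapping gene sets (available via options
but off by default), multi-parent pathways (cross-edge rate 0 by
default), and co-occurring mutation plus copy-number hits in one gene.
Passing tests on generated cohorts therefore demonstrates that the
machinery — compilation, optimization, attribution, statistics — behaves
as specified under planted signal; it does not certify performance on
real tumour profiles, where annotation error and correlated noise
dominate.

Problem sizes in the test suite are chosen to exercise every code path
on a single CPU: planted-signal comparisons at n = 150 with 5-fold CV
over 5 seeds, driver recovery at n = 800, null calibration with 200 label
permutations of 2,000-resample bootstraps. The accompanying
`scripts/acceptance.R` reruns the full pipeline (1,000 samples, default
conditions) from a single seed.

## Numerical choices, in one place

* Probability clipping `1e-7` in the loss; rescale fallback threshold
  `1e-7`; completeness verified at 1e-4 relative tolerance in tests.
* Mask-fan-in Glorot initialization, uniform in `±sqrt(6 / fan_in)`.
* Adam `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`.
* Degree adjustment uses the population standard deviation per layer;
  degree 0 can never exceed the threshold, so no division by zero.
* Checkpoints are a single JSON container (full precision) holding
  masks, weights, biases, head parameters, node lists and history — a
  portable, diff-able, self-describing serialization.
* Empty inputs: an empty relation table compiles to an empty hierarchy;
  an empty gene overlap is a hard "empty gene layer" error; a sample
  intersection of zero between mutation and copy-number sources is a
  hard error; single-class label vectors are errors wherever a
  two-class quantity is requested.

## Known limitations

* The layer-collapse and copy-node rules are this package's choices;
  reproducing the exact node counts of any particular published
  compilation additionally requires that publication's preprocessing.
* Training is plain R matrix algebra: comfortable up to a few thousand
  genes and samples on one CPU, not a GPU-scale implementation.
* Only the three stated feature channels are implemented; the tensor
  layout is extensible but expression/fusion channels are out of scope.
* The bootstrap comparison resamples within class to keep ranking
  metrics defined; with very small test sets its p-values are coarse.
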