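---
title: "Two-round gene selection and attention-based CNN classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-round gene selection and attention-based CNN classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attbiomarker)
```

## The problem

Case/control expression studies (microarray or RNA-seq on the log2 scale)
measure thousands of genes on a few dozen samples. Classifying such data —
for instance, preeclamptic versus normotensive pregnancies from blood or
placental profiles — runs into two obstacles: the curse of dimensionality
(far more genes than samples) and redundancy (co-expressed genes carry the
same information many times over). `attbiomarker` implements a workflow that
tackles both: a permissive per-study p-value prefilter, two rounds of
supervised feature selection (a univariate Fisher-criterion filter, then a
redundancy-aware mRMR reranking), and an attention-based 1-D convolutional
classifier used to score candidate subsets. Downstream, selected subsets are
intersected with differential-expression calls and, when an interaction
network is available, ranked by degree to nominate hub genes.

## Stage 1: prefiltering and the common matrix

Each study contributes a per-gene statistics table — either computed
internally by `per_gene_welch_t()` (Welch two-sample t with
Welch–Satterthwaite degrees of freedom and `log_fc` = case mean − control
mean) or ingested verbatim from an external differential-expression tool via
`read_gene_stats()`. The package deliberately does **not** reimplement the
empirical-Bayes moderated t-test; users who filtered their real data with
moderated statistics should supply those tables so the filters reproduce
their numbers exactly. Welch's test is the built-in stand-in: it is exact
under the same Gaussian model the simulator uses and agrees with
`stats::t.test` to ten decimal places in the test suite.

`filter_by_pvalue()` keeps genes with p strictly below a permissive
threshold (default 0.25 — the point is to hand a broad candidate pool to
the supervised stages, not to make significance claims), and
`build_common_matrix()` intersects the per-study survivor sets and stacks
all samples into one matrix S (samples × genes, gene columns sorted
lexicographically). No batch correction is applied — the workflow treats
study effects as part of the noise the selection stages must overcome — and
the function warns accordingly.

The "adjusted vs raw p-value" question is left to the caller: filters
operate on whatever `p_value` column they are given.

## Stage 2, round 1: Fisher scores

For gene $i$ with classes $x = 1..L$ of sizes $q_x$:

$$f(i) = \frac{\sum_x q_x\,(\mu_i^x - \mu_i)^2}{\sum_x q_x\,(\sigma_i^x)^2}$$

with *population* (divide-by-$n$) standard deviations. This convention is a
deliberate choice: the subset-level trace criterion
$f(S') = \mathrm{tr}(M_b)/\mathrm{tr}(M_w)$ uses unnormalized scatter sums,
and with population variances the single-gene score and the single-gene
trace ratio coincide exactly — a property the test suite asserts. The
within-class scatter $M_w$ is the standard pooled form
$\sum_j (z_j - \bar\mu_{\mathrm{class}(j)})(z_j - \bar\mu_{\mathrm{class}(j)})^T$;
a "total scatter" variant (deviations from the grand mean) is sometimes
printed in the literature but measures within+between jointly, so the
standard form is used here.

Degenerate genes are handled explicitly: no variance and no separation
scores 0; positive separation over zero variance gets an `Inf` sentinel
that sorts above all finite scores (ties among sentinels by gene index).

Subset sizing automates what is usually done by eye on the sorted score
curve: `detect_deflection()` min–max normalizes both axes and returns the
interior index with the maximum perpendicular distance to the chord joining
the curve's endpoints (the Kneedle construction). Curves with no knee —
constant or near-linear decay — return "keep everything" with a warning.
Because published analyses typically chose subset sizes by visual
inspection, explicit size grids (e.g. 5000/4500/4000/3500 on a ~5300-gene
matrix) remain first-class inputs everywhere the automatic knee is offered.

## Stage 2, round 2: mRMR

Round 2 reranks the round-1 winner by greedily maximizing the difference
form (MID) of the mRMR objective:

$$\max_{f \in \Phi_t}\Big[ I(f, t) - \tfrac{1}{m}\sum_{f_i \in \Phi_s} I(f, f_i) \Big]$$

The quotient form is intentionally not offered. Mutual information is the
plug-in estimator on discretized expression: per-gene equal-frequency
binning with $B = 5$ bins by default, natural-log units, label treated as an
already-discrete variable. Classic mRMR practice discretizes continuous
inputs; the bin count and an equal-width alternative are configuration
knobs rather than findings — nothing in the method's source pins the
estimator, so the package declares its defaults instead of guessing.
Duplicated quantile edges on heavily tied genes are collapsed (realized bin
counts are recorded), constant genes collapse to a single code and are
flagged. The first pick is pure relevance (redundancy over the empty set is
defined as 0); ties break by ascending gene index so runs are reproducible.

One estimator subtlety is worth recording. If a candidate feature is an
*exact copy* of the binary label, then for any third feature $f$ the
relevance $I(f, t)$ and the redundancy $I(f, \text{copy})$ are computed on
identical partitions and cancel exactly, so "noise beats duplicate" is
decided by the tie-break, not the objective. The redundancy penalty shows
its teeth as soon as the informative feature is continuous (its 5-bin
partition is finer than the label's): a duplicate then pays $\approx H(f_1)$
in redundancy against $\le H(t)$ in relevance and drops behind independent
noise — the configuration the tests pin down.

## The classifier

The AttCNN consumes a sample's $p$ selected genes as a length-$p$,
one-channel sequence:

1. two 1-D convolutions (32 then 64 filters, kernel 3, "same" padding,
   stride 1, ReLU) — positions stay at $p$ throughout;
2. global average pooling of the conv-2 map to a 64-channel vector
   $g_c = \tfrac1n\sum_i h_{ic}$;
3. an attention head: a dense layer maps $g$ to one score per position,
   softmax-normalized into weights $\alpha$
   ($\alpha_i = e^{u_i}/\sum_j e^{u_j}$, computed with max-subtraction);
4. position-wise reweighting $\tilde h_{ic} = \alpha_i h_{ic}$ — summing
   $\tilde h$ over positions gives the classical attention context vector
   $c = \sum_i \alpha_i h_i$, but the positions are *kept* and flattened so
   the dense head sees the full $p \times 64$ resolution;
5. dense 128 (ReLU), dropout 0.5, and a sigmoid output unit.

The wiring in (3)–(4) is the one whose parameter count is exact: at
$p = 1000$ the layer table is $128 + 6208 + 65\,000 + 8\,192\,128 + 129 =
8\,263\,593$ trainable parameters, and `build_attcnn()`'s spec arithmetic
is asserted against the instantiated weight tensors for every variant. A
summed 64-dimensional context vector could not feed an 8.19M-parameter
dense layer, which is what fixes the reweight-then-flatten interpretation.

Because no deep-learning framework ships in this package's dependency
footprint, the network is implemented directly: convolutions as $k$ shifted
BLAS matrix products, analytic backpropagation through the attention
softmax and GAP paths, Adam, mini-batches of 16, binary cross-entropy, at
most 50 epochs with early stopping on validation loss (patience 5, best
weights restored). The backward pass is verified against central finite
differences in every wiring (relative error below $10^{-4}$ on randomly
probed coordinates; observed around $10^{-6}$). Training is deterministic
given `cfg$seed` on a fixed backend: same seed, same machine, identical
probabilities. Bit-reproducibility across BLAS builds is not promised.

### Ablation family

The ablation variants are defined against a *two-attention* parent that
adds a symmetric block after conv-1 (GAP over 32 channels → dense($p$) →
softmax → reweight): `WFAL` drops the first block, `WSAL` the second,
`RBAL` both (flatten the raw conv-2 map), `RFCL` removes the dense-128
layer. The parent's parameter count at $p = 1000$ is the baseline's plus
33 000; the single-attention *baseline* — not the two-attention parent —
is the canonical architecture, since only its count matches the
8 263 593-parameter budget above. `head = "gap"` with no attention yields the plain-CNN comparator
(conv → conv → GAP → dense-128 → output).

## Evaluation

`make_split_plan()` fixes one stratified 80/20 holdout and stratified
5-fold CV folds on the training part. Per-class test counts use R's
round-half-even; fold class counts differ by at most one sample.
`binary_metrics()` reports ACC/PRE/REC/F1 at threshold 0.5 (ties predict
positive; the positive class is the case label 1) plus rank-based AUC
(midranks, equal to exhaustive pair counting with ties worth ½).
`delong_test()` implements the structural-component (midrank) estimator for
correlated AUCs with a normal two-sided p-value and no small-sample
correction; it is cross-checked against pROC's independent implementation
and against a stratified-bootstrap null in the tests. Zero variance of the
AUC difference with zero difference returns $z = 0, p = 1$; with a nonzero
difference it is an error rather than a fabricated infinity.

`crossval_evaluate()` reports both the per-fold CV metrics and the
held-out-test metrics of a model refit on the full training split; the
held-out numbers are the headline, matching the stated 80/20-then-CV
protocol. When a `train_config` carries a hyperparameter grid (defaults:
learning rate {1e-3, 1e-4}, dropout {0.3, 0.5}, filter pairs {(32,64),
(16,32)}), each combination is cross-validated and the best mean fold
accuracy (AUC tie-break) is refit. `compare_classifiers()` runs adapters
(SVM via e1071, gradient boosting via xgboost, the plain CNN) on identical
splits and DeLong-tests every pair of held-out score vectors — the
comparators are thin adapters around established implementations, not
reimplementations.

## The pipeline

`run_attbiomarker()` chains the stages: prefilter → common matrix → one
holdout fixed up front and reused by both rounds → Fisher grid → per-size
evaluation → winner (highest held-out accuracy; ties broken by AUC, then
the smaller subset) → mRMR grid on the winner → winner → DEG intersection →
optional hub ranking. Round-2 genes are a subset of round-1 genes, which
are a subset of the prefiltered common genes — asserted on every run. Note
that, mirroring common practice in the source literature, feature selection
runs on the full matrix rather than inside the resampling loop; held-out
metrics are therefore optimistic for selection-inclusive generalization
claims and should be read as subset-comparison scores, not unbiased
estimates. When a round has a single candidate size, the fold loop is
skipped (the winner is trivial) and only the retrain + held-out evaluation
runs. All stage seeds derive deterministically from one master seed via a
stage-name hash, so any stage can be re-run in isolation.

## The synthetic generator

`synthetic_spec()` defines the validation world: per study,
$n$ samples per class; null genes $\mathcal{N}(\text{baseline}_{gs},
\sigma^2)$ with per-study per-gene baselines
$\mathcal{N}(0, \text{study\_shift\_sd}^2)$ emulating uncorrected batch
structure; planted genes add $\delta\sigma$ to the case mean; each
redundant block re-emits one latent class-informative signal
`block_size` times with pairwise correlation $\rho$
(member $= \delta y + \sqrt{\rho}\, z + \sqrt{1-\rho}\,\varepsilon$),
which is precisely the structure mRMR's redundancy term is meant to
punish. Defaults — 3 studies, 25/class/study ($\approx$ 150 samples), 2000
genes, 50 planted at $\delta = 1.5$, 10 blocks of 5 at $\rho = 0.95$,
$\sigma = 1$, study shift sd 0.5 — were chosen once to mirror a
three-study microarray case/control design of desk-scale size.

What the generator does *not* emulate: probe/platform effects,
missing-value mechanisms, count-distributed (negative binomial) noise,
correlated null p-values between studies, and gene–gene correlation beyond
the planted blocks. Two consequences matter for interpreting green tests.
First, null p-values are independent across simulated studies, so a
per-study p < 0.25 intersection shrinks multiplicatively (to roughly
$0.25^3$ of the nulls) instead of retaining the large overlapping fraction
real correlated studies show; recovery experiments therefore pool all genes
before round 1 rather than prefiltering. Second, passing recovery tests
show the machinery is correct and well-powered under a favorable Gaussian
world — they do not certify performance on real arrays.

## Numerical choices and edge cases

* Welch t on doubly-degenerate genes: equal means give $t=0, p=1$; unequal
  means give $p=0$ with a `degenerate` flag rather than a silent infinity.
* All filters use strict inequalities; thresholds are documented as such.
* Plug-in MI values within $-10^{-12}$ of zero are clamped to 0; anything
  more negative raises an error (it would indicate a broken estimator).
* Deflection detection declares "no knee" below a $10^{-9}$ normalized
  distance.
* Softmax uses max-subtraction; `attention_weights(c(1000, 0))` is finite.
* Training aborts with a diagnostic on non-finite loss instead of
  returning a poisoned model; inference clamps probabilities to
  $(10^{-7}, 1-10^{-7})$ to honor the open-interval contract.
* Sample ids colliding across studies are prefixed with the study name.

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run at sizes chosen once for
desk-scale reproducibility: the recovery experiment uses the generator's
3-study design with 2000 genes, 50 planted at $\delta = 1.5$, 100 samples
per class per study, Fisher 500 → mRMR 100; the selection-versus-baseline
trend experiment uses 400 genes, 15 planted at $\delta = 1.0$, 25 per
class per study across 5 seeds (Fisher 150 → mRMR 50) — deliberately a
weaker-signal world than the recovery experiment, so that neither arm sits
at perfect accuracy and the comparison is informative. Oracle checks (Fisher brute force, mRMR
exhaustive steps, AUC pair counting, DeLong bootstrap and type-I
simulation) run at small n where exhaustive computation is exact.

## Known limitations

* Binary classification only; the Fisher formulas accept $L > 2$ classes
  but multi-class behavior is untested beyond the formulas.
* Continuous (Kraskov-style) MI estimators are not provided.
* No batch correction; concatenation mirrors the uncorrected multi-study
  design and is flagged with a warning.
* The CNN engine is CPU-only and single-threaded by design; it is sized
  for thousands of input genes and hundreds of samples, not for
  genome-wide inputs.
* Hub ranking implements degree centrality only, on a user-supplied edge
  list; network construction is out of scope.
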