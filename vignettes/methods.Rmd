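---
title: "Knowledge-graph embedded clinical indicators: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph embedded clinical indicators: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`kgdx` predicts a binary disease label from routine laboratory measurements
by first *encoding the measurements against medical knowledge* — the
reference ranges of the indicators — and only then applying a neural
classifier. The pipeline has four stages:

1. **Knowledge graph.** Each indicator's measurement axis is discretized
   into a grid of value entities, and every (indicator, value) pair becomes a
   triple *(indicator, severity band, value)*. The severity band is one of
   seven ordered categories — severely low, generally low, slightly low,
   normal, slightly high, generally high, severely high — locating the value
   relative to the indicator's reference interval.
2. **Translational embedding.** Entities and the seven band relations are
   embedded in $\mathbb{R}^k$ with TransE, TransH, or TransR, trained so that
   $l_h + l_r \approx l_t$ for true triples.
3. **Patient encoding.** A patient's record becomes the $k \times m$
   *relation matrix* whose column $j$ is $e_{v_j} - e_{c_j}$: the embedding
   of the matched value entity minus the embedding of indicator $j$. Under a
   well-trained model this difference approximates the severity-band
   relation vector, so the matrix is a learned, continuous severity code.
4. **Classifier.** Two stacked self-attention layers let every indicator
   aggregate information from all others; a bank of convolution filters of
   window widths 2/3/4 with max-over-positions pooling extracts features;
   a two-unit affine layer with softmax produces class probabilities,
   trained with cross-entropy.

# Severity bands

Reference ranges state only the normal interval $[\ell, u]$; the outer band
boundaries are not standardized. We use a parametric, symmetric rule: with
width $W = u - \ell$ and fractions $0 < \alpha_1 < \alpha_2$ (defaults
$\alpha_1 = 0.25$, $\alpha_2 = 0.75$),

* severely low: $v < \ell - \alpha_2 W$
* generally low: $\ell - \alpha_2 W \le v < \ell - \alpha_1 W$
* slightly low: $\ell - \alpha_1 W \le v < \ell$
* normal: $\ell \le v \le u$ (closed on both ends)
* slightly high: $u < v \le u + \alpha_1 W$
* generally high: $u + \alpha_1 W < v \le u + \alpha_2 W$
* severely high: $v > u + \alpha_2 W$

The normal band owns both boundaries and the outer bands are half-open, so
band assignment is total, deterministic, and monotone in $v$. With the
defaults, a fasting glucose of 7.1 mmol/L against the 3.9–6.1 mmol/L
reference interval falls in the *generally high* band — consistent with the
clinical rule of thumb that values above 7.0 mmol/L raise suspicion of
diabetes. Both fractions are overridable per analysis when local expert
guidance differs; prediction quality inherits whatever band convention is
chosen, which is a genuine modelling limitation, not an implementation one.

# Value grids

The grid runs from $\ell - sW$ to $u + sW$ (span factor $s = 1$ by default)
in steps of `grid_step`, which defaults to $W/100$ rounded to the decimal
precision at which the bounds are stated. Concentrations and activities are
clamped at zero (a per-indicator flag disables the clamp for signed
quantities). This yields on the order of a hundred value entities per
indicator — enough resolution that nearest-grid matching loses little
information, few enough that every value entity receives training signal.
Measured values are matched to the nearest grid value, rounding half up;
values beyond the grid map to the `<HIGHEST>` / `<LOWEST>` entities, and
missing cells to `<UNK>`. The three specials are ordinary trainable entities
that simply carry no triples; they are regularized only by the norm
constraint, which is adequate because the classifier learns to interpret
their (arbitrary but fixed) directions.

# Embedding training

The three translational scoring rules are

* TransE: $f_r(h,t) = \lVert l_h + l_r - l_t \rVert_{1/2}$,
* TransH: the same after projecting $l_h, l_t$ onto the hyperplane of unit
  normal $w_r$ ($e \mapsto e - (w_r^\top e)\, w_r$),
* TransR: the same after mapping entities with a relation-specific matrix
  $M_r$ (we set the source and target dimensions equal; $M_r$ is initialized
  at the identity).

Only the scoring rules are fixed by the model family; the training objective
is the standard margin-ranking loss
$\sum \max(0, f_r(h,t) + \gamma - f_r(h',t'))$ over uniformly corrupted
negatives — heads are replaced by random indicator entities and tails by
random value entities, with probability one half each, never the relation.
Optimization is Adam (learning rate $10^{-3}$, batch 128, 500 epochs,
margin $\gamma = 1$ by default); after every batch, entity norms are clipped
to at most 1 and hyperplane normals are renormalized to unit length. Hard
constraint projection was chosen over soft penalties because it yields
invariants that can be asserted exactly in tests.

Link prediction follows the raw (unfiltered) protocol: the entity on the
chosen side is replaced by *every* entity of the catalog, corrupted triples
are scored and sorted ascending, and the true triple's rank is
$1 + \#\{\text{strictly better candidates}\}$ (optimistic ties). Mean Rank
is the average rank; Hit@10 is the percentage of ranks at most 10. Ties are
broken optimistically because it is deterministic and standard. Note that
this graph is intrinsically hard for tail-side ranking: hundreds of grid
values share each (indicator, band) pair, so many corrupted triples are
semantically near-correct, and MR stays far from 1 even for good embeddings.
The two metrics can also disagree on which model is "best"; the package
reports both and takes no stance.

# The attention-convolution classifier

Per attention layer, with input matrix $E \in \mathbb{R}^{k \times m}$
(columns = indicators): $Q = w_q E$, $K = w_k E$, $V = w_v E$, and the
output is $V \cdot \mathrm{softmax}(K^\top Q / \sqrt{D_k})$ with the softmax
normalizing each column, so each output column is a convex combination of
the columns of $V$. The query/key/value maps are square ($k \times k$,
single head) so two layers compose without reshaping; no residual
connections or normalization layers are inserted between them — flagging
the layers' outputs through unchanged would alter the published topology,
and the architecture is shallow enough not to need them. The scaled
dot-product form with column softmax is taken as authoritative where the
per-vector and matrix formulations of attention could be read differently.

The convolution stage treats the $m$ attended columns as a sequence. A
filter of window width $h$ produces a feature map of length $m - h + 1$ by
$\mathrm{relu}(\langle W^f, \text{window}\rangle + b)$, which is max-pooled
to one value; 100 filters per window width in $\{2, 3, 4\}$ give the pooled
feature vector $Z$ of length 300. Dropout (rate 0.5) is applied to $Z$
before the two-unit fully connected layer — the published rate does not fix
the site, and pre-classifier dropout is the standard placement for this
conv-pool topology; dropout inside attention is left off for the same
reason. Scores pass through a softmax and training minimizes binary
cross-entropy (probabilities clamped to $[10^{-7}, 1-10^{-7}]$ to avoid
$\log 0$), by Adam with batch 32, learning rate $2 \times 10^{-4}$, 100
epochs by default. All weights initialize uniform in $(-0.1, 0.1)$ under a
seed; biases start at zero. The decision threshold is 0.5 on the positive
class.

The trained first attention layer is exportable as an $m \times m$
row-stochastic matrix (rows = querying indicator, columns = attended
indicator), averaged over a dataset — the package's interpretability
surface.

The forward and backward passes are implemented in RcppArmadillo,
single-threaded, drawing all randomness (initialization, shuffling, dropout)
from R's RNG, so training is bit-reproducible from `set.seed()`. The
compiled path is cross-checked in the test suite against a pure-R
definitional composition of the layer operations (forward equality and
numeric-vs-analytic gradient agreement to $10^{-4}$).

# Evaluation protocol

Classification is scored by accuracy, recall, and F1 with the diseased
class positive, from the 2x2 confusion table. Splits are stratified: each
class is shuffled and dealt round-robin across folds, so fold class counts
deviate from exact stratification by at most one. The default protocol is a
single stratified holdout of one fold in five (an 80/20 split); full
five-fold cross-validation is available, with the aggregate computed from
the pooled confusion matrix (equivalently, the sample-weighted mean of fold
accuracies).

SMOTE oversamples the minority class to the majority count by interpolating
uniformly along segments between a minority row and one of its five nearest
minority neighbours. It operates on *raw measured values*, before entity
matching, and synthetic rows then pass through the normal encoder — this
keeps the knowledge-graph pipeline intact regardless of representation.
Missing cells are mean-imputed (within the minority class) for the distance
and interpolation arithmetic only, and a synthetic row inherits its seed
row's missingness pattern. By default only the training portion is
resampled; resampling held-out data as well is supported behind a flag for
protocol parity with studies that do so, but it is off because it inflates
apparent performance.

# The synthetic cohort generator

Hospital examination data cannot be redistributed, so the package ships a
generator whose signal is *exactly the structure the knowledge encoding is
designed to expose*. Each patient has a latent disease state $z$ drawn at a
target prevalence (default 0.1, i.e. roughly 1:9 imbalance as is typical
for diabetes screening cohorts). Causal indicators of diseased patients are
shifted 0.3–1.5 range-widths above the upper normal bound (the generally-to-
severely elevated bands); causal indicators of healthy patients concentrate
near mid-range (s.d. $W/4$); non-causal indicators scatter across bands
independently of disease (s.d. $W/2$). The label is Bernoulli with logit
$\beta_0 + \sum_j \beta_j s_j$, where $s_j \in \{-3..3\}$ is the signed
severity band of indicator $j$ under the same band rule the graph uses. The
intercept is calibrated by root-finding so the expected prevalence matches
the target. Cells are masked missing at a default rate of 5% — a
round number chosen once for realism, as examination panels are mostly
complete. The latent truth (severities, probabilities) is retained, so the
Bayes-optimal accuracy (thresholding the true probability at 0.5) is
computable as a recovery ceiling.

The *strong-signal benchmark* (`strong_signal_spec()`) fixes the recovery
conditions: 4000 patients, 11 indicators, 3 causal indicators, effect size
8 per severity step (saturating the sigmoid, so labels are deterministic
given the values), balanced classes, and no missingness — the ceiling
comparison is only meaningful when the model sees the same information as
the generating rule. Balanced classes make the label-permuted control
interpretable: a model trained on permuted labels should sit at accuracy
0.5.

What passing on this cohort does **not** show: robustness to the marginal
distributions, measurement error, missing-not-at-random patterns, or
age/sex-dependent reference ranges of real hospital data. The generator
emulates the *shape* of such data (continuous indicators, reference ranges,
imbalance, missingness, band-driven risk), not its content.

# Problem sizes and numerical choices

The benchmark experiments in the test suite and the acceptance script run
at embedding dimension 32, 100–1000 embedding epochs, and 30 classifier
epochs — sizes at which the whole pipeline completes in about a minute on a
single CPU while leaving the recovery conclusions unchanged; the package
defaults (dimension 256, 100 classifier epochs) reflect the settings used
with large hospital cohorts. Other numerical choices: nearest-grid matching
rounds half up; ranking ties are optimistic; the cross-entropy clamp is
$10^{-7}$; hinge-loss gradients at exactly zero distance use a guarded
denominator ($10^{-12}$); training refuses single-class training sets;
a window wider than the indicator sequence is an error.

# Known limitations

* Band boundaries beyond the normal interval are a parametric stand-in for
  unpublished expert conventions; results depend on them.
* Reference ranges are age- and sex-independent.
* The learned-embedding ablation (`encoder = "learned"`) and the
  knowledge encoder share the classifier, but the ablation's table is
  trained jointly with it, so its capacity differs from the knowledge
  route's fixed embeddings by design.
* Link-prediction metrics on severity-band graphs are dominated by the
  many near-correct value entities; they are comparable across embedding
  models on the same graph but not across graphs.
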