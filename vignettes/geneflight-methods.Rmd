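---
title: "geneflight: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geneflight: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

geneflight classifies two-class gene-expression profiles through three
stages — per-gene Z-scoring, wrapper gene selection by an improved
Levy-flight cuckoo search (ICSO), and a small "weighted" convolutional
network (WCNN) — evaluated with stratified splits, k-fold
cross-validation, confusion-matrix metrics and ROC/AUC. This vignette
records the model, its assumptions, and the design decisions taken where
the method description leaves genuine freedom.

## Data model and assumptions

An expression table is a tibble of samples by genes with a two-level label.
The pipeline assumes only a *location-shift* signal: informative genes
differ between classes in their mean, on an otherwise comparable scale.
Missing values are not supported (they are a validation error): imputation
is a separate concern and silently propagating NA through a distance-based
fitness or a gradient-based classifier produces quiet nonsense.

Label coding is deterministic without configuration: the lexicographically
smaller label string becomes class 0, the larger class 1. Precision and
recall take class 1 (in the motivating datasets, the tumor class) as
positive by default; `positive_class` switches this.

## Z-score normalization

For every gene `A`, `v' = (v - mean_A) / sd_A`.

* **Divisor.** `sd_A` is the population standard deviation (divisor `n`)
  by default, the plain reading of "the standard deviation of A";
  `divisor = "n-1"` is available. The choice is immaterial downstream (it
  rescales every gene by the same factor `sqrt(n/(n-1))`).
* **Zero variance.** Constant genes map to 0 everywhere rather than
  erroring: they are uninformative, common in subsetted microarray panels,
  and 0 is the value a vanishing-variance limit gives.
* **No leakage.** Inside the pipeline, statistics are always fitted on the
  training partition only and applied to both partitions. Normalizing
  before splitting would leak test-set means into training.
* Normalization is per gene, not per sample: the statistic is explicitly
  the mean and deviation of a *feature*.

## Improved cuckoo search (ICSO) gene selection

Each nest holds a continuous position `h` in `[0, 1]^G`; gene `g` is
selected when `h_g >= binarize_threshold`. This continuous-position /
thresholded-mask encoding is the standard binary adaptation of cuckoo
search; the method description searches continuous "positions" yet selects
genes, and thresholding is the minimal bridge between the two.

Per iteration `t = 1 ... T`:

1. A randomly picked nest proposes `h' = clip(h + alpha_t * L)`, where `L`
   is a Levy step and `alpha_t` the adaptive step size below. Out-of-cube
   coordinates are clipped (simplest bounded-search rule; reflection or
   wrapping would change nothing structurally).
2. The proposal replaces a randomly chosen nest if strictly fitter.
3. The worst `ceiling(p_a * N)` nests are abandoned and re-seeded at
   uniform-random positions.
4. The best solution ever seen is retained (elitism), so the recorded
   best-fitness trace is non-decreasing by construction. With `T = 0` the
   trace holds one entry, the best of the random initial population.

**Levy steps.** The step-length law `Levy(lambda) ~ t^(-lambda)`,
`1 < lambda < 3`, is a tail-density statement, not a sampling recipe. We
sample by the Mantegna construction — `u / |v|^(1/beta)` with Gaussian
`u, v` and the Mantegna scale — with stability index
`beta = lambda - 1` (default `lambda = 2.5`, `beta = 1.5`, the canonical
cuckoo-search choice). The package verifies the tail empirically (Hill
estimator on 1e5 draws).

**Adaptive step size.** `alpha_t = a_max * (a_max/a_min)^(-t/T) * ran *
0.01`, `ran ~ U(0,1)`: the deterministic factor decays geometrically from
`a_max` at `t = 0` to `a_min` at `t = T`. The printed `0.01` factor is
kept verbatim although it makes unit-cube steps minuscule at the nominal
`a_max = 1`; `a_max`/`a_min` are exposed to compensate, and benchmark runs
in this package use `a_max = 100` so that early steps are O(1) in the unit
cube and late steps are of the order of single-gene flips. (The original
step-size formula contains an obvious typo, `a_amin`, read as `a_min`; and
the flight update is read as `h^(t+1) = h^(t) + alpha_t * L`, the only
self-consistent interpretation of its printed indices.)

**Fitness.** Classification accuracy of an evaluator trained on the masked
training genes and scored on masked validation data. The default evaluator
is a nearest-centroid classifier: deterministic, hyperparameter-free,
O(samples x genes), cheap enough to sit inside the loop. The WCNN itself
is far too expensive there but can be injected for a final slow run.
The empty mask has fitness 0. Fitness ties are broken toward fewer genes —
selection exists to shrink the panel — both in nest replacement and in
best-solution tracking. The abandonment rule re-seeds uniformly because
"deserting a bad nest" specifies no structure to preserve.

Defaults (`N = 25`, `p_a = 0.25`, `a_max = 1`, `a_min = 0.01`, `T = 100`,
threshold 0.5) are ours; the source gives none.

### The parameter-recovery benchmark world

The test suite checks that selection recovers planted informative genes
(recall >= 80%, spurious fraction of the selected panel <= 20%, averaged
over 10 seeds). Designing that world needs care, because wrapper selection
on *accuracy alone* has two failure regimes that no optimizer can escape:

* **Winner's curse.** With a finite validation set, some noise genes
  genuinely raise validation accuracy (their estimated centroid difference
  happens to point the right way for these particular samples). We
  measured this directly: in moderate-effect worlds the fittest masks
  contain lucky noise genes and *strictly lose* fitness when any of them
  is dropped. There, <= 20% spurious is unattainable by construction.
* **Saturation without necessity.** With a very strong per-gene effect,
  small subsets of the planted genes already classify perfectly, the
  fewer-genes tie-break prunes to a *minimal* perfect subset, and recall
  collapses.

The benchmark world sits deliberately between the two: 20 genes, 6 planted
with a 2.5-sd shift, 100 training and 2000 validation samples per class.
There the full planted panel is (with high probability) the *minimal
perfectly separating subset*: every planted gene is needed to reach
validation accuracy 1, no noise gene can improve on 1, and the tie-break
prunes everything else. Search parameters for the benchmark: `N = 15`,
`p_a = 0.1`, `T = 800`, `a_max = 100`, `a_min = 5`, threshold 0.75 (a
sparsity-matched threshold: 0.5 would make every random nest select half
of all genes). These were fixed from the analysis above and are documented
here precisely because the property would silently fail in
innocent-looking worlds on either side of this band.

## The weighted CNN

**Meaning of "weighted".** The weighting stage is motivated as repairing
first-layer information loss, and its interface is a weighted convolution
`X = conv(W, P)` with a derivative contract for `dX/dW`. We realize it as
a learnable per-gene weight vector applied entrywise before grid embedding
— a 1x1 weighted convolution — trained jointly with the rest of the
network using exactly those gradients (`dW = upstream * P`,
`dP = upstream * W`). This is the minimal construction satisfying both the
interface and the motivation. Alternatives the description cannot rule out
(weighting filter maps, or loss terms) are noted here; the per-gene-input
reading is the one that addresses "information loss in the first layer".

**Grid embedding.** 5x5 kernels need a 2D arrangement, so the gene vector
is laid out row-major on a near-square grid (`height = ceiling(sqrt(G))`,
`width = ceiling(G/height)`), trailing cells zero-padded. The embedding is
arbitrary but fixed and invertible; the network can learn any spatial
arrangement of an arbitrary layout equally well.

**Architecture.** Weighted input, 5x5 conv, 2x2 max pool, 5x5 conv, 2x2
max pool, 1x1 conv, 1x1 pool, one hidden dense layer, softmax output.
Defaults: filters 8/16/16, 32 hidden units. Channel counts are ours; the
source figure is not legible on this point.

* **Pooling edges.** Max pooling keeps partial trailing blocks (output
  size `ceiling(input/pool)`, "ceil mode"). This is what makes the stack's
  minimum grid 13x13: 13 -> 9 -> 5 -> 1 -> 1. Floor-truncating edges
  would both discard edge genes (against the stated information-loss
  motivation) and raise the minimum viable panel to 16x16 = 256 genes.
* **Small panels.** The selection stage routinely yields panels under 169
  genes, so by default the grid is padded up to 13x13
  (`pad_to_min = TRUE`); with `pad_to_min = FALSE` small panels are a
  validation error naming the 169-gene minimum.
* **Activation.** The conv-layer equation writes no nonlinearity; a purely
  linear conv stack cannot benefit from depth, so ReLU follows each conv
  bias (switchable to identity).
* **Initialization.** Originally a fixed-width uniform(-0.05, 0.05) scheme
  was specified. It demonstrably fails here: through three conv layers the
  activations shrink by orders of magnitude, the softmax output is flat at
  (0.5, 0.5), and training cannot leave chance level at any learning rate.
  Weights are therefore drawn from the fan-in-scaled (He) uniform
  `U(-sqrt(6/fan_in), +sqrt(6/fan_in))`, biases start at zero, and the
  gene weights start at 1 so the weighted stage begins as an identity — a
  plain CNN that learns per-gene importance during training. All draws
  come from the seeded stream; training is bit-reproducible.
* **Optimizer.** Plain mini-batch SGD on mean cross-entropy
  (learning rate 0.01, 100 epochs, batch 16 by default; the source names
  only softmax, so cross-entropy is the canonical pairing). The per-epoch
  history records loss and full-training-set accuracy after each epoch's
  updates; monotone decrease is *not* asserted anywhere — SGD does not
  guarantee it.
* **Gradients.** Every layer's backward pass is analytic (im2col
  convolution, argmax-routed pooling with first-of-block tie-breaking,
  dense and softmax/cross-entropy). The test suite checks all eleven
  parameter groups against central finite differences at 1e-5 relative
  (biases are nudged off zero there: exact zeros sit on ReLU kinks where
  finite differences are one-sided).
* **Prediction ties** (probability exactly 0.5/0.5) go to class 0, making
  degenerate models deterministic.
* **Serialization** writes config, grid, label levels and all parameters
  to JSON with doubles rendered as `%.17g` strings — plain JSON number
  formatting loses the final bits and would break bit-exact round-trips.

## Metrics

Accuracy, precision, recall, F-measure and error rate are reported in
percent. Two definitional quirks are handled explicitly:

* The printed "accuracy" formula `TP/(TP+FP)` is the precision formula;
  every results table plainly treats accuracy as overall correctness.
  Default accuracy is `(TP+TN)/total`; the literal variant stays available
  as `accuracy_pct(counts, "paper_literal")` for transparency.
* The printed error-rate formula ("approximate vs exact value") is not
  computable from a confusion matrix; the tables are consistent with
  `error = 100 - accuracy` up to rounding drift, which is the implemented
  default. Consequently `accuracy + error_rate = 100` exactly.

Metrics with zero denominators raise a typed condition and appear as `NA`
in reports. Values are computed at full precision and rounded (half-up) to
two decimals only when serialized, mirroring the printed tables. ROC
curves sweep descending unique score thresholds with a sentinel above the
maximum; AUC is the trapezoid rule, which on this step curve equals the
Mann-Whitney U-statistic probability — the suite asserts that identity to
1e-12.

## Synthetic data generator

The generator emulates the shape of the motivating lung-cancer microarray
set: two unbalanced classes (defaults 70 normal / 86 tumor), thousands of
genes (default 2000; 7129 reproduces the full-scale shape), a small
planted informative subset (default 50) with a class-conditional mean
shift of `effect_size * noise_sd` (default 1 sd), optional equicorrelation
inside the planted block via a single shared Gaussian factor, and
everything else iid Gaussian noise. The baseline level is 0 because
Z-scoring makes any constant offset irrelevant. Defaults not fixed by the
emulated dataset (informative count, effect, correlation) were chosen once
as typical of a clearly-separable microarray benchmark and are exercised
at smaller scales in tests purely for runtime.

What it does *not* emulate: probe-level artifacts, batch effects,
heavy-tailed or skewed expression distributions, missingness, and
gene-gene correlation outside the planted block. A green test therefore
establishes correct behaviour under location-shift signal — the only
signal the downstream stages model — not robustness to real microarray
technical structure.

## Reproducibility and the pipeline

`run_pipeline()` derives every stage seed deterministically from one
global seed (a fixed integer hash of the stage name), so a stage can be
re-run in isolation and whole runs are bit-reproducible; the cuckoo-search
fitness is evaluated on an inner stratified 70/30 split of the training
partition, never on test data. The outer 70/30 split is stratified
per class with floor rounding for the training share (class sizes 86/70
give 60+49 train, 26+21 test); whether the original protocol stratified is
unstated, but with unbalanced classes stratification is the defensible
default. `crossval_pipeline()` refits normalization, selection and the
network from scratch inside every fold. The CLI mirrors all of this with
one flag (`--no-selection`) toggling the with/without-selection ablation
from a single config.

## Known limitations

* Binary classification only; the softmax head is two-class by scope.
* The WCNN is CPU-only and modest; it is a faithful from-scratch
  implementation, not a performance-tuned deep-learning stack.
* Wrapper selection inherits the winner's curse discussed above: on real
  data, selected panels should be validated on samples never touched by
  the selection fitness.
* Headline real-data benchmark numbers from the motivating study are not
  reproducible here by design: they require an external dataset and
  unspecified hyperparameters. The acceptance suite substitutes exact
  desk-checks of the published metric arithmetic plus property-based
  checks (oracle equivalence, parameter recovery, gradient exactness,
  convolution equivalence, step-size law, normalization post-conditions,
  AUC identity, end-to-end accuracy) that this package computes itself.
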