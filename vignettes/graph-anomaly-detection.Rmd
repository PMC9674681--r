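---
title: "Detecting anomalous graphs with a contrastive graph-convolutional autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting anomalous graphs with a contrastive graph-convolutional autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Graph-level anomaly detection asks which whole graphs in a collection
deviate from the majority pattern — e.g. spotting molecules with unusual
structure in a compound library, where each molecule is a graph of atoms
(nodes) and bonds (edges). Two kinds of deviation matter:

* **local anomalies** — the graph's overall motif is intact but one node's
  links break the pattern (a ring opened by a rewired atom);
* **global anomalies** — the whole-graph pattern differs (extra nodes, a
  different motif).

Anomalous graphs are rare and their patterns unknown in advance, so the
detector is trained **one-class**: only normal graphs are used for
training, and at test time a graph is scored by how badly the model —
which only knows the normal pattern — represents it.

## The model

Each graph has an adjacency matrix $A \in \{0,1\}^{n\times n}$ and node
features $X \in \mathbb{R}^{n\times d}$ (for plain graphs we derive
features from node degrees; see below). The architecture is:

**Shared GCN encoder.** Two graph-convolution layers
$Z_{l} = \phi\!\left(\tilde D^{-1/2}\tilde A\tilde D^{-1/2} Z_{l-1}\theta_l\right)$,
with $\tilde A = A + I$, $\tilde D_{ii} = \sum_j \tilde A_{ij}$, widths
$d\!-\!256\!-\!128$, $\phi = \mathrm{ReLU}$ on hidden layers, no biases.
Following the standard graph-autoencoder convention for inner-product
decoders, the final embedding layer is left *linear*
(`encoder_output = "linear"`): if the last layer were also ReLU, every
embedding would be non-negative and the decoded edge probability
$\mathrm{sigmoid}(z_i^\top z_j)$ could never drop below $0.5$ — the
decoded graph would be dense for every input, the re-encoder would smooth
it, and the representation-error mechanism would lose its meaning on
sparse graphs (we observed exactly this failure mode: a high reconstruction
floor and reconstruction-side representations collapsing toward zero).
The all-activated variant remains available
(`encoder_output = "activation"`). The final node matrix is $Z_{node}$;
the graph readout $Z_G$ is the coordinate-wise maximum over nodes
(max pooling).

**Perturbed twin encoder.** A second view of the same graph is produced by
the same encoder with Gaussian-perturbed weights
$\theta'_l = \theta_l + \eta\,\Delta\theta_l$,
$\Delta\theta_l \sim N(0, \sigma_l^2)$, redrawn once per minibatch. This
gives a contrastive pair *without* data augmentation, so no graph edges or
features are corrupted. The noise scale $\sigma_l$ defaults to the
empirical standard deviation of $\theta_l$'s entries at the moment of
perturbation, which keeps the perturbation proportionate layer by layer; a
constant can be supplied instead. Gradients do not flow into
$\Delta\theta_l$.

**Projection head.** A shared two-layer MLP (width 128) maps both readouts
into the space where the contrastive loss acts.

**Decoders.** The structure decoder is the inner-product model
$\hat A = \mathrm{sigmoid}(Z_{node}Z_{node}^{\top})$; the attribute decoder
is a mirrored GCN stack ($128\!-\!256\!-\!d$) on the *input* graph's
normalized adjacency, with the activation applied on every layer including
the output (`decoder_output = "activation"`, the default). This matters
more than it looks: with non-negative inputs such as degree one-hots, a
linear output layer produces negative reconstructed features, which drive
every ReLU of the shared re-encoder to zero — the re-encoded
representations collapse to exactly $0$ and the anomaly score degenerates
into a representation norm. An activated output keeps $\hat X$ in the same
orthant as $X$ and the re-encoder alive. For signed real-valued features
(e.g. Gaussian attributes) the activated output cannot reach negative
values, so `decoder_output = "linear"` is provided for that case.

**Re-encoding.** The decoded graph $(\hat A, \hat X)$ is passed through the
*same* encoder (shared parameters, not a copy) to give $Z'_{node}$ and
$Z'_G$. $\hat A$ is used as a continuous weighted adjacency — self-loops
added, degrees = row sums — with no thresholding, which keeps the whole
objective differentiable; binarizing would cut the gradient path into the
decoders.

## The objective

Training minimizes, per minibatch of $N$ normal graphs, the unweighted sum
$L = L_1 + L_2 + L_3$:

* $L_1 = \lVert A - \hat A\rVert_F^2 + \lVert X - \hat X\rVert_F^2$
  (mean over the minibatch). Diagonal entries of $A$ vs $\hat A$ are
  excluded — self-loops are not data — and each graph's term is computed
  per graph before averaging, so the batch size does not rescale the
  objective.
* $L_2$: temperature-scaled cosine cross-entropy between the clean and
  perturbed projections. For anchor $i$ the positive is its own perturbed
  projection and the denominator sums the $N-1$ other graphs of the batch;
  the positive pair is not included in the denominator, so $L_2$ may be
  negative (it is not clamped). Negatives default to the perturbed-encoder
  representations (`negatives = "perturbed"`); the package also implements
  the variant whose denominator pairs clean projections with each other
  (`negatives = "unperturbed"`), because the two conventions both occur in
  the contrastive-learning literature and they differ only in the
  denominator. We default to the perturbed-negative form and expose the
  other as a switch rather than pretending the choice is forced.
* $L_3 = L_{node} + L_{graph}$ with
  $L_{node} = \frac{1}{|\mathcal G|}\sum_G \frac{1}{|G|}\sum_i
  \lVert Z_{node,i} - Z'_{node,i}\rVert^2$ and
  $L_{graph} = \frac{1}{|\mathcal G|}\sum_G \lVert Z_G - Z'_G\rVert^2$.
  During training $\mathcal G$ is the current minibatch.

Optimization is Adam (implemented in the package; there is no optimizer
library in base R), learning rate $10^{-4}$, batch 300, 100 epochs, $\eta = 1$,
$\tau = 0.2$ by default. A trailing minibatch of one graph is dropped
because the contrastive loss has no negatives there. Ablation switches
(`ablate = c("node", "graph", "cl")`) drop the corresponding component
from $L$, mirroring the model's ablation studies.

All gradients — including the awkward path through the degree
normalization of the *continuous* reconstructed adjacency — are derived by
hand and verified against central finite differences in the test suite
(`test-gradients.R`, relative agreement within 1e-5 asserted over every
parameter, all architecture variants).

## Scoring

At inference the perturbed branch is never used. A graph's anomaly score is

$$\mathrm{Score}_G = \frac{1}{|G|}\sum_{i}\lVert Z_{node,i} -
Z'_{node,i}\rVert^2 + \lVert Z_G - Z'_G\rVert^2,$$

i.e. exactly the per-graph representation error the training loss drives
down *for normal graphs*. A model trained only on normals reconstructs and
re-encodes unseen anomalous patterns badly, so anomalies receive larger
errors. Evaluation is by ROC AUC with midrank tie handling (the rank-sum
identity); no score threshold is ever set — the package reports raw scores
and AUC only.

## Data handling

* **TUDataset layout.** `read_tudataset()` / `export_tudataset()` handle
  the standard multi-file plain-text layout (1-based indices on disk,
  0-based in memory; undirected edges OR-merged). The raw class labels are
  mapped to anomaly flags by an explicit `anomaly_class` argument — there
  is no default because which class is "anomalous" is a dataset-level
  scientific decision.
* **Degree features.** Plain graphs get degree-derived features;
  the default is a one-hot over `0..max_degree` (dataset-wide maximum),
  which gives the attribute decoder a nontrivial reconstruction target; a
  scalar encoding is available. When a dataset has both attributes and
  node labels, attributes win; the package does not concatenate them.
* **Folds.** Five-fold cross-validation with anomalies removed from every
  training fold. Folds are stratified by label — otherwise a test fold
  could contain a single class, where AUC is undefined. Repeats reseed
  both the fold shuffle and the initialization.

## Synthetic benchmarks

Real molecular graph sets need downloads, so the package ships generators
that emulate the two anomaly types with ground truth:

* **Motif set** (`generate_motif_set()`): normal graphs are a 3-ring and a
  4-ring joined by one bridge (7 nodes, 8 edges). *Local* anomalies rewire
  all links of one large-ring node onto the small ring — the 4-ring
  pattern is destroyed, node count unchanged, graph still connected.
  *Global* anomalies attach two extra nodes. *Attribute* anomalies keep
  the topology and shift the feature mean by `mu_shift` (default 2), the
  minimal controllable feature signal. The default anomaly ratio used in
  the benchmarks (80 of 480, ~17%) matches the ratios typical of the
  public molecular anomaly sets.
* **ER contrast set** (`generate_er_contrast_set()`): normal graphs
  $G(20, 0.15)$ vs anomalous $G(20, 0.6)$ — a gross density contrast;
  with equal densities it becomes a null control whose AUC must hover
  near 0.5. As discussed below, the density contrast is also a stress
  test that the absolute-error score does not pass in the expected
  direction.

These generators emulate structural deviation and class imbalance; they do
not attempt chemistry (no valence rules or atom types), feature noise
correlated with structure, or the size heterogeneity of real molecule
sets. Passing the planted-anomaly benchmarks therefore shows the
mechanism works — normal-pattern training produces larger representation
errors on unseen patterns — not that any particular real-world AUC will be
attained.

## Numerical and design notes

* **Activation.** ReLU for hidden layers (standard GCN practice); the
  structure decoder is sigmoid as the inner-product link model requires;
  `tanh`/`identity` are available (the gradient tests use `tanh` to avoid
  ReLU kinks in finite differences).
* **Max-pool ties** are broken by the first maximal node; scoring is
  invariant to node relabeling to within 1e-5.
* **Empty features** are rejected at fit time with a pointer to
  `degree_features()`.
* **Raw readouts, not projections,** feed the error losses and the anomaly
  score; the projection head exists only for the contrastive term. The
  alternative (scoring in projection space) is deliberately not taken: the
  error loss and the score must live in the same space for the training
  objective to calibrate the score.
* **Determinism.** Every random step (init, shuffling, perturbation draw,
  fold assignment, generators) is driven by the caller's seed; two
  identical seeded runs produce bit-identical parameters and scores in
  single-threaded BLAS mode. Callers' RNG state is saved and restored.
* **Checkpoints** are versioned RDS containers holding all weights, the
  resolved configuration and the seed; restoration is bit-faithful.

## Problem sizes used by the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) use:
motif benchmark 400 normal + 80 local anomalies, 50 epochs, batch 64, a
single stratified held-out fold, averaged over 3 seeds; ER contrast
benchmark 200 + 40 graphs of 20 nodes at the same training settings (50
epochs, batch 64, for cross-benchmark symmetry); null control with equal
densities, 10 epochs, full 5-fold CV over 3 seeds; ablation comparison at
the motif benchmark's settings. These sizes keep every experiment well
under a few minutes on one core while the motif separation, the null
behaviour and the ablation direction are stable across seeds.

### When the absolute error score fails: the density confound

The ER contrast benchmark deliberately makes anomalies *much denser* than
normals, and it exposes a real limitation of the absolute
representation-error score. Under symmetric degree normalization, a dense
near-regular graph is smoothed toward a mean-field signal: both its
encoding and the re-encoding of its (dense) reconstruction are close to
constant across nodes, so the model reproduces it *consistently* even
though it never saw such graphs in training — its absolute error is
genuinely *smaller* than that of structured sparse normals. The
"unseen pattern receives a bigger error" premise fails when the unseen
pattern carries less structural information than the normal one; on this
benchmark the score ranks the classes in reverse (AUC far below 0.5 — the
classes are separated, with inverted sign). A scale-normalized variant of
the same error recovers much of the separation in our diagnostics, but the
package deliberately scores with the absolute error as the method defines
it and reports what it measures. Practitioners whose anomalies may be
low-information (denser/more regular than normal) should inspect score
distributions per class rather than trusting the ranking direction
blindly.

## Limitations

* Dense per-graph computation: fine for molecule-sized graphs (tens of
  nodes), not for graphs with thousands of nodes.
* No edge attributes (the model never consumes them).
* The two contrastive-denominator conventions are exposed but not
  empirically arbitrated here.
* AUC is the only evaluation; calibrated thresholds or precision at k are
  out of scope because the method defines no operating point.
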