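---
title: "Methods: multimodal MRI fusion with cross-modal feature alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal MRI fusion with cross-modal feature alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuse)
```

## The model

`neurofuse` trains a binary diagnostic classifier (patient vs. control)
from paired resting-state fMRI and structural MRI. The two modalities are
encoded by separate branches and fused at the feature level:

**Functional branch.** Regional BOLD series (M time points x N ROIs) are
summarized by the Pearson functional-connectivity matrix
$B = (b_{ij}) \in [-1,1]^{N \times N}$, treated as an undirected graph:
the adjacency $A$ comes from one of three constructions (k-nearest
neighbours on connectivity strength, thresholding, or the fully-connected
weighted graph $|B|$), and the node features are $X = B$ — each node is
described by its whole connection profile. Two spectral graph-convolution
layers propagate
$H^{(l+1)} = \mathrm{ReLU}(\tilde A H^{(l)} W^{(l)})$ with
$\tilde A = \hat D^{-1/2}(A + I)\hat D^{-1/2}$, the readout concatenates
the channel-wise mean and maximum over nodes, and one fully-connected
ReLU layer maps the pooled vector to a 64-dimensional embedding $g_F$.

**Structural branch.** The gray-matter volume passes through convolution
blocks (3x3x3 same-padding stride-1 convolution, batch normalization,
ReLU, 2x2x2 max-pooling with floor division), global average pooling, and
two fully-connected ReLU layers (128 and 64 units, dropout 0.5 after each
in training) to a 64-dimensional embedding $g_S$. With the default four
blocks of 16/32/64/128 channels and a 121x145x121 input, the spatial
chain is 121x145x121 -> 60x72x60 -> 30x36x30 -> 15x18x15 -> 7x9x7; the
chain is available without allocating weights via `propagateShapes()`.

**Alignment and fusion.** Per mini-batch, the maximum-mean-discrepancy
penalty
$L_M = \lVert \frac1{|G_F|}\sum \phi(g_F) - \frac1{|G_S|}\sum \phi(g_S)\rVert$
pulls the two embedding distributions together; the embeddings are
concatenated (functional first) and classified by a 64-unit ReLU layer, a
2-unit layer and a softmax. Training minimizes
$L = L_C + \lambda L_M$, where $L_C$ is mean binary cross-entropy on the
class-1 probability, with Adam.

Ablation variants keep the same surface: `structural` and `functional`
train one branch with a 64 -> 64 -> 2 head (capacity comparable to the
fused head), `no_mmd` sets $\lambda = 0$, and `late_fusion` trains the two
single-branch classifiers independently and averages their softmax
outputs with weight `lfWeight` on the functional branch.

## Assumptions

- Images arrive preprocessed: registered, segmented, atlas-averaged BOLD
  series and modulated gray-matter maps. The package does no slice
  timing, realignment, normalization or filtering.
- Connectivity is static full-scan Pearson correlation; no windowed or
  dynamic variants.
- The diagnosis is binary, with class 1 the patient class throughout
  (losses, metrics, reported probabilities).

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| graph strategy | `knn` | `threshold` and `full` available |
| `k` (knn) | 10 | neighbours per node before OR-symmetrization |
| `q` (threshold) | 0.2 | applied to connectivity strength |
| edge strength | `absolute` | `signed` available as a switch |
| GCN widths | 64, 64 | head 64 |
| CNN channels | 16, 32, 64, 128 | 3–6 blocks supported |
| FC widths | 128, 64 | dropout 0.5 after each (train only) |
| $\lambda$ | 0.01 | weight of $L_M$ |
| MMD kernel | linear | RBF with median-heuristic bandwidth optional |
| optimizer | Adam, lr 1e-4 | weight decay 0.0015 on weights only |
| epochs / batch | 100 / 16 | flat schedule, no early stopping |

The defaults mirror the full-scale recipe; the desk-scale configuration
used by the package's own test suite is described below.

Several details are deliberate choices where more than one reading was
possible:

- **Connectivity "strength" is $|b_{ij}|$** for both the KNN and the
  threshold construction: strength is a magnitude, and strong
  anticorrelations are biologically meaningful edges. A `signed` switch
  exists for sensitivity analyses.
- **k = 10** for the KNN graph: a common sparsity for connectomes of
  roughly a hundred nodes; it is a required, visible configuration field
  rather than a hidden constant.
- **Top-k selection is symmetrized by logical OR** (an edge survives if
  either endpoint selects it), because the graph is declared undirected;
  ties at the k-th rank break towards the lower ROI index so results are
  platform-independent.
- **Self-loops are never stored** in a `ConnectivityGraph`; they are
  added exactly once, inside `normalizeAdjacency()`, whose degree matrix
  is computed on $A + I$ so degrees are strictly positive and the
  operator is always finite.
- **The functional branch ends in a fully-connected layer** (128 -> 64)
  so that the MMD penalty compares like-sized features; its width matches
  the structural branch's final FC layer.
- **$\phi$ is the identity map by default** (linear-kernel MMD, the
  distance between batch feature means) and the penalty is the unsquared
  norm, matching the loss as written; a squared option and an RBF kernel
  are available. At the origin the unsquared norm is not differentiable;
  the gradient is defined as zero there.
- **MMD is computed per mini-batch** between the two modality embeddings
  of the same subjects — the only tractable reading for a loss term.
- **Dropout applies after each of the two structural FC layers**, taken
  literally; the graph-convolution layers carry no dropout and no biases.
- **Weight decay** is added to the gradient of weight matrices and
  convolution kernels only, never to biases or batch-norm parameters.

## Numerical choices

- Batch normalization uses $\varepsilon = 10^{-5}$ and momentum 0.1 for
  running moments; batch variance is the biased estimator, the running
  variance the unbiased one. Training-mode batches must contain at least
  2 subjects; a trailing singleton batch is merged with its predecessor.
- **Post-training re-estimation of batch-norm moments.** Exponential
  running moments estimated during optimization describe activations of
  *earlier* weights; on small cohorts this lag is large enough to corrupt
  evaluation-mode predictions. After the last epoch the package therefore
  freezes the weights and recomputes each layer's population mean and
  variance exactly, in one pass over the training set. Evaluation is
  bit-deterministic.
- Weight initialization is uniform Glorot (fan-based), drawn from the
  seeded RNG; the seed also controls batch shuffling, dropout masks and
  the data split, so a full run is bit-reproducible.
- Cross-entropy probabilities are clipped to $[10^{-7}, 1-10^{-7}]$
  before the logarithm; gradients use the exact softmax form.
- Max-pooling drops trailing voxels that do not fill a window (floor
  division), which is what produces the 121 -> 60 -> 30 -> 15 -> 7 chain;
  pooling ties resolve to the first voxel in memory order.
- Volumes are standardized per subject (mean 0, sd 1) before the first
  block; a configuration switch disables this.

## The synthetic cohort generator

Real consortium data of this kind are access-restricted, so the package
ships a seeded generator with the statistical structure the model
assumes, making every training-dependent property testable:

- **Functional modality**: zero-mean multivariate-normal series whose
  covariance is a community-block correlation matrix (communities of 5
  ROIs, within-community correlation 0.3), plus a shift of 0.4 on eight
  designated cross-community edges for class 1. Positive definiteness is
  restored, when needed, by the smallest sufficient convex shrinkage
  toward the base matrix (bisection on the minimum eigenvalue). AR(1)
  smoothing (`x_t = a x_{t-1} + sqrt(1-a^2) z_t`, a = 0.3) models BOLD
  autocorrelation while preserving the cross-sectional covariance.
- **Structural modality**: a smooth ellipsoidal intensity profile plus
  voxelwise Gaussian noise (sd 0.3), with class-1 intensity reductions of
  0.5 inside four radius-3 spherical blobs — a stylized atrophy pattern.
  Each affected subject's blob effect is scaled by a uniform severity
  multiplier in [0.1, 1]: patient groups are heterogeneous, and the
  severity gradient keeps every patient informative for training while
  leaving mild cases close to the control distribution, so the structural
  modality alone cannot be perfect.
- **Complementarity**: `modalitySignalSplit` routes a fraction of the
  effect list exclusively to the functional modality and the rest
  exclusively to the structural one. At the default 0.5, four effect
  edges and two blobs are active, neither modality carries the full class
  signal, and fusing them is provably better than either alone — which is
  exactly what the acceptance suite trains models to demonstrate.

The generator emulates second-order functional structure and regional
volumetric differences. It does **not** emulate hemodynamic response
shapes, motion or physiological artifacts, site or scanner effects,
registration error, or realistic cortical geometry. Passing tests
therefore demonstrate that the architecture, losses and training loop do
what they claim on data with the assumed statistical structure — not that
the method attains any particular accuracy on real clinical cohorts.

## Desk-scale configuration

The test and acceptance runs use cohorts of 150 + 150 subjects with 20
ROIs, 120 time points and 24x28x24 volumes, a three-block CNN with
4/8/16 channels, the default GCN, batch 16, 30 epochs, and Adam at
lr 1e-3 — larger than the full-scale 1e-4 because a desk run takes about
450 optimization steps where a full-scale run takes thousands. These
sizes keep a single training run under a minute while preserving every
architectural element; the input size is a parameter, not part of the
contract, and `propagateShapes()` validates any combination before
weights are allocated.

## Known limitations

- Training is single-device, full-precision, with no learning-rate
  schedule, early stopping, or hyperparameter search beyond the exposed
  $\lambda$ and depth/width grids.
- The MMD penalty aligns *marginal* embedding distributions; it does not
  enforce subject-level correspondence between modalities.
- Alternative alignment objectives (adversarial, optimal transport) and
  attention/Chebyshev graph filters are out of scope.
- The paired t-test pools each subject's test-set occurrences across
  repeats as independent pairs; that pooling is a documented convention
  of this package, and other conventions exist.
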