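# neurofuse

Multimodal fusion of functional and structural MRI for binary
brain-disorder classification (for example, separating patients with
major depressive disorder from healthy controls).

Resting-state fMRI and structural MRI carry complementary information —
large-scale functional connectivity on one side, regional gray-matter
morphology on the other — but their feature spaces are heterogeneous, and
naive concatenation lets that heterogeneity dominate. `neurofuse` builds
a two-branch classifier that encodes each modality separately, explicitly
*aligns* the two embedding spaces, and fuses them for the diagnosis:

- **Functional branch.** Regional BOLD time series → Pearson functional
  connectivity matrix `B` → graph (k-nearest-neighbour sparsification by
  default; threshold and fully-connected constructions available) with
  node features `X = B` → two spectral graph-convolution layers
  `H⁽ˡ⁺¹⁾ = ReLU(Ã H⁽ˡ⁾ W⁽ˡ⁾)`, `Ã = D̂^{-1/2}(A+I)D̂^{-1/2}` → mean‖max
  readout → 64-dim embedding `g_F`.
- **Structural branch.** 3D gray-matter volume → stacked blocks of
  3×3×3 same-padding convolution + batch norm + ReLU + 2×2×2 max-pool
  (16/32/64/128 channels by default) → global average pooling → two FC
  layers (128, 64; dropout 0.5) → 64-dim embedding `g_S`.
- **Alignment + fusion.** A cross-modal maximum-mean-discrepancy penalty
  `L_M = ‖mean φ(g_F) − mean φ(g_S)‖` is added to the cross-entropy
  `L_C`, giving the training loss `L = L_C + λ·L_M` (λ = 0.01 by
  default); the concatenated embeddings feed a 64→2 softmax head.

The package also provides the ablation variants (single-branch models,
λ = 0, decision-level fusion with weighted softmax averaging), a
repeated 80/20-holdout evaluation protocol with eight metrics
(ACC/SEN/SPE/BAC/PPV/NPV/F1/AUC) and paired t-tests on predicted
probabilities, a seeded synthetic two-class multimodal cohort generator,
readers/writers for time-series TSV and NIfTI volumes, and a command-line
front end (`inst/cli/neurofuse.R`) with `simulate`, `connectome`,
`train`/`evaluate`, `compare` and `sweep` subcommands.

All neural-network arithmetic (3D convolution, batch normalization,
pooling, graph convolution, backpropagation, Adam) is implemented in the
package itself, with the dense 3D kernels in compiled code; training is
bit-reproducible under a fixed seed.

## Worked example

Generate a synthetic cohort whose class signal is split between the two
modalities, then train and evaluate the fused model:

```r
library(neurofuse)

cfg <- syntheticCohortConfig(nClass0 = 60, nClass1 = 60, seed = 42)
cohort <- generateCohort(cfg)
cohort[[1]]$ts
#> TimeSeriesMatrix 'sub001': 120 time points x 20 ROIs

B <- pearsonFCN(cohort[[1]]$ts)
B
#> ConnectivityMatrix (pearson): 20 x 20, range [-0.226, 1.000]
buildKnnGraph(B, k = 10)
#> ConnectivityGraph [knn (param 10)]: 20 nodes, 111 undirected edges

prep <- prepareCohort(cohort, strategy = "knn", k = 10)
tc <- trainConfig(variant = "multimodal", epochs = 30, batchSize = 16,
                  learningRate = 1e-3, seed = 1,
                  cnn = cnnBranchConfig(convChannels = c(4, 8, 16)))
ev <- repeatedHoldout(prep,
        function(coh, seed) { tc$seed <- seed; trainModel(coh, tc) },
        nRepeats = 2, baseSeed = 1)
print(ev)
#> Repeated-holdout evaluation:
#>   ACC: 0.729 (0.029)
#>   SEN: 0.708 (0.059)
#>   SPE: 0.750 (0.118)
#>   BAC: 0.729 (0.029)
#>   PPV: 0.746 (0.076)
#>   NPV: 0.721 (0.009)
#>   F1: 0.724 (0.005)
#>   AUC: 0.812 (0.088)
```

Each line is a test-set metric, mean (standard deviation) over the
independent random partitions: the fused model recovers about 73% of the
diagnoses and ranks patients above controls with AUC ≈ 0.81 on this
120-subject cohort, where neither modality carries the full class signal
(see the methods vignette for what the generator does and does not
emulate). Paired significance testing between two methods' saved test
probabilities uses `pairedTTest()`:

```r
pairedTTest(c(2, 4, 6), c(1, 2, 3))[c("t", "df", "p")]
#> $t
#> [1] 3.464102
#> $df
#> [1] 2
#> $p
#> [1] 0.07417990
```

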