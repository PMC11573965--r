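# meshgat

Benign/malignant classification of breast-tumor lesions from the
three-dimensional shape of their surface mesh.

Radiologists separate benign from malignant breast masses largely by
margin morphology: benign lesions tend to be oval, smooth or gently
macrolobulated, while malignant lesions are larger, irregular,
microlobulated and spiculated. `meshgat` turns that contrast into a
quantitative pipeline for closed triangle meshes of tumor regions:

1. **Mesh I/O and quality control.** Read/write PLY (ascii and binary
   little-endian), OBJ, OFF and STL. A mesh is rejected when more than 10%
   of its undirected edges are boundary edges (edges incident to exactly
   one triangle — the discrete signature of surface holes left by
   reconstruction). Signed-distance queries (closest point, offset,
   unsigned and signed distance via angle-weighted pseudo-normals) support
   geometric analysis of the surfaces.
2. **Ten shape features per mesh.** With λ₁ ≥ λ₂ ≥ λ₃ ≥ 0 the normalized
   covariance eigenvalues of a vertex's k-nearest-neighbor patch
   (k = 30), averaged over vertices:
   curvature `C = mean(λ₃/(λ₁+λ₂+λ₃))`, anisotropy
   `A = mean((λ₁−λ₃)/λ₁)`, eigen entropy `E = mean(−Σ λᵢ ln λᵢ)`;
   plus volume `V = |Σ ⅙ (v₁×v₂)·v₃|`, surface area
   `Sₐ = Σ ½ ‖(v₂−v₁)×(v₃−v₁)‖`, sphericity
   `S = π^{1/3}(6V)^{2/3}/Sₐ` (1 for a sphere), mesh diameter, mean
   centroid-to-vertex distance, and min/max vertex-to-bounding-box-corner
   distances.
3. **Feature assessment.** One-way ANOVA F per feature (for two groups,
   exactly the squared pooled t statistic) and greedy
   minimum-redundancy maximum-relevance ranking (F-relevance /
   mean-|correlation|-redundancy quotient), plus a subset-mean pattern
   analysis per class.
4. **Sample-similarity graph.** Rows of the feature table become nodes;
   an undirected edge connects two meshes when the Spearman correlation of
   their ten-feature profiles is ≥ 0.7.
5. **Graph attention network.** A multi-head graph attention classifier
   (scores `e_ij = LeakyReLU(a·[Wx_i ‖ Wx_j])`, softmax-normalized
   attention per neighborhood, heads concatenated on hidden layers and
   averaged on the last) trained transductively with momentum gradient
   descent; stratified splits, confusion-matrix metrics, k-fold cross
   validation and a sequential one-axis-at-a-time ablation protocol.

A synthetic tumor-shape generator (`make_dataset()`) emulates the two
morphologies as radially deformed icospheres — watertight by construction,
bit-reproducible per seed, with a `separation` dial from identical classes
(0) to full contrast (1) — so the whole pipeline is exercisable without any
clinical data.

## Worked example

```r
library(meshgat)

ds  <- make_dataset(n_benign = 30, n_malignant = 15, separation = 0.8, seed = 7)
tab <- build_feature_table(ds$meshes, ds$labels)
round(tab[1:3, c("unique_id", "sphericity", "curvature", "volume", "surface_area")], 4)
#>   unique_id sphericity curvature volume surface_area
#> 1         1     0.9170    0.0525 6.7438      18.8242
#> 2         2     0.7550    0.1208 1.9498       9.9972
#> 3         3     0.8003    0.0982 4.7474      17.0682

g <- build_graph(tab, threshold = 0.7, standardize = TRUE)
g
#> sample_graph: 45 nodes, 137 edges (threshold >= 0.7)
#>   intra-benign 95, intra-malignant 40, inter-class 2

fit <- train_gat(tab, g, gat_config(attention_layers = 1L, heads = 4L,
                                    learning_rate = 5e-3, batch_size = 16L,
                                    epochs = 150L, seed = 42))
fit
#> gat_model: 1 attention layers x 4 heads, 32 hidden units
#>   accuracy train 96.77% / validation 100.00% / test 100.00%
fit$report$confusion
#> TP TN FP FN
#>  3  5  0  0
```

Row 1 is a smooth benign-like mesh (sphericity 0.92, low curvature); row 2
is a spiculated malignant-like mesh (sphericity 0.76, curvature 0.12, and
note it is *smaller* here only because of per-mesh size jitter — the class
*means* differ strongly). Of the 137 graph edges only 2 cross the class
boundary, and the attention classifier separates the held-out nodes
perfectly on this small cohort.

The full pipeline — simulate, QC, features, ANOVA/MRMR, patterns, graph,
train, evaluate, with every artifact written to a run directory — is one
call:

```r
res <- run_all(pipeline_config(n_benign = 120, n_malignant = 60, seed = 1))
res$report$metrics[["test_accuracy"]]
```

A thin command-line front end with the same stages as subcommands
(`simulate`, `roi`, `qc`, `features`, `select`, `patterns`, `graph`,
`sweep`, `train`, `cv`, `run-all`) is installed at
`system.file("cli", "meshgat", package = "meshgat")`.

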