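# rrgcn

Multi-omics cancer subtype classification with a residual graph
convolutional network.

## What this solves

Tumour subtypes — e.g. the four TCGA molecular subtypes of gastric
adenocarcinoma (EBV, MSI, GS, CIN, coded 0–3) — are defined jointly by
several omics layers, and molecularly similar patients tend to share a
subtype. `rrgcn` classifies patients from three omics views (expression,
copy number, somatic mutation features) by combining both sources of
information:

1. **Cleaning** — dead features (zero/missing everywhere) dropped,
   duplicated feature ids resolved to the column with smallest |mean|,
   optional `log2(FPKM + 0.1)` for expression, median imputation.
2. **Weighted autoencoder** — the concatenated views (min–max scaled) pass
   through a fully connected sigmoid autoencoder with hidden widths
   (500, 200, 500); the reconstruction loss is the per-view weighted MSE
   `L = a·mse(x₁, x̄₁) + b·mse(x₂, x̄₂) + c·mse(x₃, x̄₃)` with
   `a, b, c = 0.4, 0.3, 0.3`. The 200-dimensional middle layer is the
   node-feature matrix `X`.
3. **Patient similarity network** — per view, a scaled exponential kernel
   `W(i,j) = exp(−ρ²(xᵢ,xⱼ)/(μ·ε(i,j)))` (μ = 0.5, K = 20 neighbours) is
   normalized (`P`, diagonal ½) and localized (`S`, row-stochastic kNN
   affinity); similarity network fusion iterates
   `Pᵥ ← Sᵥ (Σₖ≠ᵥ Pₖ / (m−1)) Sᵥᵀ` to a fused network. Patients whose
   fused similarity profiles correlate above a Pearson threshold (0.8)
   are joined by an edge, giving a binary adjacency `A`.
4. **Residual GCN** — with `Â = D̃^(−1/2)(A + I)D̃^(−1/2)`, four graph
   convolution layers of widths 64, 32, 16, k are wrapped in two residual
   blocks whose skip connections add an independent linear projection of
   `X` (`H ← elu(H + XB + b)`), followed by a softmax. Training is
   transductive with masked cross-entropy, Adam (lr 1e-4, weight decay
   0.01), 1200 epochs.

Evaluation is repeated stratified 5-fold cross-validation reporting
macro-averaged precision, recall, F1, ROC AUC, PR AUC and global accuracy.
A synthetic multi-omics cohort generator with planted subtype structure
(default: 272 samples in classes of 25/60/51/136, three views) makes every
stage testable without any data download; single- vs multi-omics ablation
and grid-searched random-forest / SVM baselines are included.

## Worked example

```r
library(rrgcn)

spec <- cohortSpec(classSizes = c(10, 20, 15, 35),
                   views = list(list(name = "mrna", nFeatures = 60, nInformative = 16),
                                list(name = "cnv",  nFeatures = 40, nInformative = 8)),
                   effectSize = 2.5, seed = 1)
cohort <- generateCohort(spec)
clean  <- lapply(cohort$views, preprocessView)
ae     <- trainAutoencoder(clean, aeConfig(hiddenDims = c(60, 24, 60),
                                           epochs = 150, seed = 1))
ae$latent
#> LatentFeatures: 80 samples x 24 latent dimensions

bundle <- buildSimilarityBundle(lapply(clean, viewMatrix), K = 15)
graph  <- buildPatientGraph(bundle, threshold = 0.8)
graph
#> PatientGraph: 80 patients, 4 edges (density 0.001)

report <- repeatedStratifiedCV(ae$latent, graph, unname(cohort$labels),
                               cfg = rrgcnConfig(nClasses = 4),
                               folds = 5, repeats = 2, seed = 1)
report
#> MetricsReport: 2 repeat(s) x 5 fold(s)
#>   precision = 0.9073, recall = 0.9268, f1 = 0.9111, accuracy = 0.9437, auc = 0.9978, pr_auc = 0.9912
```

Reading the output: the cohort plants a 2.5-noise-SD mean shift on a few
informative features per class, so the latent space separates most — not
all — patients; held-out accuracy 0.94 and macro AUC 0.998 say the planted
four-class structure is recovered almost everywhere, with the residual
confusion concentrated in the smallest class (n = 10; see
`perClassMetrics(report)`). At this signal strength the 0.8 correlation
threshold admits only 4 edges, so most of the performance here comes from
the latent features; stronger cohorts produce dense within-class graphs.

The same stages are scriptable from a shell via
`inst/scripts/rrgcn-cli.R` (subcommands `simulate`, `preprocess`,
`train-ae`, `build-graph`, `train`, `evaluate`, `ablation`, `baselines`,
`run`), and `runPipeline()` executes everything end to end from a YAML
config, persisting every intermediate and reproducing bit-identically for
a fixed master seed.

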