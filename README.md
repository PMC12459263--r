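# scBatchNet

Batch-effect correction for heterogeneous single-cell expression data, for
analysts who need to integrate batches from different experiments,
platforms or donors **without** letting the correction blur genuine cell
types.

## What it does

Integration proceeds in two phases:

1. **Cross-batch clustering** decides which populations are the same
   across batches:
   * high-resolution Leiden clustering within each batch (SNN graph in
     100-PC space, resolution 3.0), deliberately over-segmenting;
   * mutual nearest-neighbour (MNN) pairs between every batch pair
     (cosine distance on the first 10 PCs, k = 10), including intra-batch
     pairs, expanded for T = 10 steps by a deterministic
     nearest-neighbour walk that propagates pairs to each endpoint's
     within-batch 1-NN;
   * a cluster-level similarity graph — edge weight = #MNN pairs linking
     two clusters / (|c|·|d|) — partitioned by normalized-Laplacian
     spectral clustering, with the group count chosen by the largest
     eigengap unless overridden.
2. **A residual correction network** (two blocks of
   linear–batchnorm–PReLU–linear–batchnorm with identity skips, then a
   linear projection to 32 dimensions) embeds cells so that the global
   cluster labels are geometrically enforced, by minimising the tuplet
   margin loss with mini-batch SGD:

   L = log(1 + Σᵢ exp{d(xₐ, xₚ) − d(xₐ, xₙᵢ)}),

   where d is the Euclidean distance between embeddings, xₐ an anchor,
   xₚ a positive from the same global cluster and xₙᵢ negatives from
   other clusters.

The package also ships the standard preprocessing workflow (QC →
library-size normalisation ×10⁴ + log1p → 2000 HVGs → z-score → 100-PC
PCA), a Splatter-style multi-batch negative-binomial count simulator, an
integration metric suite (ARI, NMI, cell-type silhouette width, an iLISI
deviation score, BatchKL, plus two composites), and readers/writers for
CSV, MatrixMarket triplets and AnnData h5ad containers.

See `vignettes/integration-method.Rmd` for the full methodological
account.

## Worked example

```r
library(scBatchNet)

ds  <- make_dataset1_analog(seed = 0)   # 4 types x 3 batches, 2000 x 2000
run <- run_pipeline(ds, bn_config(rng_seed = 0))
print(run)
```

```
<bn_run> 2000 cells, 4 global clusters, embed dim 32
<bn_metric_report>
  ari                      1.0000
  nmi                      1.0000
  asw_celltype             0.7747
  ilisi                    0.1351
  batch_kl                 0.0790
  biological_conservation  0.9249
  batch_mixing             0.5094
```

Reading the report: the global cluster labels match the simulated cell
types exactly (ARI = NMI = 1); the corrected embedding separates types
more cleanly than raw PCA (cell-type silhouette 0.77 vs 0.61); and batches
are well mixed (BatchKL 0.08 vs 1.04 on raw PCA; the iLISI deviation score
is near its ideal of 0 — for both mixing metrics lower is better).

```r
# persist results: CSV always, plus write-back into an h5ad container
save_result(run$embedding, run$clusters$global$assignment,
            "corrected.csv")
```

A thin command-line front end is installed under
`inst/cli/scbatchnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/scbatchnet.R", package="scBatchNet"))')" \
    simulate --seed 0 --output sim.h5ad
Rscript .../scbatchnet.R run --input sim.h5ad --format h5ad \
    --batch-key batch --label-key cell_type --seed 0 --out-dir run1
```

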