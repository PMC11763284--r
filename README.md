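# cci — consensus-clustering imputation of scRNA-seq dropouts

Single-cell RNA-seq count matrices are riddled with *dropouts*: genes that
are expressed in a cell but recorded as zero because of technical capture
failure, with lower-expressed genes dropping out more often. Dropouts blur
cell-type structure, corrupt differential-expression (DE) calls, and bias
per-gene analyses. This package is for analysts who want to fill those zeros
using information from transcriptionally similar cells — without a
parametric model of the dropout process and without touching any nonzero
measurement.

## The method

Cell-to-cell similarity is estimated by **consensus clustering**. With a
log-normalized matrix $X$ (genes × cells):

1. sample a proportion $p$ of a variable-gene pool, embed the subset
   (PCA → 2-D UMAP), cluster with K-means ($k$ clusters), and record the
   binary co-membership matrix $C^{(t)}_{ij} = \mathbb 1\{i,j \text{ share a
   cluster}\}$;
2. repeat $m$ times and average into the consensus matrix
   $\bar C = \frac1m\sum_t C^{(t)}$, whose $(i,j)$ entry is the fraction of
   runs in which cells $i$ and $j$ co-clustered;
3. define neighbor weights $w_{ik} = \bar C_{ik}\,\mathbb 1\{\bar C_{ik} \ge c\}$
   (self-weight zero), and impute each zero entry as the weighted average

$$\hat x_{ij} = \frac{\sum_{k\neq i} w_{ik}\,x_{kj}}{\sum_{k\neq i} w_{ik} + \epsilon}.$$

Defaults: $p=0.8$ over the top-100 variable genes, $k=4$, $m=50$, $c=0.2$,
$\epsilon=10^{-6}$, weighted averaging. An unweighted variant (plain mean
over qualifying neighbors) is available. Cells with no neighbor above the
cutoff keep their zeros, which also protects biological zeros shared across
a neighborhood.

The package additionally ships a Splat-style synthetic-data generator
(gamma gene means, expression outliers, log-normal DE factors and library
sizes, BCV overdispersion, Poisson counts, mean-dependent logistic dropout),
Seurat-style log normalization and variable-gene selection, SNN/Louvain
clustering, and an evaluation suite (adjusted Rand index, compactness
$B/(B+W)$, Wilcoxon DE calling with Jaccard/sensitivity/specificity against
the simulated truth, and per-gene Spearman recovery).

## Worked example

```r
library(cci)

# two groups, moderate DE signal, moderate dropout
sim <- splat_simulate(sim_params(seed = 1, de_fac_loc = 0.2, dropout_mid = 4,
                                 cells_per_group = 500))
sim
#> Simulated scRNA-seq dataset: 500 genes x 1000 cells, 2 groups
#>   true DE genes: 102
#>   zero fraction after dropout: 65.6% (65.5% zeroed by dropout)

fit <- cci_run(sim$counts_dropout, cci_params(seed = 1))
fit
#> CCI run: 500 genes x 1000 cells, m = 50, weighted imputation
#>   imputed 328149 zero entries (65.6% of matrix) in 48.3s

truth <- log_normalize(sim$counts)
corrupted <- log_normalize(sim$counts_dropout)

# clustering recovery: corrupted vs imputed
cl_drop <- snn_cluster(corrupted, embed = FALSE)
cl_imp  <- snn_cluster(fit$imputed, embed = FALSE)
adjusted_rand_index(cl_drop$labels, sim$group_labels)
#> [1] 0.6786544
adjusted_rand_index(cl_imp$labels, sim$group_labels)
#> [1] 0.9525285

# per-gene recovery of the true expression pattern (true DE genes)
gene_recovery_correlation(corrupted, truth, sim$true_de_genes)[1]
#> [1] 0.3397371
gene_recovery_correlation(fit$imputed, truth, sim$true_de_genes)[1]
#> [1] 0.3954188
```

Dropout at this level degrades the two-group structure (ARI 0.68 against the
simulated labels); after imputation SNN clustering recovers it almost fully
(ARI 0.95), and the average per-gene Spearman correlation with the
dropout-free truth rises from 0.34 to 0.40. Imputed values replace only
zeros — nonzero entries are bit-identical to the input.

A command-line wrapper over the same functions is installed at
`system.file("cli", "cci", package = "cci")` with subcommands `simulate`,
`normalize`, `consensus`, `impute`, `evaluate`, and `benchmark`.

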