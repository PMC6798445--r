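# divimpute

Dropout imputation for single-cell RNA-seq count matrices by
divide-and-conquer neural sub-networks, together with the evaluation
machinery needed to judge whether imputation actually helped: a realistic
masking benchmark, clustering-agreement metrics, a differential-expression
recovery score, and distribution comparisons against orthogonal
measurements such as single-molecule RNA FISH. A built-in Splatter-style
count simulator with full ground truth makes every stage testable offline.

## The problem

Droplet-based scRNA-seq measures each transcript in each cell with low
capture efficiency, so many true transcripts are recorded as zeros
("dropouts"). Those false zeros blur cell-type structure and hide
differentially expressed genes. Imputation replaces likely dropouts with
predicted values while leaving everything actually measured untouched.

## The method

Let `Y` be the `log(1 + x)`-transformed count matrix (cells × genes).

1. **Gene selection.** Only genes with variance-over-mean ratio above a
   threshold (default 0.5) are imputed; the rest pass through unchanged.
2. **Divide and conquer.** The imputable genes are shuffled into subsets of
   at most `S = 512` *target* genes. Each subset gets its own small dense
   network: inputs are the top 5 non-target genes by absolute Pearson
   correlation with each target (union over targets), one hidden layer of
   256 rectified units, 20% training-time dropout, and a rectified output
   per target gene.
3. **Weighted loss.** Each sub-network is trained with Adam (learning rate
   1e-4, batch size 64) on the per-cell loss

   `Loss_c = Σ_i Y_ci · (Y_ci − Ŷ_ci)²`

   which weights residuals by the observed value: confidently measured
   (high) entries dominate, and observed zeros — the very entries suspected
   of being dropouts — contribute nothing.
4. **Early stopping.** Cells are split 95%/5%; training stops when the
   held-out loss fails to improve for 5 consecutive epochs (or at 500
   epochs), restoring the best weights.
5. **Imputation.** Predictions are transformed back to the raw scale and
   written into the matrix **only where the input is zero**; every nonzero
   entry is preserved bit-exactly.

## Worked example

```r
library(divimpute)

# simulate a small grouped dataset with known dropout
sim <- simulate_counts(sim_params(n_genes = 600, n_cells = 400, seed = 7))
sim$counts
#> <expression_matrix> 400 cells x 600 genes, raw space
#>   zeros: 12.1%; value range: [0, 1.41e+03]

# fit the imputer and fill in the zeros
fit <- divimpute(sim$counts, seed = 7)
fit
#> Divide-and-conquer dropout imputer
#>   2 sub-networks over 600 imputable genes (of 600); activation: relu
#>   cells: 380 train / 20 test
imputed <- predict(fit)

# benchmark: hide known nonzero entries, ask the model to recover them
bm <- masking_benchmark(sim$counts, config = train_config(seed = 7),
                        n_per_gene = 10, seed = 7)
bm$report
#> <accuracy_report> 6000 masked entries
#>   MSE (log counts): 0.1293   Pearson: 0.7813
bm$baseline_reports$gene_mean$overall_mse  # 0.1352 - filling with gene means
bm$baseline_reports$zero$overall_mse       # 24.49  - leaving zeros in place
```

The report says: on entries hidden from the model, its reconstructions are
closer to the truth (log-scale MSE 0.129) than the strong per-gene-mean
baseline (0.135) and vastly closer than not imputing at all (24.5), with a
Pearson correlation of 0.78 to the held-out values.

Downstream metrics take any labelling/embedding:

```r
auc <- de_auc(imputed, sim$truth$group, sim$truth, top_n = 500)
adjusted_rand(sim$truth$group, sim$truth$group)   # 1 on identical partitions
```

A command-line wrapper over the same functions ships in
`inst/cli/divimpute.R` with subcommands `simulate`, `impute`, `benchmark`
and `evaluate`.

## Scope

The package implements the imputation method and its evaluation metrics.
It does not compute UMAP embeddings or graph clusterings (it consumes them
as inputs), does not wrap competing imputation tools, and reads only dense
CSV/TSV and MatrixMarket (10x-style) matrices.
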