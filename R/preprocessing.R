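#' Select imputable genes by variance-over-mean ratio
#'
#' Dropout imputation is only worthwhile for genes with appreciable
#' dispersion; following common single-cell practice, genes are kept when
#' their variance-over-mean ratio (VMR) on raw counts exceeds a threshold
#' (default 0.5). Genes with zero mean have an undefined ratio and are never
#' selected.
#'
#' @param matrix An [expression_matrix] in raw space.
#' @param threshold VMR cut-off; a gene is selected when `vmr > threshold`
#'   (strict).
#' @param variance `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1). The convention only shifts genes on the threshold
#'   boundary.
#' @return A list of class `gene_selection` with elements
#'   `imputable_genes` (character, in original column order), `vmr`
#'   (named numeric over all genes; `NA` for zero-mean genes) and
#'   `threshold`.
#' @export
select_genes <- function(matrix, threshold = 0.5,
                         variance = c("population", "sample")) {
  variance <- match.arg(variance)
  matrix <- as_expression_matrix(matrix)
  if (em_space(matrix) != "raw") stop_validation("select_genes expects raw counts")
  v <- em_values(matrix)
  if (ncol(v) == 0 || nrow(v) == 0) stop_validation("empty expression matrix")
  n <- nrow(v)
  mu <- colMeans(v)
  ss <- colMeans(v^2) - mu^2
  var_g <- if (variance == "population") ss else ss * n / (n - 1)
  vmr <- ifelse(mu > 0, var_g / mu, NA_real_)
  names(vmr) <- colnames(v)
  keep <- !is.na(vmr) & vmr > threshold
  structure(list(imputable_genes = colnames(v)[keep],
                 vmr = vmr, threshold = threshold, variance = variance),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("<gene_selection> %d imputable genes (vmr > %g, %s variance) of %d\n",
              length(x$imputable_genes), x$threshold, x$variance, length(x$vmr)))
  invisible(x)
}

#' Log-transform counts
#'
#' Element-wise `log(1 + x)` with a pseudo-count of 1, the transform under
#' which the networks are trained. [inverse_log_transform()] restores the raw
#' scale.
#'
#' @param matrix An [expression_matrix] in raw space.
#' @return An [expression_matrix] in log space.
#' @export
log_transform <- function(matrix) {
  matrix <- as_expression_matrix(matrix)
  if (em_space(matrix) != "raw") stop_validation("matrix is already log-transformed")
  expression_matrix(log1p(em_values(matrix)), space = "log")
}

#' @rdname log_transform
#' @export
inverse_log_transform <- function(matrix) {
  matrix <- as_expression_matrix(matrix, space = "log")
  if (em_space(matrix) != "log") stop_validation("matrix is not in log space")
  expression_matrix(pmax(expm1(em_values(matrix)), 0), space = "raw")
}

#' Partition genes into random target subsets
#'
#' Shuffles the gene list with a seeded RNG and splits it into
#' `ceiling(length(genes) / subset_size)` balanced groups whose sizes differ
#' by at most one. Each group becomes the output (target) layer of one
#' sub-network.
#'
#' @param genes Character vector of gene identifiers.
#' @param subset_size Maximum genes per subset (default 512).
#' @param seed Integer seed controlling the shuffle.
#' @return A list of character vectors; disjoint, union equal to `genes`.
#' @export
partition_targets <- function(genes, subset_size = 512, seed = 1) {
  if (length(genes) == 0) stop_validation("no genes to partition")
  if (subset_size < 1) stop_validation("subset_size must be >= 1")
  shuffled <- with_seed(seed, sample(genes))
  n <- length(genes)
  n_groups <- ceiling(n / subset_size)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  split(shuffled, rep(seq_len(n_groups), times = sizes))
}

#' Select predictor genes for a target subset
#'
#' For each target gene, ranks every non-target gene by the absolute Pearson
#' correlation with it (computed on log-space values across cells) and keeps
#' the top `k`; the union over targets, deduplicated and returned in the
#' matrix's column order, is the sub-network's input layer. Constant genes
#' (zero variance) have undefined correlations and are never selected. Ties
#' are broken by column order.
#'
#' @param matrix An [expression_matrix] in log space containing the targets.
#' @param targets Character vector of target gene identifiers.
#' @param k Predictors retained per target (default 5).
#' @return Character vector of predictor gene identifiers.
#' @export
select_predictors <- function(matrix, targets, k = 5) {
  matrix <- as_expression_matrix(matrix, space = "log")
  if (em_space(matrix) != "log") stop_validation("predictor selection expects log space")
  if (k < 1) stop_validation("k must be >= 1")
  v <- em_values(matrix)
  all_genes <- colnames(v)
  if (!all(targets %in% all_genes)) {
    stop_validation("targets absent from matrix: ",
                    paste(setdiff(targets, all_genes), collapse = ", "))
  }
  candidates <- setdiff(all_genes, targets)
  if (length(candidates) == 0) stop_validation("no non-target genes available as predictors")
  r <- suppressWarnings(stats::cor(v[, candidates, drop = FALSE],
                                   v[, targets, drop = FALSE]))
  score <- abs(r)
  score[is.na(score)] <- -Inf # constant genes: undefined correlation
  chosen <- logical(length(candidates))
  kk <- min(k, length(candidates))
  for (j in seq_along(targets)) {
    ord <- order(-score[, j], seq_along(candidates))[seq_len(kk)]
    ord <- ord[is.finite(score[ord, j])]
    chosen[ord] <- TRUE
  }
  sel <- candidates[chosen]
  sel[order(match(sel, all_genes))]
}
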