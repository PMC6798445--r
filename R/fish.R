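# Comparison of expression distributions against an orthogonal reference
# measurement (e.g. single-molecule RNA FISH), following the
# housekeeping-normalisation / Gini / K-S procedure used for imputation
# validation.

#' Housekeeping-gene normalisation with outlier trimming
#'
#' Removes cells whose housekeeping-gene value lies strictly below the 10th
#' or strictly above the 90th percentile (linear-interpolation percentiles),
#' then rescales each remaining cell's row by
#' `factor(cell) = mean(housekeeping) / housekeeping[cell]`, the mean taken
#' over retained cells. After normalisation every retained cell has the same
#' housekeeping value.
#'
#' @param matrix A raw-space [expression_matrix].
#' @param housekeeping_gene Gene id of the housekeeping gene (e.g. GAPDH).
#' @param lower,upper Trimming percentiles (defaults 0.10 and 0.90).
#' @return The trimmed, rescaled [expression_matrix].
#' @export
gapdh_normalize <- function(matrix, housekeeping_gene, lower = 0.10,
                            upper = 0.90) {
  matrix <- as_expression_matrix(matrix)
  v <- em_values(matrix)
  if (!housekeeping_gene %in% colnames(v)) {
    stop_validation("housekeeping gene not in matrix: ", housekeeping_gene)
  }
  hk <- v[, housekeeping_gene]
  if (all(hk == 0)) stop_validation("housekeeping gene is all-zero")
  q <- stats::quantile(hk, c(lower, upper), type = 7, names = FALSE)
  keep <- hk >= q[1] & hk <= q[2]
  v <- v[keep, , drop = FALSE]
  hk <- hk[keep]
  if (any(hk == 0)) {
    stop_validation("retained cells include zero housekeeping values; cannot rescale")
  }
  factors <- mean(hk) / hk
  expression_matrix(v * factors, space = em_space(matrix))
}

#' Gini coefficient of an expression distribution
#'
#' `sum_ij |x_i - x_j| / (2 n^2 mean(x))` for a non-negative vector; 0 for a
#' constant vector, approaching 1 when all mass sits in one coordinate.
#' Scale-invariant.
#'
#' @param values Non-negative numeric vector, not all zero.
#' @return Scalar in `[0, 1)`.
#' @export
gini <- function(values) {
  if (length(values) < 1) stop_validation("empty vector")
  if (any(values < 0)) stop_validation("values must be non-negative")
  if (all(values == 0)) stop_validation("Gini undefined for an all-zero vector")
  n <- length(values)
  xs <- sort(values)
  # O(n log n) identity for the pairwise-difference sum
  (2 * sum(seq_len(n) * xs)) / (n * sum(xs)) - (n + 1) / n
}

#' Compare per-gene expression distributions to a reference
#'
#' For each shared gene, rescales the method's values by the efficiency
#' factor `mean(reference) / mean(method)` (aligning capture efficiency),
#' then compares distributions: the two-sample Kolmogorov-Smirnov statistic
#' always, and—when the vectors are paired (equal length)—the summed squared
#' difference and the Pearson correlation. Gini coefficients of both vectors
#' are reported for the Gini-agreement analysis. Genes whose method mean is
#' zero are skipped with a warning.
#'
#' @param reference Named list of per-gene numeric vectors (e.g. FISH
#'   measurements).
#' @param method Named list of per-gene numeric vectors (e.g. imputed
#'   expression); compared on the genes shared with `reference`.
#' @param strict_corr Evaluate the correlation with a `Var * Var`
#'   denominator instead of standard Pearson (default FALSE).
#' @return A data.frame of class `fish_comparison`: one row per gene with
#'   `efficiency`, `ks`, `mse`, `corr`, `gini_reference`, `gini_method`,
#'   `n_reference`, `n_method`.
#' @export
distribution_compare <- function(reference, method, strict_corr = FALSE) {
  genes <- intersect(names(reference), names(method))
  if (length(genes) == 0) stop_validation("no shared genes to compare")
  rows <- lapply(genes, function(g) {
    ref <- as.numeric(reference[[g]])
    met <- as.numeric(method[[g]])
    if (length(ref) == 0 || length(met) == 0) {
      stop_validation("empty vector for gene ", g)
    }
    if (mean(met) == 0) {
      warning("gene ", g, " has zero method mean; skipped")
      return(NULL)
    }
    eff <- mean(ref) / mean(met)
    met_s <- met * eff
    ks <- unname(suppressWarnings(stats::ks.test(ref, met_s)$statistic))
    paired <- length(ref) == length(met_s)
    mse <- if (paired) sum((ref - met_s)^2) else NA_real_
    corr <- if (paired && length(ref) > 1) {
      if (strict_corr) {
        stats::cov(ref, met_s) / (stats::var(ref) * stats::var(met_s))
      } else {
        suppressWarnings(stats::cor(ref, met_s))
      }
    } else NA_real_
    data.frame(gene_id = g, efficiency = eff, ks = ks, mse = mse, corr = corr,
               gini_reference = gini(ref), gini_method = gini(met),
               n_reference = length(ref), n_method = length(met),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  class(out) <- c("fish_comparison", "data.frame")
  out
}
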