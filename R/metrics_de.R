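#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score against binary labels, with
#' midrank handling of ties.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical vector, same length.
#' @return AUC in `[0, 1]`; NA when a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_validation("length mismatch")
  labels <- as.logical(labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# Vectorised Welch two-sided t-tests of one group of cells against the rest,
# one p-value per gene (column). Zero-variance degenerate genes get p = 1
# when the group means agree and p = 0 otherwise.
welch_p_values <- function(logv, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  if (n1 < 2 || n2 < 2) {
    stop_validation("each group needs at least 2 cells for the t-test")
  }
  x1 <- logv[in_group, , drop = FALSE]
  x2 <- logv[!in_group, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0 | !is.finite(p)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Pooled differential-expression calls
#'
#' For every group, runs a two-sided Welch t-test of each gene in the group
#' versus all other cells on log-transformed values, adjusts p-values within
#' the group by Benjamini-Hochberg, and keeps the `top_n` genes with the
#' smallest adjusted p. The per-group lists are pooled (union); a gene kept
#' in several groups gets its maximum calling probability
#' `1 - pval_adj`.
#'
#' @param matrix An [expression_matrix]; raw counts are `log1p`-transformed
#'   internally.
#' @param groups Group labels per cell (named vector or factor).
#' @param top_n Genes retained per group (default 500).
#' @return A data.frame with columns `gene_id` and `calling_prob`.
#' @export
de_calls <- function(matrix, groups, top_n = 500) {
  matrix <- as_expression_matrix(matrix)
  logv <- if (em_space(matrix) == "raw") log1p(em_values(matrix)) else em_values(matrix)
  groups <- if (is.factor(groups)) {
    stats::setNames(as.character(groups), names(groups))
  } else as.character2(groups)
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), rownames(logv))) {
      stop_validation("group labels cover different cells than the matrix")
    }
    groups <- groups[rownames(logv)]
  } else if (length(groups) != nrow(logv)) {
    stop_validation("group labels length does not match cells")
  }
  groups <- unname(groups)
  levels_ <- unique(groups)
  if (length(levels_) < 2) stop_validation("need at least 2 groups")
  genes <- colnames(logv)
  best <- stats::setNames(rep(-Inf, length(genes)), genes)
  picked <- logical(length(genes))
  for (g in levels_) {
    p <- welch_p_values(logv, groups == g)
    padj <- stats::p.adjust(p, method = "BH")
    ord <- order(padj, seq_along(padj))[seq_len(min(top_n, length(padj)))]
    prob <- 1 - padj[ord]
    take <- prob > best[ord]
    best[ord][take] <- prob[take]
    picked[ord] <- TRUE
  }
  data.frame(gene_id = genes[picked], calling_prob = unname(best[picked]),
             stringsAsFactors = FALSE)
}

#' Differential-expression recovery AUC
#'
#' The full evaluation: pool top-`top_n` differential-expression calls per
#' group ([de_calls()]) and compute the ROC AUC of the calling probability
#' `1 - pval_adj` against the ground truth (a gene is truly DE when its
#' simulated DE factor differs from 1 in any group), over the pooled genes.
#'
#' @inheritParams de_calls
#' @param truth A `sim_truth` object from [simulate_counts()], or a named
#'   logical vector of true per-gene DE labels.
#' @return Scalar AUC with attributes `n_pooled` (pooled gene count) and
#'   `calls` (the pooled table with truth attached).
#' @export
de_auc <- function(matrix, groups, truth, top_n = 500) {
  calls <- de_calls(matrix, groups, top_n = top_n)
  labels <- if (inherits(truth, "sim_truth")) truth_de_labels(truth) else truth
  if (is.null(names(labels))) {
    stop_validation("truth labels must be named by gene id")
  }
  if (!all(calls$gene_id %in% names(labels))) {
    stop_validation("truth labels missing for some pooled genes")
  }
  calls$is_de <- as.logical(labels[calls$gene_id])
  auc <- roc_auc(calls$calling_prob, calls$is_de)
  structure(auc, n_pooled = nrow(calls), calls = calls)
}
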