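# Clustering-agreement metrics. All of them equal 1 on identical partitions
# and are approximately 0 for random assignments (ARI/AMI by explicit chance
# adjustment).

align_labels <- function(a, b) {
  a <- if (is.factor(a)) stats::setNames(as.character(a), names(a)) else as.character2(a)
  b <- if (is.factor(b)) stats::setNames(as.character(b), names(b)) else as.character2(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop_validation("label vectors cover different cell sets")
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop_validation("label vectors have different lengths and no names to align by")
  }
  list(a = unname(a), b = unname(b))
}

# as.character that keeps names
as.character2 <- function(x) {
  out <- as.character(x)
  names(out) <- names(x)
  out
}

pair_counts <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  tp <- sum(choose(tab, 2))
  pairs_a <- sum(choose(ai, 2)) # TP + FP
  pairs_b <- sum(choose(bj, 2)) # TP + FN
  list(tab = tab, n = n, ai = ai, bj = bj, TP = tp,
       FP = pairs_a - tp, FN = pairs_b - tp,
       TN = choose(n, 2) - pairs_a - pairs_b + tp)
}

#' Adjusted Rand index
#'
#' The fraction of cell pairs on which two partitions agree (placed together
#' in both, or apart in both), rescaled so that the expected value under
#' random labellings with the same cluster sizes is 0 and identical
#' partitions score 1.
#'
#' @param a,b Cluster labels: factors or character vectors, aligned by names
#'   when both are named, by position otherwise.
#' @return Scalar index (1 = identical; <= 0 possible for worse-than-chance
#'   agreement).
#' @export
adjusted_rand <- function(a, b) {
  al <- align_labels(a, b)
  pc <- pair_counts(al$a, al$b)
  idx <- pc$TP
  exp_idx <- (pc$TP + pc$FP) * (pc$TP + pc$FN) / choose(pc$n, 2)
  max_idx <- ((pc$TP + pc$FP) + (pc$TP + pc$FN)) / 2
  if (max_idx == exp_idx) return(1) # both partitions trivial
  (idx - exp_idx) / (max_idx - exp_idx)
}

#' Adjusted mutual information
#'
#' Mutual information `MI(C, K) = sum_ij P(i, j) log(P(i, j) / (P(i) P(j)))`
#' between two partitions, adjusted by its expectation under the permutation
#' (hypergeometric) model and normalised by the arithmetic mean of the two
#' entropies, so that identical partitions score 1 and independent ones
#' score about 0.
#'
#' @inheritParams adjusted_rand
#' @return Scalar in roughly `[-1, 1]`.
#' @export
adjusted_mutual_information <- function(a, b) {
  al <- align_labels(a, b)
  tab <- table(al$a, al$b)
  n <- sum(tab)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  mi <- mutual_information_from_table(tab)
  h_a <- entropy_from_counts(ai)
  h_b <- entropy_from_counts(bj)
  if (h_a == 0 && h_b == 0) return(1)
  emi <- expected_mutual_information(ai, bj, n)
  denom <- (h_a + h_b) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

mutual_information_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  terms <- p * log(p / outer(pa, pb))
  sum(terms[p > 0])
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Expectation of MI over random contingency tables with fixed margins
# (hypergeometric model).
expected_mutual_information <- function(ai, bj, n) {
  emi <- 0
  for (a_ in ai) {
    for (b_ in bj) {
      lo <- max(1, a_ + b_ - n)
      hi <- min(a_, b_)
      if (hi < lo) next
      nij <- lo:hi
      w <- stats::dhyper(nij, m = b_, n = n - b_, k = a_)
      emi <- emi + sum(w * (nij / n) * log(n * nij / (a_ * b_)))
    }
  }
  emi
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of the pairwise precision and recall,
#' `sqrt(TP/(TP+FP) * TP/(TP+FN))`, where TP counts cell pairs placed
#' together in both partitions, FP pairs together only in the first and FN
#' pairs together only in the second.
#'
#' @inheritParams adjusted_rand
#' @return Scalar in `[0, 1]`.
#' @export
fowlkes_mallows <- function(a, b) {
  al <- align_labels(a, b)
  pc <- pair_counts(al$a, al$b)
  if (pc$TP == 0) return(0)
  denom <- (pc$TP + pc$FP) * (pc$TP + pc$FN)
  if (denom == 0) return(0)
  pc$TP / sqrt(denom)
}

#' Mean silhouette coefficient
#'
#' For each cell, compares its mean Euclidean distance to its own cluster
#' (`a`) against the smallest mean distance to another cluster (`b`) as
#' `(b - a) / max(a, b)`; cells in singleton clusters contribute 0. Consumes
#' any embedding (e.g. UMAP components computed elsewhere).
#'
#' @param embedding Numeric matrix, cells x dimensions.
#' @param labels Cluster labels (>= 2 clusters); aligned to the embedding's
#'   rownames when both are named.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- if (is.factor(labels)) {
    stats::setNames(as.character(labels), names(labels))
  } else as.character2(labels)
  if (!is.null(names(labels)) && !is.null(rownames(embedding))) {
    if (!setequal(names(labels), rownames(embedding))) {
      stop_validation("labels and embedding cover different cells")
    }
    labels <- labels[rownames(embedding)]
  } else if (length(labels) != nrow(embedding)) {
    stop_validation("labels length does not match embedding rows")
  }
  labels <- unname(labels)
  if (length(unique(labels)) < 2) {
    stop_validation("silhouette needs at least 2 clusters")
  }
  d <- as.matrix(stats::dist(embedding))
  groups <- split(seq_len(nrow(d)), labels)
  s <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    own <- labels[i]
    own_idx <- setdiff(groups[[own]], i)
    if (length(own_idx) == 0) { s[i] <- 0; next } # singleton cluster
    a_i <- mean(d[i, own_idx])
    b_i <- min(vapply(groups[names(groups) != own],
                      function(idx) mean(d[i, idx]), numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}
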