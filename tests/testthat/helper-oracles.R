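# Independent brute-force oracles. Each deliberately takes the naive route
# (explicit loops / full enumeration) so that agreement with the package's
# implementations is meaningful.

brute_weighted_mse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + y[i] * (y[i] - yhat[i])^2
  s
}

brute_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Two-sample K-S statistic by scanning the empirical CDFs at every point.
brute_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  gaps <- vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1))
  max(gaps)
}

# Benjamini-Hochberg step-up, literally: sort, scale, enforce monotonicity
# from the largest p downward.
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (k in n:1) {
    running <- min(running, p[ord[k]] * n / k)
    adj[ord[k]] <- min(running, 1)
  }
  adj
}

# Pair-level confusion counts by enumerating all n(n-1)/2 cell pairs.
brute_pair_confusion <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) tp <- tp + 1
      else if (sa && !sb) fp <- fp + 1
      else if (!sa && sb) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

brute_ari <- function(a, b) {
  pc <- brute_pair_confusion(a, b)
  num <- 2 * (pc["TP"] * pc["TN"] - pc["FN"] * pc["FP"])
  den <- (pc["TP"] + pc["FN"]) * (pc["FN"] + pc["TN"]) +
    (pc["TP"] + pc["FP"]) * (pc["FP"] + pc["TN"])
  if (den == 0) return(1)
  unname(num / den)
}

brute_fmi <- function(a, b) {
  pc <- brute_pair_confusion(a, b)
  if (pc["TP"] == 0) return(0)
  unname(sqrt(pc["TP"] / (pc["TP"] + pc["FP"]) *
                pc["TP"] / (pc["TP"] + pc["FN"])))
}

# Unadjusted mutual information by direct double summation over the joint
# label distribution.
brute_mi <- function(a, b) {
  n <- length(a)
  s <- 0
  for (u in unique(a)) {
    for (v in unique(b)) {
      pij <- sum(a == u & b == v) / n
      if (pij == 0) next
      s <- s + pij * log(pij / (mean(a == u) * mean(b == v)))
    }
  }
  s
}

# Expected mutual information under the fixed-margin permutation model,
# with the hypergeometric weights computed from factorials directly (no
# dhyper), and the AMI assembled from loop-based MI and entropies.
brute_ami <- function(a, b) {
  n <- length(a)
  ai <- as.numeric(table(a))
  bj <- as.numeric(table(b))
  emi <- 0
  for (x in ai) {
    for (y in bj) {
      for (nij in max(1, x + y - n):min(x, y)) {
        if (nij < 1) next
        lw <- lfactorial(x) + lfactorial(n - x) + lfactorial(y) +
          lfactorial(n - y) - lfactorial(n) - lfactorial(nij) -
          lfactorial(x - nij) - lfactorial(y - nij) -
          lfactorial(n - x - y + nij)
        emi <- emi + exp(lw) * (nij / n) * log(n * nij / (x * y))
      }
    }
  }
  mi <- brute_mi(a, b)
  ent <- function(counts) {
    p <- counts / sum(counts)
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  h <- (ent(ai) + ent(bj)) / 2
  if (h == 0) return(1)
  denom <- h - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

# Pairwise-comparison AUC: fraction of positive/negative pairs ranked
# correctly, ties counting one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

brute_silhouette <- function(embedding, labels) {
  d <- as.matrix(dist(embedding))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (lab in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == lab]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
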