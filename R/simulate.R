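#' Simulation parameters
#'
#' Parameters of the built-in count simulator, a deliberately simplified
#' Splatter-style model: gamma-distributed gene base means, log-normal cell
#' library sizes, group-wise log-normal differential-expression (DE) factors,
#' gamma-Poisson (negative binomial) counts with a common biological
#' coefficient of variation, and an independent logistic dropout layer on
#' the expected counts. It records complete ground truth (groups, DE factors, pre-dropout
#' counts, dropout mask), which is what downstream evaluation needs; it does
#' not aim for Splatter bit-compatibility (no BCV trend, batches or paths).
#'
#' Defaults reproduce the reference simulated experiment: 4000 genes, 2000
#' cells in 5 groups with proportions 10/10/20/20/40%, and logistic dropout
#' with midpoint 1 and shape -0.5 on `log(1 + expected count)`.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param group_proportions Positive vector summing to 1; one entry per group.
#' @param de_prob Probability that a gene is DE in a given group. The
#'   default makes marker genes a minority of the transcriptome (~23% of
#'   genes DE in at least one of the five groups), so that pooled top-N
#'   differential-expression lists contain both true and false candidates
#'   and rank-based evaluation stays informative.
#' @param de_factor_location,de_factor_scale Meanlog/sdlog of the log-normal
#'   DE factor magnitude; each DE factor is inverted (downregulation) with
#'   probability 1/2.
#' @param mean_shape,mean_rate Gamma parameters of gene base means. The
#'   defaults put nearly all genes in a regime where expected counts are
#'   large enough that observed zeros are dominated by the dropout layer
#'   rather than Poisson sampling, so the per-gene zero-proportion curve
#'   follows the generating logistic and the dropout parameters are
#'   recoverable from the simulated data.
#' @param libsize_location,libsize_scale Meanlog/sdlog of log-normal cell
#'   library sizes (defaults give ~100k counts per cell).
#' @param bcv Biological coefficient of variation: each entry's expected
#'   count is multiplied by a mean-1 gamma variable with this CV before the
#'   Poisson draw, giving negative-binomial-like counts
#'   (CV^2 = 1/mean + bcv^2). The default 0.3 is typical of droplet-based
#'   data; 0 gives pure Poisson counts. Without this overdispersion,
#'   one-vs-rest tests on thousands of cells are powerful enough to call
#'   every simulated DE factor perfectly and the DE-recovery ROC degenerates.
#' @param dropout_mid,dropout_shape Midpoint and slope of the dropout
#'   logistic `1 / (1 + exp(-shape * (log1p(expected) - mid)))`; a negative
#'   shape makes highly expressed entries less likely to drop out.
#'   `dropout_shape = -Inf` is the documented dropout-off switch (probability
#'   0 everywhere).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 4000, n_cells = 2000,
                       group_proportions = c(0.10, 0.10, 0.20, 0.20, 0.40),
                       de_prob = 0.05,
                       de_factor_location = 0.1, de_factor_scale = 0.4,
                       mean_shape = 5, mean_rate = 0.5,
                       libsize_location = 11.5, libsize_scale = 0.1,
                       bcv = 0.3,
                       dropout_mid = 1, dropout_shape = -0.5,
                       seed = 1) {
  if (bcv < 0) stop_validation("bcv must be non-negative")
  if (n_genes < 1 || n_cells < 1) stop_validation("n_genes and n_cells must be >= 1")
  if (any(group_proportions <= 0)) stop_validation("group proportions must be positive")
  if (abs(sum(group_proportions) - 1) > 1e-9) {
    stop_validation("group proportions must sum to 1")
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 group_proportions = group_proportions, de_prob = de_prob,
                 de_factor_location = de_factor_location,
                 de_factor_scale = de_factor_scale,
                 mean_shape = mean_shape, mean_rate = mean_rate,
                 libsize_location = libsize_location,
                 libsize_scale = libsize_scale, bcv = bcv,
                 dropout_mid = dropout_mid, dropout_shape = dropout_shape,
                 seed = as.integer(seed)),
            class = "sim_params")
}

dropout_probability <- function(log_expected, mid, shape) {
  if (identical(shape, -Inf)) {
    return(array(0, dim = dim(log_expected) %||% length(log_expected)))
  }
  1 / (1 + exp(-shape * (log_expected - mid)))
}

#' Simulate a grouped scRNA-seq count matrix with ground truth
#'
#' Draws gene base means from a gamma distribution, assigns each cell to a
#' group (multinomial over `group_proportions`), multiplies means by
#' group-wise DE factors, rescales each cell's expected counts so that they
#' sum to its log-normal library size, draws gamma-Poisson counts (`bcv`
#' overdispersion), and zeroes each entry independently with the logistic
#' dropout probability evaluated at `log1p(expected count)`.
#'
#' @param params A [sim_params] object.
#' @return A list with `counts` (the post-dropout [expression_matrix]) and
#'   `truth`, a list of class `sim_truth` with `group` (named character per
#'   cell), `de_factors` (genes x groups matrix; 1 = not DE), `pre_counts`
#'   (cells x genes matrix before dropout), `dropout_mask` (logical matrix;
#'   TRUE = entry was zeroed), and `expected` (cells x genes expected
#'   counts).
#' @export
simulate_counts <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  G <- params$n_genes; n <- params$n_cells
  K <- length(params$group_proportions)
  res <- with_seed(params$seed, {
    base_means <- stats::rgamma(G, shape = params$mean_shape,
                                rate = params$mean_rate)
    group <- sample.int(K, n, replace = TRUE, prob = params$group_proportions)
    is_de <- matrix(stats::runif(G * K) < params$de_prob, G, K)
    magnitude <- matrix(stats::rlnorm(G * K, params$de_factor_location,
                                      params$de_factor_scale), G, K)
    down <- matrix(stats::runif(G * K) < 0.5, G, K)
    de_factors <- ifelse(down, 1 / magnitude, magnitude)
    de_factors[!is_de] <- 1
    libsize <- stats::rlnorm(n, params$libsize_location, params$libsize_scale)

    group_means <- base_means * de_factors          # G x K
    group_sums <- colSums(group_means)               # per-group normaliser
    # expected counts, cells x genes
    expected <- t(group_means[, group, drop = FALSE]) *
      (libsize / group_sums[group])
    # biological overdispersion: gamma-mixed Poisson (negative binomial)
    lambda <- if (params$bcv > 0) {
      disp <- 1 / params$bcv^2
      expected * matrix(stats::rgamma(n * G, shape = disp, rate = disp), n, G)
    } else expected
    pre <- matrix(as.double(stats::rpois(n * G, lambda = lambda)), n, G)
    # dropout depends on the systematic expected count (the mean around
    # which the biological noise fluctuates), as in Splatter-style models
    pdrop <- dropout_probability(log1p(expected), params$dropout_mid,
                                 params$dropout_shape)
    mask <- matrix(stats::runif(n * G) < pdrop, n, G)
    list(group = group, de_factors = de_factors, expected = expected,
         pre = pre, mask = mask)
  })
  cell_ids <- sprintf("cell%d", seq_len(n))
  gene_ids <- sprintf("gene%d", seq_len(G))
  post <- res$pre
  post[res$mask] <- 0
  dimnames(post) <- dimnames(res$pre) <- dimnames(res$mask) <-
    dimnames(res$expected) <- list(cell_ids, gene_ids)
  dimnames(res$de_factors) <- list(gene_ids, paste0("group", seq_len(K)))
  truth <- structure(list(
    group = stats::setNames(paste0("group", res$group), cell_ids),
    de_factors = res$de_factors,
    pre_counts = res$pre,
    dropout_mask = res$mask,
    expected = res$expected,
    params = params), class = "sim_truth")
  list(counts = expression_matrix(post, space = "raw"), truth = truth)
}

#' Ground-truth differential-expression labels
#'
#' A gene counts as truly DE when its DE factor differs from 1 in at least
#' one group.
#'
#' @param truth A `sim_truth` object from [simulate_counts()].
#' @return Named logical vector over genes.
#' @export
truth_de_labels <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  apply(truth$de_factors != 1, 1, any)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d cells in %d groups, %d genes (%d DE)\n",
              length(x$group), ncol(x$de_factors), nrow(x$de_factors),
              sum(truth_de_labels(x))))
  cat(sprintf("  dropout rate among simulated entries: %.1f%%\n",
              100 * mean(x$dropout_mask)))
  invisible(x)
}
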