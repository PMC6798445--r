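# Fixtures built in code at test time.

# Small simulated dataset with ground truth. Library size is scaled with
# the gene count so that per-gene sequencing depth (and hence the zero
# fraction and test power) matches the full-sized default simulation.
small_sim <- function(n_genes = 120, n_cells = 80, seed = 1, ...) {
  args <- list(n_genes = n_genes, n_cells = n_cells, seed = seed,
               libsize_location = 11.5 + log(n_genes / 4000))
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_counts(do.call(sim_params, args))
}

# A matrix with strong learnable structure: two blocks of genes, each a
# noisy affine image of a shared latent factor, so target genes are
# predictable from correlated predictors.
learnable_matrix <- function(n_cells = 200, n_genes = 60, seed = 1) {
  set.seed(seed)
  latent <- matrix(rexp(n_cells * 2, rate = 0.2), n_cells, 2)
  block <- rep(1:2, length.out = n_genes)
  slopes <- runif(n_genes, 0.5, 2)
  mu <- latent[, block] * rep(slopes, each = n_cells)
  counts <- matrix(rpois(n_cells * n_genes, lambda = mu), n_cells, n_genes)
  expression_matrix(counts,
                    cell_ids = paste0("c", seq_len(n_cells)),
                    gene_ids = paste0("g", seq_len(n_genes)),
                    space = "raw")
}

random_labels <- function(n, k, seed) {
  set.seed(seed)
  paste0("L", sample.int(k, n, replace = TRUE))
}

# Fast training settings for contract tests that do not need a good fit;
# callers may override any field.
quick_config <- function(...) {
  args <- list(max_epochs = 3, subset_size = 30, hidden_size = 16,
               predictors_per_target = 3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}
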