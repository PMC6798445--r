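# Logistic curve p(x) = 1 / (1 + exp(-shape * (x - mid))) with a given
# midpoint/shape, materialised as a count matrix whose per-gene zero
# proportions sit exactly on the curve.
logistic_fixture <- function(mid = 1, shape = -0.5, n_cells = 200,
                             n_genes = 40) {
  pos_values <- exp(seq(log(0.5), log(60), length.out = n_genes))
  v <- sapply(pos_values, function(val) {
    p <- 1 / (1 + exp(-shape * (log1p(val) - mid)))
    n_zero <- round(n_cells * p)
    c(rep(0, n_zero), rep(val, n_cells - n_zero))
  })
  expression_matrix(v, cell_ids = paste0("c", seq_len(n_cells)),
                    gene_ids = paste0("g", seq_len(n_genes)))
}

test_that("dropout logistic is recovered from exact logistic data", {
  em <- logistic_fixture(mid = 1, shape = -0.5)
  fit <- fit_dropout_logistic(em)
  expect_lt(abs(fit$mid - 1) / 1, 0.05)
  expect_lt(abs(fit$shape - (-0.5)) / 0.5, 0.05)

  em2 <- logistic_fixture(mid = 2, shape = -1.5)
  fit2 <- fit_dropout_logistic(em2)
  expect_lt(abs(fit2$mid - 2) / 2, 0.05)
  expect_lt(abs(fit2$shape - (-1.5)) / 1.5, 0.05)
})

test_that("fitted curve has the logistic midpoint and monotonicity", {
  em <- logistic_fixture()
  fit <- fit_dropout_logistic(em)
  expect_equal(predict(fit, fit$mid), 0.5)
  xs <- seq(-2, 6, by = 0.25)
  ps <- predict(fit, xs)
  expect_true(all(diff(ps) < 0)) # negative shape: strictly decreasing
  expect_true(all(ps > 0 & ps < 1))
})

test_that("degenerate matrices are rejected by the logistic fit", {
  all_pos <- expression_matrix(matrix(5, 10, 4))
  expect_error(fit_dropout_logistic(all_pos), "at least 3 genes")
})

test_that("masking draws the requested number of nonzero entries per gene", {
  sim <- small_sim(n_genes = 50, n_cells = 120, seed = 2)
  em <- sim$counts
  dl <- fit_dropout_logistic(em)
  mk <- mask_counts(em, dl, n_per_gene = 10, seed = 4)
  v <- unclass(em)
  nonzero_per_gene <- colSums(v > 0)
  masked_per_gene <- table(factor(mk$mask_set$gene_id, levels = colnames(em)))
  expect_identical(as.integer(masked_per_gene),
                   as.integer(pmin(10, nonzero_per_gene)))

  # every masked entry was positive and is now zero; the input is untouched
  vm <- unclass(mk$masked)
  coords <- cbind(match(mk$mask_set$cell_id, rownames(v)),
                  match(mk$mask_set$gene_id, colnames(v)))
  expect_true(all(mk$mask_set$value > 0))
  expect_true(all(vm[coords] == 0))
  expect_identical(v[coords], mk$mask_set$value)
  expect_false(anyDuplicated(mk$mask_set[c("cell_id", "gene_id")]) > 0)
  # entries outside the mask are unchanged
  untouched <- v
  untouched[coords] <- 0
  expect_identical(vm, untouched)
})

test_that("a gene with fewer nonzeros than requested masks them all", {
  set.seed(8)
  v <- cbind(sparse = c(3, 7, 2, rep(0, 17)),
             dense = rpois(20, 8) + 1,
             some0a = c(rep(0, 10), rpois(10, 5) + 1),
             some0b = c(rpois(12, 4) + 1, rep(0, 8)),
             some0c = c(0, 0, rpois(18, 12) + 1))
  em <- expression_matrix(v, cell_ids = paste0("c", 1:20))
  dl <- fit_dropout_logistic(em)
  mk <- mask_counts(em, dl, n_per_gene = 10, seed = 1)
  expect_equal(sum(mk$mask_set$gene_id == "sparse"), 3)
  expect_equal(sum(mk$mask_set$gene_id == "dense"), 10)
})

test_that("masking is reproducible under a fixed seed", {
  sim <- small_sim(n_genes = 30, n_cells = 60, seed = 5)
  dl <- fit_dropout_logistic(sim$counts)
  m1 <- mask_counts(sim$counts, dl, seed = 7)
  m2 <- mask_counts(sim$counts, dl, seed = 7)
  expect_identical(m1$mask_set, m2$mask_set)
  m3 <- mask_counts(sim$counts, dl, seed = 8)
  expect_false(identical(m1$mask_set, m3$mask_set))
})

test_that("scoring matches hand computation on log counts", {
  orig <- expression_matrix(cbind(g1 = c(exp(1) - 1, 5),
                                  g2 = c(exp(3) - 1, 2)),
                            cell_ids = c("c1", "c2"))
  imp <- expression_matrix(cbind(g1 = c(0, 5), g2 = c(exp(3) - 1, 2)),
                           cell_ids = c("c1", "c2"))
  mask <- data.frame(cell_id = c("c1", "c1"), gene_id = c("g1", "g2"),
                     value = c(exp(1) - 1, exp(3) - 1))
  rep_ <- score_imputation(orig, imp, mask)
  # log residuals are {1, 0} -> MSE 0.5
  expect_equal(rep_$overall_mse, 0.5)

  perfect <- score_imputation(orig, orig, mask)
  expect_equal(perfect$overall_mse, 0)
  expect_equal(perfect$overall_pearson, 1)
  expect_error(score_imputation(orig, imp, mask[0, ]), "empty")
})

test_that("per-gene MSEs weighted by mask counts recover the overall MSE", {
  sim <- small_sim(n_genes = 40, n_cells = 80, seed = 9)
  dl <- fit_dropout_logistic(sim$counts)
  mk <- mask_counts(sim$counts, dl, seed = 3)
  # score an arbitrary imperfect imputation: the masked matrix itself
  rep_ <- score_imputation(sim$counts, mk$masked, mk$mask_set)
  counts <- table(mk$mask_set$gene_id)
  w <- as.numeric(counts[names(rep_$per_gene_mse)])
  expect_equal(sum(rep_$per_gene_mse * w) / sum(w), rep_$overall_mse)
  # and symmetrically per cell
  ccounts <- table(mk$mask_set$cell_id)
  wc <- as.numeric(ccounts[names(rep_$per_cell_mse)])
  expect_equal(sum(rep_$per_cell_mse * wc) / sum(wc), rep_$overall_mse)
})
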