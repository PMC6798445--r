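test_that("variance-over-mean gene selection matches hand computation", {
  m <- expression_matrix(cbind(const = rep(3, 4),
                               burst = c(0, 0, 0, 8),
                               zero = rep(0, 4),
                               mild = c(1, 2, 1, 2)),
                         cell_ids = paste0("c", 1:4))
  sel <- select_genes(m, threshold = 0.5)
  # burst: mean 2, population variance (0+0+0+36... ) -> 12, vmr 6
  expect_equal(unname(sel$vmr[["burst"]]), 12 / 2)
  expect_true("burst" %in% sel$imputable_genes)
  expect_false("const" %in% sel$imputable_genes) # vmr 0
  expect_false("zero" %in% sel$imputable_genes)  # undefined ratio
  expect_true(is.na(sel$vmr[["zero"]]))

  # threshold below every finite ratio selects all nonzero-mean genes
  all_sel <- select_genes(m, threshold = -1)
  expect_setequal(all_sel$imputable_genes, c("const", "burst", "mild"))

  # sample-variance convention scales ratios by n/(n-1)
  sel_s <- select_genes(m, threshold = 0.5, variance = "sample")
  expect_equal(unname(sel_s$vmr[["burst"]]), 12 * 4 / 3 / 2)

  no_genes <- expression_matrix(matrix(numeric(0), nrow = 2, ncol = 0),
                                cell_ids = c("c1", "c2"),
                                gene_ids = character(0))
  expect_error(select_genes(no_genes), "empty")
})

test_that("vmr agrees with a brute-force oracle on random matrices", {
  set.seed(31)
  for (rep in 1:20) {
    v <- matrix(rpois(8 * 6, lambda = 2), 8, 6)
    em <- expression_matrix(v)
    sel <- select_genes(em, threshold = 0.5)
    oracle <- vapply(seq_len(ncol(v)), function(j) {
      x <- v[, j]
      if (mean(x) == 0) return(NA_real_)
      sum((x - mean(x))^2) / length(x) / mean(x)
    }, numeric(1))
    expect_equal(unname(sel$vmr), oracle)
    expect_identical(sel$imputable_genes,
                     colnames(em)[!is.na(oracle) & oracle > 0.5])
  }
})

test_that("log transform is log1p with an exact inverse", {
  m <- expression_matrix(cbind(g1 = c(0, exp(1) - 1, 10)))
  lg <- log_transform(m)
  expect_equal(unclass(lg)[, 1], c(0, 1, log(11)), ignore_attr = TRUE)
  expect_identical(attr(lg, "space"), "log")
  back <- inverse_log_transform(lg)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-9)
  expect_error(log_transform(lg), "already log")
  expect_error(inverse_log_transform(m), "not in log space")
})

test_that("target partition is balanced, seeded, and exhaustive", {
  genes <- paste0("g", 1:1024)
  parts <- partition_targets(genes, 512, seed = 1)
  expect_length(parts, 2)
  expect_identical(lengths(parts, use.names = FALSE), c(512L, 512L))

  # 700 genes at subset size 512: two balanced groups, not 512 + 188
  p700 <- partition_targets(paste0("g", 1:700), 512, seed = 2)
  expect_identical(sort(lengths(p700, use.names = FALSE)), c(350L, 350L))

  expect_identical(partition_targets(genes, 512, seed = 9),
                   partition_targets(genes, 512, seed = 9))
  expect_false(identical(partition_targets(genes, 512, seed = 9),
                         partition_targets(genes, 512, seed = 10)))

  # property: sizes sum to n, differ by at most 1, each <= S, disjoint union
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(1:400, 1)
    s <- sample(1:100, 1)
    g <- paste0("x", seq_len(n))
    p <- partition_targets(g, s, seed = rep)
    sizes <- lengths(p)
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
    expect_lte(max(sizes), s)
    expect_setequal(unlist(p), g)
    expect_equal(anyDuplicated(unlist(p)), 0)
  }
})

test_that("predictor selection matches a brute-force correlation ranking", {
  set.seed(17)
  for (rep in 1:10) {
    v <- matrix(rpois(20 * 8, 4) + runif(160), 20, 8)
    em <- log_transform(expression_matrix(v))
    targets <- colnames(em)[c(2, 5)]
    got <- select_predictors(em, targets, k = 2)
    # oracle: full correlation matrix, rank |r| per target over non-targets
    lv <- unclass(em)
    cand <- setdiff(colnames(em), targets)
    expected <- unique(unlist(lapply(targets, function(tg) {
      r <- abs(vapply(cand, function(g) cor(lv[, g], lv[, tg]), numeric(1)))
      cand[order(-r, seq_along(r))][1:2]
    })))
    expect_setequal(got, expected)
  }
})

test_that("predictor selection: exact copies rank first, constants never chosen", {
  set.seed(3)
  base <- rpois(30, 5) + runif(30)
  v <- cbind(target = base,
             copy = base,            # |r| = 1 with target
             const = rep(2, 30),     # zero variance
             noise1 = runif(30), noise2 = runif(30))
  em <- log_transform(expression_matrix(v, cell_ids = paste0("c", 1:30)))
  got <- select_predictors(em, "target", k = 1)
  expect_identical(got, "copy")
  expect_false("const" %in% select_predictors(em, "target", k = 3))
  expect_error(select_predictors(em, colnames(v), k = 1), "non-target")
})

test_that("predictor selection is invariant to cell and gene order", {
  set.seed(23)
  v <- matrix(rpois(25 * 10, 3) + runif(250), 25, 10)
  em <- log_transform(expression_matrix(v))
  targets <- c("gene3", "gene7")
  ref <- select_predictors(em, targets, k = 3)

  perm_cells <- sample(nrow(v))
  em2 <- log_transform(expression_matrix(v[perm_cells, ],
                                         cell_ids = rownames(em)[perm_cells]))
  expect_setequal(select_predictors(em2, targets, k = 3), ref)

  perm_genes <- sample(ncol(v))
  em3 <- log_transform(expression_matrix(v[, perm_genes],
                                         gene_ids = colnames(em)[perm_genes]))
  expect_setequal(select_predictors(em3, targets, k = 3), ref)
})
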