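test_that("weighted loss matches the closed form and kills zero-weight terms", {
  expect_equal(weighted_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(weighted_mse(2, 1), 2 * (2 - 1)^2)
  expect_equal(weighted_mse(0, 7), 0) # zeros never penalise the prediction
  expect_error(weighted_mse(1:3, 1:2), "length")
  expect_error(weighted_mse(-1, 0), "non-negative")

  set.seed(11)
  for (rep in 1:100) {
    n <- sample(1:10, 1)
    y <- round(rexp(n), 3)
    yhat <- round(rexp(n), 3)
    expect_equal(weighted_mse(y, yhat), brute_weighted_mse(y, yhat))
  }
  # with unit weights the loss collapses to the plain sum of squares
  y1 <- rep(1, 6); yh <- runif(6)
  expect_equal(weighted_mse(y1, yh), sum((1 - yh)^2))
})

test_that("sub-network parameter counts match the closed-form formula", {
  plan <- subnet_plan(targets = paste0("t", 1:4),
                      predictors = paste0("p", 1:10),
                      hidden_size = 256)
  net <- build_subnetwork(plan, seed = 1)
  expect_equal(n_parameters(net), 10 * 256 + 256 + 256 * 4 + 4) # 3844
  expect_equal(n_parameters(net), 3844)

  net0 <- build_subnetwork(plan, activation = "none_hidden", seed = 1)
  expect_equal(n_parameters(net0), 10 * 4 + 4)

  set.seed(4)
  for (rep in 1:10) {
    p <- sample(1:50, 1); t_ <- sample(1:20, 1); h <- sample(1:64, 1)
    pl <- subnet_plan(paste0("t", 1:t_), paste0("p", 1:p), hidden_size = h)
    expect_equal(n_parameters(build_subnetwork(pl, seed = rep)),
                 p * h + h + h * t_ + t_)
  }
})

test_that("plans reject overlapping or empty gene lists", {
  expect_error(subnet_plan("a", character(0)), "predictor")
  expect_error(subnet_plan(character(0), "b"), "target")
  expect_error(subnet_plan(c("a", "b"), c("b", "c")), "overlap")
})

test_that("inference is deterministic (dropout only active in training)", {
  plan <- subnet_plan(paste0("t", 1:3), paste0("p", 1:5),
                      hidden_size = 8, dropout_rate = 0.5)
  net <- build_subnetwork(plan, seed = 2)
  X <- matrix(runif(10 * 5), 10, 5)
  p1 <- divimpute:::subnet_forward(net, X)
  p2 <- divimpute:::subnet_forward(net, X)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0)) # rectified outputs
})

test_that("training reduces the held-out loss on learnable structure", {
  em <- learnable_matrix(n_cells = 200, n_genes = 40, seed = 8)
  fit <- divimpute(em, subset_size = 20, hidden_size = 32, max_epochs = 80,
                   test_fraction = 0.1, seed = 3)
  for (lg in training_log(fit)) {
    expect_lt(min(lg$test_loss), lg$test_loss[1])
    expect_lt(tail(lg$test_loss, 1) / lg$test_loss[1], 0.9)
  }
})

test_that("fitting is reproducible: same seed gives identical training logs", {
  em <- learnable_matrix(n_cells = 120, n_genes = 40, seed = 5)
  f1 <- divimpute(em, config = quick_config(max_epochs = 6, seed = 21))
  f2 <- divimpute(em, config = quick_config(max_epochs = 6, seed = 21))
  expect_identical(training_log(f1), training_log(f2))
  expect_identical(coef(f1), coef(f2))
  f3 <- divimpute(em, config = quick_config(max_epochs = 6, seed = 22))
  expect_false(identical(training_log(f1), training_log(f3)))
})

test_that("imputation preserves every nonzero entry and out-of-model zeros", {
  sim <- small_sim(n_genes = 80, n_cells = 60, seed = 13)
  em <- sim$counts
  fit <- divimpute(em, config = quick_config(seed = 2))
  imp <- predict(fit)
  v0 <- unclass(em); v1 <- unclass(imp)
  nz <- v0 > 0
  expect_identical(v1[nz], v0[nz]) # bit-exact preservation
  expect_true(all(v1 >= 0))
  out_of_model <- setdiff(colnames(em), fit$gene_selection$imputable_genes)
  if (length(out_of_model)) {
    expect_identical(v1[, out_of_model], v0[, out_of_model])
  }
  # input with no zeros comes back unchanged
  dense_in <- expression_matrix(v0 + 1, gene_ids = colnames(em))
  expect_identical(unclass(predict(fit, dense_in)), v0 + 1)
})

test_that("full-prediction mode fills imputable genes everywhere", {
  sim <- small_sim(n_genes = 60, n_cells = 50, seed = 19)
  fit <- divimpute(sim$counts, config = quick_config(seed = 4))
  full <- predict(fit, type = "predictions")
  imputable <- fit$gene_selection$imputable_genes
  expect_false(identical(unclass(full)[, imputable],
                         unclass(sim$counts)[, imputable]))
  not_model <- setdiff(colnames(sim$counts), imputable)
  if (length(not_model)) {
    expect_identical(unclass(full)[, not_model],
                     unclass(sim$counts)[, not_model])
  }
})

test_that("a reduced training-cell fraction stays close to the full model", {
  # subsampling plateau: with cells to spare, training on 40% of them costs
  # little accuracy; needs a cell count large enough that both runs reach
  # convergence at the default learning rate
  em <- learnable_matrix(n_cells = 5000, n_genes = 40, seed = 41)
  dl <- fit_dropout_logistic(em)
  mk <- mask_counts(em, dl, n_per_gene = 10, seed = 6)
  mse_of <- function(frac) {
    cfg <- train_config(subset_size = 20, hidden_size = 32, seed = 9,
                        train_cell_fraction = frac)
    fit <- divimpute(mk$masked, config = cfg)
    score_imputation(em, predict(fit), mk$mask_set)$overall_mse
  }
  expect_lte(mse_of(0.4), 1.2 * mse_of(1))
})

test_that("cells below the test-split minimum are rejected", {
  em <- learnable_matrix(n_cells = 10, n_genes = 20, seed = 1)
  expect_error(divimpute(em, config = quick_config(test_fraction = 0.05)),
               "test split")
})
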