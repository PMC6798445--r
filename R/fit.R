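#' Training configuration
#'
#' Collects every tunable of the imputer with its default: subsets of 512
#' target genes, a 256-unit
#' hidden layer with 20% dropout, Adam at learning rate 1e-4, batch size 64,
#' at most 500 epochs with early stopping after 5 consecutive epochs without
#' test-loss improvement, and a 95/5 train/test cell split.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param subset_size Target genes per sub-network.
#' @param hidden_size Hidden-layer width.
#' @param dropout_rate Hidden-layer dropout fraction during training.
#' @param max_epochs Epoch cap.
#' @param patience Consecutive non-improving epochs tolerated before
#'   stopping (test loss, strict improvement, best weights restored).
#' @param test_fraction Fraction of cells held out to monitor overfitting.
#'   Held-out cells are still imputed.
#' @param train_cell_fraction Fraction of cells used for training; with
#'   values below 1 a seeded random subset trains the networks while
#'   prediction still covers every cell.
#' @param vmr_threshold Variance-over-mean cut-off for imputable genes.
#' @param predictors_per_target Correlated predictor genes kept per target.
#' @param activation `"relu"`, `"linear"`, or `"none_hidden"`.
#' @param seed Master seed; all per-sub-network seeds derive from it.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64,
                         subset_size = 512, hidden_size = 256,
                         dropout_rate = 0.2, max_epochs = 500, patience = 5,
                         test_fraction = 0.05, train_cell_fraction = 1,
                         vmr_threshold = 0.5, predictors_per_target = 5,
                         activation = c("relu", "linear", "none_hidden"),
                         seed = 1) {
  activation <- match.arg(activation)
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              subset_size = as.integer(subset_size),
              hidden_size = as.integer(hidden_size),
              dropout_rate = dropout_rate, max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), test_fraction = test_fraction,
              train_cell_fraction = train_cell_fraction,
              vmr_threshold = vmr_threshold,
              predictors_per_target = as.integer(predictors_per_target),
              activation = activation, seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$batch_size >= 1, cfg$subset_size >= 1,
            cfg$hidden_size >= 1, cfg$max_epochs >= 1, cfg$patience >= 1,
            cfg$predictors_per_target >= 1)
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 1) {
    stop_validation("test_fraction must be in (0, 1)")
  }
  if (cfg$train_cell_fraction <= 0 || cfg$train_cell_fraction > 1) {
    stop_validation("train_cell_fraction must be in (0, 1]")
  }
  class(cfg) <- "train_config"
  cfg
}

#' Fit the divide-and-conquer imputer
#'
#' Trains an ensemble of small dense neural networks that jointly predict the
#' log-expression of every imputable gene from correlated predictor genes.
#' The pipeline is: select genes with variance-over-mean ratio above the
#' threshold; log-transform (`log(1 + x)`); shuffle the imputable genes into
#' subsets of at most `subset_size` targets; for each subset, pick the top
#' correlated non-target genes as inputs and train a one-hidden-layer
#' network on the weighted squared-error loss [weighted_mse()] with the Adam
#' optimiser; monitor a held-out cell split for early stopping.
#'
#' @param x A cells x genes count matrix or [expression_matrix] (raw space).
#' @param config A [train_config]; individual fields may also be overridden
#'   through `...`.
#' @param keep_data Store the input matrix in the fitted object so
#'   `predict()` can run without `newdata` (default TRUE).
#' @param verbose Print per-sub-network progress.
#' @param ... Overrides for [train_config] fields, e.g. `seed = 7`.
#' @return An object of class `divimpute`; see [predict.divimpute()].
#' @examples
#' sim <- simulate_counts(sim_params(n_genes = 60, n_cells = 50, seed = 1))
#' fit <- divimpute(sim$counts, max_epochs = 30, subset_size = 20, seed = 1)
#' imp <- predict(fit)
#' @export
divimpute <- function(x, config = train_config(), keep_data = TRUE,
                      verbose = FALSE, ...) {
  dots <- list(...)
  if (length(dots)) {
    base <- unclass(config)
    base[names(dots)] <- dots
    config <- do.call(train_config, base)
  }
  em <- as_expression_matrix(x)
  if (em_space(em) != "raw") stop_validation("divimpute expects raw counts")
  n_cells <- nrow(em)

  selection <- select_genes(em, config$vmr_threshold)
  if (length(selection$imputable_genes) == 0) {
    stop_validation("no genes pass the variance-over-mean filter")
  }
  logm <- log_transform(em)
  logv <- em_values(logm)

  # cell subset (optional) and train/test split, shared by every sub-network
  pool <- seq_len(n_cells)
  if (config$train_cell_fraction < 1) {
    n_keep <- max(2L, round(config$train_cell_fraction * n_cells))
    pool <- with_seed(derive_seed(config$seed, 0L), sort(sample(pool, n_keep)))
  }
  n_test <- floor(length(pool) * config$test_fraction)
  if (n_test < 1) {
    stop_validation("too few cells for a nonempty ", config$test_fraction * 100,
                    "% test split (", length(pool), " training cells)")
  }
  test_idx <- with_seed(derive_seed(config$seed, 1L),
                        sort(sample(pool, n_test)))
  train_idx <- setdiff(pool, test_idx)

  target_sets <- partition_targets(selection$imputable_genes,
                                   config$subset_size, config$seed)
  nets <- vector("list", length(target_sets))
  for (i in seq_along(target_sets)) {
    targets <- target_sets[[i]]
    predictors <- select_predictors(logm, targets,
                                    k = config$predictors_per_target)
    plan <- subnet_plan(targets, predictors,
                        hidden_size = config$hidden_size,
                        dropout_rate = config$dropout_rate)
    plan_seed <- derive_seed(config$seed, i + 1L)
    net <- build_subnetwork(plan, activation = config$activation,
                            seed = plan_seed)
    t0 <- proc.time()[["elapsed"]]
    net <- train_subnetwork(net,
                            X_train = logv[train_idx, predictors, drop = FALSE],
                            Y_train = logv[train_idx, targets, drop = FALSE],
                            X_test = logv[test_idx, predictors, drop = FALSE],
                            Y_test = logv[test_idx, targets, drop = FALSE],
                            learning_rate = config$learning_rate,
                            batch_size = config$batch_size,
                            max_epochs = config$max_epochs,
                            patience = config$patience,
                            seed = derive_seed(plan_seed, 1L))
    if (verbose) {
      message(sprintf(
        "sub-network %d/%d: %d targets, %d predictors, %d epochs, test loss %.4f (%.1fs)",
        i, length(target_sets), length(targets), length(predictors),
        nrow(net$log), min(net$log$test_loss), proc.time()[["elapsed"]] - t0))
    }
    nets[[i]] <- net
  }

  structure(list(networks = nets,
                 gene_selection = selection,
                 config = config,
                 cell_split = list(train = rownames(em)[train_idx],
                                   test = rownames(em)[test_idx]),
                 gene_ids = colnames(em),
                 data = if (keep_data) em else NULL,
                 call = match.call()),
            class = "divimpute")
}

#' Impute dropouts with a fitted model
#'
#' Predictions are made in log space for every imputable gene, transformed
#' back to the raw scale, and written into the matrix only where the input
#' is zero: every nonzero entry, and every gene outside the
#' variance-over-mean selection, is returned bit-identical to the input.
#'
#' @param object A fitted [divimpute] model.
#' @param newdata A cells x genes matrix or [expression_matrix] with the same
#'   gene set as the training data; defaults to the stored training matrix.
#' @param type `"imputed"` (default; zeros filled, everything else
#'   preserved) or `"predictions"` (the full predicted matrix for imputable
#'   genes, other genes passed through — for diagnostics).
#' @param ... Unused.
#' @return An [expression_matrix] in raw space, same shape as the input.
#' @export
predict.divimpute <- function(object, newdata = NULL,
                              type = c("imputed", "predictions"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    newdata <- object$data
    if (is.null(newdata)) {
      stop("model was fitted with keep_data = FALSE; supply newdata")
    }
  }
  em <- as_expression_matrix(newdata)
  if (em_space(em) != "raw") stop_validation("newdata must be raw counts")
  if (!identical(colnames(em), object$gene_ids)) {
    if (setequal(colnames(em), object$gene_ids)) {
      em <- expression_matrix(em_values(em)[, object$gene_ids, drop = FALSE],
                              space = "raw")
    } else {
      stop_validation("gene set of newdata does not match the training genes")
    }
  }
  logv <- log1p(em_values(em))
  out <- em_values(em)
  for (net in object$networks) {
    plan <- net$plan
    pred_log <- subnet_forward(net, logv[, plan$predictors, drop = FALSE])
    pred_raw <- pmax(expm1(pred_log), 0)
    block <- out[, plan$targets, drop = FALSE]
    if (type == "imputed") {
      zero <- block == 0
      block[zero] <- pred_raw[zero]
    } else {
      block <- pred_raw
    }
    out[, plan$targets] <- block
  }
  expression_matrix(out, space = "raw")
}

#' @rdname predict.divimpute
#' @param matrix Raw count matrix to impute.
#' @param model A fitted [divimpute] object.
#' @export
impute <- function(matrix, model) {
  stopifnot(inherits(model, "divimpute"))
  predict(model, newdata = matrix)
}

#' @export
print.divimpute <- function(x, ...) {
  cat("Divide-and-conquer dropout imputer\n")
  cat(sprintf("  %d sub-networks over %d imputable genes (of %d); activation: %s\n",
              length(x$networks), length(x$gene_selection$imputable_genes),
              length(x$gene_ids), x$config$activation))
  cat(sprintf("  cells: %d train / %d test\n",
              length(x$cell_split$train), length(x$cell_split$test)))
  invisible(x)
}

#' @export
summary.divimpute <- function(object, ...) {
  nets <- object$networks
  df <- data.frame(
    subnet = seq_along(nets),
    n_targets = vapply(nets, function(n) length(n$plan$targets), integer(1)),
    n_predictors = vapply(nets, function(n) length(n$plan$predictors), integer(1)),
    n_parameters = vapply(nets, n_parameters, numeric(1)),
    epochs = vapply(nets, function(n) nrow(n$log), integer(1)),
    best_test_loss = vapply(nets, function(n) min(n$log$test_loss), numeric(1)))
  structure(list(table = df, config = object$config,
                 n_imputable = length(object$gene_selection$imputable_genes),
                 n_genes = length(object$gene_ids)),
            class = "summary.divimpute")
}

#' @export
print.summary.divimpute <- function(x, ...) {
  cat(sprintf("Imputer over %d of %d genes; %d sub-networks\n",
              x$n_imputable, x$n_genes, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.divimpute <- function(object, ...) {
  lapply(object$networks, function(n) n$weights)
}

#' Training-loss curves
#'
#' Plots per-epoch training and held-out loss for each sub-network.
#'
#' @param x A fitted [divimpute] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.divimpute <- function(x, ...) {
  logs <- training_log(x)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(logs)))
  on.exit(graphics::par(op))
  for (i in seq_along(logs)) {
    lg <- logs[[i]]
    graphics::matplot(lg$epoch, cbind(lg$train_loss, lg$test_loss),
                      type = "l", lty = 1, col = c("grey40", "firebrick"),
                      xlab = "epoch", ylab = "weighted MSE",
                      main = paste("sub-network", i), ...)
    graphics::legend("topright", c("train", "test"), lty = 1,
                     col = c("grey40", "firebrick"), bty = "n")
  }
  invisible(x)
}

#' @rdname plot.divimpute
#' @export
training_log <- function(x) {
  stopifnot(inherits(x, "divimpute"))
  lapply(x$networks, function(n) n$log)
}
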