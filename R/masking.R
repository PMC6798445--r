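#' Fit the gene-level dropout logistic
#'
#' For every gene with at least one zero and one positive value, takes the
#' proportion of zeros and the `log1p` of the mean of its positive values,
#' then fits `p(x) = 1 / (1 + exp(-shape * (x - mid)))` to those points by
#' nonlinear least squares. This models how likely a gene of a given
#' expression level is to drop out and drives the realistic masking of the
#' accuracy benchmark.
#'
#' @param matrix An [expression_matrix] in raw space.
#' @return A list of class `dropout_logistic` with `mid`, `shape`, and the
#'   fitted per-gene points (`x`, `p`).
#' @export
fit_dropout_logistic <- function(matrix) {
  matrix <- as_expression_matrix(matrix)
  if (em_space(matrix) != "raw") stop_validation("expects raw counts")
  v <- em_values(matrix)
  zero_prop <- colMeans(v == 0)
  pos_mean <- apply(v, 2, function(col) {
    p <- col[col > 0]
    if (length(p)) mean(p) else NA_real_
  })
  usable <- zero_prop > 0 & zero_prop < 1 & !is.na(pos_mean)
  if (sum(usable) < 3) {
    stop("need at least 3 genes with both zero and positive values to fit ",
         "the dropout curve")
  }
  x <- log1p(pos_mean[usable])
  p <- zero_prop[usable]
  start <- list(mid = stats::median(x), shape = -1)
  fit <- minpack.lm::nlsLM(p ~ 1 / (1 + exp(-shape * (x - mid))),
                           data = data.frame(x = x, p = p),
                           start = start,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-8, ptol = 1e-8))
  est <- stats::coef(fit)
  structure(list(mid = unname(est[["mid"]]), shape = unname(est[["shape"]]),
                 x = x, p = p),
            class = "dropout_logistic")
}

#' @rdname fit_dropout_logistic
#' @param object A `dropout_logistic` fit.
#' @param x Values of `log1p` expression at which to evaluate the curve.
#' @param ... Unused.
#' @return `predict()`: dropout probabilities in (0, 1).
#' @export
predict.dropout_logistic <- function(object, x, ...) {
  1 / (1 + exp(-object$shape * (x - object$mid)))
}

#' @export
print.dropout_logistic <- function(x, ...) {
  cat(sprintf("<dropout_logistic> mid = %.4f, shape = %.4f (fit on %d genes)\n",
              x$mid, x$shape, length(x$x)))
  invisible(x)
}

#' Mask nonzero entries under the fitted dropout model
#'
#' For each gene, every nonzero entry gets a dropout probability from the
#' fitted logistic evaluated at its own `log1p` value; the probabilities are
#' normalised to weights and `min(n_per_gene, #nonzero)` distinct cells are
#' drawn without replacement proportionally to them. The drawn entries are
#' recorded with their original values and set to zero in the returned
#' matrix. Only nonzero entries are maskable (masking a zero is
#' unobservable). Genes with no positive values are skipped.
#'
#' @param matrix An [expression_matrix] in raw space (left unmodified).
#' @param model A `dropout_logistic` from [fit_dropout_logistic()].
#' @param n_per_gene Entries to mask per gene (default 10).
#' @param seed Integer seed; fixed seed reproduces the mask.
#' @return A list with `masked` (the matrix with masked entries zeroed) and
#'   `mask_set`, a data.frame of class `mask_set` with columns `cell_id`,
#'   `gene_id`, `value`.
#' @export
mask_counts <- function(matrix, model, n_per_gene = 10, seed = 1) {
  matrix <- as_expression_matrix(matrix)
  if (em_space(matrix) != "raw") stop_validation("expects raw counts")
  stopifnot(inherits(model, "dropout_logistic"))
  if (n_per_gene < 1) stop_validation("n_per_gene must be >= 1")
  v <- em_values(matrix)
  masked <- v
  picks <- with_seed(seed, {
    lapply(seq_len(ncol(v)), function(j) {
      nz <- which(v[, j] > 0)
      if (length(nz) == 0) return(integer(0))
      p <- predict(model, log1p(v[nz, j]))
      n_draw <- min(n_per_gene, length(nz))
      if (length(nz) == 1) nz else nz[sample.int(length(nz), n_draw, prob = p)]
    })
  })
  n_per <- lengths(picks)
  gene_idx <- rep.int(seq_len(ncol(v)), n_per)
  cell_idx <- unlist(picks, use.names = FALSE)
  coords <- cbind(cell_idx, gene_idx)
  values <- v[coords]
  masked[coords] <- 0
  mask_set <- data.frame(cell_id = rownames(v)[cell_idx],
                         gene_id = colnames(v)[gene_idx],
                         value = values, stringsAsFactors = FALSE)
  class(mask_set) <- c("mask_set", "data.frame")
  list(masked = expression_matrix(masked, space = "raw"), mask_set = mask_set)
}

#' Score an imputation against masked truth
#'
#' Restricted to the masked coordinates, both the original and the imputed
#' values are `log1p`-transformed and compared: overall mean squared error,
#' overall Pearson correlation, and MSE grouped per gene and per cell.
#'
#' @param original The unmasked [expression_matrix] (raw space).
#' @param imputed The imputed [expression_matrix] (raw space, same shape).
#' @param mask_set A `mask_set` from [mask_counts()].
#' @return A list of class `accuracy_report`: `overall_mse`,
#'   `overall_pearson`, `per_gene_mse` (named), `per_cell_mse` (named),
#'   `n_masked`.
#' @export
score_imputation <- function(original, imputed, mask_set) {
  original <- as_expression_matrix(original)
  imputed <- as_expression_matrix(imputed)
  if (!identical(dim(original), dim(imputed))) {
    stop_validation("original and imputed shapes differ")
  }
  if (nrow(mask_set) == 0) stop_validation("empty mask set")
  ci <- match(mask_set$cell_id, rownames(original))
  gi <- match(mask_set$gene_id, colnames(original))
  if (anyNA(ci) || anyNA(gi)) stop_validation("mask set refers to unknown cells/genes")
  coords <- cbind(ci, gi)
  truth <- log1p(em_values(original)[coords])
  est <- log1p(em_values(imputed)[coords])
  sq <- (truth - est)^2
  structure(list(
    overall_mse = mean(sq),
    overall_pearson = if (stats::sd(truth) > 0 && stats::sd(est) > 0) {
      stats::cor(truth, est)
    } else NA_real_,
    per_gene_mse = tapply(sq, mask_set$gene_id, mean),
    per_cell_mse = tapply(sq, mask_set$cell_id, mean),
    n_masked = length(sq)), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d masked entries\n", x$n_masked))
  cat(sprintf("  MSE (log counts): %.4f   Pearson: %.4f\n",
              x$overall_mse, x$overall_pearson))
  invisible(x)
}

#' One-call masking benchmark
#'
#' Convenience wrapper running the full accuracy benchmark: fit the dropout
#' logistic on the data, mask `n_per_gene` nonzero entries per gene, train
#' the imputer on the masked matrix, impute, and score against the held-out
#' originals. Baselines (`zero`: leave masked entries at zero; `gene_mean`:
#' fill each masked entry with the gene's mean positive value in the masked
#' matrix) put the model's error in context.
#'
#' @param matrix Raw-count [expression_matrix].
#' @param config A [train_config] for the imputer.
#' @param n_per_gene Masked entries per gene (default 10).
#' @param seed Seed for the mask draw.
#' @param baselines Also score the zero and gene-mean baselines.
#' @return A list with `model` (the [divimpute] fit), `report`
#'   (the model's `accuracy_report`), `mask_set`, and optionally
#'   `baseline_reports`.
#' @export
masking_benchmark <- function(matrix, config = train_config(),
                              n_per_gene = 10, seed = 1, baselines = TRUE) {
  matrix <- as_expression_matrix(matrix)
  dl <- fit_dropout_logistic(matrix)
  mk <- mask_counts(matrix, dl, n_per_gene = n_per_gene, seed = seed)
  fit <- divimpute(mk$masked, config = config)
  imp <- predict(fit)
  out <- list(model = fit, dropout_fit = dl, mask_set = mk$mask_set,
              report = score_imputation(matrix, imp, mk$mask_set))
  if (baselines) {
    v <- em_values(mk$masked)
    gm <- apply(v, 2, function(col) {
      p <- col[col > 0]
      if (length(p)) mean(p) else 0
    })
    mean_filled <- v
    zero <- v == 0
    mean_filled[zero] <- gm[col(v)][zero]
    out$baseline_reports <- list(
      zero = score_imputation(matrix, mk$masked, mk$mask_set),
      gene_mean = score_imputation(matrix,
                                   expression_matrix(mean_filled, space = "raw"),
                                   mk$mask_set))
  }
  out
}
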