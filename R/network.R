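#' Weighted squared-error loss
#'
#' The training loss for one cell: `sum(y * (y - yhat)^2)`. Weighting each
#' squared residual by the true value concentrates the fit on confidently
#' measured (high) values and makes true zeros contribute nothing, so the
#' network is not penalised for disagreeing with entries that are likely
#' dropouts.
#'
#' @param y Numeric vector of true log-expression values (non-negative).
#' @param yhat Numeric vector of predictions, same length.
#' @return The scalar loss.
#' @examples
#' weighted_mse(c(2, 0), c(1, 7)) # second term is killed by the zero weight
#' @export
weighted_mse <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop_validation("y and yhat must have the same length")
  }
  if (any(y < 0)) stop_validation("y must be non-negative")
  sum(y * (y - yhat)^2)
}

#' Describe one sub-network
#'
#' A plan pairs a target-gene subset (the output layer) with its predictor
#' genes (the input layer) and the layer hyperparameters.
#'
#' @param targets Character vector of target gene ids (the genes this
#'   sub-network imputes).
#' @param predictors Character vector of predictor gene ids; must be disjoint
#'   from `targets` and nonempty.
#' @param hidden_size Hidden-layer width (default 256).
#' @param dropout_rate Training-time unit-dropout fraction on the hidden
#'   layer (default 0.2).
#' @return A list of class `subnet_plan`.
#' @export
subnet_plan <- function(targets, predictors, hidden_size = 256,
                        dropout_rate = 0.2) {
  if (length(targets) < 1) stop_validation("plan needs at least one target gene")
  if (length(predictors) < 1) stop_validation("plan needs predictor genes")
  if (length(intersect(targets, predictors)) > 0) {
    stop_validation("targets and predictors overlap")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_validation("dropout_rate must be in [0, 1)")
  }
  structure(list(targets = as.character(targets),
                 predictors = as.character(predictors),
                 hidden_size = as.integer(hidden_size),
                 dropout_rate = dropout_rate),
            class = "subnet_plan")
}

#' Build an untrained sub-network
#'
#' Architecture: `|predictors|` inputs, one fully connected hidden layer of
#' `hidden_size` units with the configured activation, a training-time
#' dropout layer, and `|targets|` output units. A rectifier on the output
#' keeps log-space predictions non-negative. The `none_hidden` variant is a
#' single affine map (no hidden layer). Weights are Glorot-uniform
#' initialised under `seed`.
#'
#' @param plan A [subnet_plan].
#' @param activation `"relu"` (default), `"linear"` (identity hidden
#'   activation), or `"none_hidden"` (no hidden layer).
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `subnetwork` holding the weight arrays.
#' @export
build_subnetwork <- function(plan, activation = c("relu", "linear", "none_hidden"),
                             seed = 1) {
  activation <- match.arg(activation)
  stopifnot(inherits(plan, "subnet_plan"))
  p <- length(plan$predictors)
  t_ <- length(plan$targets)
  h <- plan$hidden_size
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  weights <- with_seed(seed, {
    if (activation == "none_hidden") {
      list(W = glorot(p, t_), b = numeric(t_))
    } else {
      list(W1 = glorot(p, h), b1 = numeric(h),
           W2 = glorot(h, t_), b2 = numeric(t_))
    }
  })
  structure(list(plan = plan, activation = activation, weights = weights),
            class = "subnetwork")
}

#' Number of trainable parameters of a sub-network
#'
#' `|predictors| * hidden + hidden + hidden * |targets| + |targets|` for the
#' hidden-layer architectures, `|predictors| * |targets| + |targets|` for the
#' `none_hidden` variant.
#'
#' @param net A `subnetwork`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  stopifnot(inherits(net, "subnetwork"))
  sum(vapply(net$weights, length, numeric(1)))
}

# Forward pass without dropout (inference). X: cells x predictors in log
# space, columns already ordered as plan$predictors.
subnet_forward <- function(net, X) {
  w <- net$weights
  if (net$activation == "none_hidden") {
    Z <- sweep(X %*% w$W, 2, w$b, "+")
    return(pmax(Z, 0))
  }
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
  H <- if (net$activation == "relu") pmax(Z1, 0) else Z1
  Z2 <- sweep(H %*% w$W2, 2, w$b2, "+")
  pmax(Z2, 0)
}

# Mean over cells of the per-cell weighted squared-error loss.
batch_loss <- function(Y, Yhat) {
  sum(Y * (Y - Yhat)^2) / nrow(Y)
}

adam_state <- function(weights) {
  lapply(weights, function(w) list(m = w * 0, v = w * 0))
}

adam_update <- function(weights, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(weights)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(weights = weights, state = state)
}

# One minibatch gradient step. Returns updated weights/state and the batch
# loss (computed before the update).
subnet_step <- function(net, X, Y, state, lr, t, dropout_rate, rng_dropout) {
  w <- net$weights
  B <- nrow(X)
  if (net$activation == "none_hidden") {
    Z <- sweep(X %*% w$W, 2, w$b, "+")
    Yhat <- pmax(Z, 0)
    G <- (2 / B) * Y * (Yhat - Y) * (Z > 0)
    grads <- list(W = crossprod(X, G), b = colSums(G))
    loss <- batch_loss(Y, Yhat)
    upd <- adam_update(w, grads, state, lr, t)
    net$weights <- upd$weights
    return(list(net = net, state = upd$state, loss = loss))
  }
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
  H <- if (net$activation == "relu") pmax(Z1, 0) else Z1
  if (dropout_rate > 0 && rng_dropout) {
    # inverted dropout: zero units with prob `rate`, rescale the survivors
    M <- matrix(stats::rbinom(length(H), 1L, 1 - dropout_rate), nrow(H)) /
      (1 - dropout_rate)
    Hd <- H * M
  } else {
    M <- NULL
    Hd <- H
  }
  Z2 <- sweep(Hd %*% w$W2, 2, w$b2, "+")
  Yhat <- pmax(Z2, 0)
  loss <- batch_loss(Y, Yhat)

  G2 <- (2 / B) * Y * (Yhat - Y) * (Z2 > 0)
  GH <- G2 %*% t(w$W2)
  if (!is.null(M)) GH <- GH * M
  G1 <- if (net$activation == "relu") GH * (Z1 > 0) else GH
  grads <- list(W1 = crossprod(X, G1), b1 = colSums(G1),
                W2 = crossprod(Hd, G2), b2 = colSums(G2))
  upd <- adam_update(w, grads, state, lr, t)
  net$weights <- upd$weights
  list(net = net, state = upd$state, loss = loss)
}

# Train one sub-network with Adam, minibatches, and test-loss early stopping
# (stop after `patience` consecutive epochs without strict improvement;
# best-epoch weights are restored).
train_subnetwork <- function(net, X_train, Y_train, X_test, Y_test,
                             learning_rate = 1e-4, batch_size = 64,
                             max_epochs = 500, patience = 5, seed = 1) {
  # Start at the optimal constant predictor under the weighted loss: for a
  # constant output b the loss sum(Y * (Y - b)^2) is minimised by
  # b* = sum(Y^2) / sum(Y). The output weights start at zero so the network
  # begins exactly there and every gradient step goes into per-cell
  # structure; Adam's step size (bounded by the learning rate) would
  # otherwise spend tens of thousands of updates just climbing the output
  # scale. Hidden weights keep their Glorot draw, so units differentiate as
  # soon as the output layer moves off zero.
  ysum <- colSums(Y_train)
  b_star <- ifelse(ysum > 0, colSums(Y_train^2) / ysum, 0)
  if (net$activation == "none_hidden") {
    net$weights$b <- b_star
    net$weights$W[] <- 0
  } else {
    net$weights$b2 <- b_star
    net$weights$W2[] <- 0
  }
  state <- adam_state(net$weights)
  n <- nrow(X_train)
  best_loss <- Inf
  best_weights <- net$weights
  stale <- 0L
  t_step <- 0L
  log_train <- numeric(0)
  log_test <- numeric(0)
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      epoch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- idx[starts[bi]:min(starts[bi] + batch_size - 1, n)]
        t_step <- t_step + 1L
        res <- subnet_step(net, X_train[rows, , drop = FALSE],
                           Y_train[rows, , drop = FALSE],
                           state, learning_rate, t_step,
                           net$plan$dropout_rate, rng_dropout = TRUE)
        net <- res$net
        state <- res$state
        epoch_losses[bi] <- res$loss
      }
      test_loss <- batch_loss(Y_test, subnet_forward(net, X_test))
      log_train <- c(log_train, mean(epoch_losses))
      log_test <- c(log_test, test_loss)
      if (test_loss < best_loss) {
        best_loss <- test_loss
        best_weights <- net$weights
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  })
  net$weights <- best_weights
  net$log <- data.frame(epoch = seq_along(log_train),
                        train_loss = log_train, test_loss = log_test)
  net
}
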