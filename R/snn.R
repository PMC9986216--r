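# Shallow neural network with a TP/FP trade-off loss.
#
# Architecture: input -> single hidden layer (ReLU) -> sigmoid output.
# The training objective is
#
#   loss = 1 - (TP - lambda1 * FP) + lambda2 * ||w_out||^2
#
# where TP is the summed predicted probability over true cases and FP the
# summed predicted probability over true controls (soft, differentiable
# counts; the hard counts are recovered when predictions saturate to 0/1).
# lambda1 prices a false positive in units of true positives, which pushes
# the decision surface toward very low false-positive rates. Training is
# full-batch Adam so the loss keeps raw-count semantics; lambda1's scale
# therefore depends on cohort size.

#' SNN hyperparameters
#'
#' @param lambda1 false-positive penalty weight in the loss (> 0).
#' @param hidden_units number of hidden-layer neurons.
#' @param lambda2 L2 regularization weight on the output layer (>= 0).
#' @param learning_rate Adam learning rate.
#' @param epochs number of full-batch training epochs.
#' @param seed integer seed controlling weight initialization.
#' @return an `snn_hyperparams` list.
#' @export
snn_hyperparams <- function(lambda1 = 2, hidden_units = 16, lambda2 = 1e-3,
                            learning_rate = 1e-2, epochs = 200, seed = 1) {
  hp <- list(lambda1 = lambda1, hidden_units = as.integer(hidden_units),
             lambda2 = lambda2, learning_rate = learning_rate,
             epochs = as.integer(epochs), seed = as.integer(seed))
  if (!is.numeric(lambda1) || lambda1 <= 0) stop("lambda1 must be > 0", call. = FALSE)
  if (hp$hidden_units < 1) stop("hidden_units must be a positive integer", call. = FALSE)
  if (!is.numeric(lambda2) || lambda2 < 0) stop("lambda2 must be >= 0", call. = FALSE)
  if (!is.numeric(learning_rate) || learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (hp$epochs < 1) stop("epochs must be a positive integer", call. = FALSE)
  structure(hp, class = "snn_hyperparams")
}

#' Default hyperparameter search grid
#'
#' Spans under- and over-penalization of false positives and small-to-medium
#' hidden layers. Every entry is an `snn_hyperparams`; the grid is a plain
#' list, so callers can subset or extend it freely.
#'
#' @param lambda1,hidden_units,lambda2,learning_rate,epochs,seed vectors of
#'   candidate values, crossed.
#' @return list of `snn_hyperparams`.
#' @export
default_snn_grid <- function(lambda1 = c(0.5, 1, 2, 5, 10),
                             hidden_units = c(8, 16, 32, 64),
                             lambda2 = c(0, 1e-4, 1e-3, 1e-2),
                             learning_rate = c(1e-3, 1e-2),
                             epochs = 200, seed = 1) {
  grid <- expand.grid(lambda1 = lambda1, hidden_units = hidden_units,
                      lambda2 = lambda2, learning_rate = learning_rate,
                      epochs = epochs, seed = seed)
  lapply(seq_len(nrow(grid)), function(i) do.call(snn_hyperparams, as.list(grid[i, ])))
}

#' Custom TP/FP loss
#'
#' `1 - (TP - lambda1 * FP)` with soft counts: TP is the sum of predicted
#' probabilities over true cases, FP the sum over true controls. Lower is
#' better.
#'
#' @param labels 0/1 vector of true labels.
#' @param predicted vector of predicted probabilities in `[0, 1]`.
#' @param lambda1 false-positive penalty weight.
#' @return scalar loss value.
#' @export
custom_loss <- function(labels, predicted, lambda1) {
  if (length(labels) != length(predicted)) {
    stop("labels and predicted must have equal length", call. = FALSE)
  }
  if (length(labels) == 0) stop("labels and predicted must be non-empty", call. = FALSE)
  if (any(predicted < 0 | predicted > 1)) {
    stop("predicted probabilities must lie in [0, 1]", call. = FALSE)
  }
  tp <- sum(predicted[labels == 1])
  fp <- sum(predicted[labels == 0])
  1 - (tp - lambda1 * fp)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

snn_init_weights <- function(input_dim, hidden_units, seed) {
  with_seed(seed, {
    lim1 <- 1 / sqrt(input_dim)
    lim2 <- 1 / sqrt(hidden_units)
    list(
      W1 = matrix(stats::runif(input_dim * hidden_units, -lim1, lim1),
                  nrow = input_dim, ncol = hidden_units),
      b1 = rep(0, hidden_units),
      w2 = stats::runif(hidden_units, -lim2, lim2),
      b2 = 0
    )
  })
}

snn_forward <- function(w, x) {
  z1 <- sweep(x %*% w$W1, 2, w$b1, "+")
  h <- pmax(z1, 0)
  s <- drop(h %*% w$w2) + w$b2
  list(p = sigmoid(s), h = h, z1 = z1)
}

#' Fit the shallow neural network
#'
#' Full-batch Adam on the custom TP/FP loss plus an L2 penalty on the output
#' layer. Deterministic given the data and the hyperparameter seed: two fits
#' with identical inputs produce identical weights.
#'
#' @param train a `feature_matrix` with at least one case and one control.
#' @param hp an `snn_hyperparams`.
#' @return an `snn_model`: weights, hyperparameters and the training feature
#'   schema.
#' @export
snn_fit <- function(train, hp = snn_hyperparams()) {
  x <- train$x
  y <- train$labels
  if (all(y == 1)) stop("training set has no controls", call. = FALSE)
  if (all(y == 0)) stop("training set has no cases", call. = FALSE)
  n <- nrow(x)
  d <- ncol(x)
  w <- snn_init_weights(d, hp$hidden_units, hp$seed)

  # dLoss/dp: -1 for cases, +lambda1 for controls (soft-count gradient)
  gp <- ifelse(y == 1, -1, hp$lambda1)

  # Adam state
  m <- lapply(w, function(z) z * 0)
  v <- lapply(w, function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- hp$learning_rate

  for (t in seq_len(hp$epochs)) {
    fw <- snn_forward(w, x)
    p <- fw$p
    ds <- gp * p * (1 - p)                     # dLoss/ds
    g_w2 <- drop(crossprod(fw$h, ds)) + 2 * hp$lambda2 * w$w2
    g_b2 <- sum(ds)
    dh <- outer(ds, w$w2) * (fw$z1 > 0)        # back through ReLU
    g_W1 <- crossprod(x, dh)
    g_b1 <- colSums(dh)
    grads <- list(W1 = g_W1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
    for (nm in names(w)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^t)
      vhat <- v[[nm]] / (1 - beta2^t)
      w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  structure(list(
    input_dim = d,
    weights = w,
    hyperparams = hp,
    feature_schema = colnames(x)
  ), class = "snn_model")
}

#' Predict case probabilities with a fitted SNN
#'
#' Input columns are aligned to the model's feature schema by name
#' (reordered; schema columns absent from the data are zero-filled).
#'
#' @param model an `snn_model`.
#' @param data a `feature_matrix` or numeric matrix with column names.
#' @return named numeric vector of probabilities in `(0, 1)`, one per row,
#'   order preserved.
#' @export
snn_predict <- function(model, data) {
  x <- align_features(data, model$feature_schema)
  p <- snn_forward(model$weights, x)$p
  names(p) <- rownames(x)
  p
}

#' @export
predict.snn_model <- function(object, newdata, ...) snn_predict(object, newdata)

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf("snn_model: %d -> %d -> 1 (lambda1=%g, lambda2=%g, lr=%g, epochs=%d, seed=%d)\n",
              x$input_dim, x$hyperparams$hidden_units, x$hyperparams$lambda1,
              x$hyperparams$lambda2, x$hyperparams$learning_rate,
              x$hyperparams$epochs, x$hyperparams$seed))
  invisible(x)
}

# Stratified fold assignment: shuffles within each label under `seed` and
# deals samples round-robin into k folds, keeping fold case:control ratios
# within one sample of the global ratio.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# CV selection metric: fraction of validation cases scored strictly above the
# maximum validation-control score.
cases_above_max_control <- function(case_scores, control_scores) {
  if (length(control_scores) == 0) {
    stop("validation fold has no controls; use stratified folding", call. = FALSE)
  }
  if (length(case_scores) == 0) return(NA_real_)
  mean(case_scores > max(control_scores))
}

#' Select SNN hyperparameters by cross-validation
#'
#' k-fold cross-validation on the training matrix (folds stratified by label
#' and shared across grid points). Each grid point is scored by the mean over
#' folds of the fraction of validation cases with predicted probability
#' strictly greater than that of every validation control — the selection
#' criterion for operating at near-zero false-positive rates. Ties are broken
#' by grid order.
#'
#' @param train a `feature_matrix`.
#' @param grid list of `snn_hyperparams` (see [default_snn_grid()]).
#' @param k number of folds.
#' @param seed seed for fold assignment.
#' @return the winning `snn_hyperparams`, with attributes `cv_scores` (per
#'   grid point) and `folds`.
#' @export
optimize_hyperparams <- function(train, grid, k = 3, seed = 1) {
  if (length(grid) == 0) stop("hyperparameter grid is empty", call. = FALSE)
  fold <- stratified_folds(train$labels, k, seed)
  for (f in seq_len(k)) {
    if (sum(train$labels[fold == f] == 0) == 0) {
      stop(sprintf("fold %d has no controls; use stratified folding", f), call. = FALSE)
    }
  }
  scores <- vapply(grid, function(hp) {
    per_fold <- vapply(seq_len(k), function(f) {
      tr <- subset_feature_matrix(train, train$sample_ids[fold != f])
      va <- subset_feature_matrix(train, train$sample_ids[fold == f])
      model <- snn_fit(tr, hp)
      p <- snn_predict(model, va)
      cases_above_max_control(p[va$labels == 1], p[va$labels == 0])
    }, numeric(1))
    mean(per_fold, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)  # which.max takes the first maximum: grid-order ties
  out <- grid[[best]]
  attr(out, "cv_scores") <- scores
  attr(out, "folds") <- fold
  out
}

#' Serialize an SNN model to JSON
#'
#' Self-describing format (version tag, schema, hyperparameters, weights at
#' full precision); [read_snn()] reproduces predictions bit-for-bit.
#'
#' @param model an `snn_model`.
#' @param path output path.
#' @export
write_snn <- function(model, path) {
  obj <- list(
    format = "denovoSNN/snn_model",
    version = 1L,
    input_dim = model$input_dim,
    feature_schema = model$feature_schema,
    hyperparams = unclass(model$hyperparams),
    weights = list(
      W1 = model$weights$W1, b1 = model$weights$b1,
      w2 = model$weights$w2, b2 = model$weights$b2
    )
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load an SNN model saved by [write_snn()]
#'
#' @param path input path.
#' @return an `snn_model`.
#' @export
read_snn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "denovoSNN/snn_model")) {
    stop("not a serialized snn_model file", call. = FALSE)
  }
  W1 <- matrix(unlist(obj$weights$W1), nrow = obj$input_dim, byrow = FALSE)
  if (is.matrix(obj$weights$W1)) W1 <- obj$weights$W1
  structure(list(
    input_dim = obj$input_dim,
    weights = list(W1 = W1, b1 = obj$weights$b1,
                   w2 = obj$weights$w2, b2 = obj$weights$b2),
    hyperparams = do.call(snn_hyperparams, obj$hyperparams),
    feature_schema = obj$feature_schema
  ), class = "snn_model")
}
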