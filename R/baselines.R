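# Baseline classifiers (random forest, linear SVM, ridge logistic
# regression), max-probability combination across variant-class-specific
# models, ensemble averaging, and heuristic gene-list/threshold classifiers.
#
# The three baselines are implemented in-package (deterministic under a
# seed): a probability forest with Gini splits and sqrt(p) feature sampling,
# a squared-hinge linear SVM trained by full-batch gradient descent, and
# ridge-penalized logistic regression fit by IRLS. Each baseline's own loss —
# not the TP/FP loss — drives its hyperparameter selection.

#' Baseline model specification
#'
#' @param kind `"random_forest"`, `"linear_svm"` or `"logistic_regression"`.
#' @param grid data.frame of candidate hyperparameters (one row per
#'   candidate); defaults: RF trees {100, 500} x max depth {Inf, 10},
#'   SVM C {0.01, 0.1, 1, 10}, LR C {0.01, 0.1, 1, 10} (L2).
#' @param seed integer seed (bootstrap and feature sampling for RF; fold
#'   assignment during tuning).
#' @return a `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("random_forest", "linear_svm", "logistic_regression"),
                          grid = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      random_forest = expand.grid(num_trees = c(100, 500), max_depth = c(Inf, 10)),
      linear_svm = data.frame(C = c(0.01, 0.1, 1, 10)),
      logistic_regression = data.frame(C = c(0.01, 0.1, 1, 10))
    )
  }
  if (nrow(grid) == 0) stop("baseline hyperparameter grid is empty", call. = FALSE)
  structure(list(kind = kind, grid = grid, seed = as.integer(seed)),
            class = "baseline_spec")
}

# ---- random forest -------------------------------------------------------

# Probability forest: bootstrap + per-node sqrt(p) feature sampling, Gini
# splits, leaves emit case fractions, averaged across trees. Tree growth and
# prediction run in C++ (src/forest.cpp) on R's RNG stream, so the forest is
# reproducible under the supplied seed. Columns are quantized once per
# forest: exactly when a column has <= 64 distinct values (typical for
# indicator and sparse pathogenicity columns), by quantile bins otherwise.
rf_quantize <- function(x, max_bins = 64L) {
  n <- nrow(x); p <- ncol(x)
  codes <- matrix(0L, n, p)
  thresholds <- vector("list", p)
  for (j in seq_len(p)) {
    u <- sort(unique(x[, j]))
    if (length(u) > max_bins) {
      u <- unique(stats::quantile(x[, j], probs = seq(0, 1, length.out = max_bins),
                                  names = FALSE, type = 7))
    }
    if (length(u) == 1) {
      thresholds[[j]] <- numeric(0)
      next
    }
    codes[, j] <- findInterval(x[, j], u) - 1L  # 0-based bin index
    thresholds[[j]] <- (u[-1] + u[-length(u)]) / 2
  }
  list(codes = codes, thresholds = thresholds)
}

rf_fit <- function(x, y, num_trees = 100, max_depth = Inf, min_node = 5, seed = 1) {
  mtry <- max(1L, floor(sqrt(ncol(x))))
  depth <- if (is.finite(max_depth)) as.integer(max_depth) else .Machine$integer.max
  q <- rf_quantize(x)
  trees <- with_seed(seed, {
    forest_fit_cpp(q$codes, as.integer(y), q$thresholds,
                   as.integer(num_trees), mtry, depth, as.integer(min_node))
  })
  list(trees = trees, num_trees = num_trees)
}

rf_predict <- function(fit, x) {
  forest_predict_cpp(fit$trees, x)
}

# ---- linear SVM (squared hinge) ------------------------------------------

# Largest eigenvalue of X'X by deterministic power iteration (curvature
# bound for the squared-hinge objective).
spectral_bound <- function(x, iters = 25) {
  v <- rep(1, ncol(x)) / sqrt(ncol(x))
  lam <- 0
  for (t in seq_len(iters)) {
    w <- drop(crossprod(x, x %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
  }
  lam
}

# Minimizes 0.5 ||w||^2 + C * sum max(0, 1 - y_i f_i)^2 by full-batch
# gradient descent with momentum; y in {-1, +1}. Smooth objective, so plain
# gradient descent with a step below the curvature bound converges and the
# fit is deterministic.
svm_fit <- function(x, y, C = 1, iters = 500, lr = NULL) {
  ypm <- ifelse(y == 1, 1, -1)
  n <- nrow(x); d <- ncol(x)
  w <- rep(0, d); b <- 0
  if (is.null(lr)) lr <- 0.9 / (1 + 2 * C * (spectral_bound(x) + n))
  vel_w <- rep(0, d); vel_b <- 0; mom <- 0.9
  for (t in seq_len(iters)) {
    f <- drop(x %*% w) + b
    margin <- 1 - ypm * f
    active <- margin > 0
    # d/dw [C * sum active margin^2] = -2C * X' (y * margin * active)
    coef <- -2 * C * ypm * margin * active
    g_w <- w + drop(crossprod(x, coef))
    g_b <- sum(coef)
    vel_w <- mom * vel_w - lr * g_w
    vel_b <- mom * vel_b - lr * g_b
    w <- w + vel_w
    b <- b + vel_b
  }
  list(w = w, b = b, C = C)
}

svm_decision <- function(fit, x) drop(x %*% fit$w) + fit$b

# Order-preserving min-max rescale of decision scores to [0, 1] within the
# prediction batch; constant scores map to 0.5.
rescale01 <- function(s) {
  r <- range(s)
  if (r[1] == r[2]) return(rep(0.5, length(s)))
  (s - r[1]) / (r[2] - r[1])
}

# ---- ridge logistic regression (IRLS) ------------------------------------

lr_fit <- function(x, y, C = 1, max_iter = 50, tol = 1e-9) {
  n <- nrow(x); d <- ncol(x)
  lambda <- 1 / C
  X <- cbind(Intercept = 1, x)
  beta <- rep(0, d + 1)
  pen <- c(0, rep(lambda, d))  # intercept unpenalized
  for (t in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- sigmoid(eta)
    wts <- pmax(p * (1 - p), 1e-10)
    g <- drop(crossprod(X, y - p)) - pen * beta
    H <- crossprod(X * wts, X)
    diag(H) <- diag(H) + pen + 1e-12
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, C = C)
}

lr_predict <- function(fit, x) sigmoid(drop(cbind(1, x) %*% fit$beta))

# ---- unified baseline training -------------------------------------------

fit_baseline_kind <- function(kind, x, y, hp, seed) {
  switch(kind,
    random_forest = rf_fit(x, y, num_trees = hp$num_trees, max_depth = hp$max_depth, seed = seed),
    linear_svm = svm_fit(x, y, C = hp$C),
    logistic_regression = lr_fit(x, y, C = hp$C)
  )
}

predict_baseline_kind <- function(kind, fit, x) {
  switch(kind,
    random_forest = rf_predict(fit, x),
    linear_svm = rescale01(svm_decision(fit, x)),
    logistic_regression = lr_predict(fit, x)
  )
}

# Per-learner validation loss used for tuning (each model minimizes its own
# loss): misclassification-complemented Brier for RF, squared hinge for SVM,
# logistic deviance for LR.
baseline_val_loss <- function(kind, fit, x, y) {
  switch(kind,
    random_forest = mean((rf_predict(fit, x) - y)^2),
    linear_svm = {
      f <- svm_decision(fit, x)
      mean(pmax(0, 1 - ifelse(y == 1, 1, -1) * f)^2)
    },
    logistic_regression = {
      p <- pmin(pmax(lr_predict(fit, x), 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
  )
}

#' Train a baseline classifier
#'
#' Hyperparameters are chosen by stratified k-fold cross-validation
#' minimizing the learner's own loss (deviance for logistic regression,
#' squared hinge for the SVM, Brier score for the forest), then the model is
#' refit on the full training matrix. With a single-row grid the CV step is
#' skipped. Linear-SVM decision scores are min-max rescaled to `[0, 1]`
#' within each prediction batch so all models emit comparable probabilities.
#'
#' @param train a `feature_matrix` with both classes present.
#' @param spec a `baseline_spec`.
#' @param k number of CV folds.
#' @return a `baseline_model` with a `predict` method returning named
#'   probabilities in `[0, 1]`.
#' @export
train_baseline <- function(train, spec, k = 3) {
  x <- train$x
  y <- train$labels
  if (all(y == 1) || all(y == 0)) {
    stop("baseline training requires both cases and controls", call. = FALSE)
  }
  grid <- spec$grid
  best_row <- 1L
  if (nrow(grid) > 1) {
    fold <- stratified_folds(y, k, spec$seed)
    losses <- vapply(seq_len(nrow(grid)), function(g) {
      hp <- as.list(grid[g, , drop = FALSE])
      mean(vapply(seq_len(k), function(f) {
        tr <- fold != f
        fit <- fit_baseline_kind(spec$kind, x[tr, , drop = FALSE], y[tr], hp,
                                 seed = derive_seed(spec$seed, g * k + f))
        baseline_val_loss(spec$kind, fit, x[!tr, , drop = FALSE], y[!tr])
      }, numeric(1)))
    }, numeric(1))
    best_row <- which.min(losses)
  }
  hp <- as.list(grid[best_row, , drop = FALSE])
  fit <- fit_baseline_kind(spec$kind, x, y, hp, seed = spec$seed)
  structure(list(kind = spec$kind, fit = fit, hyperparams = hp,
                 feature_schema = colnames(x), spec = spec),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- align_features(newdata, object$feature_schema)
  p <- predict_baseline_kind(object$kind, object$fit, x)
  names(p) <- rownames(x)
  p
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("baseline_model: %s (%s)\n", x$kind,
              paste(names(x$hyperparams), unlist(x$hyperparams), sep = "=", collapse = ", ")))
  invisible(x)
}

# ---- combination ---------------------------------------------------------

#' Combine LGD- and missense-specific predictions per sample
#'
#' For a sample scored by both variant-class-specific models, the combined
#' prediction is the maximum of the two probabilities. `both_only` restricts
#' the output to samples present in both maps (the reported "combined"
#' evaluation cohort); `all` lets one-sided samples keep their single model's
#' probability.
#'
#' @param p_lgd,p_missense named numeric vectors of probabilities keyed by
#'   sample ID.
#' @param cohort `"both_only"` or `"all"`.
#' @return named numeric vector.
#' @export
combined_predict <- function(p_lgd, p_missense, cohort = c("both_only", "all")) {
  cohort <- match.arg(cohort)
  both <- intersect(names(p_lgd), names(p_missense))
  if (cohort == "both_only") {
    one_sided <- c(setdiff(names(p_lgd), both), setdiff(names(p_missense), both))
    if (length(one_sided) > 0) {
      stop(sprintf("samples missing from one map in both_only mode: %s",
                   paste(utils::head(one_sided, 5), collapse = ", ")), call. = FALSE)
    }
    out <- pmax(p_lgd[both], p_missense[both])
    names(out) <- both
    return(out)
  }
  ids <- union(names(p_lgd), names(p_missense))
  out <- stats::setNames(numeric(length(ids)), ids)
  out[names(p_lgd)] <- p_lgd
  out[both] <- pmax(p_lgd[both], p_missense[both])
  only_mis <- setdiff(names(p_missense), both)
  out[only_mis] <- p_missense[only_mis]
  out
}

#' Average predictions across models (ensemble)
#'
#' Arithmetic per-sample mean over the supplied probability maps. Dropping
#' the SNN map gives the baselines-only ensemble variant.
#'
#' @param prob_maps list of named numeric vectors covering identical samples.
#' @return named numeric vector of per-sample means.
#' @export
ensemble_predict <- function(prob_maps) {
  if (length(prob_maps) == 0) stop("no probability maps supplied", call. = FALSE)
  ids <- names(prob_maps[[1]])
  for (m in prob_maps) {
    if (!setequal(names(m), ids)) {
      stop("probability maps do not cover the same samples", call. = FALSE)
    }
  }
  mat <- vapply(prob_maps, function(m) m[ids], numeric(length(ids)))
  if (length(ids) == 1) mat <- matrix(mat, nrow = 1)
  out <- rowMeans(mat)
  names(out) <- ids
  out
}

# ---- heuristics ----------------------------------------------------------

#' Define a heuristic classification rule
#'
#' A sample is called a case iff it carries at least one LGD variant in a
#' qualifying gene: membership in a provided list (`gene_list`),
#' `pli >= threshold` (default 0.90), or `loeuf < threshold` (default 0.35).
#' Missense variants never trigger a heuristic.
#'
#' @param kind `"gene_list"`, `"pli_threshold"` or `"loeuf_threshold"`.
#' @param genes character vector of gene symbols (gene_list rules).
#' @param threshold numeric cutoff (score rules).
#' @return a `heuristic_rule`.
#' @export
heuristic_rule <- function(kind = c("gene_list", "pli_threshold", "loeuf_threshold"),
                           genes = NULL, threshold = NULL) {
  kind <- match.arg(kind)
  if (kind == "gene_list") {
    if (length(genes) == 0) stop("gene_list rules need a non-empty gene set", call. = FALSE)
  } else if (is.null(threshold)) {
    threshold <- if (kind == "pli_threshold") 0.90 else 0.35
  }
  structure(list(rule_kind = kind, gene_set = genes, threshold = threshold),
            class = "heuristic_rule")
}

#' Apply a heuristic rule to a cohort
#'
#' @param variants a `variant_table` (all samples in it are classified).
#' @param scores a `gene_scores` table (required for score rules; genes
#'   absent from it never qualify).
#' @param rule a `heuristic_rule`.
#' @return named integer vector (1 = called case, 0 = not) over all samples.
#' @export
heuristic_classify <- function(variants, scores = NULL, rule) {
  samples <- unique(variants$sample_id)
  lgd <- variants[variants$variant_class == "lgd", , drop = FALSE]
  qualifying <- switch(rule$rule_kind,
    gene_list = lgd$gene %in% rule$gene_set,
    pli_threshold = {
      if (is.null(scores)) stop("score rules require a gene_scores table", call. = FALSE)
      idx <- match(lgd$gene, scores$gene)
      absent <- is.na(idx)
      if (any(absent)) {
        message(sprintf("%d LGD variant(s) in genes absent from the score table treated as non-qualifying",
                        sum(absent)))
      }
      ok <- !absent & !scores$pli_missing[idx] & scores$pli[idx] >= rule$threshold
      ok[is.na(ok)] <- FALSE
      ok
    },
    loeuf_threshold = {
      if (is.null(scores)) stop("score rules require a gene_scores table", call. = FALSE)
      idx <- match(lgd$gene, scores$gene)
      absent <- is.na(idx)
      if (any(absent)) {
        message(sprintf("%d LGD variant(s) in genes absent from the score table treated as non-qualifying",
                        sum(absent)))
      }
      ok <- !absent & !scores$loeuf_missing[idx] & scores$loeuf[idx] < rule$threshold
      ok[is.na(ok)] <- FALSE
      ok
    }
  )
  hit <- unique(lgd$sample_id[qualifying])
  out <- stats::setNames(as.integer(samples %in% hit), samples)
  out
}
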