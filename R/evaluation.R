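# Low-FPR evaluation: TPR at FPR < fpr_max, ROC-AUC, PR-AUC, the randomized
# reference model, percentile confidence intervals and z-scores, and the
# repeated 75/25-split experiment harness in which every model sees identical
# splits within an iteration.

#' True-positive rate at a bounded false-positive rate
#'
#' With `m` control scores, let `k` be the largest integer with
#' `k/m < fpr_max`. The decision threshold is the `(k+1)`-th largest control
#' score and the returned TPR is the fraction of case scores strictly greater
#' than it, i.e. the best achievable TPR while keeping FPR strictly below
#' `fpr_max`. At `k = 0` this is the fraction of cases scored above the
#' maximum control — the cross-validation selection criterion.
#'
#' @param case_scores,control_scores numeric score vectors.
#' @param fpr_max upper bound (exclusive) on the false-positive rate.
#' @return scalar TPR in `[0, 1]`.
#' @export
tpr_at_fpr <- function(case_scores, control_scores, fpr_max = 0.01) {
  if (length(control_scores) == 0) {
    stop("control score vector is empty; threshold undefined", call. = FALSE)
  }
  if (length(case_scores) == 0) stop("case score vector is empty", call. = FALSE)
  if (fpr_max < 0 || fpr_max > 1) stop("fpr_max must lie in [0, 1]", call. = FALSE)
  m <- length(control_scores)
  k <- ceiling(m * fpr_max) - 1
  if (ceiling(m * fpr_max) == m * fpr_max) k <- m * fpr_max - 1  # k/m strictly < fpr_max
  k <- max(0, min(k, m - 1))
  sorted <- sort(control_scores, decreasing = TRUE)
  threshold <- sorted[k + 1]
  mean(case_scores > threshold)
}

#' Area under the ROC curve
#'
#' Mann-Whitney probability that a random case outscores a random control,
#' ties counted one half. Invariant to strictly monotone score transforms.
#'
#' @param case_scores,control_scores numeric score vectors.
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(case_scores, control_scores) {
  if (length(case_scores) == 0 || length(control_scores) == 0) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  nc <- length(case_scores)
  nu <- length(control_scores)
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  (sum(r[seq_len(nc)]) - nc * (nc + 1) / 2) / (nc * nu)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: walking thresholds down through the unique score
#' values, each recall increment contributes `delta_recall * precision` at
#' that threshold (no interpolation between points, avoiding the optimism of
#' trapezoidal PR integration). For uniformly random scores the expected
#' value approaches the case prevalence.
#'
#' @param case_scores,control_scores numeric score vectors.
#' @return scalar PR-AUC in `(0, 1]`.
#' @export
pr_auc <- function(case_scores, control_scores) {
  if (length(case_scores) == 0 || length(control_scores) == 0) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  scores <- c(case_scores, control_scores)
  y <- c(rep(1L, length(case_scores)), rep(0L, length(control_scores)))
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  # group tied scores: all samples at one threshold enter together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(grp != c(grp[-1], -1))  # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / length(case_scores)
  precision <- tp / (tp + fp)
  d_recall <- diff(c(0, recall))
  sum(d_recall * precision)
}

#' ROC and precision-recall curve points
#'
#' @param case_scores,control_scores numeric score vectors.
#' @return list of two data.frames: `roc` (fpr, tpr) and `pr`
#'   (recall, precision), one row per distinct threshold.
#' @export
score_curves <- function(case_scores, control_scores) {
  scores <- c(case_scores, control_scores)
  y <- c(rep(1L, length(case_scores)), rep(0L, length(control_scores)))
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(grp != c(grp[-1], -1))
  tp <- tp[last]; fp <- fp[last]
  list(
    roc = data.frame(fpr = c(0, fp / length(control_scores)),
                     tpr = c(0, tp / length(case_scores))),
    pr = data.frame(recall = tp / length(case_scores),
                    precision = tp / (tp + fp))
  )
}

#' Uniform-random reference predictions
#'
#' The randomized reference model: probabilities drawn i.i.d. Uniform(0, 1)
#' and assigned to samples, reproducible under `seed`.
#'
#' @param sample_ids character vector of sample IDs.
#' @param seed integer seed.
#' @return named numeric vector.
#' @export
randomized_predictions <- function(sample_ids, seed = 1) {
  if (length(sample_ids) == 0) return(stats::setNames(numeric(0), character(0)))
  with_seed(seed, stats::setNames(stats::runif(length(sample_ids)), sample_ids))
}

#' z-score of a model against the randomized reference
#'
#' `(mean(model) - mean(random)) / sd(random)` over per-iteration metric
#' values, sd with the n-1 denominator.
#'
#' @param model_values,random_values numeric vectors of per-iteration metric
#'   values (length >= 2 each).
#' @return scalar z-score.
#' @export
zscore <- function(model_values, random_values) {
  if (length(model_values) < 2 || length(random_values) < 2) {
    stop("both vectors need at least 2 iterations", call. = FALSE)
  }
  s <- stats::sd(random_values)
  if (s == 0) stop("randomized model has zero variance; z-score undefined", call. = FALSE)
  (mean(model_values) - mean(random_values)) / s
}

#' Stratified repeated train/test split plans
#'
#' Each plan assigns `round(fraction_train * n)` samples to training,
#' stratified by label so every test set retains both classes.
#'
#' @param sample_ids character vector.
#' @param labels 0/1 vector aligned with `sample_ids`.
#' @param n_iter number of independent splits.
#' @param fraction_train training fraction (default 0.75).
#' @param seed base seed; split `i` uses a seed derived from `(seed, i)`.
#' @return list of plans, each `list(iteration, train_ids, test_ids, seed)`.
#' @export
make_splits <- function(sample_ids, labels, n_iter, fraction_train = 0.75, seed = 1) {
  n <- length(sample_ids)
  n_train_total <- round(fraction_train * n)
  idx_case <- which(labels == 1)
  idx_ctrl <- which(labels == 0)
  n_tr_case <- round(fraction_train * length(idx_case))
  n_tr_ctrl <- n_train_total - n_tr_case
  n_tr_ctrl <- max(0, min(n_tr_ctrl, length(idx_ctrl)))
  lapply(seq_len(n_iter), function(i) {
    s <- derive_seed(seed, i)
    with_seed(s, {
      tr <- c(sample(idx_case, n_tr_case), sample(idx_ctrl, n_tr_ctrl))
    })
    list(iteration = i,
         train_ids = sample_ids[sort(tr)],
         test_ids = sample_ids[setdiff(seq_len(n), sort(tr))],
         fraction_train = fraction_train,
         seed = s)
  })
}

split_scores <- function(p, labels_by_id) {
  lab <- labels_by_id[names(p)]
  list(case = unname(p[lab == 1]), control = unname(p[lab == 0]))
}

compute_metrics <- function(p, labels_by_id, fpr_max) {
  sc <- split_scores(p, labels_by_id)
  c(tpr_at_fpr = tpr_at_fpr(sc$case, sc$control, fpr_max),
    roc_auc = roc_auc(sc$case, sc$control),
    pr_auc = pr_auc(sc$case, sc$control))
}

#' Run the repeated-split evaluation experiment
#'
#' For each of `n_iter` iterations one stratified 75/25 split of the cohort
#' is shared by every model. LGD-specific and missense-specific models are
#' trained on the training rows of their class-specific feature matrices and
#' scored on the test rows; combined (per-sample max over samples carrying
#' both variant classes), ensemble (per-sample mean over all models),
#' ensemble-without-SNN, and uniform-random predictions are derived from
#' them. Metrics (TPR at FPR < `fpr_max`, ROC-AUC, PR-AUC) are aggregated as
#' mean, percentile 95% CI, and z-score against the randomized model.
#'
#' @param variants a `variant_table`.
#' @param scores a `gene_scores` table.
#' @param models character subset of `c("snn", "random_forest", "linear_svm",
#'   "logistic_regression")`.
#' @param settings character subset of `c("lgd", "missense", "combined")`.
#' @param n_iter number of split iterations (>= 2).
#' @param seed base seed.
#' @param snn_hp `snn_hyperparams` used when `tune = FALSE`.
#' @param mode `"full"` or `"trivial"` (one-hot ablation: gene indicators
#'   only, no score features, no pathogenicity weighting).
#' @param missense_filter `"none"`; `"deleterious_train"` (build missense
#'   features from deleterious variants, PrimateAI >= `primateai_threshold`,
#'   keeping every sample); or `"deleterious_only"` (additionally drop
#'   samples without a deleterious missense variant from training and
#'   testing).
#' @param primateai_threshold deleteriousness cutoff (default 0.803).
#' @param fpr_max FPR bound for the TPR metric.
#' @param tune if `TRUE`, run per-split hyperparameter optimization
#'   ([optimize_hyperparams()] for the SNN, per-learner CV for baselines);
#'   expensive, off by default.
#' @param snn_grid grid for `tune = TRUE` (default [default_snn_grid()]).
#' @param fraction_train training fraction.
#' @return a `metrics_report`: `table` (model x setting x metric summary
#'   data.frame), `values` (per-iteration metric arrays), `splits`, `n_iter`,
#'   `seed`.
#' @export
run_experiment <- function(variants, scores,
                           models = c("snn", "random_forest", "linear_svm", "logistic_regression"),
                           settings = c("lgd", "missense", "combined"),
                           n_iter = 100, seed = 1,
                           snn_hp = snn_hyperparams(),
                           mode = c("full", "trivial"),
                           missense_filter = c("none", "deleterious_train", "deleterious_only"),
                           primateai_threshold = 0.803,
                           fpr_max = 0.01,
                           tune = FALSE, snn_grid = NULL,
                           fraction_train = 0.75) {
  mode <- match.arg(mode)
  missense_filter <- match.arg(missense_filter)
  if (n_iter < 2) stop("n_iter must be >= 2 for confidence intervals", call. = FALSE)
  if (length(models) == 0) stop("at least one model is required", call. = FALSE)

  need_lgd <- any(c("lgd", "combined") %in% settings)
  need_mis <- any(c("missense", "combined") %in% settings)
  fm_lgd <- if (need_lgd) build_feature_matrix(variants, scores, "lgd", mode) else NULL
  fm_mis <- NULL
  if (need_mis) {
    if (missense_filter == "none") {
      fm_mis <- build_feature_matrix(variants, scores, "missense", mode)
    } else {
      keep <- variants$variant_class != "missense" |
        (!is.na(variants$pathogenicity) & variants$pathogenicity >= primateai_threshold)
      v_del <- variants[keep, , drop = FALSE]
      class(v_del) <- class(variants)
      if (missense_filter == "deleterious_train") {
        universe <- unique(variants$sample_id[variants$variant_class == "missense"])
        fm_mis <- build_feature_matrix(v_del, scores, "missense", mode,
                                       allow_empty_rows = TRUE, sample_universe = universe)
        # labels for zero-variant rows come from the full table
        lab <- variants$phenotype[match(fm_mis$sample_ids, variants$sample_id)]
        fm_mis$labels <- as.integer(lab == "case")
      } else {
        fm_mis <- build_feature_matrix(v_del, scores, "missense", mode)
      }
    }
  }

  # the split universe is the union of samples entering any requested model
  cohort_ids <- unique(c(if (need_lgd) fm_lgd$sample_ids,
                         if (need_mis) fm_mis$sample_ids))
  lab_by_id <- stats::setNames(
    integer(length(cohort_ids)), cohort_ids)
  if (need_lgd) lab_by_id[fm_lgd$sample_ids] <- fm_lgd$labels
  if (need_mis) lab_by_id[fm_mis$sample_ids] <- fm_mis$labels
  if (all(lab_by_id == 1) || all(lab_by_id == 0)) {
    stop("cohort must contain both cases and controls", call. = FALSE)
  }
  splits <- make_splits(cohort_ids, lab_by_id[cohort_ids], n_iter, fraction_train, seed)

  all_model_names <- c(models, "ensemble", "ensemble_minus_snn", "randomized")
  metrics <- c("tpr_at_fpr", "roc_auc", "pr_auc")
  values <- array(NA_real_,
                  dim = c(n_iter, length(all_model_names), length(settings), length(metrics)),
                  dimnames = list(NULL, all_model_names, settings, metrics))
  prevalence <- matrix(NA_real_, nrow = n_iter, ncol = length(settings),
                       dimnames = list(NULL, settings))

  fit_one <- function(kind, fm_train, iter_seed, idx) {
    if (kind == "snn") {
      hp <- snn_hp
      if (tune) {
        grid <- snn_grid %||% default_snn_grid()
        hp <- optimize_hyperparams(fm_train, grid, k = 3, seed = iter_seed)
      }
      hp$seed <- derive_seed(iter_seed, idx)
      snn_fit(fm_train, hp)
    } else {
      grid <- NULL
      if (!tune) {
        grid <- switch(kind,
          random_forest = data.frame(num_trees = 100, max_depth = 10),
          linear_svm = data.frame(C = 1),
          logistic_regression = data.frame(C = 1))
      }
      train_baseline(fm_train, baseline_spec(kind, grid = grid,
                                             seed = derive_seed(iter_seed, idx)))
    }
  }

  for (i in seq_len(n_iter)) {
    plan <- splits[[i]]
    preds <- list()  # preds[[setting]][[model]]
    for (cls in c("lgd", "missense")) {
      fm <- if (cls == "lgd") fm_lgd else fm_mis
      if (is.null(fm)) next
      tr_ids <- intersect(plan$train_ids, fm$sample_ids)
      te_ids <- intersect(plan$test_ids, fm$sample_ids)
      fm_tr <- subset_feature_matrix(fm, tr_ids)
      fm_te <- subset_feature_matrix(fm, te_ids)
      if (length(te_ids) == 0 || all(fm_tr$labels == 1) || all(fm_tr$labels == 0)) next
      preds[[cls]] <- list()
      for (mi in seq_along(models)) {
        model <- fit_one(models[mi], fm_tr, plan$seed, mi)
        p <- if (models[mi] == "snn") snn_predict(model, fm_te) else predict(model, fm_te)
        preds[[cls]][[models[mi]]] <- p
      }
    }
    if ("combined" %in% settings && !is.null(preds$lgd) && !is.null(preds$missense)) {
      both <- intersect(names(preds$lgd[[1]]), names(preds$missense[[1]]))
      if (length(both) > 0) {
        preds$combined <- lapply(stats::setNames(models, models), function(mm) {
          combined_predict(preds$lgd[[mm]][both], preds$missense[[mm]][both], "both_only")
        })
      }
    }
    for (st in settings) {
      pr <- preds[[st]]
      if (is.null(pr) || length(pr) == 0) next
      pr$ensemble <- ensemble_predict(pr[models])
      if ("snn" %in% models && length(models) > 1) {
        pr$ensemble_minus_snn <- ensemble_predict(pr[setdiff(models, "snn")])
      }
      pr$randomized <- randomized_predictions(names(pr[[1]]),
                                              seed = derive_seed(plan$seed, match(st, settings)))
      lab <- lab_by_id[names(pr[[1]])]
      if (sum(lab == 1) == 0 || sum(lab == 0) == 0) next
      for (nm in names(pr)) {
        values[i, nm, st, ] <- compute_metrics(pr[[nm]], lab_by_id, fpr_max)
      }
      prevalence[i, st] <- mean(lab)
    }
  }

  rows <- list()
  for (st in settings) {
    for (nm in all_model_names) {
      for (met in metrics) {
        vals <- values[, nm, st, met]
        if (all(is.na(vals))) next
        ci <- ci_percentile(vals)
        z <- NA_real_
        if (nm != "randomized") {
          rv <- values[, "randomized", st, met]
          if (stats::sd(rv) > 0) z <- zscore(vals, rv)
        }
        rows[[length(rows) + 1]] <- data.frame(
          setting = st, model = nm, metric = met,
          mean = mean(vals), ci_low = ci[["low"]], ci_high = ci[["high"]],
          z = z, stringsAsFactors = FALSE)
      }
    }
  }
  report <- list(
    table = do.call(rbind, rows),
    values = values,
    splits = splits,
    n_iter = n_iter,
    seed = seed,
    prevalence = prevalence,
    config = list(models = models, settings = settings, mode = mode,
                  missense_filter = missense_filter, fpr_max = fpr_max,
                  tune = tune, fraction_train = fraction_train,
                  ci_method = "percentile",
                  z_denominator = "sd of randomized model iteration values")
  )
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d iterations, seed %d\n", x$n_iter, x$seed))
  tab <- x$table
  tab$mean <- round(tab$mean, 4)
  tab$ci_low <- round(tab$ci_low, 4)
  tab$ci_high <- round(tab$ci_high, 4)
  tab$z <- round(tab$z, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export a metrics report
#'
#' Writes a JSON file with per-model blocks
#' `{metric: {mean, ci_low, ci_high, z}}` and a flat TSV
#' (setting, model, metric, mean, ci_low, ci_high, z).
#'
#' @param report a `metrics_report`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @export
write_metrics_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    out <- list(n_iter = report$n_iter, seed = report$seed, config = report$config)
    tab <- report$table
    for (st in unique(tab$setting)) {
      out[[st]] <- list()
      sub <- tab[tab$setting == st, ]
      for (nm in unique(sub$model)) {
        block <- list()
        for (met in unique(sub$metric)) {
          r <- sub[sub$model == nm & sub$metric == met, ]
          block[[met]] <- list(mean = r$mean, ci_low = r$ci_low,
                               ci_high = r$ci_high, z = r$z)
        }
        out[[st]][[nm]] <- block
      }
    }
    jsonlite::write_json(out, json_path, digits = NA, auto_unbox = TRUE, na = "null")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(report$table, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
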