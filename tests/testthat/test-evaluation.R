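# Exhaustive-threshold oracle: best TPR over all thresholds keeping
# FPR strictly below fpr_max (thresholds at every observed score plus
# sentinels; decision rule is score > threshold).
tpr_oracle <- function(cases, controls, fpr_max) {
  thresholds <- sort(unique(c(cases, controls, -Inf)))
  best <- 0
  for (t in thresholds) {
    fpr <- mean(controls > t)
    if (fpr < fpr_max) best <- max(best, mean(cases > t))
  }
  best
}

test_that("tpr_at_fpr handles boundary threshold cases", {
  # one case above max control at k = 0
  expect_equal(tpr_at_fpr(c(0.9, 0.2), c(0.5), fpr_max = 0.01), 0.5)
  expect_equal(tpr_at_fpr(c(0.9, 0.8), c(0.5, 0.4), fpr_max = 0.01), 1.0)
  expect_error(tpr_at_fpr(c(0.5), numeric(0)), "empty")
})

test_that("tpr_at_fpr equals an exhaustive threshold sweep", {
  set.seed(17)
  for (rep in 1:60) {
    nc <- sample(5:40, 1); nu <- sample(5:40, 1)
    cases <- round(runif(nc), 2)     # rounding forces ties
    controls <- round(runif(nu), 2)
    for (fpr_max in c(0.01, 0.05, 0.1)) {
      expect_equal(tpr_at_fpr(cases, controls, fpr_max),
                   tpr_oracle(cases, controls, fpr_max),
                   info = sprintf("rep %d fpr %g", rep, fpr_max))
    }
  }
})

test_that("tpr_at_fpr is monotone in fpr_max and reaches 1 as fpr_max -> 1", {
  set.seed(23)
  for (rep in 1:20) {
    cases <- runif(30); controls <- runif(25)
    grid <- c(0.01, 0.05, 0.1, 0.3, 0.6, 0.999999)
    vals <- sapply(grid, function(f) tpr_at_fpr(cases, controls, f))
    expect_true(all(diff(vals) >= 0))
  }
  # when thresholds below all case scores are admissible, TPR = 1
  expect_equal(tpr_at_fpr(runif(10, 0.5, 1), runif(10), fpr_max = 0.9999), 1)
})

test_that("roc_auc equals concordant-pair counting with ties at 1/2", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(roc_auc(0.9, 0.9), 0.5)           # pure tie
  expect_equal(roc_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)  # constant scores

  set.seed(31)
  for (rep in 1:30) {
    nc <- sample(3:25, 1); nu <- sample(3:25, 1)
    cases <- sample(seq(0, 1, 0.1), nc, replace = TRUE)
    controls <- sample(seq(0, 1, 0.1), nu, replace = TRUE)
    conc <- 0
    for (a in cases) for (b in controls) {  # pairwise oracle
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
    expect_equal(roc_auc(cases, controls), conc / (nc * nu))
  }
})

test_that("roc_auc is invariant to strictly monotone transforms", {
  set.seed(37)
  cases <- runif(40); controls <- runif(30)
  base <- roc_auc(cases, controls)
  expect_equal(roc_auc(exp(3 * cases), exp(3 * controls)), base)
  expect_equal(roc_auc(qlogis(cases), qlogis(controls)), base)
})

test_that("pr_auc is 1 under perfect separation and ~prevalence under random scores", {
  expect_equal(pr_auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  set.seed(41)
  vals <- replicate(200, {
    pr_auc(runif(60), runif(140))
  })
  expect_lt(abs(mean(vals) - 0.3), 0.02)  # prevalence 60/200
})

test_that("randomized_predictions are reproducible uniforms", {
  ids <- sprintf("s%03d", 1:50)
  expect_identical(randomized_predictions(ids, 7), randomized_predictions(ids, 7))
  expect_false(identical(randomized_predictions(ids, 7), randomized_predictions(ids, 8)))
  big <- randomized_predictions(sprintf("s%05d", 1:10000), 3)
  expect_lt(abs(mean(big) - 0.5), 0.02)
  expect_equal(length(randomized_predictions(character(0), 1)), 0)
})

test_that("zscore matches substitution and behaves under the null", {
  x <- c(0.5, 0.6, 0.4, 0.55)
  expect_equal(zscore(x, x), 0)
  r <- c(0.1, 0.2, 0.3, 0.2)
  shifted <- r + 2 * sd(r)
  expect_equal(zscore(shifted, r), 2.0)
  expect_error(zscore(x, rep(0.5, 4)), "zero variance")

  set.seed(43)
  zs <- replicate(500, zscore(rnorm(100), rnorm(100)))
  expect_gte(mean(abs(zs) < 4), 0.99)
})

test_that("make_splits is stratified with the stated sizes", {
  labels <- c(rep(1, 61), rep(0, 39))
  ids <- sprintf("s%03d", 1:100)
  plans <- make_splits(ids, labels, n_iter = 10, seed = 2)
  for (p in plans) {
    expect_equal(length(p$train_ids), round(0.75 * 100))
    expect_equal(sort(c(p$train_ids, p$test_ids)), sort(ids))
    expect_equal(length(intersect(p$train_ids, p$test_ids)), 0)
    te_lab <- labels[match(p$test_ids, ids)]
    expect_gt(sum(te_lab == 0), 0)  # test controls always retained
    expect_gt(sum(te_lab == 1), 0)
  }
  # reproducible
  expect_identical(plans, make_splits(ids, labels, n_iter = 10, seed = 2))
})

test_that("run_experiment plumbing: rows, errors, shared splits", {
  sim <- small_planted_cohort()
  expect_error(run_experiment(sim$variants, sim$scores, n_iter = 1, seed = 1),
               "n_iter")
  rep <- run_experiment(sim$variants, sim$scores,
                        models = c("snn", "logistic_regression"),
                        settings = c("lgd", "missense"),
                        n_iter = 2, seed = 3,
                        snn_hp = snn_hyperparams(epochs = 20))
  tab <- rep$table
  # exactly the configured model x setting x metric rows
  expect_setequal(unique(tab$model),
                  c("snn", "logistic_regression", "ensemble", "ensemble_minus_snn",
                    "randomized"))
  expect_setequal(unique(tab$setting), c("lgd", "missense"))
  expect_equal(nrow(tab), 5 * 2 * 3)
  expect_true(all(tab$ci_low <= tab$mean + 1e-12 & tab$mean <= tab$ci_high + 1e-12))
  metr <- tab[tab$metric %in% c("tpr_at_fpr", "roc_auc", "pr_auc"), ]
  expect_true(all(metr$mean >= 0 & metr$mean <= 1))
  # split plans are part of the report (shared by construction across models)
  expect_equal(length(rep$splits), 2)
})

test_that("percentile and normal CIs agree on 100-iteration vectors", {
  # per-iteration metric vectors are tightly concentrated and near-symmetric
  set.seed(47)
  for (rep in 1:20) {
    x <- rnorm(100, mean = 0.6, sd = 0.04)
    pc <- denovoSNN:::ci_percentile(x)
    nc <- mean(x) + c(-1.96, 1.96) * sd(x)
    expect_lt(abs(pc[["low"]] - nc[1]), 0.02)
    expect_lt(abs(pc[["high"]] - nc[2]), 0.02)
  }
})

test_that("metrics report exports JSON and TSV", {
  sim <- small_planted_cohort()
  rep <- run_experiment(sim$variants, sim$scores, models = "logistic_regression",
                        settings = "lgd", n_iter = 2, seed = 3)
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_metrics_report(rep, jp, tp)
  parsed <- jsonlite::read_json(jp)
  expect_true("lgd" %in% names(parsed))
  expect_true(is.numeric(parsed$lgd$logistic_regression$roc_auc$mean))
  flat <- utils::read.delim(tp)
  expect_equal(nrow(flat), nrow(rep$table))
})
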