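test_that("artificial LGD samples mirror real single-variant rows", {
  fm <- build_feature_matrix(separable_cohort(), separable_scores(), "lgd", "full")
  art <- make_artificial_samples(c("RISK", "SAFE", "BG"), "lgd",
                                 separable_scores(), fm$feature_schema <- colnames(fm$x))
  expect_equal(nrow(art$x), 3)
  # each row has exactly one gene indicator set
  gene_cols <- art$gene_columns
  expect_true(all(rowSums(art$x[, gene_cols, drop = FALSE]) == 1))

  # artificial row equals the feature vector of a real single-LGD sample
  v <- variant_table(data.frame(
    sample_id = "only", phenotype = "case", gene = "RISK",
    variant_class = "lgd", pathogenicity = NA_real_, stringsAsFactors = FALSE))
  real <- build_feature_matrix(v, separable_scores(), "lgd", "full")
  real_row <- align_features(real, colnames(art$x))
  expect_identical(unname(art$x["RISK", ]), unname(real_row["only", ]))

  expect_error(make_artificial_samples(character(0), "lgd", separable_scores(),
                                       colnames(fm$x)), "empty")
})

test_that("genes outside indicator-only schemas are unrankable; score schemas extrapolate", {
  schema_trivial <- c("A", "B")
  expect_message(
    art <- make_artificial_samples(c("A", "B", "NEW"), "lgd", NULL, schema_trivial),
    "unrankable")
  expect_equal(attr(art, "unrankable"), "NEW")
  expect_equal(art$sample_ids, c("A", "B"))

  schema_full <- c("A", "B", "pli", "loeuf", "rvis", "phastcons")
  expect_message(
    art2 <- make_artificial_samples(c("A", "NEW"), "lgd", toy_scores(), schema_full),
    "extrapolated")
  expect_true(attr(art2, "extrapolated")[["NEW"]])
  expect_equal(sum(art2$x["NEW", c("A", "B")]), 0)  # score features only
})

test_that("missense artificial samples carry the configured pathogenicity", {
  art <- make_artificial_samples(c("A", "B"), "missense", NULL, c("A", "B"),
                                 pathogenicity = 0.8)
  expect_equal(unname(diag(art$x)), c(0.8, 0.8))
})

test_that("rank_genes orders by mean probability with lexicographic ties and CI", {
  fm <- build_feature_matrix(separable_cohort(), separable_scores(), "lgd", "full")
  m <- snn_fit(fm, snn_hyperparams(epochs = 200, seed = 1))
  art <- make_artificial_samples(c("RISK", "SAFE"), "lgd", separable_scores(),
                                 colnames(fm$x))
  rk <- rank_genes(list(m), art)
  expect_equal(rk$gene[rk$rank == 1], "RISK")
  expect_equal(rk$gene[rk$rank == 2], "SAFE")
  # single model: zero-width CI
  expect_equal(rk$ci_low, rk$mean_probability)
  expect_equal(rk$ci_high, rk$mean_probability)

  # identical models across iterations: still zero-width CI
  rk2 <- rank_genes(list(m, m, m), art)
  expect_equal(rk2$ci_high - rk2$ci_low, c(0, 0))

  # ranking invariant to gene input order
  art_rev <- make_artificial_samples(c("SAFE", "RISK"), "lgd", separable_scores(),
                                     colnames(fm$x))
  rk_rev <- rank_genes(list(m), art_rev)
  expect_equal(rk_rev$gene[order(rk_rev$rank)], rk$gene[order(rk$rank)])
})

test_that("enrichment_diff matches hand substitution and conserves to zero", {
  rk <- structure(data.frame(
    gene = c("A", "B"), mean_probability = c(0.9, 0.1),
    ci_low = c(0.9, 0.1), ci_high = c(0.9, 0.1), rank = 1:2,
    extrapolated = FALSE, stringsAsFactors = FALSE
  ), class = c("gene_ranking", "data.frame"))
  v <- variant_table(data.frame(
    sample_id = sprintf("s%d", 1:15),
    phenotype = c(rep("case", 10), rep("control", 5)),
    gene = c(rep("A", 2), rep("B", 8), rep("B", 5)),
    variant_class = "lgd", pathogenicity = NA_real_, stringsAsFactors = FALSE))
  ed <- enrichment_diff(rk, v, "lgd")
  # gene A: 2 case variants of 10, 0 of 5 controls -> 0.2
  expect_equal(ed$per_gene$e_diff[ed$per_gene$gene == "A"], 0.2)
  # conservation: sums to zero when all genes are ranked
  expect_equal(sum(ed$per_gene$e_diff), 0)

  # equal distribution -> all zeros
  v_eq <- variant_table(data.frame(
    sample_id = sprintf("s%d", 1:8),
    phenotype = rep(c("case", "control"), 4),
    gene = rep(c("A", "A", "B", "B"), 2),
    variant_class = "lgd", pathogenicity = NA_real_, stringsAsFactors = FALSE))
  ed_eq <- enrichment_diff(rk, v_eq, "lgd")
  expect_equal(ed_eq$per_gene$e_diff, c(0, 0))

  v_onesided <- v
  v_onesided$phenotype <- "case"
  expect_error(enrichment_diff(rk, variant_table(v_onesided), "lgd"), "controls")
})

test_that("correlate_with_constraint matches a rank-based oracle", {
  set.seed(19)
  n <- 40
  genes <- sprintf("G%02d", 1:n)
  pli <- runif(n)
  prob <- plogis(qlogis(pmin(pmax(pli, 0.01), 0.99)) + rnorm(n, 0, 0.5))
  gs <- gene_score_table(list(pli = stats::setNames(pli, genes),
                              loeuf = stats::setNames(2 - 2 * pli, genes)))
  rk <- structure(data.frame(
    gene = genes, mean_probability = prob, ci_low = prob, ci_high = prob,
    rank = rank(-prob), extrapolated = FALSE, stringsAsFactors = FALSE
  ), class = c("gene_ranking", "data.frame"))
  out <- correlate_with_constraint(rk, gs)

  # brute-force Spearman from explicit ranks
  rho_oracle <- stats::cor(rank(prob), rank(pli))
  expect_equal(out$rho[out$score == "pli"], rho_oracle, tolerance = 1e-12)
  expect_equal(out$rho[out$score == "loeuf"], -rho_oracle, tolerance = 1e-12)

  # perfectly monotone case: rho exactly 1
  rk2 <- rk; rk2$mean_probability <- pli
  out2 <- correlate_with_constraint(rk2, gs)
  expect_equal(out2$rho[out2$score == "pli"], 1)

  # constant score errors
  gs_const <- gene_score_table(list(pli = stats::setNames(rep(0.5, n), genes)))
  expect_error(correlate_with_constraint(rk, gs_const), "constant")
})

test_that("probability independent of a permuted score gives small |rho|", {
  set.seed(29)
  n <- 50
  genes <- sprintf("G%02d", 1:n)
  hits <- 0
  for (rep in 1:200) {
    prob <- runif(n)
    pli <- sample(runif(n))  # permuted: independent of prob
    gs <- gene_score_table(list(pli = stats::setNames(pli, genes)))
    rk <- structure(data.frame(
      gene = genes, mean_probability = prob, ci_low = prob, ci_high = prob,
      rank = rank(-prob), extrapolated = FALSE, stringsAsFactors = FALSE
    ), class = c("gene_ranking", "data.frame"))
    rho <- correlate_with_constraint(rk, gs)$rho[1]
    if (abs(rho) < 0.4) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("planted risk genes rank above background", {
  sim <- small_planted_cohort()
  fm <- build_feature_matrix(sim$variants, sim$scores, "lgd", "full")
  models <- lapply(1:3, function(s) snn_fit(fm, snn_hyperparams(epochs = 150, seed = s)))
  art <- make_artificial_samples(sim$scores$gene[sim$scores$gene %in% fm$gene_columns],
                                 "lgd", sim$scores, colnames(fm$x))
  rk <- rank_genes(models, art)
  planted <- rk$rank[rk$gene %in% sim$risk_genes]
  other <- rk$rank[!rk$gene %in% sim$risk_genes]
  wt <- stats::wilcox.test(planted, other, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})
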