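# Gene prioritization via artificial single-variant samples.
#
# Every gene of interest becomes one artificial individual carrying exactly
# one variant in that gene. Scoring those individuals with trained
# variant-class-specific models yields a per-gene predicted probability that
# orders genes by their apparent contribution to case status; averaging over
# the models from repeated split iterations gives a mean and percentile CI
# per gene. A case/control enrichment difference per gene (a documented
# proxy: the gene's share of case variants minus its share of control
# variants) and rank correlations with constraint scores characterize the
# ranking.

#' Build artificial single-variant samples
#'
#' One row per gene. LGD mode: indicator 1 at that gene plus the gene's own
#' score features (when the schema carries score columns). Missense mode: the
#' gene cell is set to `pathogenicity` (default 1, the most deleterious
#' score). Genes absent from the schema's gene columns are ranked from score
#' features alone when score columns exist (flagged `extrapolated`);
#' otherwise they are excluded and listed in the `unrankable` attribute.
#'
#' @param genes character vector of gene symbols.
#' @param variant_class `"lgd"` or `"missense"`.
#' @param scores a `gene_scores` table (needed when the schema has score
#'   columns).
#' @param schema feature schema of the trained model
#'   (`model$feature_schema`).
#' @param pathogenicity missense cell value.
#' @return a `feature_matrix` whose rows are named by gene, with attributes
#'   `extrapolated` (logical per row) and `unrankable` (excluded genes).
#' @export
make_artificial_samples <- function(genes, variant_class = c("lgd", "missense"),
                                    scores = NULL, schema, pathogenicity = 1.0) {
  variant_class <- match.arg(variant_class)
  if (length(genes) == 0) stop("gene list is empty", call. = FALSE)
  genes <- unique(genes)
  score_cols <- intersect(GENE_SCORE_NAMES, schema)
  gene_cols <- setdiff(schema, score_cols)
  in_schema <- genes %in% gene_cols

  if (length(score_cols) == 0) {
    unrankable <- genes[!in_schema]
    if (length(unrankable) > 0) {
      message(sprintf("%d gene(s) outside the model schema are unrankable and were excluded",
                      length(unrankable)))
    }
    keep <- genes[in_schema]
    if (length(keep) == 0) stop("no rankable genes: none are in the model schema", call. = FALSE)
    x <- matrix(0, nrow = length(keep), ncol = length(schema),
                dimnames = list(keep, schema))
    val <- if (variant_class == "missense") pathogenicity else 1
    x[cbind(seq_along(keep), match(keep, schema))] <- val
    extrapolated <- rep(FALSE, length(keep))
    genes_used <- keep
  } else {
    if (is.null(scores)) stop("gene scores are required when the schema has score columns", call. = FALSE)
    x <- matrix(0, nrow = length(genes), ncol = length(schema),
                dimnames = list(genes, schema))
    hit <- which(in_schema)
    x[cbind(hit, match(genes[hit], schema))] <- 1
    gs <- lookup_gene_scores(scores, genes, quiet = TRUE)
    x[, score_cols] <- gs[, score_cols]
    extrapolated <- !in_schema
    if (any(extrapolated)) {
      message(sprintf("%d gene(s) outside the model schema are ranked from score features only (extrapolated)",
                      sum(extrapolated)))
    }
    genes_used <- genes
    unrankable <- character(0)
  }

  fm <- structure(list(
    x = x,
    labels = rep(NA_integer_, nrow(x)),
    sample_ids = genes_used,
    gene_columns = gene_cols,
    score_columns = score_cols,
    variant_class = variant_class,
    mode = if (length(score_cols) > 0) "full" else "trivial"
  ), class = "feature_matrix")
  attr(fm, "extrapolated") <- stats::setNames(extrapolated, genes_used)
  attr(fm, "unrankable") <- unrankable
  fm
}

#' Rank genes by mean predicted probability
#'
#' Scores the artificial samples with each supplied model (typically the
#' per-iteration models of a repeated-split experiment), then ranks genes by
#' the mean probability (descending; ties broken by gene symbol) with a
#' percentile 95% CI across models.
#'
#' @param models list of fitted models (`snn_model` or `baseline_model`).
#' @param artificial a `feature_matrix` from [make_artificial_samples()].
#' @return a `gene_ranking` data.frame: `gene`, `mean_probability`, `ci_low`,
#'   `ci_high`, `rank`, `extrapolated`.
#' @export
rank_genes <- function(models, artificial) {
  if (length(models) == 0) stop("at least one model is required", call. = FALSE)
  probs <- vapply(models, function(m) {
    p <- if (inherits(m, "snn_model")) snn_predict(m, artificial) else predict(m, artificial)
    unname(p)
  }, numeric(nrow(artificial$x)))
  if (nrow(artificial$x) == 1) probs <- matrix(probs, nrow = 1)
  mp <- rowMeans(probs)
  if (length(models) > 1) {
    cis <- t(apply(probs, 1, ci_percentile))
  } else {
    cis <- cbind(mp, mp)
  }
  genes <- artificial$sample_ids
  ord <- order(-mp, genes)
  rank <- integer(length(mp))
  rank[ord] <- seq_along(mp)
  extr <- attr(artificial, "extrapolated") %||% rep(FALSE, length(genes))
  out <- data.frame(
    gene = genes,
    mean_probability = mp,
    ci_low = cis[, 1],
    ci_high = cis[, 2],
    rank = rank,
    extrapolated = unname(extr[genes]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  attr(out, "n_models") <- length(models)
  out
}

#' Case/control enrichment difference per gene
#'
#' For gene `g`, `e_diff(g) = c_g / C - u_g / U`, where `c_g` and `u_g`
#' count the class-matching variants in `g` among cases and controls and
#' `C`, `U` are the corresponding totals over all variants of that class.
#' This is a documented proxy for the enrichment statistic whose exact
#' published form is unavailable; the formula is recorded in the output
#' metadata. Also returns the mean enrichment within 20 equal-width
#' predicted-probability bins.
#'
#' @param ranking a `gene_ranking`.
#' @param variants a `variant_table` with phenotype labels.
#' @param mutation_class `"lgd"` or `"missense"`.
#' @param n_bins number of probability bins for the curve.
#' @return list with `per_gene` (gene, mean_probability, e_diff), `curve`
#'   (bin_mid, mean_e_diff, n_genes), and `formula`.
#' @export
enrichment_diff <- function(ranking, variants, mutation_class = c("lgd", "missense"),
                            n_bins = 20) {
  mutation_class <- match.arg(mutation_class)
  v <- variants[variants$variant_class == mutation_class, , drop = FALSE]
  C <- sum(v$phenotype == "case")
  U <- sum(v$phenotype == "control")
  if (C == 0 || U == 0) {
    stop(sprintf("no %s variants in %s; enrichment undefined", mutation_class,
                 if (C == 0) "cases" else "controls"), call. = FALSE)
  }
  cg <- table(factor(v$gene[v$phenotype == "case"], levels = ranking$gene))
  ug <- table(factor(v$gene[v$phenotype == "control"], levels = ranking$gene))
  e <- as.numeric(cg) / C - as.numeric(ug) / U
  per_gene <- data.frame(gene = ranking$gene,
                         mean_probability = ranking$mean_probability,
                         e_diff = e, stringsAsFactors = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(per_gene$mean_probability, breaks = breaks, include.lowest = TRUE)
  curve <- data.frame(
    bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_e_diff = as.numeric(tapply(per_gene$e_diff, bin, mean)[levels(bin)]),
    n_genes = as.integer(table(bin)[levels(bin)])
  )
  list(per_gene = per_gene, curve = curve,
       formula = "proxy: e_diff(g) = c_g/C - u_g/U (case variant share minus control variant share)")
}

#' Rank correlation between predicted probability and constraint scores
#'
#' Spearman correlation of the mean predicted probability with each gene
#' score, genes with a missing score excluded pairwise. The expected sign
#' convention is positive for pLI and phastCons (constraint/conservation up,
#' probability up) and negative for LOEUF and RVIS.
#'
#' @param ranking a `gene_ranking`.
#' @param scores a `gene_scores` table.
#' @return data.frame with one row per score: `score`, `rho`, `p_value`,
#'   `n`.
#' @export
correlate_with_constraint <- function(ranking, scores) {
  idx <- match(ranking$gene, scores$gene)
  rows <- lapply(GENE_SCORE_NAMES, function(nm) {
    vals <- scores[[nm]][idx]
    miss <- is.na(idx) | scores[[paste0(nm, "_missing")]][idx]
    miss[is.na(miss)] <- TRUE
    keep <- !miss
    if (sum(keep) < 3) return(NULL)
    v <- vals[keep]
    p <- ranking$mean_probability[keep]
    if (length(unique(v)) == 1) {
      stop(sprintf("%s is constant across ranked genes; correlation undefined", nm),
           call. = FALSE)
    }
    ct <- suppressWarnings(stats::cor.test(p, v, method = "spearman"))
    data.frame(score = nm, rho = unname(ct$estimate), p_value = ct$p.value,
               n = sum(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a gene ranking to TSV
#'
#' Columns: Gene, MeanProbability, CI_low, CI_high, Rank, E_diff (when
#' supplied), Extrapolated, plus optional user annotation columns joined by
#' gene symbol.
#'
#' @param ranking a `gene_ranking`.
#' @param path output path.
#' @param e_diff optional result of [enrichment_diff()].
#' @param annotations optional data.frame with a `gene` column to join.
#' @export
write_gene_ranking <- function(ranking, path, e_diff = NULL, annotations = NULL) {
  out <- data.frame(Gene = ranking$gene,
                    MeanProbability = ranking$mean_probability,
                    CI_low = ranking$ci_low, CI_high = ranking$ci_high,
                    Rank = ranking$rank,
                    Extrapolated = ranking$extrapolated,
                    stringsAsFactors = FALSE)
  if (!is.null(e_diff)) {
    out$E_diff <- e_diff$per_gene$e_diff[match(out$Gene, e_diff$per_gene$gene)]
  }
  if (!is.null(annotations)) {
    extra <- annotations[match(out$Gene, annotations$gene),
                         setdiff(names(annotations), "gene"), drop = FALSE]
    out <- cbind(out, extra)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
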