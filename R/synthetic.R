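# Synthetic case/control cohorts with planted risk genes.
#
# Emulates a de novo variant cohort: per-sample variant counts are Poisson
# with class-specific rates (cases carry LGD variants at roughly twice the
# control rate, defaults 0.21 vs 0.12 per sample), control variants land on
# genes uniformly, and the case excess is routed to a planted set of risk
# genes. Risk genes receive skewed constraint scores (high pLI, low LOEUF);
# RVIS and phastCons are noisy monotone transforms of LOEUF and pLI so the
# constraint metrics are realistically collinear. Missense pathogenicity
# scores are Beta-distributed, stochastically higher for case variants in
# risk genes.

#' Configuration for a synthetic cohort
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_genes total genes in the simulated genome. The default is
#'   genome-scale relative to the cohort so that, as in real de novo
#'   databases, most mutated genes are hit once and recurrence concentrates
#'   in the risk set; compressing the universe makes control variants pile
#'   onto risk genes at unrealistic density and destroys the low-FPR regime.
#' @param n_risk_genes number of planted risk genes (<= `n_genes`).
#' @param lgd_rate_case,lgd_rate_control expected LGD variants per sample
#'   (defaults 0.21 and 0.12, the observed case/control rates in simplex
#'   autism families).
#' @param missense_rate_case,missense_rate_control expected missense variants
#'   per sample (defaults 1.2 and 1.0: roughly one event per individual, as
#'   in large de novo databases, with a mild case excess).
#' @param risk_gene_share fraction of the case LGD/missense excess routed to
#'   risk genes.
#' @param pathogenicity_shift elevation of the mean pathogenicity score for
#'   case variants in risk genes (0 disables the shift entirely).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_cases = 1000, n_controls = 1000,
                          n_genes = 2000, n_risk_genes = 20,
                          lgd_rate_case = 0.21, lgd_rate_control = 0.12,
                          missense_rate_case = 1.2, missense_rate_control = 1.0,
                          risk_gene_share = 0.5, pathogenicity_shift = 0.2,
                          seed = 1) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes), n_risk_genes = as.integer(n_risk_genes),
              lgd_rate_case = lgd_rate_case, lgd_rate_control = lgd_rate_control,
              missense_rate_case = missense_rate_case,
              missense_rate_control = missense_rate_control,
              risk_gene_share = risk_gene_share,
              pathogenicity_shift = pathogenicity_shift,
              seed = as.integer(seed))
  rates <- c(cfg$lgd_rate_case, cfg$lgd_rate_control,
             cfg$missense_rate_case, cfg$missense_rate_control)
  if (any(rates < 0)) stop("variant rates must be >= 0", call. = FALSE)
  if (cfg$risk_gene_share < 0 || cfg$risk_gene_share > 1) {
    stop("risk_gene_share must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$pathogenicity_shift < 0 || cfg$pathogenicity_shift >= 0.5) {
    stop("pathogenicity_shift must lie in [0, 0.5)", call. = FALSE)
  }
  if (cfg$n_risk_genes > cfg$n_genes) {
    stop("n_risk_genes must not exceed n_genes", call. = FALSE)
  }
  if (cfg$n_cases < 1 || cfg$n_controls < 1 || cfg$n_genes < 1) {
    stop("cohort sizes and gene count must be positive", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Pathogenicity draw: Beta(2, 2) baseline; a shifted mean m = 0.5 + shift is
# realized as Beta(2m/(1-m), 2), which reduces to the baseline at shift 0.
rbeta_shifted <- function(n, shift) {
  m <- 0.5 + shift
  a <- 2 * m / (1 - m)
  stats::rbeta(n, a, 2)
}

#' Simulate a de novo variant cohort
#'
#' See the module header for the generative model. Case variants land on a
#' uniformly chosen risk gene with probability
#' `risk_gene_share * (rate_case - rate_control) / rate_case` (i.e. the case
#' excess is routed to risk genes), otherwise uniformly on all genes;
#' control variants are always uniform.
#'
#' @param config a `cohort_config`.
#' @return list with `variants` (a `variant_table`), `scores` (a
#'   `gene_scores` table), and `risk_genes` (the planted truth set).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    risk_genes <- if (cfg$n_risk_genes > 0) genes[seq_len(cfg$n_risk_genes)] else character(0)
    is_risk <- genes %in% risk_genes

    # constraint scores: risk genes intolerant, others tolerant
    pli <- ifelse(is_risk, stats::rbeta(cfg$n_genes, 5, 1), stats::rbeta(cfg$n_genes, 1, 5))
    loeuf <- 2 * ifelse(is_risk, stats::rbeta(cfg$n_genes, 1, 5), stats::rbeta(cfg$n_genes, 5, 1))
    rvis <- 2 * (loeuf - 1) + stats::rnorm(cfg$n_genes, 0, 0.3)
    phastcons <- pmin(1, pmax(0, 0.15 + 0.7 * pli + stats::rnorm(cfg$n_genes, 0, 0.08)))
    scores <- gene_score_table(data.frame(
      gene = genes, pli = pli, loeuf = loeuf, rvis = rvis, phastcons = phastcons,
      stringsAsFactors = FALSE))

    sample_ids <- c(sprintf("case_%05d", seq_len(cfg$n_cases)),
                    sprintf("ctrl_%05d", seq_len(cfg$n_controls)))
    phenos <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))

    draw_class <- function(vclass, rate_case, rate_control) {
      rates <- ifelse(phenos == "case", rate_case, rate_control)
      counts <- stats::rpois(length(rates), rates)
      tot <- sum(counts)
      if (tot == 0) return(NULL)
      sid <- rep(sample_ids, counts)
      ph <- rep(phenos, counts)
      # probability a case variant is an excess event routed to risk genes
      p_excess <- if (rate_case > 0) {
        cfg$risk_gene_share * max(0, rate_case - rate_control) / rate_case
      } else 0
      to_risk <- ph == "case" & length(risk_genes) > 0 & stats::runif(tot) < p_excess
      gene <- character(tot)
      if (any(to_risk)) gene[to_risk] <- sample(risk_genes, sum(to_risk), replace = TRUE)
      if (any(!to_risk)) gene[!to_risk] <- sample(genes, sum(!to_risk), replace = TRUE)
      path <- rep(NA_real_, tot)
      if (vclass == "missense") {
        in_risk_case <- ph == "case" & gene %in% risk_genes
        path[!in_risk_case] <- rbeta_shifted(sum(!in_risk_case), 0)
        if (any(in_risk_case)) {
          path[in_risk_case] <- rbeta_shifted(sum(in_risk_case), cfg$pathogenicity_shift)
        }
      }
      data.frame(sample_id = sid, phenotype = ph, gene = gene,
                 variant_class = vclass, pathogenicity = path,
                 stringsAsFactors = FALSE)
    }

    v_lgd <- draw_class("lgd", cfg$lgd_rate_case, cfg$lgd_rate_control)
    v_mis <- draw_class("missense", cfg$missense_rate_case, cfg$missense_rate_control)
    variants <- rbind(v_lgd, v_mis)
    if (is.null(variants)) {
      variants <- data.frame(sample_id = character(0), phenotype = character(0),
                             gene = character(0), variant_class = character(0),
                             pathogenicity = numeric(0), stringsAsFactors = FALSE)
    }
    variants <- variant_table(variants)
    list(variants = variants, scores = scores, risk_genes = risk_genes)
  })
}

#' Write a cohort to disk in the package's input dialects
#'
#' Emits `variants.tsv` (SampleID, Phenotype, Gene, Class, PrimateAI), one
#' two-column TSV per gene score (`pli.tsv`, `loeuf.tsv`, `rvis.tsv`,
#' `phastcons.tsv`), and `risk_genes.tsv` (Gene, IsRiskGene) when a truth
#' set is supplied. Numeric values are written at full precision, so
#' re-reading reproduces the generated cohort exactly.
#'
#' @param variants a `variant_table`.
#' @param scores a `gene_scores` table.
#' @param out_dir output directory (created if needed).
#' @param risk_genes optional character vector of planted risk genes.
#' @return named list of the written file paths.
#' @export
write_cohort <- function(variants, scores, out_dir, risk_genes = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  vpath <- file.path(out_dir, "variants.tsv")
  hdr <- "SampleID\tPhenotype\tGene\tClass\tPrimateAI"
  lines <- if (nrow(variants) > 0) {
    paste(variants$sample_id, variants$phenotype, variants$gene,
          variants$variant_class, format_full(variants$pathogenicity), sep = "\t")
  } else character(0)
  writeLines(c(hdr, lines), vpath)
  paths$variants <- vpath

  for (nm in GENE_SCORE_NAMES) {
    spath <- file.path(out_dir, paste0(nm, ".tsv"))
    keep <- !scores[[paste0(nm, "_missing")]]
    lines <- paste(scores$gene[keep], format_full(scores[[nm]][keep]), sep = "\t")
    writeLines(c("Gene\tScore", lines), spath)
    paths[[nm]] <- spath
  }

  if (!is.null(risk_genes)) {
    tpath <- file.path(out_dir, "risk_genes.tsv")
    all_genes <- scores$gene
    writeLines(c("Gene\tIsRiskGene",
                 paste(all_genes, as.integer(all_genes %in% risk_genes), sep = "\t")),
               tpath)
    paths$truth <- tpath
  }
  paths
}
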