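# Shared fixtures, built in code at test time.

# Write a variant TSV from a data.frame of records.
write_variant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  if (is.null(df$PrimateAI)) df$PrimateAI <- NA_real_
  header <- "SampleID\tPhenotype\tGene\tClass\tPrimateAI"
  lines <- paste(df$SampleID, df$Phenotype, df$Gene, df$Class,
                 ifelse(is.na(df$PrimateAI), "NA", format(df$PrimateAI)), sep = "\t")
  writeLines(c(header, lines), path)
  path
}

write_score_tsv <- function(scores, path = tempfile(fileext = ".tsv")) {
  writeLines(c("Gene\tScore", paste(names(scores), scores, sep = "\t")), path)
  path
}

# A small deterministic variant table used across modules.
toy_variants <- function() {
  variant_table(data.frame(
    sample_id = c("s1", "s1", "s2", "s3", "s3", "s4", "s5"),
    phenotype = c("case", "case", "case", "control", "control", "control", "case"),
    gene = c("A", "B", "A", "C", "A", "B", "C"),
    variant_class = c("lgd", "missense", "lgd", "lgd", "missense", "lgd", "missense"),
    pathogenicity = c(NA, 0.9, NA, NA, 0.4, NA, 0.7),
    stringsAsFactors = FALSE
  ))
}

toy_scores <- function() {
  gene_score_table(list(
    pli = c(A = 0.99, B = 0.50, C = 0.05),
    loeuf = c(A = 0.20, B = 0.80, C = 1.50),
    rvis = c(A = -1.5, B = 0.0, C = 1.2),
    phastcons = c(A = 0.95, B = 0.60, C = 0.20)
  ))
}

# A linearly separable cohort: every case has an LGD in gene RISK, every
# control an LGD in gene SAFE (plus shared background gene BG so the matrix
# has > 1 column of each kind).
separable_cohort <- function(n_case = 20, n_ctrl = 20) {
  ids_case <- sprintf("ca%02d", seq_len(n_case))
  ids_ctrl <- sprintf("co%02d", seq_len(n_ctrl))
  df <- data.frame(
    sample_id = c(ids_case, ids_ctrl, ids_case, ids_ctrl),
    phenotype = rep(c(rep("case", n_case), rep("control", n_ctrl)), 2),
    gene = c(rep("RISK", n_case), rep("SAFE", n_ctrl), rep("BG", n_case + n_ctrl)),
    variant_class = "lgd",
    stringsAsFactors = FALSE
  )
  variant_table(df)
}

separable_scores <- function() {
  gene_score_table(list(
    pli = c(RISK = 0.99, SAFE = 0.01, BG = 0.5),
    loeuf = c(RISK = 0.1, SAFE = 1.9, BG = 1.0),
    rvis = c(RISK = -2, SAFE = 2, BG = 0),
    phastcons = c(RISK = 0.9, SAFE = 0.1, BG = 0.5)
  ))
}

# Small planted-signal cohort for cross-module tests (fast to fit).
small_planted_cohort <- function(seed = 101) {
  simulate_cohort(cohort_config(
    n_cases = 400, n_controls = 400, n_genes = 500, n_risk_genes = 10,
    risk_gene_share = 0.9, seed = seed))
}
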