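# Variant / gene-score input and feature-matrix construction.
#
# Feature matrices are variant-class specific: one matrix for likely
# gene-disruptive (LGD) variation and one for missense variation. Rows are
# individuals carrying at least one de novo variant of that class, columns are
# the genes mutated anywhere in the cohort. LGD matrices use 0/1 gene
# indicators plus per-sample constraint/conservation score features; missense
# matrices store the maximum per-gene pathogenicity score and carry no gene
# score features.

GENE_SCORE_NAMES <- c("pli", "loeuf", "rvis", "phastcons")

# Least-constrained defaults used when a gene is absent from a score table:
# an unknown gene must not masquerade as a constrained one.
GENE_SCORE_IMPUTE <- c(pli = 0, loeuf = 2.0, rvis = 0, phastcons = 0)

#' Read a de novo variant table
#'
#' Reads a tab-separated variant table with columns `SampleID`,
#' `Phenotype` (`case`/`control`), `Gene`, `Class` (`lgd`/`missense`/`other`)
#' and optionally `PrimateAI` (missense pathogenicity in `[0, 1]`, `NA`
#' allowed). Records whose class is not in `classes` are dropped; file order
#' is preserved.
#'
#' @param path path to the TSV file.
#' @param classes character vector of variant classes to keep.
#' @return a `data.frame` of class `variant_table` with columns `sample_id`,
#'   `phenotype`, `gene`, `variant_class`, `pathogenicity`.
#' @export
read_variants <- function(path, classes = c("lgd", "missense")) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  required <- c("SampleID", "Phenotype", "Gene", "Class")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop(sprintf("variant table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"PrimateAI" %in% names(dt)) dt$PrimateAI <- NA_real_
  for (nm in required) dt[[nm]] <- as.character(dt[[nm]])
  v <- data.frame(
    sample_id     = dt$SampleID,
    phenotype     = tolower(dt$Phenotype),
    gene          = dt$Gene,
    variant_class = tolower(dt$Class),
    pathogenicity = as.numeric(dt$PrimateAI),
    stringsAsFactors = FALSE
  )
  validate_variants(v)
  v <- v[v$variant_class %in% classes, , drop = FALSE]
  rownames(v) <- NULL
  class(v) <- c("variant_table", "data.frame")
  v
}

#' Construct a variant table from in-memory data
#'
#' Validates and classes a data frame with the same columns [read_variants()]
#' produces. Used by the synthetic-cohort simulator and useful for tests.
#'
#' @param df data.frame with columns `sample_id`, `phenotype`, `gene`,
#'   `variant_class`, and optionally `pathogenicity`.
#' @return a `variant_table`.
#' @export
variant_table <- function(df) {
  if (is.null(df$pathogenicity)) df$pathogenicity <- NA_real_
  df <- df[, c("sample_id", "phenotype", "gene", "variant_class", "pathogenicity")]
  validate_variants(df)
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

validate_variants <- function(v) {
  if (nrow(v) == 0) return(invisible(v))
  bad_pheno <- which(!v$phenotype %in% c("case", "control"))
  if (length(bad_pheno) > 0) {
    stop(sprintf("invalid Phenotype at row %d: %s (expected case|control)",
                 bad_pheno[1], v$phenotype[bad_pheno[1]]), call. = FALSE)
  }
  bad_class <- which(!v$variant_class %in% c("lgd", "missense", "other"))
  if (length(bad_class) > 0) {
    stop(sprintf("invalid Class at row %d: %s (expected lgd|missense|other)",
                 bad_class[1], v$variant_class[bad_class[1]]), call. = FALSE)
  }
  if (any(is.na(v$gene) | !nzchar(v$gene))) {
    stop(sprintf("empty Gene symbol at row %d", which(is.na(v$gene) | !nzchar(v$gene))[1]),
         call. = FALSE)
  }
  bad_score <- which(!is.na(v$pathogenicity) & (v$pathogenicity < 0 | v$pathogenicity > 1))
  if (length(bad_score) > 0) {
    stop(sprintf("PrimateAI score outside [0, 1] at row %d: %g",
                 bad_score[1], v$pathogenicity[bad_score[1]]), call. = FALSE)
  }
  # pathogenicity is defined for missense variants only
  misplaced <- !is.na(v$pathogenicity) & v$variant_class != "missense"
  if (any(misplaced)) {
    warning(sprintf("dropping PrimateAI scores on %d non-missense record(s)", sum(misplaced)),
            call. = FALSE)
    v$pathogenicity[misplaced] <- NA_real_
  }
  invisible(v)
}

#' Read per-gene constraint and conservation scores
#'
#' Each input file is a two-column TSV `Gene<TAB>Score`. The tables are joined
#' on the gene symbol (bare string, case sensitive); a gene absent from a file
#' gets that score flagged missing. Pass paths for any subset of `pli`,
#' `loeuf`, `rvis`, `phastcons`.
#'
#' @param pli,loeuf,rvis,phastcons paths to the per-score TSV files (each
#'   optional, at least one required).
#' @return a `data.frame` of class `gene_scores` with one row per gene:
#'   columns `gene`, the four scores, and logical `<score>_missing` flags.
#' @export
read_gene_scores <- function(pli = NULL, loeuf = NULL, rvis = NULL, phastcons = NULL) {
  paths <- list(pli = pli, loeuf = loeuf, rvis = rvis, phastcons = phastcons)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0) stop("at least one score file is required", call. = FALSE)
  tabs <- lapply(names(paths), function(nm) {
    dt <- data.table::fread(paths[[nm]], sep = "\t", header = TRUE, data.table = FALSE,
                            colClasses = list(character = 1))
    if (ncol(dt) < 2) stop(sprintf("%s file must have columns Gene and Score", nm), call. = FALSE)
    val <- suppressWarnings(as.numeric(dt[[2]]))
    bad <- which(is.na(val) & !is.na(dt[[2]]) & nzchar(as.character(dt[[2]])))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric %s score for gene %s", nm, dt[[1]][bad[1]]), call. = FALSE)
    }
    stats::setNames(val, dt[[1]])
  })
  names(tabs) <- names(paths)
  gene_score_table(tabs)
}

#' Assemble a gene score table from named score vectors
#'
#' @param scores a named list with any of `pli`, `loeuf`, `rvis`, `phastcons`,
#'   each a named numeric vector keyed by gene symbol, or a data.frame with a
#'   `gene` column plus score columns.
#' @return a `gene_scores` data.frame (see [read_gene_scores()]).
#' @export
gene_score_table <- function(scores) {
  if (is.data.frame(scores)) {
    df <- scores
    tabs <- lapply(intersect(GENE_SCORE_NAMES, names(df)), function(nm) {
      keep <- !is.na(df[[nm]])
      stats::setNames(df[[nm]][keep], df$gene[keep])
    })
    names(tabs) <- intersect(GENE_SCORE_NAMES, names(df))
    scores <- tabs
  }
  unknown <- setdiff(names(scores), GENE_SCORE_NAMES)
  if (length(unknown) > 0) {
    stop(sprintf("unknown score name(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  genes <- sort(unique(unlist(lapply(scores, names), use.names = FALSE)))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in GENE_SCORE_NAMES) {
    if (nm %in% names(scores)) {
      vals <- scores[[nm]][genes]
      out[[nm]] <- unname(vals)
      out[[paste0(nm, "_missing")]] <- is.na(vals)
    } else {
      out[[nm]] <- NA_real_
      out[[paste0(nm, "_missing")]] <- TRUE
    }
  }
  if (any(!out$pli_missing & (out$pli < 0 | out$pli > 1))) {
    stop("pLI values must lie in [0, 1]", call. = FALSE)
  }
  if (any(!out$phastcons_missing & (out$phastcons < 0 | out$phastcons > 1))) {
    stop("phastCons values must lie in [0, 1]", call. = FALSE)
  }
  rownames(out) <- out$gene
  class(out) <- c("gene_scores", "data.frame")
  out
}

# Look up scores for `genes`, imputing least-constrained defaults for genes
# absent from the table or with a missing score.
lookup_gene_scores <- function(scores, genes, quiet = FALSE) {
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(GENE_SCORE_NAMES),
                dimnames = list(genes, GENE_SCORE_NAMES))
  idx <- match(genes, scores$gene)
  n_imputed <- 0L
  for (nm in GENE_SCORE_NAMES) {
    vals <- scores[[nm]][idx]
    miss <- is.na(idx) | scores[[paste0(nm, "_missing")]][idx]
    miss[is.na(miss)] <- TRUE
    n_imputed <- n_imputed + sum(miss)
    vals[miss] <- GENE_SCORE_IMPUTE[[nm]]
    out[, nm] <- vals
  }
  if (n_imputed > 0 && !quiet) {
    message(sprintf("imputed %d missing gene-score value(s) with least-constrained defaults",
                    n_imputed))
  }
  out
}

#' Build a variant-class-specific feature matrix
#'
#' Rows are samples with at least one variant of `variant_class`; columns are
#' the genes mutated in this class anywhere in the cohort (sorted), optionally
#' followed by gene score features. In `full` mode, LGD matrices use 0/1 gene
#' indicators plus four per-sample score features aggregated over the sample's
#' mutated genes (max pLI, min LOEUF, min RVIS, max phastCons — the most
#' deleterious value of each); missense matrices store the maximum
#' pathogenicity score among the sample's missense variants in each gene and
#' append no score features. In `trivial` mode both classes reduce to plain
#' 0/1 indicators (the one-hot ablation).
#'
#' @param variants a `variant_table`.
#' @param scores a `gene_scores` table (may be `NULL` for missense or trivial
#'   mode).
#' @param variant_class `"lgd"` or `"missense"`.
#' @param mode `"full"` or `"trivial"`.
#' @param allow_empty_rows keep samples listed in `sample_universe` even when
#'   they have no variant of this class (used by the deleterious-missense
#'   training mode that retains all samples).
#' @param sample_universe optional character vector fixing the row universe.
#' @return a `feature_matrix` object: list with elements `x` (numeric matrix),
#'   `labels` (0/1 integer vector), `sample_ids`, `gene_columns`,
#'   `score_columns`, `variant_class`, `mode`.
#' @export
build_feature_matrix <- function(variants, scores = NULL,
                                 variant_class = c("lgd", "missense"),
                                 mode = c("full", "trivial"),
                                 allow_empty_rows = FALSE,
                                 sample_universe = NULL) {
  variant_class <- match.arg(variant_class)
  mode <- match.arg(mode)
  v <- variants[variants$variant_class == variant_class, , drop = FALSE]
  if (nrow(v) == 0 && !allow_empty_rows) {
    stop(sprintf("no %s variants to build a feature matrix from", variant_class), call. = FALSE)
  }
  if (variant_class == "missense" && mode == "full" && nrow(v) > 0) {
    if (all(is.na(v$pathogenicity))) {
      stop(paste("all missense pathogenicity scores are absent;",
                 "supply PrimateAI scores or set a default fill policy",
                 "(records with some scores present are filled with 0.5)"), call. = FALSE)
    }
    n_fill <- sum(is.na(v$pathogenicity))
    if (n_fill > 0) {
      warning(sprintf("filled %d missing missense pathogenicity score(s) with 0.5", n_fill),
              call. = FALSE)
      v$pathogenicity[is.na(v$pathogenicity)] <- 0.5
    }
  }

  if (is.null(sample_universe)) {
    sample_ids <- unique(v$sample_id)  # first-appearance order
  } else {
    sample_ids <- sample_universe
    if (!allow_empty_rows) sample_ids <- sample_ids[sample_ids %in% v$sample_id]
    v <- v[v$sample_id %in% sample_ids, , drop = FALSE]
  }
  genes <- sort(unique(v$gene))
  n <- length(sample_ids)
  p <- length(genes)
  x <- matrix(0, nrow = n, ncol = p, dimnames = list(sample_ids, genes))

  ri <- match(v$sample_id, sample_ids)
  ci <- match(v$gene, genes)
  if (variant_class == "missense" && mode == "full") {
    for (k in seq_len(nrow(v))) {
      x[ri[k], ci[k]] <- max(x[ri[k], ci[k]], v$pathogenicity[k])
    }
  } else {
    x[cbind(ri, ci)] <- 1
  }

  score_columns <- character(0)
  if (variant_class == "lgd" && mode == "full") {
    if (is.null(scores)) stop("gene scores are required for LGD full mode", call. = FALSE)
    gs <- lookup_gene_scores(scores, genes, quiet = TRUE)
    sc <- matrix(NA_real_, nrow = n, ncol = 4,
                 dimnames = list(sample_ids, GENE_SCORE_NAMES))
    for (i in seq_len(n)) {
      gi <- unique(ci[ri == i])
      if (length(gi) == 0) {
        # empty row (allow_empty_rows): least-constrained defaults
        sc[i, ] <- GENE_SCORE_IMPUTE[GENE_SCORE_NAMES]
      } else {
        sc[i, "pli"]       <- max(gs[gi, "pli"])
        sc[i, "loeuf"]     <- min(gs[gi, "loeuf"])
        sc[i, "rvis"]      <- min(gs[gi, "rvis"])
        sc[i, "phastcons"] <- max(gs[gi, "phastcons"])
      }
    }
    x <- cbind(x, sc)
    score_columns <- GENE_SCORE_NAMES
  }

  # one consistent phenotype label per sample
  ph <- v$phenotype[match(sample_ids, v$sample_id)]
  conflicting <- tapply(v$phenotype, v$sample_id, function(z) length(unique(z)) > 1)
  if (any(conflicting, na.rm = TRUE)) {
    stop(sprintf("conflicting phenotype labels for sample %s",
                 names(conflicting)[which(conflicting)[1]]), call. = FALSE)
  }
  labels <- as.integer(ph == "case")
  labels[is.na(labels)] <- 0L  # empty rows in allow_empty_rows mode: resolved below
  if (allow_empty_rows && !is.null(sample_universe)) {
    # labels for variant-free samples must come from the full variant table
    missing_lab <- !sample_ids %in% v$sample_id
    if (any(missing_lab)) {
      ph_all <- variants$phenotype[match(sample_ids[missing_lab], variants$sample_id)]
      labels[missing_lab] <- as.integer(ph_all == "case")
    }
  }

  structure(list(
    x = x,
    labels = labels,
    sample_ids = sample_ids,
    gene_columns = genes,
    score_columns = score_columns,
    variant_class = variant_class,
    mode = mode
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%d gene, %d score), class=%s, mode=%s\n",
              nrow(x$x), ncol(x$x), length(x$gene_columns), length(x$score_columns),
              x$variant_class, x$mode))
  cat(sprintf("  cases: %d, controls: %d\n", sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Subset a feature matrix by sample ID
#'
#' @param fm a `feature_matrix`.
#' @param ids sample IDs to keep (order preserved).
#' @return a `feature_matrix` restricted to `ids`.
#' @export
subset_feature_matrix <- function(fm, ids) {
  keep <- match(ids, fm$sample_ids)
  keep <- keep[!is.na(keep)]
  out <- fm
  out$x <- fm$x[keep, , drop = FALSE]
  out$labels <- fm$labels[keep]
  out$sample_ids <- fm$sample_ids[keep]
  out
}

#' Write a feature matrix to TSV
#'
#' Header row is the gene columns followed by score columns; one sample per
#' row (first column `SampleID`), final column `Label`. Values are written at
#' full precision so a read round trip is bit-exact.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  hdr <- c("SampleID", colnames(fm$x), "Label")
  lines <- vapply(seq_len(nrow(fm$x)), function(i) {
    paste(c(fm$sample_ids[i], format_full(fm$x[i, ]), fm$labels[i]), collapse = "\t")
  }, character(1))
  writeLines(c(paste(hdr, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path input path.
#' @param variant_class,mode metadata to attach (not stored in the TSV).
#' @param score_columns names of trailing non-gene columns.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path, variant_class = "lgd", mode = "full",
                                score_columns = intersect(GENE_SCORE_NAMES, names(utils::read.delim(path, nrows = 0, check.names = FALSE)))) {
  dt <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_ids <- as.character(dt$SampleID)
  labels <- as.integer(dt$Label)
  feat <- as.matrix(dt[, setdiff(names(dt), c("SampleID", "Label")), drop = FALSE])
  rownames(feat) <- sample_ids
  genes <- setdiff(colnames(feat), score_columns)
  structure(list(
    x = feat, labels = labels, sample_ids = sample_ids,
    gene_columns = genes, score_columns = score_columns,
    variant_class = variant_class, mode = mode
  ), class = "feature_matrix")
}

#' Read a heuristic gene list
#'
#' One gene symbol per line; `#` starts a comment; blank lines ignored.
#'
#' @param path input path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Align a feature matrix (or plain matrix) to a model's feature schema
#'
#' Columns are matched by name; schema columns absent from the data are
#' zero-filled, extra data columns are dropped.
#'
#' @param x numeric matrix with column names, or a `feature_matrix`.
#' @param schema character vector of expected column names, in order.
#' @return numeric matrix with columns exactly `schema`.
#' @export
align_features <- function(x, schema) {
  if (inherits(x, "feature_matrix")) x <- x$x
  if (is.null(colnames(x))) stop("feature data must have column names", call. = FALSE)
  shared <- intersect(colnames(x), schema)
  if (length(shared) == 0) {
    stop("no feature columns shared with the model schema; cannot align", call. = FALSE)
  }
  out <- matrix(0, nrow = nrow(x), ncol = length(schema),
                dimnames = list(rownames(x), schema))
  out[, shared] <- x[, shared, drop = FALSE]
  n_missing <- length(setdiff(schema, colnames(x)))
  n_extra <- length(setdiff(colnames(x), schema))
  if (n_extra > 0) {
    message(sprintf("%d feature column(s) not in the model schema were dropped", n_extra))
  }
  out
}
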