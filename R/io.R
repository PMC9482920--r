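variant_columns <- c("patient_id", "arm", "timepoint", "gene", "variant_id",
                     "effect_class", "maf_percent")

#' Read and validate a long-format variant table
#'
#' TSV with header columns `patient_id`, `arm`, `timepoint`, `gene`,
#' `variant_id`, `effect_class`, `maf_percent`. Vocabulary (timepoints
#' PRE/OTH/EOT, the four effect classes, arms A/B), the MAF range \[0, 100\]
#' and (patient, timepoint, variant) uniqueness are enforced; violations
#' error with the offending line number rather than being coerced.
#'
#' @param path TSV file path.
#' @return validated data.frame of variant observations.
#' @export
read_variant_table <- function(path) {
  x <- read_table_tsv(path)
  miss <- setdiff(variant_columns, names(x))
  if (length(miss))
    stop_input("missing column(s): ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(x)) + 1L  # header is line 1
  bad_vocab <- function(col, allowed) {
    bad <- !x[[col]] %in% allowed
    if (any(bad))
      stop_input("invalid ", col, " '", x[[col]][bad][1], "' at line ",
                 line[bad][1])
  }
  bad_vocab("timepoint", timepoint_levels)
  bad_vocab("effect_class", effect_class_levels)
  bad_vocab("arm", c("A", "B"))
  maf <- suppressWarnings(as.numeric(x$maf_percent))
  bad <- is.na(maf) | maf < 0 | maf > 100
  if (any(bad))
    stop_input("maf_percent out of [0, 100] at line ", line[bad][1])
  x$maf_percent <- maf
  dup <- duplicated(x[c("patient_id", "timepoint", "variant_id")])
  if (any(dup))
    stop_input("duplicate (patient, timepoint, variant) at line ",
               line[dup][1])
  x[variant_columns]
}

#' @rdname read_variant_table
#' @param x variant table to write.
#' @export
write_variant_table <- function(x, path) {
  write_table_tsv(x[variant_columns], path)
}

#' Read an expression matrix with sample annotations
#'
#' The matrix is either a genes x samples TSV whose first column is the gene
#' id, or a MatrixMarket file (`.mtx`) with plain-text row/column name
#' sidecars at `<path>.rows` / `<path>.cols`. Sample sets of matrix and
#' annotation table are reconciled by intersection; dropped samples are
#' reported in `attr(x, "dropped_samples")`. Duplicate gene ids and an empty
#' intersection are errors.
#'
#' @param path_matrix matrix file path (`.mtx` triggers MatrixMarket
#'   parsing).
#' @param path_annotations annotation TSV keyed by `sample_id` with columns
#'   `arid1a_status`, `erasbraf_status`, `msi_status`, `arm`.
#' @return list with `counts` (base matrix) and `annotations` (rows aligned
#'   to matrix columns).
#' @export
read_expression <- function(path_matrix, path_annotations) {
  if (grepl("\\.mtx$", path_matrix)) {
    m <- as.matrix(Matrix::readMM(path_matrix))
    rownames(m) <- readLines(paste0(path_matrix, ".rows"))
    colnames(m) <- readLines(paste0(path_matrix, ".cols"))
  } else {
    x <- read_table_tsv(path_matrix)
    genes <- x[[1]]
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- genes
  }
  if (anyDuplicated(rownames(m)))
    stop_input("duplicate gene id: ",
               rownames(m)[duplicated(rownames(m))][1])
  ann <- read_table_tsv(path_annotations)
  need <- c("sample_id", "arid1a_status", "erasbraf_status", "msi_status",
            "arm")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_input("annotations missing column(s): ",
               paste(miss, collapse = ", "))
  common <- intersect(colnames(m), ann$sample_id)
  if (length(common) == 0L)
    stop_input("no samples shared between matrix and annotations")
  dropped <- union(setdiff(colnames(m), common),
                   setdiff(ann$sample_id, common))
  m <- m[, common, drop = FALSE]
  ann <- ann[match(common, ann$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  out <- list(counts = m, annotations = ann)
  attr(out, "dropped_samples") <- dropped
  out
}

#' @rdname read_expression
#' @param counts genes x samples matrix to write.
#' @param path output path (TSV writer).
#' @export
write_expression_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_tsv(df, path)
}

#' @rdname read_expression
#' @export
write_expression_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".rows"))
  writeLines(colnames(counts), paste0(path, ".cols"))
  invisible(path)
}

#' Serialize a fitted signature to JSON and back
#'
#' Stores the directional gene sets, z-normalization statistics, PC1
#' loadings, orientation sign and scoring mode — everything needed to score a
#' new cohort, but not the fitting-cohort data.
#'
#' @param model an [fit_signature()] object.
#' @param path JSON file path.
#' @export
write_signature <- function(model, path) {
  if (!inherits(model, "expr_signature"))
    stop_input("model must be an expr_signature")
  payload <- list(
    up_genes = model$up_genes, down_genes = model$down_genes,
    gene_means = as.list(model$gene_means),
    gene_sds = as.list(model$gene_sds),
    loadings = as.list(model$loadings),
    orientation_sign = model$orientation_sign,
    mode = model$mode, fdr_cutoff = model$fdr_cutoff)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    up_genes = as.character(p$up_genes %||% character(0)),
    down_genes = as.character(p$down_genes %||% character(0)),
    gene_means = unlist(p$gene_means), gene_sds = unlist(p$gene_sds),
    loadings = unlist(p$loadings),
    orientation_sign = p$orientation_sign, mode = p$mode,
    fdr_cutoff = p$fdr_cutoff),
    class = "expr_signature")
}

#' Adapt standard MAF-style variant calls to the variant-table schema
#'
#' Maps the common mutation-annotation-format columns (`Hugo_Symbol`,
#' `t_alt_count`, `t_depth`) to the package's long variant table; the MAF
#' percentage is `100 * t_alt_count / t_depth`.
#'
#' @param maf data.frame with columns `Hugo_Symbol`, `t_alt_count`,
#'   `t_depth`, plus `patient_id`, `arm`, `timepoint`, and optionally
#'   `variant_id` (default `Hugo_Symbol` + row index) and `effect_class`
#'   (default `nonsyn_snv`).
#' @return data.frame in the [read_variant_table()] schema.
#' @export
maf_to_variant_table <- function(maf) {
  need <- c("Hugo_Symbol", "t_alt_count", "t_depth", "patient_id", "arm",
            "timepoint")
  miss <- setdiff(need, names(maf))
  if (length(miss))
    stop_input("MAF input missing column(s): ", paste(miss, collapse = ", "))
  if (any(maf$t_depth <= 0)) stop_input("t_depth must be positive")
  data.frame(
    patient_id = maf$patient_id,
    arm = maf$arm,
    timepoint = maf$timepoint,
    gene = maf$Hugo_Symbol,
    variant_id = maf$variant_id %||%
      paste0(maf$Hugo_Symbol, "_m", seq_len(nrow(maf))),
    effect_class = maf$effect_class %||% "nonsyn_snv",
    maf_percent = 100 * maf$t_alt_count / maf$t_depth,
    stringsAsFactors = FALSE)
}
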