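#' Log2 counts-per-million normalization
#'
#' `log2((count + 0.5) / library_size * 1e6)`. With library sizes equal to
#' column sums, the pre-log CPM columns sum to exactly one million; the
#' pseudo-count of 0.5 keeps zeros finite.
#'
#' @param counts non-negative genes x samples count matrix.
#' @param lib_sizes per-sample library sizes (default: column sums).
#' @return log2-CPM matrix with the same dimnames.
#' @export
normalize_counts <- function(counts, lib_sizes = colSums(counts)) {
  if (!is.matrix(counts) || any(counts < 0))
    stop_input("counts must be a non-negative matrix")
  if (length(lib_sizes) != ncol(counts))
    stop_input("lib_sizes length must equal ncol(counts)")
  if (any(lib_sizes <= 0))
    stop_input("zero or negative library size")
  log2(sweep(counts + 0.5, 2, lib_sizes, "/") * 1e6)
}

## Design matrix for the confounder-aware model. reference level = WT.
de_design <- function(annotations, include_msi, include_covariates) {
  a <- as.integer(annotations$arid1a_status == "mutant")
  if (!include_covariates)
    return(cbind("(Intercept)" = 1, arid1a = a))
  e <- as.integer(annotations$erasbraf_status == "mutant")
  d <- cbind("(Intercept)" = 1, arid1a = a, erasbraf = e)
  if (include_msi)
    d <- cbind(d, msi = as.integer(annotations$msi_status == "MSI"))
  cbind(d, "arid1a:erasbraf" = a * e)
}

#' Confounder-aware differential expression for signature derivation
#'
#' Fits, per gene, a linear model of log expression on mutation status with
#' the confounding driver label and its interaction as covariates
#' (`~ ARID1A + eRAS/BRAF [+ MSI] + ARID1A:eRAS/BRAF`, treatment coding with
#' wild type as reference). The reported effect and test are for the ARID1A
#' main-effect coefficient, i.e. the mutant-vs-WT shift within the
#' eRAS/BRAF-WT stratum — shifts occurring only through eRAS/BRAF load on the
#' covariate and interaction terms instead of leaking into the signature.
#' Fitting and (optional, default on) empirical-Bayes variance moderation are
#' delegated to \pkg{limma}.
#'
#' @param log_expr genes x samples log-expression matrix (e.g. from
#'   [normalize_counts()]).
#' @param annotations data.frame with `arid1a_status`, `erasbraf_status` (and
#'   `msi_status` when `include_msi`), values `"mutant"`/`"WT"` (MSI:
#'   `"MSI"`/`"MSS"`), rows aligned to columns of `log_expr`.
#' @param include_msi include MSI status as a covariate.
#' @param include_covariates set `FALSE` for the naive one-covariate model
#'   (`~ ARID1A` only); used to demonstrate confounder leakage.
#' @param moderate apply empirical-Bayes variance moderation (moderated t);
#'   `FALSE` gives the classical per-gene OLS t-test.
#' @param coef_mode `"main"` tests the ARID1A main effect; `"joint"` tests
#'   main effect and interaction jointly (moderated F; requires `moderate`).
#' @return data.frame, one row per gene: `gene`, `log2_effect`, `t_stat`,
#'   `p_value`, `fdr`, `direction` (`up`/`down`). Zero-variance genes get NA
#'   statistics and are excluded from the FDR ranking.
#' @export
fit_de_model <- function(log_expr, annotations, include_msi = TRUE,
                         include_covariates = TRUE, moderate = TRUE,
                         coef_mode = c("main", "joint")) {
  coef_mode <- match.arg(coef_mode)
  if (!is.matrix(log_expr))
    stop_input("log_expr must be a matrix")
  if (nrow(annotations) != ncol(log_expr))
    stop_input("annotations rows must match log_expr columns")
  need <- c("arid1a_status", "erasbraf_status",
            if (include_msi && include_covariates) "msi_status")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop_input("annotations missing column(s): ", paste(miss, collapse = ", "))
  design <- de_design(annotations, include_msi, include_covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop_input("confounded design, collinear column(s): ",
               paste(bad, collapse = ", "))
  }

  gene_var <- apply(log_expr, 1, stats::var)
  usable <- gene_var > 1e-12
  fit <- limma::lmFit(log_expr[usable, , drop = FALSE], design)
  coef_name <- "arid1a"
  effect <- fit$coefficients[, coef_name]

  if (moderate) {
    eb <- limma::eBayes(fit)
    if (coef_mode == "joint") {
      joint <- c("arid1a", "arid1a:erasbraf")
      if (!all(joint %in% colnames(design)))
        stop_input("joint test requires the interaction model")
      tt <- limma::topTable(eb, coef = joint, number = Inf, sort.by = "none")
      tstat <- tt$F
      pval <- tt$P.Value
    } else {
      tstat <- eb$t[, coef_name]
      pval <- eb$p.value[, coef_name]
    }
  } else {
    if (coef_mode == "joint")
      stop_input("coef_mode = 'joint' requires moderate = TRUE")
    se <- fit$stdev.unscaled[, coef_name] * fit$sigma
    tstat <- effect / se
    pval <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  }

  out <- data.frame(
    gene = rownames(log_expr),
    log2_effect = NA_real_, t_stat = NA_real_, p_value = NA_real_,
    fdr = NA_real_, direction = NA_character_,
    stringsAsFactors = FALSE)
  out$log2_effect[usable] <- effect
  out$t_stat[usable] <- tstat
  out$p_value[usable] <- pval
  out$fdr[usable] <- bh_adjust(pval)
  out$direction[usable] <- ifelse(effect > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "zero_variance") <- rownames(log_expr)[!usable]
  attr(out, "design") <- colnames(design)
  out
}

#' Select signature genes at an FDR cutoff
#'
#' Splits genes passing the FDR cutoff by effect sign into the up- and
#' down-regulated signature sets, each ordered by FDR then gene label.
#'
#' @param de output of [fit_de_model()].
#' @param fdr_cutoff FDR threshold (default 0.05; genes with `fdr <
#'   fdr_cutoff` are selected).
#' @return list with `up_genes` and `down_genes` character vectors.
#' @export
select_signature_genes <- function(de, fdr_cutoff = 0.05) {
  check_number(fdr_cutoff, "fdr_cutoff", 0, 1)
  hit <- !is.na(de$fdr) & de$fdr < fdr_cutoff
  pick <- function(dir) {
    rows <- de[hit & de$direction == dir, , drop = FALSE]
    rows$gene[order(rows$fdr, rows$gene)]
  }
  out <- list(up_genes = pick("up"), down_genes = pick("down"))
  if (length(out$up_genes) + length(out$down_genes) == 0L)
    warning("no genes pass the FDR cutoff; empty signature")
  out
}
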