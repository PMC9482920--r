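#' Derive a mutant-like transcriptional signature
#'
#' End-to-end signature derivation on a fitting cohort: confounder-aware
#' differential expression ([fit_de_model()]), FDR gene selection
#' ([select_signature_genes()]), and construction of the scoring model — the
#' per-gene z-normalization statistics, the first-principal-component
#' loadings of the z-scored signature-gene matrix, and a deterministic
#' orientation sign chosen so that higher scores mean "more mutant-like"
#' (the score correlates positively with mean z of up-genes minus mean z of
#' down-genes; this subsumes the usual "reverse the PC sign" convention and
#' removes eigenvector sign ambiguity).
#'
#' @param log_expr genes x samples log-expression matrix of the fitting
#'   cohort.
#' @param annotations sample annotations aligned to `log_expr` columns (see
#'   [fit_de_model()]).
#' @param fdr_cutoff FDR threshold for signature membership.
#' @param include_msi,moderate passed to [fit_de_model()].
#' @param mode default scoring mode for new cohorts: `"refit_per_cohort"`
#'   (re-estimate z statistics and PC1 on the scoring cohort, the default) or
#'   `"frozen_projection"` (project onto the stored loadings).
#' @return object of class `expr_signature` with components `de`, `up_genes`,
#'   `down_genes`, `gene_means`, `gene_sds`, `loadings`, `orientation_sign`,
#'   `mode`, and `scores` (fitting-cohort scores from [score_samples()]).
#' @seealso [score_samples()], [stratify_quartiles()],
#'   [quartile_mutant_enrichment()]
#' @export
fit_signature <- function(log_expr, annotations, fdr_cutoff = 0.05,
                          include_msi = TRUE, moderate = TRUE,
                          mode = c("refit_per_cohort", "frozen_projection")) {
  mode <- match.arg(mode)
  de <- fit_de_model(log_expr, annotations, include_msi = include_msi,
                     moderate = moderate)
  sets <- select_signature_genes(de, fdr_cutoff)
  genes <- c(sets$up_genes, sets$down_genes)
  if (length(genes) < 2L)
    stop_input("signature has fewer than 2 genes; nothing to score")
  sub <- log_expr[genes, , drop = FALSE]
  gene_means <- rowMeans(sub)
  gene_sds <- apply(sub, 1, stats::sd)
  z <- t((sub - gene_means) / gene_sds)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  loadings <- pc$rotation[, 1]
  loadings <- loadings / sqrt(sum(loadings^2))

  object <- structure(list(
    de = de, up_genes = sets$up_genes, down_genes = sets$down_genes,
    gene_means = gene_means, gene_sds = gene_sds, loadings = loadings,
    orientation_sign = 1, mode = mode, fdr_cutoff = fdr_cutoff),
    class = "expr_signature")
  ## orientation determined on the fitting cohort and stored
  raw <- drop(z %*% loadings)
  object$orientation_sign <- orientation_sign(raw, z, sets$up_genes,
                                              sets$down_genes,
                                              annotations$arid1a_status)
  object$scores <- score_samples(log_expr, object, mode = "refit_per_cohort",
                                 labels = annotations$arid1a_status)
  object$fit_labels <- annotations$arid1a_status
  object
}

## Sign making the score agree with the up-minus-down mean-z contrast; falls
## back to the mutant-group-mean rule on an exactly null correlation.
orientation_sign <- function(raw, z, up_genes, down_genes, labels = NULL) {
  up <- intersect(up_genes, colnames(z))
  down <- intersect(down_genes, colnames(z))
  contrast <- rep(0, nrow(z))
  if (length(up)) contrast <- contrast + rowMeans(z[, up, drop = FALSE])
  if (length(down)) contrast <- contrast - rowMeans(z[, down, drop = FALSE])
  r <- suppressWarnings(stats::cor(raw, contrast))
  if (!is.na(r) && r != 0) return(sign(r))
  if (!is.null(labels)) {
    d <- mean(raw[labels == "mutant"]) - mean(raw[labels != "mutant"])
    if (!is.na(d) && d != 0) return(sign(d))
  }
  stop_input("orientation undefined: score uncorrelated with signature ",
             "contrast and no usable mutation labels")
}

#' Score samples with a fitted signature
#'
#' Signature genes present in the expression matrix with nonzero variance are
#' z-scored and combined into the oriented first-principal-component score.
#' In `refit_per_cohort` mode the z statistics and PC1 are re-estimated on
#' the scoring cohort (the orientation rule is re-applied, so the sign stays
#' deterministic); in `frozen_projection` mode the fitting cohort's z
#' statistics, loadings and sign are reused.
#'
#' @param log_expr genes x samples log-expression matrix to score.
#' @param model an [fit_signature()] object.
#' @param mode override of the model's scoring mode.
#' @param labels optional mutation-status labels (used only by the
#'   orientation fallback when the primary rule is exactly null).
#' @param min_genes minimum usable signature genes (default 2; set to 1 to
#'   allow degenerate single-gene scoring).
#' @return data.frame with `sample_id` and `score`; the number of dropped
#'   genes is in `attr(x, "dropped_genes")`.
#' @export
score_samples <- function(log_expr, model, mode = NULL, labels = NULL,
                          min_genes = 2L) {
  if (!inherits(model, "expr_signature"))
    stop_input("model must be an expr_signature")
  mode <- mode %||% model$mode
  mode <- match.arg(mode, c("refit_per_cohort", "frozen_projection"))
  if (ncol(log_expr) < 3L)
    stop_input("need at least 3 samples to score")
  genes <- c(model$up_genes, model$down_genes)
  present <- intersect(genes, rownames(log_expr))
  sub <- log_expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  usable <- present[sds > 1e-12]
  dropped <- length(genes) - length(usable)
  if (dropped > 0)
    message(dropped, " signature gene(s) missing or zero-variance; dropped")
  if (length(usable) < min_genes)
    stop_input("fewer than ", min_genes, " usable signature genes")
  sub <- log_expr[usable, , drop = FALSE]

  if (mode == "refit_per_cohort") {
    z <- t((sub - rowMeans(sub)) / apply(sub, 1, stats::sd))
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    loadings <- pc$rotation[, 1]
    loadings <- loadings / sqrt(sum(loadings^2))
    raw <- drop(z %*% loadings)
    s <- orientation_sign(raw, z, model$up_genes, model$down_genes, labels)
    score <- s * raw
  } else {
    mu <- model$gene_means[usable]
    sd_ <- model$gene_sds[usable]
    z <- t((sub - mu) / sd_)
    score <- model$orientation_sign * drop(z %*% model$loadings[usable])
  }
  out <- data.frame(
    sample_id = colnames(log_expr) %||% as.character(seq_len(ncol(log_expr))),
    score = unname(score),
    stringsAsFactors = FALSE)
  attr(out, "dropped_genes") <- dropped
  attr(out, "mode") <- mode
  out
}

#' Quartile stratification of signature scores
#'
#' Cutoffs at the empirical 25th/50th/75th percentiles (linear-interpolation
#' quantile definition); a sample is assigned quartile `Q1`-`Q4` by strict
#' comparison, so ties exactly at the 75th percentile fall in Q3 and the
#' mutant-like group is `score > Q3 cutoff`.
#'
#' @param scores numeric vector of scores, or a data.frame with a `score`
#'   column (as returned by [score_samples()]).
#' @return data.frame with `score`, `quartile` (`Q1`..`Q4`) and `group`
#'   (`mutant_like` for Q4, else `wt_like`); `attr(x, "cutoffs")` holds the
#'   three cutpoints.
#' @export
stratify_quartiles <- function(scores) {
  df <- if (is.data.frame(scores)) scores else
    data.frame(score = as.numeric(scores))
  s <- df$score
  if (length(s) < 4L) stop_input("need at least 4 samples to stratify")
  if (max(s) == min(s)) stop_input("all scores identical; cannot stratify")
  q <- stats::quantile(s, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  idx <- 1L + (s > q[1]) + (s > q[2]) + (s > q[3])
  df$quartile <- paste0("Q", idx)
  df$group <- ifelse(idx == 4L, "mutant_like", "wt_like")
  attr(df, "cutoffs") <- stats::setNames(q, c("Q1", "Q2", "Q3"))
  df
}

#' Mutant enrichment by score quartile
#'
#' The fraction of mutation-positive samples in each score quartile, plus a
#' two-sided Wilcoxon rank-sum test of score by mutation status.
#'
#' @param stratified output of [stratify_quartiles()] (needs `score` and
#'   `quartile`).
#' @param labels per-sample mutation labels (`"mutant"` vs anything else).
#' @return list: `quartile_fractions` (named Q1..Q4 mutant fractions),
#'   `wilcoxon` (statistic and p-value from [rank_sum_compare()]).
#' @export
quartile_mutant_enrichment <- function(stratified, labels) {
  if (length(labels) != nrow(stratified))
    stop_input("labels must match scored samples")
  mut <- labels == "mutant"
  frac <- vapply(paste0("Q", 1:4), function(q) {
    inq <- stratified$quartile == q
    if (!any(inq)) NA_real_ else mean(mut[inq])
  }, numeric(1))
  if (!any(mut) || all(mut)) {
    warning("one mutation group is empty; rank-sum p is NA")
    w <- list(statistic = NA_real_, p_value = NA_real_)
  } else {
    w <- rank_sum_compare(stratified$score, ifelse(mut, "mutant", "WT"))
  }
  list(quartile_fractions = frac, wilcoxon = w)
}

#' One-way ANOVA of scores across groups with BH-adjusted pairwise tests
#'
#' @param scores numeric vector.
#' @param groups group labels (>= 2 groups with >= 2 samples each for the
#'   omnibus test; pairwise comparisons involving singleton groups are NA).
#' @return list: `f_value`, `df` (between-group degrees of freedom), `p_value`,
#'   and `pairwise` (data.frame of pooled-variance two-sample t-tests with
#'   BH-adjusted p).
#' @export
group_anova <- function(scores, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop_input("need at least 2 groups")
  fit <- stats::aov(scores ~ factor(groups))
  an <- summary(fit)[[1]]
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_value = apply(pairs, 2, function(pr) {
      x <- scores[groups == pr[1]]
      y <- scores[groups == pr[2]]
      if (length(x) < 2L || length(y) < 2L) return(NA_real_)
      stats::t.test(x, y, var.equal = TRUE)$p.value
    }),
    stringsAsFactors = FALSE)
  pw$p_adjusted <- bh_adjust(pw$p_value)
  list(f_value = an[["F value"]][1], df = an[["Df"]][1],
       p_value = an[["Pr(>F)"]][1], pairwise = pw)
}

## ---- expr_signature methods ------------------------------------------------

#' @export
print.expr_signature <- function(x, ...) {
  cat("Mutant-like expression signature\n")
  cat(sprintf("  %d up / %d down genes (FDR < %s)\n",
              length(x$up_genes), length(x$down_genes),
              format(x$fdr_cutoff)))
  cat(sprintf("  scoring mode: %s; orientation sign: %+d\n",
              x$mode, x$orientation_sign))
  invisible(x)
}

#' @export
summary.expr_signature <- function(object, ...) {
  cat("Mutant-like expression signature\n")
  cat(sprintf("  genes tested: %d (of which %d zero-variance)\n",
              nrow(object$de), length(attr(object$de, "zero_variance"))))
  cat(sprintf("  signature: %d up, %d down at FDR < %s\n",
              length(object$up_genes), length(object$down_genes),
              format(object$fdr_cutoff)))
  if (!is.null(object$fit_labels)) {
    mut <- object$fit_labels == "mutant"
    cat(sprintf(
      "  fitting-cohort score: mutant mean %.2f (n=%d) vs WT mean %.2f (n=%d)\n",
      mean(object$scores$score[mut]), sum(mut),
      mean(object$scores$score[!mut]), sum(!mut)))
  }
  invisible(object)
}

#' @export
coef.expr_signature <- function(object, ...) {
  object$orientation_sign * object$loadings
}

#' @rdname score_samples
#' @param object an `expr_signature`.
#' @param newdata genes x samples log-expression matrix to score.
#' @param ... passed to [score_samples()].
#' @export
predict.expr_signature <- function(object, newdata, ...) {
  score_samples(newdata, object, ...)
}

#' @export
plot.expr_signature <- function(x, ...) {
  if (is.null(x$fit_labels)) {
    graphics::hist(x$scores$score, main = "Signature scores",
                   xlab = "score", ...)
  } else {
    graphics::boxplot(x$scores$score ~ factor(x$fit_labels),
                      xlab = "mutation status", ylab = "signature score",
                      main = "Signature score by mutation status", ...)
  }
  invisible(x)
}
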