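#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: monotone non-decreasing in rank
#' order and capped at 1. Thin validated front over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs preserved).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_input("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop_input("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Two-tailed Fisher exact test on a 2x2 selected/not x arm table.
## Orientation: OR = odds(selected | arm B) / odds(selected | arm A), i.e.
## arm A is the reference column, so OR < 1 when selection is more frequent
## in arm A. Conditional maximum-likelihood estimate with exact 95% CI
## (sample cross-product OR available via or_method = "sample").
fisher_arm_test <- function(sel_a, not_a, sel_b, not_b,
                            or_method = c("conditional", "sample")) {
  or_method <- match.arg(or_method)
  m <- matrix(c(not_a, sel_a, not_b, sel_b), nrow = 2,
              dimnames = list(c("not", "selected"), c("A", "B")))
  ft <- stats::fisher.test(m, alternative = "two.sided")
  or <- if (or_method == "conditional") unname(ft$estimate) else {
    (sel_b / not_b) / (sel_a / not_a)
  }
  list(p_value = ft$p.value, odds_ratio = or,
       ci_lo = ft$conf.int[1], ci_hi = ft$conf.int[2])
}

#' Per-gene treatment-arm enrichment of selected mutations
#'
#' For each gene, counts patients (each at most once) with at least one
#' selected variant in that gene per arm, screens out genes without at least
#' `min_selected` selected patients in either arm, and tests the remaining
#' genes with a two-tailed Fisher exact test on the selected/not x arm table.
#' P-values are Benjamini-Hochberg adjusted across the tested genes only;
#' genes with adjusted p below `fdr_cutoff` are flagged significant. The odds
#' ratio is the conditional maximum-likelihood estimate with exact 95% CI,
#' oriented with arm A as the reference column (OR < 1 = enrichment in arm
#' A).
#'
#' @param calls selection calls from [call_selected_mutations()].
#' @param arm_sizes named vector `c(A = , B = )` of paired-patient counts per
#'   arm (e.g. `attr(simulate_cfdna_cohort(cfg), "arm_sizes")`, or the paired
#'   patient counts after [pair_timepoints()]).
#' @param min_selected minimum selected patients in at least one arm for a
#'   gene to be tested.
#' @param fdr_cutoff FDR significance cutoff (default 0.2).
#' @param or_method `"conditional"` (conditional MLE, default) or `"sample"`
#'   (cross-product ratio).
#' @return data.frame of class `gene_enrichment`, one row per tested gene:
#'   counts, `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`, `fdr`, `significant`;
#'   genes screened out are listed in `attr(x, "filtered")`.
#' @export
gene_arm_enrichment <- function(calls, arm_sizes, min_selected = 2L,
                                fdr_cutoff = 0.2,
                                or_method = c("conditional", "sample")) {
  or_method <- match.arg(or_method)
  if (!all(c("A", "B") %in% names(arm_sizes)))
    stop_input("arm_sizes must be named A and B")
  n_a <- as.integer(arm_sizes[["A"]])
  n_b <- as.integer(arm_sizes[["B"]])
  sel <- calls[calls$selected, , drop = FALSE]
  ## patient-level counting: a patient with several selected variants in one
  ## gene contributes once to that gene
  sel <- sel[!duplicated(sel[c("patient_id", "gene")]), , drop = FALSE]
  genes <- sort(unique(sel$gene))
  cnt_a <- vapply(genes, function(g)
    sum(sel$gene == g & sel$arm == "A"), integer(1))
  cnt_b <- vapply(genes, function(g)
    sum(sel$gene == g & sel$arm == "B"), integer(1))
  if (any(cnt_a > n_a) || any(cnt_b > n_b))
    stop_input("selected patient counts exceed arm totals")

  tested <- cnt_a >= min_selected | cnt_b >= min_selected
  filtered <- genes[!tested]
  genes <- genes[tested]
  cnt_a <- cnt_a[tested]
  cnt_b <- cnt_b[tested]

  if (length(genes) == 0L) {
    out <- data.frame(gene = character(0), n_selected_armA = integer(0),
                      n_selected_armB = integer(0),
                      n_total_armA = integer(0), n_total_armB = integer(0),
                      odds_ratio = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0))
  } else {
    tests <- lapply(seq_along(genes), function(i)
      fisher_arm_test(cnt_a[i], n_a - cnt_a[i], cnt_b[i], n_b - cnt_b[i],
                      or_method = or_method))
    out <- data.frame(
      gene = genes,
      n_selected_armA = cnt_a, n_selected_armB = cnt_b,
      n_total_armA = n_a, n_total_armB = n_b,
      odds_ratio = vapply(tests, `[[`, numeric(1), "odds_ratio"),
      ci_lo = vapply(tests, `[[`, numeric(1), "ci_lo"),
      ci_hi = vapply(tests, `[[`, numeric(1), "ci_hi"),
      p_value = vapply(tests, `[[`, numeric(1), "p_value"),
      stringsAsFactors = FALSE)
    out$fdr <- bh_adjust(out$p_value)
    out$significant <- out$fdr < fdr_cutoff
    out <- out[order(out$fdr, out$p_value, out$gene), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "filtered") <- filtered
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("gene_enrichment", "data.frame")
  out
}

#' @export
print.gene_enrichment <- function(x, ...) {
  cat(sprintf(
    "Per-gene treatment-arm enrichment: %d gene(s) tested, %d significant at FDR < %s\n",
    nrow(x), sum(x$significant), format(attr(x, "fdr_cutoff"))))
  filtered <- attr(x, "filtered")
  if (length(filtered))
    cat(sprintf("  (%d gene(s) below the minimum selected-count screen)\n",
                length(filtered)))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}
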