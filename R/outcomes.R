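#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous product-limit survival estimate, non-increasing from 1;
#' subjects censored exactly at an event time are counted at risk through the
#' event (the standard convention). Computation is delegated to
#' [survival::survfit()].
#'
#' @param times positive event/censoring times.
#' @param events 1 = event, 0 = censored.
#' @return data.frame step function: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_estimate <- function(times, events) {
  if (any(!is.finite(times)) || any(times <= 0))
    stop_input("times must be positive and finite")
  if (!all(events %in% c(0, 1)))
    stop_input("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Log-rank test across survival groups
#'
#' Observed-minus-expected log-rank statistic with hypergeometric variance,
#' `df = groups - 1`, via [survival::survdiff()].
#'
#' @param times,events as in [km_estimate()].
#' @param groups group labels (>= 2 non-empty groups).
#' @return list: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L)
    stop_input("need at least 2 groups")
  if (any(!is.finite(times)) || any(times <= 0))
    stop_input("times must be positive and finite")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Biomarker-by-treatment interaction proportional-hazards model
#'
#' Cox partial-likelihood fit of
#' `Surv(time, event) ~ biomarker * arm + covariates + strata(...)` with
#' Efron tie handling, the model form used to test whether a biomarker
#' modifies treatment benefit. Hazard ratios are `exp(coef)` with Wald 95%
#' confidence intervals and Wald p-values per term. Fitting is delegated to
#' [survival::coxph()]; rank-deficient designs error naming the collinear
#' terms, non-convergence errors rather than returning a dubious fit.
#'
#' @param records data.frame with `time`, `event`, the biomarker column, the
#'   arm column, and any covariate/strata columns.
#' @param biomarker,arm column names of the interacting terms.
#' @param covariates character vector of adjustment columns.
#' @param strata character vector of stratification columns (separate
#'   baseline hazards).
#' @return object of class `cox_interaction`: list with `table` (per-term
#'   coef, `hr`, `ci_lo`, `ci_hi`, `z`, `p_value`), `interaction_term`, and
#'   the underlying `fit`.
#' @export
fit_cox_interaction <- function(records, biomarker = "biomarker_group",
                                arm = "arm", covariates = character(0),
                                strata = character(0)) {
  need <- c("time", "event", biomarker, arm, covariates, strata)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_input("records missing column(s): ", paste(miss, collapse = ", "))
  for (v in c(biomarker, arm, covariates)) {
    if (length(unique(records[[v]])) < 2L)
      stop_input("rank-deficient design: term '", v, "' is constant")
  }
  rhs <- paste(c(sprintf("`%s` * `%s`", biomarker, arm),
                 sprintf("`%s`", covariates),
                 if (length(strata))
                   sprintf("strata(%s)",
                           paste(sprintf("`%s`", strata), collapse = ", "))),
               collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = records, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 25))
  if (!is.null(fit$info) && isTRUE(grepl("did not converge", fit$info)))
    stop_input("Cox model did not converge")
  cf <- fit$coefficients
  if (anyNA(cf))
    stop_input("rank-deficient design, collinear term(s): ",
               paste(names(cf)[is.na(cf)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  z <- cf / se
  tab <- data.frame(
    term = names(cf), coef = unname(cf), hr = exp(unname(cf)),
    ci_lo = exp(unname(cf) - 1.96 * se), ci_hi = exp(unname(cf) + 1.96 * se),
    z = unname(z), p_value = 2 * stats::pnorm(-abs(unname(z))),
    stringsAsFactors = FALSE)
  interaction_term <- grep(":", names(cf), value = TRUE)
  structure(list(table = tab, interaction_term = interaction_term,
                 fit = fit, n = fit$n, n_event = fit$nevent),
            class = "cox_interaction")
}

#' @export
print.cox_interaction <- function(x, ...) {
  cat(sprintf("Interaction Cox model (%d subjects, %d events)\n",
              x$n, x$n_event))
  print(x$table, digits = 3, row.names = FALSE)
  if (length(x$interaction_term)) {
    it <- x$table[x$table$term %in% x$interaction_term, , drop = FALSE]
    cat(sprintf("Interaction HR %.2f [%.2f, %.2f], p = %.3g\n",
                it$hr[1], it$ci_lo[1], it$ci_hi[1], it$p_value[1]))
  }
  invisible(x)
}

#' Overall response rate comparison between two groups
#'
#' Responders are complete or partial responses (CR, PR); stable and
#' progressive disease are non-responders. Group response rates are compared
#' with a two-tailed Fisher exact test (conditional-MLE odds ratio).
#'
#' @param responses best-response categories (`CR`, `PR`, `SD`, `PD`).
#' @param groups two-level group labels.
#' @param responder_classes categories counted as response.
#' @return list: `orr` (named per-group rates), `n` (group sizes),
#'   `p_value`, `odds_ratio` (odds of response in the second group level
#'   relative to the first), `ci`.
#' @export
orr_compare <- function(responses, groups,
                        responder_classes = c("CR", "PR")) {
  responses <- as.character(responses)
  if (!all(responses %in% response_levels))
    stop_input("responses must be CR, PR, SD or PD")
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop_input("need exactly 2 non-empty groups")
  resp <- responses %in% responder_classes
  n <- c(sum(groups == lev[1]), sum(groups == lev[2]))
  r <- c(sum(resp[groups == lev[1]]), sum(resp[groups == lev[2]]))
  ft <- fisher_arm_test(r[1], n[1] - r[1], r[2], n[2] - r[2])
  list(orr = stats::setNames(r / n, lev), n = stats::setNames(n, lev),
       p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       ci = c(ft$ci_lo, ft$ci_hi))
}

#' Classify xenograft response from percent tumor-volume change
#'
#' Conventional volume-change thresholds (not assay-derived; configurable):
#' partial response (PR) at or below the lower threshold, progressive disease
#' (PD) at or above the upper threshold (boundary inclusive on the PD side),
#' stable disease (SD) between.
#'
#' @param pct_volume_change finite percent change(s) from baseline.
#' @param pr_threshold upper bound of PR (default -50).
#' @param pd_threshold lower bound of PD (default +35).
#' @param responders_include_sd count SD together with PR as response (the
#'   "PR, SD-PR" grouping); reflected in `attr(x, "responder_classes")`.
#' @return character vector of categories `PR`/`SD`/`PD`.
#' @export
classify_pdx_response <- function(pct_volume_change, pr_threshold = -50,
                                  pd_threshold = 35,
                                  responders_include_sd = TRUE) {
  if (pr_threshold >= pd_threshold)
    stop_config("pr_threshold must be below pd_threshold")
  if (any(!is.finite(pct_volume_change)))
    stop_input("pct_volume_change must be finite")
  out <- ifelse(pct_volume_change <= pr_threshold, "PR",
                ifelse(pct_volume_change >= pd_threshold, "PD", "SD"))
  attr(out, "responder_classes") <-
    if (responders_include_sd) c("PR", "SD") else "PR"
  out
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact enumeration when both groups have at most 10 observations and no
#' ties; otherwise the normal approximation with tie correction (and
#' continuity correction). Degenerate input (all values identical across both
#' groups) returns p = 1 with a warning.
#'
#' @param values numeric vector.
#' @param groups two-level group labels.
#' @return list: `statistic` (Mann-Whitney W for the first group level),
#'   `p_value`, `exact` (whether exact enumeration was used).
#' @export
rank_sum_compare <- function(values, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop_input("need exactly 2 non-empty groups")
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (max(values) == min(values)) {
    warning("all values identical across groups; p = 1")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                exact = FALSE))
  }
  ties <- anyDuplicated(values) > 0L
  exact <- length(x) <= 10L && length(y) <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
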