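#' Simulate a longitudinal cfDNA variant cohort
#'
#' Generates a long-format table of plasma variant observations (one row per
#' patient, timepoint and variant) with the structure the selection analysis
#' assumes. Each patient carries a truncal clone plus a Poisson number of
#' baseline subclones with log-normal %MAF. All of a sample's MAFs are jointly
#' scaled by the timepoint's tumor-fraction multiplier (default: on-treatment
#' dip, progression rebound), so relative MAF is unaffected by tumor fraction
#' except through limit-of-detection censoring. Treatment-selected resistance
#' subclones are planted per gene and arm: seeded at a low fraction of the
#' patient's maximum baseline MAF (pre-existing with probability
#' `subclonal_seed_probability`, otherwise first detectable on treatment) and
#' multiplicatively expanded at end of study.
#'
#' The planted clones form a hidden truth channel, returned as
#' `attr(x, "truth")` — a data frame of (patient_id, arm, gene, variant_id,
#' origin) — so recovery of the selection calls can be tested. In the
#' noise-free, LOD-0 limit the default seeding and expansion parameters
#' guarantee every planted clone's relative-MAF increase exceeds 25 points
#' while unplanted clones never increase.
#'
#' @param config a [cfdna_sim_config()].
#' @return data.frame with columns `patient_id`, `arm`, `timepoint`, `gene`,
#'   `variant_id`, `effect_class`, `maf_percent`; attributes `truth` (planted
#'   clones) and `arm_sizes` (named patient counts).
#' @export
simulate_cfdna_cohort <- function(config) {
  if (!inherits(config, "cfdna_sim_config"))
    stop_config("config must be a cfdna_sim_config")
  set.seed(config$seed)
  n <- config$n_patients
  if (n < 1L || length(config$genes) < 1L)
    stop_config("need at least one patient and one gene")

  patient_id <- sprintf("P%04d", seq_len(n))
  n_a <- max(1L, min(n - 1L, round(n * config$arm_ratio)))
  if (n == 1L) n_a <- 1L
  arm <- c(rep("A", n_a), rep("B", n - n_a))

  ## -- baseline clones (truncal + subclones), one row per clone ------------
  k <- stats::rpois(n, config$baseline_clones_per_patient) + 1L
  pat_idx <- rep(seq_len(n), k)
  total <- length(pat_idx)
  clone <- data.frame(
    pat = pat_idx,
    gene = sample(config$genes, total, replace = TRUE),
    maf = stats::rlnorm(total, config$baseline_maf_meanlog,
                        config$baseline_maf_sdlog),
    effect_class = sample(c("nonsyn_snv", "indel", "synonymous"), total,
                          replace = TRUE, prob = c(0.6, 0.15, 0.25)),
    planted = FALSE, pre_existing = TRUE,
    stringsAsFactors = FALSE)
  ## patient maximum baseline MAF (the normalizing clone); joint per-patient
  ## rescaling keeps unexpanded MAFs below the reporting cap at every
  ## timepoint, so the cap never distorts relative MAF of unplanted clones
  max_maf <- unname(tapply(clone$maf, clone$pat, max)[as.character(seq_len(n))])
  cap_scale <- pmin(1, (config$max_maf_percent /
                          max(config$tumor_fraction_trajectory)) / max_maf)
  clone$maf <- clone$maf * cap_scale[clone$pat]
  max_maf <- max_maf * cap_scale

  ## -- planted resistance subclones ---------------------------------------
  sel_genes <- unique(c(names(config$selection_probability$A),
                        names(config$selection_probability$B)))
  planted_list <- list()
  for (g in sel_genes) {
    p_arm <- c(A = unname(config$selection_probability$A[g] %||% NA),
               B = unname(config$selection_probability$B[g] %||% NA))
    p_arm[is.na(p_arm)] <- 0
    p_pat <- p_arm[arm]
    hit <- stats::rbinom(n, 1L, p_pat) == 1L
    if (!any(hit)) next
    idx <- which(hit)
    f <- stats::runif(length(idx), config$seed_fraction_range[1],
                      config$seed_fraction_range[2])
    planted_list[[g]] <- data.frame(
      pat = idx, gene = g, maf = f * max_maf[idx],
      effect_class = sample(c("nonsyn_snv", "indel"), length(idx),
                            replace = TRUE, prob = c(0.7, 0.3)),
      planted = TRUE,
      pre_existing = stats::runif(length(idx)) <
        config$subclonal_seed_probability,
      stringsAsFactors = FALSE)
  }
  if (length(planted_list))
    clone <- rbind(clone, do.call(rbind, planted_list))

  ## per-patient variant ids (stable within patient)
  ord <- order(clone$pat)
  clone <- clone[ord, , drop = FALSE]
  within_idx <- stats::ave(seq_along(clone$pat), clone$pat, FUN = seq_along)
  clone$variant_id <- paste0(clone$gene, "_v", within_idx)
  is_truncal <- clone$maf == stats::ave(clone$maf, clone$pat, FUN = max) &
    !clone$planted
  ## only the first maximal clone per patient is flagged truncal
  is_truncal <- is_truncal &
    !duplicated(paste(clone$pat, is_truncal))

  ## -- expand to timepoints -----------------------------------------------
  tf <- config$tumor_fraction_trajectory
  m <- nrow(clone)
  tp <- rep(timepoint_levels, each = m)
  latent <- rep(clone$maf, times = 3L)
  ## expansion at EOT for planted clones
  eot <- tp == "EOT"
  planted_rep <- rep(clone$planted, times = 3L)
  latent[eot & planted_rep] <- latent[eot & planted_rep] *
    config$expansion_factor
  ## acquired clones absent at PRE
  pre <- tp == "PRE"
  absent <- pre & planted_rep & !rep(clone$pre_existing, times = 3L)
  observed <- latent * tf[tp]
  if (config$noise_sd > 0)
    observed <- observed * exp(stats::rnorm(length(observed), 0,
                                            config$noise_sd))
  observed <- pmin(observed, config$max_maf_percent)
  ## the truncal clone is guaranteed reportable at PRE and EOT
  truncal_rep <- rep(is_truncal, times = 3L)
  fix <- truncal_rep & tp %in% c("PRE", "EOT")
  observed[fix] <- pmax(observed[fix], config$lod_percent)

  keep <- !absent & observed >= config$lod_percent & observed > 0
  out <- data.frame(
    patient_id = patient_id[rep(clone$pat, times = 3L)][keep],
    arm = arm[rep(clone$pat, times = 3L)][keep],
    timepoint = tp[keep],
    gene = rep(clone$gene, times = 3L)[keep],
    variant_id = rep(clone$variant_id, times = 3L)[keep],
    effect_class = rep(clone$effect_class, times = 3L)[keep],
    maf_percent = observed[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  truth <- clone[clone$planted,
                 c("pat", "gene", "variant_id", "pre_existing")]
  truth <- data.frame(
    patient_id = patient_id[truth$pat],
    arm = arm[truth$pat],
    gene = truth$gene,
    variant_id = truth$variant_id,
    origin = ifelse(truth$pre_existing, "pre_existing", "acquired"),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  attr(out, "arm_sizes") <- c(A = n_a, B = n - n_a)
  out
}

## Solve P(mut|confounder) and P(mut|no confounder) so that the marginal
## prevalence and the odds ratio linking the two labels are both honored.
solve_conditional_prevalence <- function(p_marginal, p_confounder, odds) {
  f <- function(p0) {
    o1 <- odds * p0 / (1 - p0)
    p1 <- o1 / (1 + o1)
    p_confounder * p1 + (1 - p_confounder) * p0 - p_marginal
  }
  upper <- min(1 - 1e-9, p_marginal / (1 - p_confounder))
  p0 <- stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  o1 <- odds * p0 / (1 - p0)
  c(p0 = p0, p1 = o1 / (1 + o1))
}

#' Simulate an annotated expression cohort with a planted mutant-like signature
#'
#' Draws negative-binomial RNA-seq-like counts for `n_genes` genes in
#' `n_samples` tumors, with ARID1A, eRAS/BRAF and MSI mutation annotations.
#' `n_up` planted genes are shifted up and `n_down` down by `effect_size`
#' (log2) in ARID1A-mutant samples only; the ARID1A label is enriched among
#' eRAS/BRAF mutants by the configured odds multiplier; optional confounder
#' genes are shifted only in eRAS/BRAF mutants. The planted gene sets are the
#' truth channel for signature-recovery tests.
#'
#' @param config an [expr_sim_config()].
#' @return list with elements `counts` (genes x samples integer matrix),
#'   `annotations` (data.frame: sample_id, arid1a_status, erasbraf_status,
#'   msi_status, arm), and `truth` (list of up/down/confounder gene sets).
#' @export
simulate_expression_cohort <- function(config) {
  if (!inherits(config, "expr_sim_config"))
    stop_config("config must be an expr_sim_config")
  set.seed(config$seed)
  ns <- config$n_samples
  ng <- config$n_genes

  erasbraf <- stats::runif(ns) < config$erasbraf_prevalence
  pc <- solve_conditional_prevalence(config$arid1a_prevalence,
                                     config$erasbraf_prevalence,
                                     config$arid1a_in_erasbraf_enrichment)
  arid1a <- stats::runif(ns) < ifelse(erasbraf, pc["p1"], pc["p0"])
  msi <- stats::runif(ns) < config$msi_prevalence
  arm <- ifelse(stats::runif(ns) < 0.5, "A", "B")

  genes <- sprintf("gene_%04d", seq_len(ng))
  up <- genes[seq_len(config$n_up)]
  down <- genes[config$n_up + seq_len(config$n_down)]
  confound <- genes[config$n_up + config$n_down +
                      seq_len(config$n_confounder)]

  base_log2 <- stats::rnorm(ng, 5, 1.5)
  prop <- 2^base_log2
  prop <- prop / sum(prop)
  lib <- round(stats::runif(ns, config$library_size_range[1],
                            config$library_size_range[2]))

  shift <- matrix(0, ng, ns)
  if (config$n_up)
    shift[match(up, genes), arid1a] <- config$effect_size
  if (config$n_down)
    shift[match(down, genes), arid1a] <- -config$effect_size
  if (config$n_confounder)
    shift[match(confound, genes), erasbraf] <- config$confounder_effect

  mu <- outer(prop, lib) * 2^shift
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu, size = config$dispersion),
                   ng, ns,
                   dimnames = list(genes, sprintf("S%04d", seq_len(ns))))

  annotations <- data.frame(
    sample_id = colnames(counts),
    arid1a_status = ifelse(arid1a, "mutant", "WT"),
    erasbraf_status = ifelse(erasbraf, "mutant", "WT"),
    msi_status = ifelse(msi, "MSI", "MSS"),
    arm = arm,
    stringsAsFactors = FALSE)

  list(counts = counts, annotations = annotations,
       truth = list(up_genes = up, down_genes = down,
                    confounder_genes = confound))
}

#' Simulate survival and best-response outcomes with a planted interaction
#'
#' Event times are exponential with hazard `baseline_hazard *
#' biomarker_hr^[biomarker+] * arm_hr^[arm B] * interaction_hr^[biomarker+ and
#' arm B]`, censored by an independent exponential; best responses are drawn
#' per (arm, biomarker group) from the configured probability vectors.
#'
#' @param annotations data.frame with one row per subject, containing `arm`
#'   and the biomarker grouping column.
#' @param config an [outcome_sim_config()].
#' @param group_col name of the biomarker grouping column.
#' @param positive_group level of `group_col` treated as biomarker-positive.
#' @return data.frame of outcome records: `subject_id`, `arm`,
#'   `biomarker_group`, `time` (months), `event` (1 event / 0 censored),
#'   `best_response`.
#' @export
simulate_outcomes <- function(annotations, config, group_col = "group",
                              positive_group = "mutant_like") {
  if (!inherits(config, "outcome_sim_config"))
    stop_config("config must be an outcome_sim_config")
  if (!is.data.frame(annotations) ||
      !all(c("arm", group_col) %in% names(annotations)))
    stop_input("annotations must contain columns 'arm' and '", group_col, "'")
  grp <- as.character(annotations[[group_col]])
  arm <- as.character(annotations$arm)
  if (anyNA(grp) || anyNA(arm))
    stop_input("missing arm or biomarker group labels")
  set.seed(config$seed)
  n <- nrow(annotations)

  pos <- grp == positive_group
  armb <- arm == "B"
  hazard <- config$baseline_hazard *
    config$biomarker_hr^pos * config$arm_hr^armb *
    config$interaction_hr^(pos & armb)
  t_event <- stats::rexp(n, hazard)
  t_cens <- if (config$censoring_rate > 0)
    stats::rexp(n, config$censoring_rate) else rep(Inf, n)

  key <- paste(arm, grp, sep = ".")
  missing_key <- setdiff(unique(key), names(config$response_probs))
  if (length(missing_key))
    stop_input("no response_probs for cell(s): ",
               paste(missing_key, collapse = ", "))
  best_response <- vapply(key, function(k) {
    sample(response_levels, 1L, prob = config$response_probs[[k]])
  }, character(1), USE.NAMES = FALSE)

  data.frame(
    subject_id = if ("sample_id" %in% names(annotations))
      annotations$sample_id else sprintf("SUBJ%05d", seq_len(n)),
    arm = arm,
    biomarker_group = grp,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    best_response = best_response,
    stringsAsFactors = FALSE)
}

#' Simulate a xenograft response cohort
#'
#' One percent-tumor-volume-change measurement per xenograft model, drawn from
#' the configured normal distribution of the model's biomarker group.
#'
#' @param config an [outcome_sim_config()] (the `pdx_delta_*` fields are
#'   used).
#' @param groups character vector of per-model biomarker group labels, each a
#'   name of `config$pdx_delta_means`.
#' @return data.frame with `model_id`, `biomarker_group`,
#'   `pct_volume_change`; no missing values.
#' @export
simulate_pdx_cohort <- function(config, groups) {
  if (!inherits(config, "outcome_sim_config"))
    stop_config("config must be an outcome_sim_config")
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), names(config$pdx_delta_means))
  if (length(bad))
    stop_input("unknown PDX group(s): ", paste(bad, collapse = ", "))
  set.seed(config$seed)
  data.frame(
    model_id = sprintf("PDX%03d", seq_along(groups)),
    biomarker_group = groups,
    pct_volume_change = stats::rnorm(length(groups),
                                     config$pdx_delta_means[groups],
                                     config$pdx_delta_sds[groups]),
    stringsAsFactors = FALSE)
}
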