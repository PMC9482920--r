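#' Configuration for the longitudinal cfDNA cohort simulator
#'
#' Builds and validates the parameter set consumed by
#' [simulate_cfdna_cohort()]. The defaults describe a first-line metastatic
#' colorectal cancer trial population randomized between a control arm (`"A"`,
#' e.g. anti-VEGF) and an anti-EGFR arm (`"B"`): 333 patients with paired
#' plasma draws, a handful of clonal variants per patient, a circulating
#' tumor-fraction trajectory that dips on treatment and rebounds at
#' progression, and arm-specific per-gene probabilities that a resistance
#' subclone of that gene is expanded by end of study (KRAS and ARID1A expanded
#' preferentially under anti-EGFR therapy).
#'
#' @param n_patients number of patients in the cohort.
#' @param arm_ratio fraction of patients allocated to arm `"A"`, in (0, 1).
#' @param genes character vector of gene labels available to the simulator.
#' @param baseline_clones_per_patient mean number of baseline clones per
#'   patient (Poisson; a truncal clone is always added on top).
#' @param baseline_maf_meanlog,baseline_maf_sdlog log-normal parameters of
#'   baseline clone MAF on the percent scale.
#' @param tumor_fraction_trajectory named positive multipliers for the
#'   `PRE`, `OTH` and `EOT` draws; the whole sample's MAFs are scaled jointly,
#'   emulating changes in circulating tumor fraction.
#' @param selection_probability list with elements `A` and `B`, each a named
#'   numeric vector gene -> probability that a resistance subclone of that
#'   gene is expanded at EOT in a patient of that arm. Genes not named have
#'   probability 0.
#' @param expansion_factor multiplicative MAF gain applied to a planted
#'   subclone at end of study.
#' @param subclonal_seed_probability probability that a planted subclone is
#'   already detectable at baseline (pre-existing) rather than first appearing
#'   on treatment (acquired).
#' @param seed_fraction_range planted subclones are seeded at a fraction of
#'   the patient's maximum baseline MAF drawn uniformly from this range.
#' @param lod_percent limit of detection in %MAF; observations below it are
#'   not reported.
#' @param noise_sd standard deviation of multiplicative log-normal measurement
#'   noise (0 = noise-free).
#' @param max_maf_percent cap on reported %MAF (allele fractions cannot exceed
#'   100).
#' @param seed integer seed; fixed seed gives bit-identical output.
#'
#' @return object of class `cfdna_sim_config` (a validated list).
#' @seealso [simulate_cfdna_cohort()]
#' @export
cfdna_sim_config <- function(n_patients = 333L,
                             arm_ratio = 0.5,
                             genes = c("TP53", "APC", "KRAS", "ARID1A",
                                       "PIK3CA", "SMAD4", "BRAF", "NRAS",
                                       "EGFR", "FBXW7", "TCF7L2", "SOX9",
                                       "ATM", "PTEN", "GNAS", "CTNNB1",
                                       "ERBB2", "MAP2K1"),
                             baseline_clones_per_patient = 3,
                             baseline_maf_meanlog = log(2),
                             baseline_maf_sdlog = 1.0,
                             tumor_fraction_trajectory = c(PRE = 1, OTH = 0.3,
                                                           EOT = 1.5),
                             selection_probability = list(
                               A = c(KRAS = 0.006, ARID1A = 0.006),
                               B = c(KRAS = 0.060, ARID1A = 0.036)),
                             expansion_factor = 8,
                             subclonal_seed_probability = 0.4,
                             seed_fraction_range = c(0.3, 0.4),
                             lod_percent = 0.1,
                             noise_sd = 0.15,
                             max_maf_percent = 100,
                             seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients", min = 1L)
  check_number(arm_ratio, "arm_ratio", 0, 1, allow_equal = FALSE)
  if (!is.character(genes) || length(genes) < 1L || anyDuplicated(genes))
    stop_config("genes must be a non-empty character vector without duplicates")
  check_number(baseline_clones_per_patient, "baseline_clones_per_patient", 0)
  check_number(baseline_maf_sdlog, "baseline_maf_sdlog", 0)
  if (length(tumor_fraction_trajectory) != 3L ||
      !setequal(names(tumor_fraction_trajectory), timepoint_levels))
    stop_config("tumor_fraction_trajectory must be named PRE, OTH, EOT")
  if (any(!is.finite(tumor_fraction_trajectory)) ||
      any(tumor_fraction_trajectory <= 0))
    stop_config("tumor_fraction_trajectory multipliers must be > 0")
  if (!is.list(selection_probability) ||
      !setequal(names(selection_probability), c("A", "B")))
    stop_config("selection_probability must be a list with elements A and B")
  for (arm in c("A", "B")) {
    p <- selection_probability[[arm]]
    if (length(p)) {
      if (is.null(names(p)) || any(!names(p) %in% genes))
        stop_config("selection_probability genes must appear in `genes`")
      if (any(p < 0 | p > 1)) stop_config("selection probabilities in [0,1]")
    }
  }
  check_number(expansion_factor, "expansion_factor", 0, allow_equal = FALSE)
  check_prob(subclonal_seed_probability, "subclonal_seed_probability")
  if (length(seed_fraction_range) != 2L ||
      any(seed_fraction_range <= 0) || any(seed_fraction_range >= 1) ||
      seed_fraction_range[1] > seed_fraction_range[2])
    stop_config("seed_fraction_range must be an increasing pair in (0, 1)")
  check_number(lod_percent, "lod_percent", 0)
  check_number(noise_sd, "noise_sd", 0)
  check_number(max_maf_percent, "max_maf_percent", 0, allow_equal = FALSE)
  seed <- check_count(seed, "seed")

  structure(list(
    n_patients = n_patients, arm_ratio = arm_ratio, genes = genes,
    baseline_clones_per_patient = baseline_clones_per_patient,
    baseline_maf_meanlog = baseline_maf_meanlog,
    baseline_maf_sdlog = baseline_maf_sdlog,
    tumor_fraction_trajectory = tumor_fraction_trajectory[timepoint_levels],
    selection_probability = selection_probability,
    expansion_factor = expansion_factor,
    subclonal_seed_probability = subclonal_seed_probability,
    seed_fraction_range = seed_fraction_range,
    lod_percent = lod_percent, noise_sd = noise_sd,
    max_maf_percent = max_maf_percent, seed = seed),
    class = "cfdna_sim_config")
}

#' Configuration for the annotated expression-cohort simulator
#'
#' Parameters for [simulate_expression_cohort()], which emulates a tumor
#' RNA-seq cohort with mutation annotations. A planted mutant-like signature
#' (`n_up` genes shifted up, `n_down` shifted down by `effect_size` log2 units
#' in mutant samples) is embedded in negative-binomial counts, and the mutant
#' label is deliberately confounded with a second driver label (eRAS/BRAF)
#' through `arid1a_in_erasbraf_enrichment`, so that covariate-adjusted
#' differential expression is actually exercised. Optional confounder genes
#' are shifted only in eRAS/BRAF-mutant samples, irrespective of ARID1A
#' status: a correctly specified model must exclude them from the signature.
#'
#' @param n_samples,n_genes cohort and transcriptome dimensions.
#' @param n_up,n_down numbers of planted signature genes (default 8 up / 56
#'   down, the size of the derived mutant-like signature).
#' @param effect_size log2 expression shift in mutant samples.
#' @param arid1a_prevalence marginal fraction of ARID1A-mutant samples.
#' @param erasbraf_prevalence marginal fraction of eRAS/BRAF-mutant samples.
#' @param arid1a_in_erasbraf_enrichment odds ratio linking ARID1A and
#'   eRAS/BRAF mutation labels (> 1 = enrichment of ARID1A among eRAS/BRAF
#'   mutants).
#' @param msi_prevalence marginal fraction of MSI samples.
#' @param n_confounder,confounder_effect number and log2 shift of genes
#'   perturbed only in eRAS/BRAF-mutant samples.
#' @param dispersion negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param library_size_range sampling range for per-sample library sizes.
#' @param seed integer seed.
#'
#' @return object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_samples = 337L,
                            n_genes = 2000L,
                            n_up = 8L,
                            n_down = 56L,
                            effect_size = 1.0,
                            arid1a_prevalence = 0.1,
                            erasbraf_prevalence = 0.45,
                            arid1a_in_erasbraf_enrichment = 4,
                            msi_prevalence = 0.19,
                            n_confounder = 0L,
                            confounder_effect = 1.5,
                            dispersion = 10,
                            library_size_range = c(8e5, 1.6e6),
                            seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 4L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_up <- check_count(n_up, "n_up")
  n_down <- check_count(n_down, "n_down")
  n_confounder <- check_count(n_confounder, "n_confounder")
  if (n_up + n_down + n_confounder > n_genes)
    stop_config("n_up + n_down + n_confounder exceeds n_genes")
  check_number(effect_size, "effect_size")
  check_number(confounder_effect, "confounder_effect")
  check_number(arid1a_prevalence, "arid1a_prevalence", 0, 1,
               allow_equal = FALSE)
  check_number(erasbraf_prevalence, "erasbraf_prevalence", 0, 1,
               allow_equal = FALSE)
  check_number(arid1a_in_erasbraf_enrichment, "arid1a_in_erasbraf_enrichment",
               0, allow_equal = FALSE)
  check_number(msi_prevalence, "msi_prevalence", 0, 1, allow_equal = FALSE)
  check_number(dispersion, "dispersion", 0, allow_equal = FALSE)
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      library_size_range[1] > library_size_range[2])
    stop_config("library_size_range must be an increasing positive pair")
  seed <- check_count(seed, "seed")

  structure(list(
    n_samples = n_samples, n_genes = n_genes, n_up = n_up, n_down = n_down,
    effect_size = effect_size, arid1a_prevalence = arid1a_prevalence,
    erasbraf_prevalence = erasbraf_prevalence,
    arid1a_in_erasbraf_enrichment = arid1a_in_erasbraf_enrichment,
    msi_prevalence = msi_prevalence, n_confounder = n_confounder,
    confounder_effect = confounder_effect, dispersion = dispersion,
    library_size_range = library_size_range, seed = seed),
    class = "expr_sim_config")
}

#' Configuration for the clinical outcome and xenograft simulators
#'
#' Parameters for [simulate_outcomes()] and [simulate_pdx_cohort()]. Survival
#' times are exponential with hazard
#' `baseline_hazard * biomarker_hr^[biomarker] * arm_hr^[arm] *
#' interaction_hr^[biomarker x arm]`, so `interaction_hr` is the planted
#' treatment-modification effect the interaction Cox model is meant to
#' recover. Best responses are drawn per (arm, biomarker group) from
#' `response_probs`; xenograft percent volume changes are normal per group.
#'
#' @param baseline_hazard events per month in the reference cell.
#' @param biomarker_hr hazard multiplier for biomarker-positive subjects in
#'   the reference arm.
#' @param arm_hr hazard multiplier for arm `"B"` in biomarker-negative
#'   subjects.
#' @param interaction_hr additional multiplier for biomarker-positive subjects
#'   in arm `"B"` — the planted interaction.
#' @param censoring_rate independent exponential censoring rate per month.
#' @param response_probs named list `arm.group` -> probability vector over
#'   CR, PR, SD, PD (each must sum to 1).
#' @param pdx_delta_means,pdx_delta_sds named per-group normal parameters of
#'   percent tumor-volume change at 3 weeks.
#' @param seed integer seed.
#'
#' @return object of class `outcome_sim_config`.
#' @export
outcome_sim_config <- function(baseline_hazard = 1 / 30,
                               biomarker_hr = 1.0,
                               arm_hr = 1.0,
                               interaction_hr = 3.3,
                               censoring_rate = 1 / 90,
                               response_probs = list(
                                 A.wt_like     = c(CR = 0.06, PR = 0.57,
                                                   SD = 0.27, PD = 0.10),
                                 A.mutant_like = c(CR = 0.05, PR = 0.45,
                                                   SD = 0.30, PD = 0.20),
                                 B.wt_like     = c(CR = 0.09, PR = 0.80,
                                                   SD = 0.08, PD = 0.03),
                                 B.mutant_like = c(CR = 0.04, PR = 0.40,
                                                   SD = 0.36, PD = 0.20)),
                               pdx_delta_means = c(mutant_like = 85,
                                                   wt_like = 52),
                               pdx_delta_sds = c(mutant_like = 40,
                                                 wt_like = 45),
                               seed = 1L) {
  check_number(baseline_hazard, "baseline_hazard", 0, allow_equal = FALSE)
  check_number(biomarker_hr, "biomarker_hr", 0, allow_equal = FALSE)
  check_number(arm_hr, "arm_hr", 0, allow_equal = FALSE)
  check_number(interaction_hr, "interaction_hr", 0, allow_equal = FALSE)
  check_number(censoring_rate, "censoring_rate", 0)
  if (!is.list(response_probs) || is.null(names(response_probs)))
    stop_config("response_probs must be a named list")
  for (nm in names(response_probs)) {
    p <- response_probs[[nm]]
    if (!setequal(names(p), response_levels))
      stop_config("response_probs[[", nm, "]] must be named CR, PR, SD, PD")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_config("response_probs[[", nm, "]] must sum to 1")
    response_probs[[nm]] <- p[response_levels]
  }
  if (is.null(names(pdx_delta_means)) ||
      !setequal(names(pdx_delta_means), names(pdx_delta_sds)))
    stop_config("pdx_delta_means and pdx_delta_sds must share group names")
  if (any(pdx_delta_sds < 0)) stop_config("pdx_delta_sds must be >= 0")
  seed <- check_count(seed, "seed")

  structure(list(
    baseline_hazard = baseline_hazard, biomarker_hr = biomarker_hr,
    arm_hr = arm_hr, interaction_hr = interaction_hr,
    censoring_rate = censoring_rate, response_probs = response_probs,
    pdx_delta_means = pdx_delta_means,
    pdx_delta_sds = pdx_delta_sds[names(pdx_delta_means)], seed = seed),
    class = "outcome_sim_config")
}
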