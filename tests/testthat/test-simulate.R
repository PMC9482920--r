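test_that("cfDNA simulator is bit-identical under a fixed seed and varies across seeds", {
  cfg <- cfdna_sim_config(n_patients = 40, seed = 5)
  a <- simulate_cfdna_cohort(cfg)
  b <- simulate_cfdna_cohort(cfg)
  expect_identical(a, b)
  c_ <- simulate_cfdna_cohort(cfdna_sim_config(n_patients = 40, seed = 6))
  expect_false(identical(a$maf_percent, c_$maf_percent))
})

test_that("cfDNA output respects LOD, pairing and MAF-range contracts", {
  cfg <- cfdna_sim_config(n_patients = 60, seed = 2, lod_percent = 0.25)
  x <- simulate_cfdna_cohort(cfg)
  expect_true(all(x$maf_percent >= 0.25))
  expect_true(all(x$maf_percent <= 100))
  # every patient has PRE and EOT rows
  for (tp in c("PRE", "EOT"))
    expect_setequal(unique(x$patient_id[x$timepoint == tp]),
                    sprintf("P%04d", 1:60))
  expect_false(any(duplicated(x[c("patient_id", "timepoint", "variant_id")])))
})

test_that("tumor-fraction trajectory shapes the per-sample maximum MAF", {
  cfg <- cfdna_sim_config(n_patients = 150, seed = 3,
                          tumor_fraction_trajectory = c(PRE = 1, OTH = 0.3,
                                                        EOT = 1.5))
  x <- simulate_cfdna_cohort(cfg)
  key <- paste(x$patient_id, x$timepoint)
  mx <- tapply(x$maf_percent, list(x$timepoint), function(v) v)
  mean_max <- sapply(split(x, x$timepoint), function(d)
    mean(tapply(d$maf_percent, d$patient_id, max)))
  expect_gt(mean_max[["PRE"]], mean_max[["OTH"]])  # on-treatment dip
  expect_gt(mean_max[["EOT"]], mean_max[["PRE"]])  # progression rebound
})

test_that("planted selection frequency matches the binomial truth-channel oracle", {
  cfg <- cfdna_sim_config(
    n_patients = 300, seed = 17, arm_ratio = 0.5,
    selection_probability = list(A = c(KRAS = 0.05), B = numeric(0)))
  x <- simulate_cfdna_cohort(cfg)
  truth <- attr(x, "truth")
  n_a <- attr(x, "arm_sizes")[["A"]]
  hits <- length(unique(truth$patient_id[truth$arm == "A" &
                                           truth$gene == "KRAS"]))
  ci <- qbinom(c(0.0005, 0.9995), n_a, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
  expect_equal(nrow(truth[truth$arm == "B", ]), 0L)
})

test_that("no planted effect, no noise and unit expansion give no 25-point rises", {
  cfg <- cfdna_sim_config(
    n_patients = 100, seed = 4, noise_sd = 0, expansion_factor = 1,
    lod_percent = 0,
    selection_probability = list(A = numeric(0), B = numeric(0)))
  x <- simulate_cfdna_cohort(cfg)
  calls <- call_selected_mutations(pair_timepoints(x))
  expect_true(all(calls$delta <= 25))
  expect_false(any(calls$selected))
})

test_that("expression simulator plants the configured gene sets and label confounding", {
  cfg <- expr_sim_config(n_samples = 60, n_genes = 300, seed = 8)
  ex <- simulate_expression_cohort(cfg)
  expect_length(ex$truth$up_genes, 8L)
  expect_length(ex$truth$down_genes, 56L)
  expect_identical(dim(ex$counts), c(300L, 60L))
  expect_true(all(ex$counts >= 0))
  expect_identical(ex$annotations$sample_id, colnames(ex$counts))
  expect_identical(simulate_expression_cohort(cfg)$counts, ex$counts)

  # empirical odds ratio of the two labels at large n
  big <- simulate_expression_cohort(
    expr_sim_config(n_samples = 10000, n_genes = 5, n_up = 0, n_down = 0,
                    arid1a_prevalence = 0.1, erasbraf_prevalence = 0.3,
                    arid1a_in_erasbraf_enrichment = 4, seed = 12))
  a <- big$annotations$arid1a_status == "mutant"
  e <- big$annotations$erasbraf_status == "mutant"
  or <- (sum(a & e) * sum(!a & !e)) / (sum(a & !e) * sum(!a & e))
  expect_gt(or, 2.8)
  expect_lt(or, 5.7)
})

test_that("a null expression effect yields FDR-level false positives downstream", {
  cfg <- expr_sim_config(n_samples = 120, n_genes = 500, effect_size = 0,
                         seed = 21)
  ex <- simulate_expression_cohort(cfg)
  de <- fit_de_model(normalize_counts(ex$counts), ex$annotations)
  sets <- suppressWarnings(select_signature_genes(de, 0.05))
  expect_lte(length(sets$up_genes) + length(sets$down_genes), 5L)
})

test_that("outcome simulator honors the planted response and hazard structure", {
  ann <- data.frame(arm = rep(c("A", "B"), each = 400),
                    group = rep(c("wt_like", "mutant_like"), times = 400))
  probs <- c(CR = 0.2, PR = 0.4, SD = 0.3, PD = 0.1)  # ORR 0.6 everywhere
  cfg <- outcome_sim_config(
    biomarker_hr = 1, interaction_hr = 1, seed = 30,
    response_probs = list(A.wt_like = probs, A.mutant_like = probs,
                          B.wt_like = probs, B.mutant_like = probs))
  out <- simulate_outcomes(ann, cfg)
  expect_true(all(out$time > 0))
  expect_true(all(out$event %in% 0:1))
  orr <- mean(out$best_response %in% c("CR", "PR"))
  ci <- qbinom(c(0.0005, 0.9995), 800, 0.6) / 800
  expect_gte(orr, ci[1]); expect_lte(orr, ci[2])
  expect_error(simulate_outcomes(data.frame(arm = "A"), cfg), "group")
})

test_that("PDX simulator draws per-group normals and degenerates correctly", {
  cfg <- outcome_sim_config(pdx_delta_means = c(mutant_like = 40,
                                                wt_like = -20),
                            pdx_delta_sds = c(mutant_like = 0, wt_like = 0),
                            seed = 2)
  groups <- rep(c("mutant_like", "wt_like"), each = 10)
  pdx <- simulate_pdx_cohort(cfg, groups)
  expect_equal(pdx$pct_volume_change,
               ifelse(groups == "mutant_like", 40, -20))
  expect_false(anyNA(pdx$pct_volume_change))
  expect_error(simulate_pdx_cohort(cfg, "unknown_group"), "unknown")

  # separated groups are flagged by the rank-sum comparison at large n
  cfg2 <- outcome_sim_config(pdx_delta_means = c(mutant_like = 40,
                                                 wt_like = -20),
                             pdx_delta_sds = c(mutant_like = 30,
                                               wt_like = 30), seed = 3)
  pdx2 <- simulate_pdx_cohort(cfg2, rep(c("mutant_like", "wt_like"), 60))
  rs <- rank_sum_compare(pdx2$pct_volume_change, pdx2$biomarker_group)
  expect_lt(rs$p_value, 1e-6)
  expect_gt(median(pdx2$pct_volume_change[pdx2$biomarker_group ==
                                            "mutant_like"]),
            median(pdx2$pct_volume_change[pdx2$biomarker_group ==
                                            "wt_like"]))
})

test_that("configuration invariants are enforced", {
  expect_error(cfdna_sim_config(n_patients = 0), "n_patients")
  expect_error(cfdna_sim_config(lod_percent = -1), "lod_percent")
  expect_error(cfdna_sim_config(
    tumor_fraction_trajectory = c(PRE = 1, OTH = -1, EOT = 1)), "> 0")
  expect_error(expr_sim_config(n_genes = 50, n_up = 40, n_down = 40),
               "exceeds")
  expect_error(outcome_sim_config(response_probs = list(
    A.wt_like = c(CR = 0.5, PR = 0.5, SD = 0.5, PD = 0.5))), "sum to 1")
  expect_error(outcome_sim_config(pdx_delta_sds = c(mutant_like = -1,
                                                    wt_like = 1)), ">= 0")
})
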