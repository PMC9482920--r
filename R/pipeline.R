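## allowed keys per config section; unknown keys are rejected, not ignored
pipeline_sections <- list(
  cfdna = setdiff(names(formals(cfdna_sim_config)), "seed"),
  selection = c("threshold_points", "eligible_classes", "min_selected",
                "fdr_cutoff", "acquired_pre_cutoff"),
  expression = setdiff(names(formals(expr_sim_config)), "seed"),
  signature = c("fdr_cutoff", "include_msi", "moderate", "mode"),
  outcomes = setdiff(names(formals(outcome_sim_config)), "seed"),
  pdx = c("n_models", "pr_threshold", "pd_threshold",
          "responders_include_sd"))

#' Load and validate a pipeline configuration
#'
#' YAML with top-level keys `seed`, `output_dir`, `log_level`, and sections
#' `cfdna`, `selection`, `expression`, `signature`, `outcomes`, `pdx` whose
#' entries override the corresponding function defaults. Unknown keys are
#' rejected so a typo cannot silently fall back to a default. The parsed
#' configuration round-trips losslessly through YAML.
#'
#' @param path YAML file, or a list with the same structure.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  allowed_top <- c("seed", "output_dir", "log_level",
                   names(pipeline_sections))
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(pipeline_sections)) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_sections[[sec]])
    if (length(bad))
      stop_config("unknown key(s) in section '", sec, "': ",
                  paste(bad, collapse = ", "))
  }
  cfg$seed <- check_count(cfg$seed %||% 1L, "seed")
  cfg$log_level <- match.arg(cfg$log_level %||% "info",
                             c("quiet", "info", "debug"))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

pipe_log <- function(cfg, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[cfg$log_level %||% "info"]] >= levels[[level]])
    message("[", level, "] ", ...)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in dependency order: cfDNA cohort simulation, selection calling
#' and per-gene arm enrichment; expression cohort simulation, signature
#' derivation, scoring and quartile stratification; outcome simulation with
#' Kaplan-Meier curves, log-rank, interaction Cox fit and ORR comparison; and
#' xenograft simulation with rank-sum comparison. All stage outputs are
#' written as TSV/JSON under `output_dir` together with a run manifest
#' (package version, configuration hash, per-stage row counts, output
#' checksums). Fixed seed gives byte-identical stage outputs.
#'
#' @param config a [pipeline_config()] (or path / list accepted by it).
#' @param output_dir override of the configured output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||% "resistsig_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts_log <- list()

  ## ---- cfDNA selection chain -------------------------------------------
  pipe_log(cfg, "info", "simulating cfDNA cohort")
  ccfg <- do.call(cfdna_sim_config,
                  c(cfg$cfdna, list(seed = derive_seed(cfg$seed, 1L))))
  variants <- simulate_cfdna_cohort(ccfg)
  write_variant_table(variants, file.path(out_dir, "variants.tsv"))
  write_table_tsv(attr(variants, "truth"),
                  file.path(out_dir, "variants.truth.tsv"))
  counts_log$variants <- nrow(variants)

  paired <- pair_timepoints(variants)
  counts_log$paired_patients <- length(unique(paired$patient_id))
  counts_log$dropped_patients <- length(attr(paired, "dropped"))
  sel_args <- cfg$selection %||% list()
  calls <- do.call(call_selected_mutations, c(list(paired),
    sel_args[intersect(names(sel_args),
                       c("threshold_points", "eligible_classes",
                         "acquired_pre_cutoff"))]))
  write_table_tsv(calls, file.path(out_dir, "selection_calls.tsv"))
  counts_log$selected_variants <- sum(calls$selected)

  arm_sizes <- c(A = length(unique(paired$patient_id[paired$arm == "A"])),
                 B = length(unique(paired$patient_id[paired$arm == "B"])))
  enr <- gene_arm_enrichment(
    calls, arm_sizes,
    min_selected = sel_args$min_selected %||% 2L,
    fdr_cutoff = sel_args$fdr_cutoff %||% 0.2)
  write_table_tsv(as.data.frame(enr),
                  file.path(out_dir, "gene_enrichment.tsv"))
  counts_log$genes_tested <- nrow(enr)

  ## evolution maps for patients with a selected call
  sel_pat <- unique(calls$patient_id[calls$selected])
  emap <- do.call(rbind, lapply(sel_pat, function(p) {
    m <- build_evolution_map(variants, patient_id = p)
    cbind(patient_id = p, m)
  }))
  if (is.null(emap))
    emap <- data.frame(patient_id = character(0), variant_id = character(0),
                       gene = character(0), rmaf_PRE = numeric(0),
                       rmaf_OTH = numeric(0), rmaf_EOT = numeric(0))
  write_table_tsv(emap, file.path(out_dir, "evolution_map.tsv"))

  ## ---- signature chain --------------------------------------------------
  pipe_log(cfg, "info", "simulating expression cohort, deriving signature")
  ecfg <- do.call(expr_sim_config,
                  c(cfg$expression, list(seed = derive_seed(cfg$seed, 2L))))
  expr <- simulate_expression_cohort(ecfg)
  write_table_tsv(expr$annotations, file.path(out_dir, "annotations.tsv"))
  log_expr <- normalize_counts(expr$counts)
  sig_args <- cfg$signature %||% list()
  sig <- fit_signature(log_expr, expr$annotations,
                       fdr_cutoff = sig_args$fdr_cutoff %||% 0.05,
                       include_msi = sig_args$include_msi %||% TRUE,
                       moderate = sig_args$moderate %||% TRUE,
                       mode = sig_args$mode %||% "refit_per_cohort")
  write_table_tsv(sig$de, file.path(out_dir, "de_results.tsv"))
  write_signature(sig, file.path(out_dir, "signature.json"))
  strat <- stratify_quartiles(sig$scores)
  write_table_tsv(strat, file.path(out_dir, "scores.tsv"))
  counts_log$signature_genes <- length(sig$up_genes) + length(sig$down_genes)

  ## ---- outcome chain ----------------------------------------------------
  pipe_log(cfg, "info", "simulating outcomes, fitting association models")
  ann <- cbind(expr$annotations, group = strat$group,
               stringsAsFactors = FALSE)
  ocfg <- do.call(outcome_sim_config,
                  c(cfg$outcomes, list(seed = derive_seed(cfg$seed, 3L))))
  outcomes <- simulate_outcomes(ann, ocfg)
  write_table_tsv(outcomes, file.path(out_dir, "outcomes.tsv"))

  km <- do.call(rbind, lapply(split(outcomes,
                                    paste(outcomes$arm,
                                          outcomes$biomarker_group)), \(d) {
    cbind(arm = d$arm[1], biomarker_group = d$biomarker_group[1],
          km_estimate(d$time, d$event))
  }))
  rownames(km) <- NULL
  write_table_tsv(km, file.path(out_dir, "km_curves.tsv"))

  lr <- logrank_test(outcomes$time, outcomes$event,
                     paste(outcomes$arm, outcomes$biomarker_group))
  write_table_tsv(data.frame(chisq = lr$chisq, df = lr$df,
                             p_value = lr$p_value),
                  file.path(out_dir, "logrank.tsv"))

  outcomes$biomarker_group <- factor(outcomes$biomarker_group,
                                     levels = c("wt_like", "mutant_like"))
  cox <- fit_cox_interaction(outcomes)
  write_table_tsv(cox$table, file.path(out_dir, "cox_fit.tsv"))

  orr <- lapply(split(outcomes, outcomes$arm), \(d)
    orr_compare(d$best_response, as.character(d$biomarker_group)))
  orr_df <- do.call(rbind, lapply(names(orr), \(a)
    data.frame(arm = a,
               group = names(orr[[a]]$orr),
               n = unname(orr[[a]]$n),
               orr = unname(orr[[a]]$orr),
               p_value = orr[[a]]$p_value,
               odds_ratio = orr[[a]]$odds_ratio)))
  write_table_tsv(orr_df, file.path(out_dir, "orr.tsv"))

  ## ---- xenograft chain --------------------------------------------------
  pdx_args <- cfg$pdx %||% list()
  n_models <- pdx_args$n_models %||% 132L
  pdx_groups <- rep(names(ocfg$pdx_delta_means),
                    length.out = n_models)
  pcfg <- ocfg
  pcfg$seed <- derive_seed(cfg$seed, 4L)
  pdx <- simulate_pdx_cohort(pcfg, pdx_groups)
  pdx$category <- as.character(classify_pdx_response(
    pdx$pct_volume_change,
    pr_threshold = pdx_args$pr_threshold %||% -50,
    pd_threshold = pdx_args$pd_threshold %||% 35,
    responders_include_sd = pdx_args$responders_include_sd %||% TRUE))
  write_table_tsv(pdx, file.path(out_dir, "pdx.tsv"))
  pdx_test <- rank_sum_compare(pdx$pct_volume_change, pdx$biomarker_group)

  ## ---- manifest ---------------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile()
  writeLines(cfg_json, cfg_file)
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  checksums <- tools::md5sum(file.path(out_dir, outputs))
  manifest <- list(
    tool = "resistsig",
    version = as.character(utils::packageVersion("resistsig")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    row_counts = counts_log,
    output_checksums = as.list(stats::setNames(unname(checksums), outputs)),
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(variants = variants, calls = calls, enrichment = enr,
                 signature = sig, stratified = strat, outcomes = outcomes,
                 logrank = lr, cox = cox, orr = orr, pdx = pdx,
                 pdx_test = pdx_test, manifest = manifest))
}
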