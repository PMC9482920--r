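#' Relative MAF within one sample
#'
#' A variant's relative MAF is its mutant allele frequency as a percentage of
#' the highest MAF reported in the same patient-sample. Because circulating
#' tumor-DNA fraction scales every variant's MAF in a plasma draw by a common
#' factor, this normalization cancels tumor-fraction fluctuations between
#' longitudinal draws: the sample's top variant always scores exactly 100.
#'
#' @param maf_percent numeric vector of reported %MAF values for one
#'   patient-sample (all reported variants, any effect class).
#' @return numeric vector of relative MAF in \[0, 100\]; the maximum entry is
#'   exactly 100.
#' @examples
#' compute_relative_maf(c(2, 0.5, 0.1)) # 100, 25, 5
#' @export
compute_relative_maf <- function(maf_percent) {
  if (length(maf_percent) == 0L)
    stop_input("undefined normalization: empty sample")
  if (any(!is.finite(maf_percent)) || any(maf_percent < 0))
    stop_input("maf_percent must be finite and non-negative")
  mx <- max(maf_percent)
  if (mx == 0)
    stop_input("undefined normalization: all MAFs are zero in sample")
  r <- pmin(100, 100 * maf_percent / mx)
  r[maf_percent == mx] <- 100  # the argmax is exactly 100, no fp jitter
  r
}

## Adds an rmaf_percent column per (patient, timepoint) sample. Samples whose
## normalization is undefined (all-zero) are flagged and excluded with a
## warning rather than erroring the whole table.
add_relative_maf <- function(observations) {
  key <- paste(observations$patient_id, observations$timepoint, sep = "\r")
  mx <- stats::ave(observations$maf_percent, key, FUN = max)
  bad <- mx == 0
  if (any(bad)) {
    warning(sprintf(
      "%d sample(s) with all-zero MAF excluded (undefined normalization)",
      length(unique(key[bad]))))
    observations <- observations[!bad, , drop = FALSE]
    mx <- mx[!bad]
  }
  r <- pmin(100, 100 * observations$maf_percent / mx)
  r[observations$maf_percent == mx] <- 100
  observations$rmaf_percent <- r
  observations
}

#' Pair baseline and end-of-study observations per patient
#'
#' Builds the per-patient paired variant table on which selection is called:
#' the union of variants seen at either timepoint, with MAF and relative MAF
#' set to 0 at a timepoint where the variant is unreported. Patients lacking
#' either timepoint are dropped and reported in `attr(x, "dropped")`.
#'
#' @param observations long variant table (columns `patient_id`, `arm`,
#'   `timepoint`, `gene`, `variant_id`, `effect_class`, `maf_percent`).
#' @param pre_label,post_label timepoint labels to pair (default PRE and
#'   EOT; intermediate draws feed evolution maps, not selection calls).
#' @return data.frame with one row per (patient, variant): `maf_pre`,
#'   `maf_post`, `rmaf_pre`, `rmaf_post`, `present_pre`, `present_post`.
#' @export
pair_timepoints <- function(observations, pre_label = "PRE",
                            post_label = "EOT") {
  obs <- observations[observations$timepoint %in% c(pre_label, post_label), ,
                      drop = FALSE]
  dup <- duplicated(obs[c("patient_id", "timepoint", "variant_id")])
  if (any(dup))
    stop_input("duplicate (patient, timepoint, variant) rows, e.g. ",
               obs$patient_id[dup][1], "/", obs$timepoint[dup][1], "/",
               obs$variant_id[dup][1])
  obs <- add_relative_maf(obs)

  has_pre <- unique(obs$patient_id[obs$timepoint == pre_label])
  has_post <- unique(obs$patient_id[obs$timepoint == post_label])
  complete <- intersect(has_pre, has_post)
  dropped <- setdiff(unique(obs$patient_id), complete)
  obs <- obs[obs$patient_id %in% complete, , drop = FALSE]

  key <- paste(obs$patient_id, obs$variant_id, sep = "\r")
  ukey <- !duplicated(key)
  base <- obs[ukey, c("patient_id", "arm", "gene", "variant_id",
                      "effect_class")]
  ## match within each timepoint's slice
  pre_rows <- obs[obs$timepoint == pre_label, , drop = FALSE]
  post_rows <- obs[obs$timepoint == post_label, , drop = FALSE]
  bkey <- paste(base$patient_id, base$variant_id, sep = "\r")
  i_pre <- match(bkey, paste(pre_rows$patient_id, pre_rows$variant_id,
                             sep = "\r"))
  i_post <- match(bkey, paste(post_rows$patient_id, post_rows$variant_id,
                              sep = "\r"))
  out <- data.frame(
    base,
    maf_pre = ifelse(is.na(i_pre), 0, pre_rows$maf_percent[i_pre]),
    maf_post = ifelse(is.na(i_post), 0, post_rows$maf_percent[i_post]),
    rmaf_pre = ifelse(is.na(i_pre), 0, pre_rows$rmaf_percent[i_pre]),
    rmaf_post = ifelse(is.na(i_post), 0, post_rows$rmaf_percent[i_post]),
    present_pre = !is.na(i_pre),
    present_post = !is.na(i_post),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Call treatment-selected mutations from paired relative MAF
#'
#' A variant is called selected when its relative MAF increases by strictly
#' more than `threshold_points` percentage points from baseline to end of
#' study and its effect class is eligible (default: non-synonymous SNVs and
#' indels; synonymous variants and rearrangements still participate in the
#' normalization but are not callable). Selected variants unreported at
#' baseline are classified `acquired`, those already detectable
#' `pre_existing`.
#'
#' @param paired output of [pair_timepoints()].
#' @param threshold_points strict selection threshold on the relative-MAF
#'   increase, in percentage points.
#' @param eligible_classes effect classes a selection call may have.
#' @param acquired_pre_cutoff relative MAF at baseline at or below which a
#'   reported variant still counts as acquired (default 0: any baseline
#'   report makes it pre-existing).
#' @return data.frame of selection calls: `delta` (rMAF points), `selected`,
#'   `origin`, `abs_maf_delta` (raw MAF points).
#' @export
call_selected_mutations <- function(paired, threshold_points = 25,
                                    eligible_classes = c("nonsyn_snv",
                                                         "indel"),
                                    acquired_pre_cutoff = 0) {
  check_number(threshold_points, "threshold_points", 0, 100)
  if (!all(eligible_classes %in% effect_class_levels))
    stop_config("unknown effect class in eligible_classes")
  delta <- paired$rmaf_post - paired$rmaf_pre
  eligible <- paired$effect_class %in% eligible_classes
  selected <- delta > threshold_points & eligible
  acquired <- !paired$present_pre |
    (acquired_pre_cutoff > 0 & paired$rmaf_pre <= acquired_pre_cutoff)
  out <- data.frame(
    patient_id = paired$patient_id,
    arm = paired$arm,
    gene = paired$gene,
    variant_id = paired$variant_id,
    effect_class = paired$effect_class,
    rmaf_pre = paired$rmaf_pre,
    rmaf_eot = paired$rmaf_post,
    delta = delta,
    selected = selected,
    origin = ifelse(acquired, "acquired", "pre_existing"),
    abs_maf_delta = paired$maf_post - paired$maf_pre,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build a mutation evolution map for one patient
#'
#' Per-variant relative-MAF trajectories across the available timepoints
#' (baseline, on-treatment, end of study), annotated with the maximum raw
#' %MAF per timepoint (the normalizer). Variants are ordered by end-of-study
#' relative MAF, descending, ties broken by variant label.
#'
#' @param observations long variant table restricted to (or containing) one
#'   patient.
#' @param patient_id patient to map (optional when the table has one patient).
#' @return data.frame with one row per variant and columns `rmaf_PRE`,
#'   `rmaf_OTH`, `rmaf_EOT` (NA where the variant or the whole timepoint is
#'   missing); attributes `max_maf` (named per-timepoint maximum raw %MAF)
#'   and `undefined_samples` (timepoints whose normalization was undefined).
#' @export
build_evolution_map <- function(observations, patient_id = NULL) {
  if (!is.null(patient_id))
    observations <- observations[observations$patient_id == patient_id, ,
                                 drop = FALSE]
  if (nrow(observations) == 0L)
    stop_input("no observations for patient")
  if (length(unique(observations$patient_id)) != 1L)
    stop_input("evolution map is per patient; pass patient_id")
  undefined <- character(0)
  max_maf <- c(PRE = NA_real_, OTH = NA_real_, EOT = NA_real_)
  rmaf <- list()
  for (tp in timepoint_levels) {
    rows <- observations[observations$timepoint == tp, , drop = FALSE]
    if (nrow(rows) == 0L) next
    max_maf[tp] <- max(rows$maf_percent)
    if (max_maf[tp] == 0) {
      undefined <- c(undefined, tp)
      rmaf[[tp]] <- stats::setNames(rep(NA_real_, nrow(rows)),
                                    rows$variant_id)
    } else {
      rmaf[[tp]] <- stats::setNames(compute_relative_maf(rows$maf_percent),
                                    rows$variant_id)
    }
  }
  variants <- unique(observations$variant_id)
  out <- data.frame(
    variant_id = variants,
    gene = observations$gene[match(variants, observations$variant_id)],
    stringsAsFactors = FALSE)
  for (tp in timepoint_levels)
    out[[paste0("rmaf_", tp)]] <-
      if (tp %in% names(rmaf)) unname(rmaf[[tp]][variants]) else NA_real_
  ord <- order(-ifelse(is.na(out$rmaf_EOT), -Inf, out$rmaf_EOT),
               out$variant_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_maf") <- max_maf
  attr(out, "undefined_samples") <- undefined
  out
}
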