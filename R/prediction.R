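#' Survival prediction for one patient
#'
#' Applies the patient-level decision procedure mapping assay results to a
#' positive/negative prediction:
#'
#' 1. If the MTA was given on the basis of a gene amplification rather than an
#'    assayed variant, the literature table is consulted with the key
#'    (`basis_alteration`, `mta`): a positive match predicts positive
#'    (`literature_positive`); no match predicts negative
#'    (`mta_not_assay_relevant`).
#' 2. Otherwise, if no variant targeted by the MTA is active, the prediction
#'    is negative (`variant_not_activating`). Resistance co-mutations (e.g.
#'    KRAS, NRAS, PIK3CA) are not special-cased: they act through the assay
#'    outcome of the co-transfected combination or through this rule.
#' 3. Otherwise the drug-response assay of the patient's co-transfected
#'    variants decides: inhibition of the activated pathway predicts positive
#'    (`mta_inhibits`), failure predicts negative (`mta_fails_to_inhibit`).
#'
#' @param patient tibble of cohort rows for one patient (see [load_cohort()]).
#' @param responses dose-response tibble (see [dose_response_fixture()]);
#'   inhibition is recomputed from the dose series via [call_inhibition()].
#' @param literature literature-rule tibble (see [literature_rules()]).
#' @param targets drug-target tibble (see [drug_targets()]).
#' @param activities optional tibble (`gene`, `protein_change`, `active`)
#'   overriding the cohort's activity calls.
#' @param inhibition_mode passed to [call_inhibition()].
#' @return one-row tibble: `patient_id`, `label` (`"positive"`/`"negative"`),
#'   `rationale` (one of `mta_inhibits`, `mta_fails_to_inhibit`,
#'   `variant_not_activating`, `mta_not_assay_relevant`,
#'   `literature_positive`), `details`.
#' @export
predict_patient <- function(patient,
                            responses = dose_response_fixture(),
                            literature = literature_rules(),
                            targets = drug_targets(),
                            activities = NULL,
                            inhibition_mode = "absolute") {
  pid <- unique(patient$patient_id)
  mta <- unique(patient$mta)
  stopifnot(length(pid) == 1, length(mta) == 1)
  if (!is.null(activities)) {
    patient <- patient %>%
      dplyr::select(-"active") %>%
      dplyr::left_join(activities, by = c("gene", "protein_change"))
    if (any(is.na(patient$active)))
      abort(sprintf("patient %s: activity call missing for an assayed variant", pid))
  }
  out <- function(label, rationale, details) {
    tibble::tibble(patient_id = pid, label = label, rationale = rationale,
                   details = details)
  }
  if (unique(patient$treatment_basis) == "amplification") {
    alt <- unique(patient$basis_alteration)
    hit <- literature[literature$alteration %in% alt & literature$mta == mta, ]
    if (nrow(hit) >= 1 && hit$label[1] == "positive")
      return(out("positive", "literature_positive",
                 sprintf("%s treated with %s: positive per literature", alt, mta)))
    return(out("negative", "mta_not_assay_relevant",
               sprintf("MTA given on the basis of %s, not an assayed variant; no supporting literature rule", alt)))
  }
  drugs <- strsplit(mta, " \\+ ")[[1]]
  target_genes <- targets$gene[targets$drug %in% drugs]
  targeted_active <- patient$active & patient$gene %in% target_genes
  if (!any(targeted_active)) {
    return(out("negative", "variant_not_activating",
               sprintf("no active variant targeted by %s (variants: %s)", mta,
                       paste(patient$gene, patient$protein_change, collapse = ", "))))
  }
  resp <- responses[responses$patient_id == pid & responses$drug %in% drugs, ]
  if (nrow(resp) == 0)
    abort(sprintf("patient %s: active targeted variant but no dose-response result (incomplete assay)", pid))
  resp <- resp[order(resp$dose_nM), ]
  inhibited <- call_inhibition(resp$activity, resp$untreated_activity[1],
                               mode = inhibition_mode)
  combo <- unique(resp$variant_combo)
  if (inhibited)
    out("positive", "mta_inhibits",
        sprintf("%s inhibits the pathway activated by %s", mta, combo))
  else
    out("negative", "mta_fails_to_inhibit",
        sprintf("%s fails to inhibit the pathway activated by %s", mta, combo))
}

#' Survival predictions for a whole cohort
#'
#' @param cohort cohort tibble from [load_cohort()].
#' @inheritParams predict_patient
#' @return tibble with one prediction row per patient (see
#'   [predict_patient()]), ordered by `patient_id`.
#' @examples
#' preds <- predict_cohort(load_cohort())
#' table(preds$label) # 4 positive, 8 negative
#' @export
predict_cohort <- function(cohort,
                           responses = dose_response_fixture(),
                           literature = literature_rules(),
                           targets = drug_targets(),
                           activities = NULL,
                           inhibition_mode = "absolute") {
  if (nrow(cohort) == 0)
    return(tibble::tibble(patient_id = integer(0), label = character(0),
                          rationale = character(0), details = character(0)))
  cohort %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(predict_patient, responses = responses,
                   literature = literature, targets = targets,
                   activities = activities,
                   inhibition_mode = inhibition_mode) %>%
    dplyr::arrange(.data$patient_id)
}
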