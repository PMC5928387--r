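#' Load a patient cohort table
#'
#' Reads a cohort of patients treated with molecularly targeted agents (MTAs),
#' one row per (patient, variant). The packaged example cohort
#' (`source = "builtin"`) describes 12 patients whose tumours carried variants
#' in the RTK/MAPK signalling axis, together with the MTA each received, the
#' per-variant oncogenic-activity call from the translocation reporter assay,
#' the basis on which the MTA was given (an assayed variant, or a gene
#' amplification for patients 1, 9 and 11), and progression-free survival
#' (PFS) in months. All example patients progressed, so `event` is `TRUE`
#' throughout.
#'
#' @param source `"builtin"` for the packaged cohort, or a path to a CSV with
#'   the same columns.
#' @return A tibble with columns `patient_id`, `cancer_type`, `mta`,
#'   `treatment_basis` (`"assayed_variant"` or `"amplification"`),
#'   `basis_alteration`, `gene`, `protein_change`, `variant_class` (`"VUS"` or
#'   `"known"`), `reporter_pathway`, `active` (logical oncogenic-activity
#'   call), `pfs_months`, `event`.
#' @seealso [filter_variants()], [predict_cohort()]
#' @examples
#' cohort <- load_cohort()
#' dplyr::n_distinct(cohort$patient_id) # 12
#' @export
load_cohort <- function(source = "builtin") {
  path <- if (identical(source, "builtin")) ncr_extdata("cohort.csv") else source
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_integer(),
                           pfs_months = readr::col_double(),
                           active = readr::col_logical(),
                           event = readr::col_logical(),
                           .default = readr::col_character()
                         ))
  validate_cohort(raw)
}

validate_cohort <- function(x) {
  required <- c("patient_id", "cancer_type", "mta", "treatment_basis",
                "gene", "protein_change", "variant_class",
                "reporter_pathway", "active", "pfs_months", "event")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    schema_abort("header", missing[1], "required column absent")
  if (!"basis_alteration" %in% names(x)) x$basis_alteration <- NA_character_
  if (nrow(x) == 0) return(tibble::as_tibble(x))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$patient_id[i]) || x$patient_id[i] < 1)
      schema_abort(i, "patient_id", "must be a positive integer")
    if (!x$treatment_basis[i] %in% c("assayed_variant", "amplification"))
      schema_abort(i, "treatment_basis",
                   "must be 'assayed_variant' or 'amplification'")
    if (!x$variant_class[i] %in% c("VUS", "known"))
      schema_abort(i, "variant_class", "must be 'VUS' or 'known'")
    if (is.na(x$pfs_months[i]) || x$pfs_months[i] <= 0)
      schema_abort(i, "pfs_months", "must be a positive number of months")
    if (is.na(x$active[i]))
      schema_abort(i, "active", "must be TRUE or FALSE")
    if (is.na(x$event[i]))
      schema_abort(i, "event", "must be TRUE or FALSE")
  }
  tibble::as_tibble(x)
}

#' Write a cohort table to CSV
#'
#' Round-trips with [load_cohort()]: all fields are reproduced exactly.
#'
#' @param cohort a cohort tibble as returned by [load_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Filter variant calls by sequencing quality
#'
#' Applies the retention thresholds used upstream of the functional assay:
#' a single-nucleotide variant (SNV) is kept when its allele frequency exceeds
#' 4% and its coverage exceeds 30x; an indel when frequency exceeds 10% and
#' coverage exceeds 100x; and every retained call must additionally have a
#' strand ratio above 0.2. All comparisons are strict, so boundary values are
#' discarded. Input order is preserved and the operation is idempotent.
#'
#' @param calls tibble with columns `gene`, `protein_change`, `variant_type`
#'   (`"SNV"` or `"indel"`), `allele_frequency` (0-1), `strand_ratio` (0-1),
#'   `coverage` (reads).
#' @return the retained subset of `calls`, same columns and order.
#' @examples
#' calls <- tibble::tibble(
#'   gene = c("KIT", "KIT"), protein_change = c("D572G", "V852I"),
#'   variant_type = "SNV", allele_frequency = c(0.05, 0.04),
#'   strand_ratio = 0.3, coverage = 50
#' )
#' filter_variants(calls) # only the first call survives
#' @export
filter_variants <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) return(calls)
  bad <- setdiff(unique(calls$variant_type), c("SNV", "indel"))
  if (length(bad) > 0)
    abort(paste0("unknown variant_type: ", paste(bad, collapse = ", "),
                 " (expected 'SNV' or 'indel')"))
  if (any(calls$allele_frequency < 0 | calls$allele_frequency > 1, na.rm = TRUE))
    abort("allele_frequency must lie in [0, 1]")
  if (any(calls$strand_ratio < 0 | calls$strand_ratio > 1, na.rm = TRUE))
    abort("strand_ratio must lie in [0, 1]")
  keep <- ifelse(
    calls$variant_type == "SNV",
    calls$allele_frequency > 0.04 & calls$coverage > 30,
    calls$allele_frequency > 0.10 & calls$coverage > 100
  ) & calls$strand_ratio > 0.2
  calls[keep, , drop = FALSE]
}

#' Packaged drug-to-gene target map
#'
#' The MTAs used in the example cohort and the genes they are taken to
#' target: sorafenib (FLT3, PDGFRA, KIT, RAF kinases), imatinib (KIT,
#' PDGFRA), vemurafenib (BRAF), lapatinib and trastuzumab (ERBB2/EGFR),
#' erlotinib (EGFR). A combination therapy string such as
#' `"lapatinib + trastuzumab"` targets the union of its components' genes.
#'
#' @param path optional CSV (`drug`, `gene`) to use instead of the packaged map.
#' @return tibble with columns `drug`, `gene`.
#' @export
drug_targets <- function(path = NULL) {
  readr::read_csv(path %||% ncr_extdata("drug_targets.csv"),
                  col_types = "cc")
}

#' Packaged literature rules for amplification-based treatments
#'
#' When an MTA was given on the basis of a gene amplification rather than an
#' assayed variant, the survival prediction falls back to a literature lookup
#' keyed by (alteration, MTA). The packaged table carries the single
#' literature-supported case: ERBB2 amplification treated with
#' lapatinib + trastuzumab is predicted positive.
#'
#' @param path optional CSV (`alteration`, `mta`, `label`) replacing the
#'   packaged table.
#' @return tibble with columns `alteration`, `mta`, `label`.
#' @export
literature_rules <- function(path = NULL) {
  readr::read_csv(path %||% ncr_extdata("literature_rules.csv"),
                  col_types = "ccc")
}

#' Packaged dose-response encodings for the example cohort
#'
#' Six-point dose-response activity profiles for the four patient
#' variant/drug combinations that were eligible for drug-response testing
#' (patients 3, 4, 5 and 8). The activity values are synthetic - the source
#' assay reports only the qualitative outcome - but their inhibition calls
#' under [call_inhibition()] match the recorded assay results: sorafenib
#' inhibits FLT3 M665T, imatinib inhibits KIT D572G, vemurafenib inhibits
#' BRAF V600E, and lapatinib fails to inhibit ERBB2 T862A co-expressed with
#' KRAS G12S.
#'
#' @param path optional CSV replacing the packaged table.
#' @return tibble with columns `patient_id`, `variant_combo`, `drug`,
#'   `dose_nM`, `activity`, `untreated_activity`.
#' @export
dose_response_fixture <- function(path = NULL) {
  readr::read_csv(path %||% ncr_extdata("dose_response_synthetic.csv"),
                  col_types = readr::cols(
                    patient_id = readr::col_integer(),
                    variant_combo = readr::col_character(),
                    drug = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
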