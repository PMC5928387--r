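#' Normalized oncogenic-activity score
#'
#' Rescales a tested condition's NCR against the wild-type (0%) and
#' known-activating-mutation (100%) anchors:
#' `score = 100 * (vus - wt) / (mt - wt)`. Values below 0 or above 100 are
#' returned as computed, never clamped. The score is invariant under any
#' positive affine transform applied to all three NCRs.
#'
#' @param ncr_vus,ncr_wt,ncr_mt condition-level NCRs of the tested variant,
#'   the wild-type anchor, and the known-mutation anchor (vectorised).
#' @return activity score in percent.
#' @examples
#' normalize_score(2, 1, 3) # 50
#' @export
normalize_score <- function(ncr_vus, ncr_wt, ncr_mt) {
  if (any(ncr_mt == ncr_wt))
    abort("undefined activity scale: ncr_mt equals ncr_wt")
  100 * (ncr_vus - ncr_wt) / (ncr_mt - ncr_wt)
}

#' Two-sample t-test of a variant's well medians against wild-type
#'
#' Two-sided test on the replicate-well median NCRs. Welch's unequal-variance
#' form by default; set `var_equal = TRUE` for the classic pooled form. When
#' both groups have zero variance the p-value is 1 for equal means and 0
#' otherwise.
#'
#' @param vus,wt numeric vectors of well medians (at least 3 each).
#' @param var_equal pool the variances?
#' @return two-sided p-value.
#' @export
ttest_vs_wt <- function(vus, wt, var_equal = FALSE) {
  if (length(vus) < 3 || length(wt) < 3)
    abort("at least 3 well medians are required per group")
  if (stats::var(vus) == 0 && stats::var(wt) == 0)
    return(if (isTRUE(all.equal(mean(vus), mean(wt)))) 1 else 0)
  stats::t.test(vus, wt, var.equal = var_equal)$p.value
}

#' Activity call at the 20% cutoff
#'
#' A variant is called active when its normalized activity score is at least
#' 20% (boundary inclusive). The p-value is carried along for reporting but
#' does not gate the call.
#'
#' @param score activity score in percent (vectorised).
#' @param p_value optional p-value(s), ignored by the call.
#' @param cutoff activity cutoff in percent.
#' @return logical: active?
#' @export
call_activity <- function(score, p_value = NA_real_, cutoff = 20) {
  score >= cutoff
}

dose_ranges <- list(
  sorafenib = c(1, 1500),
  imatinib = c(2.5, 2500),
  vemurafenib = c(2.5, 2500),
  lapatinib = c(2.5, 2500)
)

#' Six-point dose series for an assayed drug
#'
#' Log-uniformly spaced doses between the drug's assayed endpoints
#' (sorafenib 1-1500 nM; imatinib, vemurafenib and lapatinib 2.5-2500 nM),
#' inclusive of both endpoints, so consecutive doses share one ratio.
#'
#' @param drug one of `"sorafenib"`, `"imatinib"`, `"vemurafenib"`,
#'   `"lapatinib"`.
#' @return numeric vector of 6 doses in nM.
#' @export
build_dose_series <- function(drug) {
  rng <- dose_ranges[[drug]]
  if (is.null(rng))
    abort(paste0("unknown drug '", drug, "'; supported drugs: ",
                 paste(names(dose_ranges), collapse = ", ")))
  exp(seq(log(rng[1]), log(rng[2]), length.out = 6))
}

#' Drug-inhibition call from a dose-response series
#'
#' An active variant is called inhibited when its normalized activity drops
#' strictly below the activation cutoff (20 points on the WT/MT scale) at any
#' dose. The alternative reading - activity falling below 20% of the
#' untreated activity - is available as `mode = "relative"`.
#'
#' @param activity_by_dose activity scores (percent) at the six doses.
#' @param untreated_activity activity score without drug; must itself be at
#'   least the cutoff (only active variants are drug-tested).
#' @param mode `"absolute"` (below `cutoff` points) or `"relative"` (below
#'   `cutoff`% of the untreated activity).
#' @param cutoff threshold in percent.
#' @return logical: inhibited?
#' @examples
#' call_inhibition(c(90, 70, 40, 15, 5, 2), 95) # TRUE
#' @export
call_inhibition <- function(activity_by_dose, untreated_activity,
                            mode = c("absolute", "relative"), cutoff = 20) {
  mode <- match.arg(mode)
  if (untreated_activity < cutoff)
    abort(sprintf(
      "untreated activity %.1f%% is below the %s%% cutoff: variant is not active, inhibition is undefined",
      untreated_activity, format(cutoff)))
  threshold <- if (mode == "absolute") cutoff else cutoff / 100 * untreated_activity
  min(activity_by_dose) < threshold
}

#' Score assayed conditions against their anchors
#'
#' Turns condition-level NCRs (from [condition_ncr()]) into activity scores,
#' t-test p-values against the wild-type wells, and activity calls.
#'
#' @param conditions tibble with columns `condition_id`, `mean_ncr`,
#'   `well_medians` (list column), e.g. rows of [condition_ncr()].
#' @param wt,mt `condition_id` of the wild-type and known-mutation anchors.
#' @param cutoff activity cutoff in percent.
#' @param var_equal passed to [ttest_vs_wt()].
#' @return tibble: `condition_id`, `score`, `p_value`, `active` for every
#'   non-anchor condition.
#' @export
score_activity <- function(conditions, wt = "WT", mt = "MT", cutoff = 20,
                           var_equal = FALSE) {
  stopifnot(all(c(wt, mt) %in% conditions$condition_id))
  wt_row <- conditions[conditions$condition_id == wt, ]
  mt_row <- conditions[conditions$condition_id == mt, ]
  rest <- conditions[!conditions$condition_id %in% c(wt, mt), ]
  purrr::map_dfr(seq_len(nrow(rest)), function(i) {
    sc <- normalize_score(rest$mean_ncr[i], wt_row$mean_ncr, mt_row$mean_ncr)
    p <- ttest_vs_wt(rest$well_medians[[i]], wt_row$well_medians[[1]],
                     var_equal = var_equal)
    tibble::tibble(condition_id = rest$condition_id[i], score = sc,
                   p_value = p, active = call_activity(sc, p, cutoff))
  })
}
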