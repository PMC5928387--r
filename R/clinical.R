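#' Median progression-free survival
#'
#' Sample median (mean of the central pair for even counts), reported to one
#' decimal with half-up rounding by default.
#'
#' @param pfs_values numeric vector of PFS in months (non-empty).
#' @param round report to one decimal, rounding half up?
#' @return median PFS in months.
#' @examples
#' median_pfs(c(5.9, 8.4, 5.6, 2.0))               # 5.8
#' median_pfs(c(5.9, 8.4, 5.6, 2.0), round = FALSE) # 5.75
#' @export
median_pfs <- function(pfs_values, round = TRUE) {
  if (length(pfs_values) == 0) abort("median of an empty PFS vector is undefined")
  m <- median(pfs_values)
  if (round) round_half_up(m, 1) else m
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based comparison of a value across groups. The H statistic is
#' computed on mid-ranks with the tie correction `1 - sum(t^3 - t)/(N^3 - N)`
#' and referred to a chi-square distribution with `k - 1` degrees of freedom
#' (the standard large-sample approximation); a Monte Carlo permutation
#' p-value is available via `p_method = "permutation"`. When every value is
#' identical, H = 0 and p = 1.
#'
#' @param data data frame with one row per subject.
#' @param value column of values (e.g. PFS months), unquoted.
#' @param group column defining the groups, unquoted.
#' @param p_method `"chisq"` or `"permutation"`.
#' @param n_perm number of label permutations for the Monte Carlo p-value.
#' @param seed seed for the permutation p-value.
#' @return an object of class `ncr_kw` with fields `h_statistic`, `df`,
#'   `p_value`, `tie_corrected`, `n`, `p_method`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 4), y = c(1:4, 3:6))
#' kruskal_wallis(df, y, g)
#' @export
kruskal_wallis <- function(data, value, group, p_method = c("chisq", "permutation"),
                           n_perm = 10000, seed = 1) {
  p_method <- match.arg(p_method)
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2) abort("at least two groups are required")
  if (any(tabulate(g) == 0)) abort("every group must be non-empty")
  if (length(unique(v)) == 1) {
    res <- list(h_statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                tie_corrected = TRUE, n = length(v), p_method = p_method)
    return(structure(res, class = "ncr_kw"))
  }
  kt <- stats::kruskal.test(v, g)
  h <- unname(kt$statistic)
  p <- if (p_method == "chisq") kt$p.value else {
    withr::with_seed(seed, {
      perm <- replicate(n_perm, {
        unname(stats::kruskal.test(v, sample(g))$statistic)
      })
      (sum(perm >= h - 1e-12) + 1) / (n_perm + 1)
    })
  }
  structure(list(h_statistic = h, df = unname(kt$parameter), p_value = p,
                 tie_corrected = TRUE, n = length(v), p_method = p_method),
            class = "ncr_kw")
}

#' @export
print.ncr_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank test (tie-corrected)\n  H = %.4f, df = %d, p = %.4g (%s)\n",
              x$h_statistic, x$df, x$p_value, x$p_method))
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' Wraps [survival::survfit()]. Censored observations reduce the risk set
#' without producing a step.
#'
#' @param times event/censoring times in months (> 0).
#' @param events logical or 0/1: `TRUE` when a progression/death occurred.
#' @return tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @examples
#' kaplan_meier(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE))
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, survival = fit$surv)
}

#' PFS contrast between prediction groups
#'
#' Joins per-patient predictions onto the cohort, then summarises each
#' prediction group (n, rounded and unrounded median PFS, Kaplan-Meier
#' curve) and tests the group difference with the tie-corrected
#' Kruskal-Wallis test.
#'
#' @param cohort cohort tibble from [load_cohort()] (one or more rows per
#'   patient; PFS and event are per patient).
#' @param predictions tibble from [predict_cohort()].
#' @param ... passed to [kruskal_wallis()].
#' @return an object of class `ncr_survival`: list with `summary` (per-group
#'   tibble with a `km` list column), `test` (`ncr_kw`), and `patients` (one
#'   row per patient with its group). Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' cohort <- load_cohort()
#' fit <- survival_by_prediction(cohort, predict_cohort(cohort))
#' glance(fit)
#' @export
survival_by_prediction <- function(cohort, predictions, ...) {
  patients <- cohort %>%
    dplyr::distinct(.data$patient_id, .data$pfs_months, .data$event) %>%
    dplyr::inner_join(predictions[, c("patient_id", "label")], by = "patient_id")
  summary <- patients %>%
    dplyr::group_by(label = .data$label) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median_pfs = median_pfs(.data$pfs_months),
      median_pfs_unrounded = median_pfs(.data$pfs_months, round = FALSE),
      km = list(kaplan_meier(.data$pfs_months, .data$event)),
      .groups = "drop"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$label)) # positive first
  test <- kruskal_wallis(patients, "pfs_months", "label", ...)
  structure(list(summary = summary, test = test, patients = patients),
            class = "ncr_survival")
}

#' @export
print.ncr_survival <- function(x, ...) {
  cat("PFS by survival-prediction group\n")
  df <- dplyr::select(x$summary, -"km")
  print(as.data.frame(df), row.names = FALSE)
  print(x$test)
  invisible(x)
}

#' Write the survival report as JSON
#'
#' Per-group n, medians and Kaplan-Meier arrays plus the Kruskal-Wallis
#' result, in a plain machine-readable layout.
#'
#' @param fit an `ncr_survival` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_survival_json <- function(fit, path) {
  rlang::check_installed("jsonlite")
  groups <- purrr::map(seq_len(nrow(fit$summary)), function(i) {
    s <- fit$summary[i, ]
    list(label = s$label, n = s$n, median_pfs = s$median_pfs,
         median_pfs_unrounded = s$median_pfs_unrounded,
         km_times = s$km[[1]]$time, km_survival = s$km[[1]]$survival)
  })
  obj <- list(groups = groups,
              kruskal_wallis = list(h_statistic = fit$test$h_statistic,
                                    df = fit$test$df,
                                    p_value = fit$test$p_value,
                                    tie_corrected = fit$test$tie_corrected))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
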