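#' Tidy a Kruskal-Wallis result
#'
#' @param x an `ncr_kw` object from [kruskal_wallis()].
#' @param ... unused.
#' @return one-row tibble: `h_statistic`, `df`, `p_value`, `n`, `p_method`.
#' @method tidy ncr_kw
#' @export
tidy.ncr_kw <- function(x, ...) {
  tibble::tibble(h_statistic = x$h_statistic, df = x$df, p_value = x$p_value,
                 n = x$n, p_method = x$p_method)
}

#' @rdname tidy.ncr_kw
#' @method glance ncr_kw
#' @export
glance.ncr_kw <- tidy.ncr_kw

#' Tidy a survival-by-prediction fit
#'
#' @param x an `ncr_survival` object from [survival_by_prediction()].
#' @param ... unused.
#' @return per-group tibble (`label`, `n`, `median_pfs`,
#'   `median_pfs_unrounded`).
#' @method tidy ncr_survival
#' @export
tidy.ncr_survival <- function(x, ...) {
  dplyr::select(x$summary, -"km")
}

#' @rdname tidy.ncr_survival
#' @return for `glance()`: one-row tibble with both group medians and the
#'   Kruskal-Wallis H and p.
#' @method glance ncr_survival
#' @export
glance.ncr_survival <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_positive = sum(s$n[s$label == "positive"]),
    n_negative = sum(s$n[s$label == "negative"]),
    median_pfs_positive = s$median_pfs[s$label == "positive"][1],
    median_pfs_negative = s$median_pfs[s$label == "negative"][1],
    h_statistic = x$test$h_statistic,
    p_value = x$test$p_value
  )
}
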