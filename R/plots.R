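#' Bar chart of normalized activity scores
#'
#' One bar per condition with the activity cutoff as a dashed line; the
#' layout used to report per-variant oncogenic activity against the WT (0%)
#' and known-mutation (100%) anchors.
#'
#' @param activity tibble from [score_activity()].
#' @param cutoff cutoff line position, percent.
#' @return a ggplot object.
#' @export
plot_activity_scores <- function(activity, cutoff = 20) {
  ggplot2::ggplot(activity,
                  ggplot2::aes(x = stats::reorder(.data$condition_id, -.data$score),
                               y = .data$score, fill = .data$active)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c23b22", `FALSE` = "#7f7f7f"),
                               name = "active") +
    ggplot2::labs(x = NULL, y = "oncogenic activity (% of known mutation)") +
    ggplot2::theme_minimal()
}

#' Dose-response curves with the inhibition cutoff
#'
#' @param responses long tibble (`variant_combo`, `drug`, `dose_nM`,
#'   `activity`), e.g. [dose_response_fixture()].
#' @param cutoff inhibition cutoff, percent.
#' @return a ggplot object.
#' @export
plot_dose_response <- function(responses, cutoff = 20) {
  ggplot2::ggplot(responses,
                  ggplot2::aes(x = .data$dose_nM, y = .data$activity,
                               colour = paste(.data$variant_combo, .data$drug,
                                              sep = " / "))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "oncogenic activity (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by prediction group
#'
#' @param object an `ncr_survival` object from [survival_by_prediction()].
#' @param ... unused.
#' @return a ggplot object with one step curve per prediction group.
#' @method autoplot ncr_survival
#' @export
autoplot.ncr_survival <- function(object, ...) {
  km <- object$summary %>%
    dplyr::mutate(km = purrr::map(.data$km, function(k) {
      dplyr::bind_rows(tibble::tibble(time = 0, n_risk = NA_real_,
                                      n_event = NA_real_, n_censor = NA_real_,
                                      survival = 1), k)
    })) %>%
    tidyr::unnest("km")
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$label)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "progression-free survival",
                  colour = "prediction") +
    ggplot2::theme_minimal()
}

#' Display a simulated well
#'
#' Raster view of one channel of a well, mainly for vignettes and debugging.
#'
#' @param well one element of `generate_plate()$wells`.
#' @param channel `"nuclear"` or `"reporter"`.
#' @return a ggplot object.
#' @export
plot_well <- function(well, channel = c("reporter", "nuclear")) {
  channel <- match.arg(channel)
  m <- well[[channel]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$intensity <- as.numeric(m)[(df$col - 1L) * nrow(m) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(well$well_id, channel), x = NULL, y = NULL) +
    ggplot2::theme_void()
}
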