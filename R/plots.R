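#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of standardized mean changes
#'
#' Per-study effects with 95% CIs, point area proportional to the
#' fixed-effect weight, and the pooled summary as a diamond at the bottom;
#' the dashed zero line is guessing-level performance.
#'
#' @param object A `meta_result` from [fixed_effect_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  studies <- object$per_study
  rows <- dplyr::bind_rows(
    dplyr::transmute(studies, label = .data$study_id, effect = .data$smc,
                     ci_lower = .data$ci_lower, ci_upper = .data$ci_upper,
                     weight = .data$weight, type = "study"),
    tibble::tibble(label = "FE summary", effect = object$summary_effect,
                   ci_lower = object$ci_lower, ci_upper = object$ci_upper,
                   weight = 1, type = "summary"))
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$effect, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight,
                                     shape = .data$type)) +
    ggplot2::scale_shape_manual(values = c(study = 15, summary = 18),
                                guide = "none") +
    ggplot2::scale_size_area(max_size = 5, guide = "none") +
    ggplot2::labs(x = "Standardized mean change (observed - predicted)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Observed versus predicted source errors with within-subject CIs
#'
#' Mean observed and predicted source-error counts per retrieval task and
#' load condition; error bars are 95% Cousineau-Morey within-subject
#' confidence intervals over the observed/predicted repeated measure.
#'
#' @param predictions A predictions tibble from [guessing_predictions()] or
#'   a `recall_analysis` object.
#' @return A ggplot object.
#' @export
plot_source_errors <- function(predictions) {
  if (inherits(predictions, "recall_analysis")) {
    predictions <- predictions$predictions
  }
  d <- predictions[!is.na(predictions$predicted_source_errors), ]
  cells <- d |>
    dplyr::group_by(.data$task, .data$condition) |>
    dplyr::group_split()
  rows <- purrr::map(cells, function(cell) {
    ci <- within_subject_ci(cbind(observed = cell$observed_source_errors,
                                  predicted = cell$predicted_source_errors))
    names(ci)[names(ci) == "condition"] <- "data_type"
    ci$task <- cell$task[1]
    ci$condition <- cell$condition[1]
    ci
  }) |> purrr::list_rbind()
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$condition, y = .data$mean,
                                     fill = .data$data_type)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9),
                      width = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(group = .data$data_type,
                                        ymin = .data$mean - .data$ci_half,
                                        ymax = .data$mean + .data$ci_half),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "Concurrent load condition", y = "Source errors",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_source_errors
#' @param object A `recall_analysis` object.
#' @param ... Unused.
#' @method autoplot recall_analysis
#' @export
autoplot.recall_analysis <- function(object, ...) {
  plot_source_errors(object)
}
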