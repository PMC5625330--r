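#' Standardized mean change for an observed-versus-predicted contrast
#'
#' Per-study effect for the forest summaries: the mean of the
#' participant-level differences divided by their standard deviation, with
#' the change-score sampling variance `1/n + smc^2 / (2n)` (Becker's
#' formulation), whose inverse serves as the fixed-effect weight.
#'
#' @param observed,predicted Per-participant counts (equal length, n >= 3).
#' @param study_id Identifier carried into the forest output.
#' @return A one-row tibble of class `smc_result`: `study_id`, `smc`,
#'   `var_smc`, `n`.
#' @export
smc_effect <- function(observed, predicted, study_id = "study") {
  if (length(observed) != length(predicted)) {
    abort_domain("`observed` and `predicted` must have equal length.")
  }
  keep <- stats::complete.cases(observed, predicted)
  diffs <- (observed - predicted)[keep]
  n <- length(diffs)
  if (n < 3) abort_domain("need at least 3 paired observations.")
  sdd <- stats::sd(diffs)
  if (sdd == 0) abort_domain("zero standard deviation of differences; SMC undefined.")
  smc <- mean(diffs) / sdd
  out <- tibble::tibble(study_id = as.character(study_id), smc = smc,
                        var_smc = 1 / n + smc^2 / (2 * n), n = n)
  structure(out, class = c("smc_result", class(out)))
}

#' Fixed-effect summary of standardized mean changes
#'
#' Inverse-variance weighted pooling: summary effect
#' `sum(w * smc) / sum(w)` with `w = 1/var_smc`, standard error
#' `sqrt(1/sum(w))` and a 95% normal-theory confidence interval. Per-study
#' normalized weights are emitted for forest-plot output.
#'
#' @param studies A tibble of [smc_effect()] rows (or anything with
#'   `study_id`, `smc`, `var_smc`), or a list of such tibbles.
#' @return An object of class `meta_result` with `summary_effect`,
#'   `se_summary`, `ci_lower`, `ci_upper` and `per_study` (the input plus
#'   `weight`, normalized to sum to 1).
#' @export
fixed_effect_summary <- function(studies) {
  if (is.list(studies) && !is.data.frame(studies)) {
    studies <- purrr::list_rbind(purrr::map(studies, tibble::as_tibble))
  }
  studies <- tibble::as_tibble(studies)
  if (nrow(studies) < 1) abort_domain("need at least one study.")
  if (any(studies$var_smc <= 0)) abort_domain("`var_smc` must be > 0.")
  w <- 1 / studies$var_smc
  summary_effect <- sum(w * studies$smc) / sum(w)
  se <- sqrt(1 / sum(w))
  per_study <- dplyr::mutate(studies,
                             weight = w / sum(w),
                             ci_lower = .data$smc - 1.96 * sqrt(.data$var_smc),
                             ci_upper = .data$smc + 1.96 * sqrt(.data$var_smc))
  structure(list(
    summary_effect = summary_effect,
    se_summary = se,
    ci_lower = summary_effect - 1.96 * se,
    ci_upper = summary_effect + 1.96 * se,
    per_study = per_study),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effect summary: %.3f [%.3f, %.3f] over %d studies\n",
              x$summary_effect, x$ci_lower, x$ci_upper, nrow(x$per_study)))
  invisible(x)
}
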