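#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for fitted result objects
#'
#' broom-style one-row (or one-row-per-term) tibble summaries of the
#' pipeline's result objects.
#'
#' @param x A `paired_test`, `bf_result`, `mixed_anova`, `guessing_ratio`
#'   or `meta_result` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy paired_test
#' @export
tidy.paired_test <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, statistic = x$t,
                 df = x$df, p.value = x$p_one_tailed, d_av = x$d_av,
                 d_method = x$d_method, degenerate = x$degenerate)
}

#' @rdname tidiers
#' @method tidy bf_result
#' @export
tidy.bf_result <- function(x, ...) {
  tibble::tibble(bf10 = x$bf10, bf10_numeric = x$bf10_numeric,
                 data_mean = x$data_mean, data_se = x$data_se,
                 prior_sd = x$prior_sd)
}

#' @rdname tidiers
#' @method tidy mixed_anova
#' @export
tidy.mixed_anova <- function(x, ...) {
  x$table
}

#' @rdname tidiers
#' @method tidy guessing_ratio
#' @export
tidy.guessing_ratio <- function(x, ...) {
  tibble::tibble(task = x$task, ratio = x$ratio, n_reps = x$n_reps,
                 n_degenerate_reps = x$n_degenerate_reps)
}

#' @rdname tidiers
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  x$per_study
}

#' @rdname tidiers
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(summary_effect = x$summary_effect, se = x$se_summary,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 n_studies = nrow(x$per_study))
}

#' @rdname tidiers
#' @method glance paired_test
#' @export
glance.paired_test <- function(x, ...) tidy(x)

#' @rdname tidiers
#' @method glance bf_result
#' @export
glance.bf_result <- function(x, ...) tidy(x)
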