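#' One-tailed paired t test of observed versus predicted source errors
#'
#' Standard paired t on `observed - predicted`, one-tailed in the direction
#' observed > predicted (the step-down test of the observation-inflation
#' hypothesis). The effect size `d_av` is the mean difference divided by the
#' average of the two condition standard deviations; `d_z` (mean difference
#' over the SD of the differences) is available as an alternative.
#'
#' If the differences have zero variance the result is flagged: `t` is
#' `0` when the mean difference is also zero (p = 0.5) and `±Inf`
#' otherwise; `d_av` is still computed from the condition SDs when those
#' are nonzero.
#'
#' @param observed,predicted Per-participant counts (equal length, n >= 3).
#' @param d_method `"d_av"` (default) or `"d_z"`.
#' @return An object of class `paired_test` with fields `n`, `mean_diff`,
#'   `t`, `df`, `p_one_tailed`, `d_av`, `d_method`, `degenerate`.
#' @export
paired_t_onetailed <- function(observed, predicted, d_method = c("d_av", "d_z")) {
  d_method <- rlang::arg_match(d_method)
  if (length(observed) != length(predicted)) {
    abort_domain("`observed` and `predicted` must have equal length.")
  }
  keep <- stats::complete.cases(observed, predicted)
  observed <- observed[keep]
  predicted <- predicted[keep]
  n <- length(observed)
  if (n < 3) abort_domain("need at least 3 paired observations.")
  diffs <- observed - predicted
  mean_diff <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  degenerate <- sd_diff == 0
  if (!degenerate) {
    tt <- stats::t.test(observed, predicted, paired = TRUE, alternative = "greater")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    t_stat <- if (mean_diff == 0) 0 else sign(mean_diff) * Inf
    p <- if (mean_diff == 0) 0.5 else if (mean_diff > 0) 0 else 1
  }
  denom <- switch(d_method,
                  d_av = (stats::sd(observed) + stats::sd(predicted)) / 2,
                  d_z = sd_diff)
  d <- if (denom > 0) mean_diff / denom else if (mean_diff == 0) 0 else NA_real_
  structure(list(n = n, mean_diff = mean_diff, t = t_stat, df = n - 1L,
                 p_one_tailed = p, d_av = d, d_method = d_method,
                 sd_observed = stats::sd(observed),
                 sd_predicted = stats::sd(predicted),
                 degenerate = degenerate),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired one-tailed t (observed > predicted): t(%d) = %.3f, p = %.4g, %s = %.3f, n = %d\n",
              x$df, x$t, x$p_one_tailed, x$d_method, x$d_av, x$n))
  invisible(x)
}

#' Cousineau-Morey within-subject confidence intervals
#'
#' Subject-centers a participants-by-conditions matrix (removing the
#' between-subject offsets that do not enter repeated-measures contrasts),
#' restores the grand mean, applies the Morey bias correction
#' `sqrt(C / (C - 1))`, and returns t-based per-condition half-widths.
#'
#' @param mat Numeric matrix or data frame, participants in rows,
#'   conditions in columns; no missing cells.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with `condition`, `mean`, `ci_half`.
#' @export
within_subject_ci <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) abort_domain("need at least 2 conditions for within-subject CIs.")
  if (anyNA(mat)) abort_domain("missing cells are not supported.")
  n <- nrow(mat)
  C <- ncol(mat)
  centered <- mat - rowMeans(mat) + mean(mat)
  correction <- sqrt(C / (C - 1))
  half <- apply(centered, 2, stats::sd) * correction / sqrt(n) *
    stats::qt(1 - (1 - conf) / 2, df = n - 1)
  tibble::tibble(
    condition = colnames(mat) %||% paste0("V", seq_len(C)),
    mean = colMeans(mat),
    ci_half = unname(half))
}

#' Two-way mixed ANOVA (one between-, one within-subject factor)
#'
#' Classical sums-of-squares decomposition for the balanced-within mixed
#' design used throughout the pipeline (e.g. Task between subjects crossed
#' with Data type within subjects): the between main effect is tested
#' against subjects-within-groups, the within main effect and the
#' interaction against the subject-by-within error term. Fitted via
#' [stats::aov()] with an `Error(subject)` stratum.
#'
#' @param data Long-format data frame.
#' @param dv,subject,between,within Column names (strings) of the value,
#'   subject identifier, between-subjects factor and within-subjects factor.
#' @return An object of class `mixed_anova` whose `table` is a tibble with
#'   one row per term: `term`, `df`, `df_error`, `ss`, `ms`, `mse`,
#'   `statistic` (F), `p.value`, `pes` (partial eta squared).
#' @export
mixed_anova <- function(data, dv, subject, between, within) {
  d <- tibble::tibble(
    y = as.numeric(data[[dv]]),
    s = factor(data[[subject]]),
    b = factor(data[[between]]),
    w = factor(data[[within]]))
  if (anyNA(d$y)) abort_domain("missing values in the response; use listwise-complete data.")
  if (nlevels(d$b) < 2) abort_domain("the between-subjects factor needs >= 2 levels.")
  if (nlevels(d$w) < 2) abort_domain("the within-subjects factor needs >= 2 levels.")
  per_subj <- table(d$s, d$w)
  if (any(per_subj != 1)) {
    abort_domain(paste0("unbalanced within-subject cells: every subject needs ",
                        "exactly one observation per within level ",
                        "(aggregate or handle listwise first)."))
  }
  sb <- table(d$s, d$b)
  if (any(rowSums(sb > 0) != 1)) {
    abort_domain("each subject must belong to exactly one between-subjects group.")
  }

  fit <- stats::aov(y ~ b * w + Error(s), data = d)
  sm <- summary(fit)
  parse_stratum <- function(tab, stratum) {
    tab <- tab[[1]]
    terms <- trimws(rownames(tab))
    tibble::tibble(term = terms, df = tab$Df, ss = tab$`Sum Sq`,
                   ms = tab$`Mean Sq`,
                   statistic = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
                   p.value = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_,
                   stratum = stratum)
  }
  strata <- purrr::imap(sm, parse_stratum) |> purrr::list_rbind()
  add_effect_meta <- function(strata) {
    out <- list()
    for (st in unique(strata$stratum)) {
      rows <- strata[strata$stratum == st, ]
      err <- rows[rows$term == "Residuals", ]
      eff <- rows[rows$term != "Residuals", ]
      if (nrow(eff) == 0) next
      eff$df_error <- err$df
      eff$mse <- err$ms
      eff$pes <- eff$ss / (eff$ss + err$ss)
      out[[st]] <- eff
    }
    purrr::list_rbind(out)
  }
  table <- add_effect_meta(strata)
  rename_map <- c(b = between, w = within, `b:w` = paste0(between, ":", within))
  table$term <- unname(rename_map[table$term])
  # a zero-SS effect is a zero effect even when the error term is also zero
  zero <- table$ss == 0
  table$statistic[zero] <- 0
  table$p.value[zero] <- 1
  table$pes[zero] <- 0
  table <- table[c("term", "df", "df_error", "ss", "ms", "mse",
                   "statistic", "p.value", "pes")]
  structure(list(table = table, dv = dv, between = between, within = within,
                 n_subjects = nlevels(d$s)),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA: %s ~ %s (between) x %s (within), %d subjects\n",
              x$dv, x$between, x$within, x$n_subjects))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}
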