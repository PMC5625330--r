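#' Run the full observed-versus-predicted analysis
#'
#' Orchestrates the pipeline on one experiment: reads (or accepts) the
#' generation and recall tables, builds frequency norms from all generation
#' events, filters pair duplicates, codes every reported action, computes
#' per-cell Monte Carlo guessing predictions, and — per retrieval task and
#' load condition — the one-tailed observed > predicted paired test with
#' `d_av` and the standardized mean change for downstream meta-analysis.
#' When both retrieval tasks are present, a Task (between) x Data type
#' (within) mixed ANOVA is fitted on the no-load cells.
#'
#' @param generation,recall Paths to CSV files or event data frames.
#' @param mode Recall mode used for the report/withhold filter.
#' @param n_reps Monte Carlo replicates per participant cell.
#' @param seed Integer seed for the guessing simulation.
#' @param study_id Label attached to the emitted effects.
#' @param anova,ttests,effects Analysis toggles.
#' @return An object of class `recall_analysis`: a list with
#'   `counts_table` (per-task/condition mean and SD of correct recalls,
#'   source errors and intrusions), `counts`, `predictions`, `tests`,
#'   `effects`, `anova`, `dup_summary` and a `manifest` (seed, settings,
#'   package version, input hash).
#' @export
run_analysis <- function(generation, recall, mode = c("free_report", "extended"),
                         n_reps = 500, seed = 1L, study_id = "study",
                         anova = TRUE, ttests = TRUE, effects = TRUE) {
  mode <- rlang::arg_match(mode)
  if (is.character(generation)) generation <- read_generation_events(generation)
  if (is.character(recall)) recall <- read_recall_events(recall)
  generation <- as_generation_events(generation)
  recall <- as_recall_events(recall)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)),
                   class = "guessnull_pipeline_error", parent = e)
    })
  }

  norms <- stage("frequency_norms", build_frequency_norms(generation))
  prep <- stage("prepare_encoding", prepare_encoding(generation))
  coded <- stage("code_recall", code_recall(recall, prep, mode))
  predictions <- stage("guessing_predictions",
                       guessing_predictions(coded, prep, norms,
                                            n_reps = n_reps, seed = seed))

  counts_table <- coded$counts |>
    tidyr::pivot_longer(c("n_correct", "n_source_errors", "n_intrusions"),
                        names_to = "category", values_to = "count") |>
    dplyr::mutate(category = dplyr::recode(.data$category,
                                           n_correct = "correct",
                                           n_source_errors = "source_error",
                                           n_intrusions = "intrusion")) |>
    dplyr::group_by(.data$task, .data$condition, .data$category) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$count),
                     sd = stats::sd(.data$count), .groups = "drop")

  cells <- predictions |>
    dplyr::filter(!is.na(.data$predicted_source_errors)) |>
    dplyr::group_by(.data$task, .data$condition)
  tests <- NULL
  effect_rows <- NULL
  if (ttests || effects) {
    per_cell <- cells |>
      dplyr::group_split()
    summaries <- purrr::map(per_cell, function(d) {
      key <- tibble::tibble(task = d$task[1], condition = d$condition[1])
      tt <- if (ttests && nrow(d) >= 3)
        paired_t_onetailed(d$observed_source_errors, d$predicted_source_errors)
      ef <- if (effects && nrow(d) >= 3 &&
                stats::sd(d$observed_source_errors - d$predicted_source_errors) > 0)
        smc_effect(d$observed_source_errors, d$predicted_source_errors,
                   study_id = study_id)
      list(key = key, test = tt, effect = ef)
    })
    if (ttests) {
      tests <- purrr::map(summaries, function(s) {
        if (is.null(s$test)) return(NULL)
        dplyr::bind_cols(s$key, tidy(s$test))
      }) |> purrr::list_rbind()
    }
    if (effects) {
      effect_rows <- purrr::map(summaries, function(s) {
        if (is.null(s$effect)) return(NULL)
        dplyr::bind_cols(s$key, tibble::as_tibble(s$effect))
      }) |> purrr::list_rbind()
    }
  }

  anova_fit <- NULL
  if (anova && dplyr::n_distinct(predictions$task) == 2) {
    long <- predictions |>
      dplyr::filter(.data$condition == "none",
                    !is.na(.data$predicted_source_errors)) |>
      tidyr::pivot_longer(c("observed_source_errors", "predicted_source_errors"),
                          names_to = "data_type", values_to = "source_errors") |>
      dplyr::mutate(data_type = sub("_source_errors$", "", .data$data_type))
    anova_fit <- stage("mixed_anova",
                       mixed_anova(long, dv = "source_errors",
                                   subject = "participant_id",
                                   between = "task", within = "data_type"))
  }

  manifest <- list(
    package = "guessnull",
    version = as.character(utils::packageVersion("guessnull")),
    seed = as.integer(seed), n_reps = as.integer(n_reps), mode = mode,
    study_id = study_id,
    n_participants = dplyr::n_distinct(recall$participant_id),
    n_pairs = dplyr::n_distinct(generation$pair_id),
    input_hash = rlang::hash(list(generation, recall)))

  structure(list(counts_table = counts_table, counts = coded$counts,
                 labels = coded$labels, predictions = predictions,
                 tests = tests, effects = effect_rows, anova = anova_fit,
                 dup_summary = prep$dup_summary, norms = norms,
                 manifest = manifest),
            class = "recall_analysis")
}

#' @export
print.recall_analysis <- function(x, ...) {
  cat(sprintf("<recall_analysis> %d participants, %d pairs, seed %d, %d reps\n",
              x$manifest$n_participants, x$manifest$n_pairs,
              x$manifest$seed, x$manifest$n_reps))
  cat("\nMean reported counts (per task x condition):\n")
  print(as.data.frame(x$counts_table), digits = 3)
  if (!is.null(x$tests)) {
    cat("\nObserved vs predicted source errors (one-tailed paired t):\n")
    print(as.data.frame(x$tests), digits = 3)
  }
  invisible(x)
}

#' Write a `recall_analysis` bundle to disk
#'
#' Emits `counts.csv`, `predictions.csv`, `tests.csv`, `effects.csv`,
#' `anova.csv` (when fitted) and `manifest.json` into `dir`. Outputs are
#' byte-for-byte reproducible for a fixed seed and inputs.
#'
#' @param analysis A `recall_analysis` object.
#' @param dir Output directory (created if needed).
#' @export
write_analysis_bundle <- function(analysis, dir) {
  stopifnot(inherits(analysis, "recall_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(analysis$counts, file.path(dir, "counts.csv"))
  readr::write_csv(analysis$predictions, file.path(dir, "predictions.csv"))
  if (!is.null(analysis$tests))
    readr::write_csv(analysis$tests, file.path(dir, "tests.csv"))
  if (!is.null(analysis$effects))
    readr::write_csv(analysis$effects, file.path(dir, "effects.csv"))
  if (!is.null(analysis$anova))
    readr::write_csv(analysis$anova$table, file.path(dir, "anova.csv"))
  write_norms_json(analysis$norms, file.path(dir, "norms.json"))
  jsonlite::write_json(analysis$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pool effects across experiments and compute replication Bayes factors
#'
#' Fixed-effect standardized-mean-change summaries per task/condition group
#' over a set of per-experiment effect tables, plus half-normal-prior Bayes
#' factors for configured prior/data pairs, with forest-plot data (per-study
#' rows and summary rows) emitted as a tibble.
#'
#' @param effects A tibble of effects (as produced by [run_analysis()]),
#'   a list of such tibbles, or paths to `effects.csv` files. Must carry
#'   `study_id`, `smc`, `var_smc`, `n` plus grouping columns.
#' @param group Grouping columns for pooling (default `task`).
#' @param priors Optional tibble of Bayes-factor specifications with
#'   columns `label`, `data_mean`, `data_se`, `prior_sd`.
#' @return An object of class `meta_report`: list with `meta` (named list
#'   of `meta_result`), `forest` (tibble of study and summary rows) and
#'   `bf` (tibble, when priors are given).
#' @export
run_meta <- function(effects, group = "task", priors = NULL) {
  if (is.character(effects)) {
    effects <- purrr::map(effects, ~ readr::read_csv(.x, show_col_types = FALSE))
  }
  if (is.list(effects) && !is.data.frame(effects)) {
    effects <- purrr::list_rbind(purrr::map(effects, tibble::as_tibble))
  }
  effects <- tibble::as_tibble(effects)
  need <- c(group, "study_id", "smc", "var_smc")
  missing <- setdiff(need, names(effects))
  if (length(missing) > 0) {
    abort_schema(sprintf("effects table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }

  groups <- dplyr::group_split(dplyr::group_by(effects,
                                               dplyr::across(dplyr::all_of(group))))
  metas <- list()
  forest <- list()
  for (d in groups) {
    key <- d[1, group, drop = FALSE]
    label <- paste(unlist(key), collapse = "/")
    m <- fixed_effect_summary(d)
    metas[[label]] <- m
    forest[[length(forest) + 1L]] <- dplyr::bind_cols(
      key[rep(1, nrow(m$per_study) + 1), , drop = FALSE],
      dplyr::bind_rows(
        m$per_study |>
          dplyr::transmute(row_type = "study", study_id = .data$study_id,
                           effect = .data$smc, ci_lower = .data$ci_lower,
                           ci_upper = .data$ci_upper, weight = .data$weight),
        tibble::tibble(row_type = "summary", study_id = "FE summary",
                       effect = m$summary_effect, ci_lower = m$ci_lower,
                       ci_upper = m$ci_upper, weight = 1)))
  }
  forest <- purrr::list_rbind(forest)

  bf <- NULL
  if (!is.null(priors)) {
    priors <- tibble::as_tibble(priors)
    bf <- purrr::pmap(priors[c("data_mean", "data_se", "prior_sd")], dienes_bf) |>
      purrr::map(tidy) |>
      purrr::list_rbind()
    bf <- dplyr::bind_cols(priors["label"], bf)
  }
  structure(list(meta = metas, forest = forest, bf = bf),
            class = "meta_report")
}

#' @export
print.meta_report <- function(x, ...) {
  for (label in names(x$meta)) {
    cat(label, ": ", sep = "")
    print(x$meta[[label]])
  }
  if (!is.null(x$bf)) {
    cat("\nReplication Bayes factors:\n")
    print(as.data.frame(x$bf), digits = 3)
  }
  invisible(x)
}
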