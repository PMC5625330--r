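#' Monte Carlo guessing ratio for one participant cell
#'
#' Simulates the test phase of one participant under the guessing null: per
#' replicate, for each shape the participant's reported count of actions is
#' drawn from the shape's frequency norms by weighted sampling without
#' replacement, each sampled action is classified as matching the
#' participant's own encoding set, the partner's set, or neither (novel),
#' and counts are summed across shapes. Source errors are
#' `matched_partner` draws in the recall-own task and `matched_self` draws
#' in the recall-partner task. The per-replicate ratio is
#' `source errors / (source errors + novel)`; replicates with a 0/0
#' denominator are excluded from the mean (the ratio estimates the
#' conditional probability that a guessed *error* is a source error) and
#' their number is reported.
#'
#' @param recall_counts Reported actions per shape: a tibble with
#'   `shape_id`, `n_reported`, or a named integer vector. Counts exceeding a
#'   shape's support are truncated to the support size with a warning.
#' @param own_set,partner_set Duplicate-filtered encoding sets
#'   (tibbles with `shape_id`, `action_code`).
#' @param norms A `frequency_norms` tibble.
#' @param task `"recall_own"` or `"recall_partner"`.
#' @param n_reps Number of Monte Carlo replicates (default 500).
#' @param seed Optional integer seed for a private RNG stream.
#' @return An object of class `guessing_ratio`: a list with `ratio` (mean
#'   over non-degenerate replicates; `NA` if all replicates are
#'   degenerate), `n_reps`, `n_degenerate_reps`, `task`, `seed` and
#'   `rep_outcomes` (per-replicate matched_self / matched_partner / novel /
#'   source-error counts).
#' @export
simulate_guessing_ratio <- function(recall_counts, own_set, partner_set, norms,
                                    task = c("recall_own", "recall_partner"),
                                    n_reps = 500, seed = NULL) {
  task <- rlang::arg_match(task)
  if (is.numeric(recall_counts) && !is.null(names(recall_counts))) {
    recall_counts <- tibble::tibble(shape_id = names(recall_counts),
                                    n_reported = as.integer(recall_counts))
  }
  stopifnot(all(c("shape_id", "n_reported") %in% names(recall_counts)))
  counts <- recall_counts[recall_counts$n_reported > 0, ]

  own_keys <- action_key(own_set$shape_id, own_set$action_code)
  partner_keys <- action_key(partner_set$shape_id, partner_set$action_code)

  shape_draws <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    sid <- counts$shape_id[i]
    p <- shape_norms(norms, sid)
    k <- counts$n_reported[i]
    if (k > length(p)) {
      rlang::warn(sprintf(
        "reported count %d exceeds the support size %d for shape \"%s\"; truncating.",
        k, length(p), sid))
      k <- length(p)
    }
    keys <- action_key(sid, names(p))
    category <- ifelse(keys %in% own_keys, 1L,
                       ifelse(keys %in% partner_keys, 2L, 3L))
    shape_draws[[i]] <- list(p = unname(p), category = category, k = k)
  }

  acc <- matrix(0L, nrow = 3, ncol = n_reps)
  with_seed_if(seed, {
    for (sd_ in shape_draws) {
      n_sup <- length(sd_$p)
      if (sd_$k == n_sup) {
        # exhaustive draw: outcome is deterministic
        acc <- acc + tabulate(sd_$category, 3L)
      } else {
        for (r in seq_len(n_reps)) {
          idx <- sample.int(n_sup, sd_$k, prob = sd_$p)
          acc[, r] <- acc[, r] + tabulate(sd_$category[idx], 3L)
        }
      }
    }
  })

  src <- if (task == "recall_own") acc[2, ] else acc[1, ]
  nov <- acc[3, ]
  valid <- (src + nov) > 0
  ratio <- if (any(valid)) mean(src[valid] / (src[valid] + nov[valid])) else NA_real_
  structure(list(
    ratio = ratio,
    n_reps = n_reps,
    n_degenerate_reps = sum(!valid),
    task = task,
    seed = seed,
    rep_outcomes = tibble::tibble(
      n_matched_self = acc[1, ], n_matched_partner = acc[2, ],
      n_novel = nov, n_source_errors = src)),
    class = "guessing_ratio")
}

#' @export
print.guessing_ratio <- function(x, ...) {
  cat(sprintf("<guessing_ratio> task = %s, ratio = %s (%d reps, %d degenerate)\n",
              x$task, format(x$ratio, digits = 4), x$n_reps, x$n_degenerate_reps))
  invisible(x)
}

#' Predicted source errors from the guessing ratio
#'
#' Scales a participant's observed intrusion count (reported actions that
#' were never generated at encoding, and therefore must be guesses) by the
#' odds implied by the simulated ratio:
#' `predicted = intrusions * ratio / (1 - ratio)`.
#'
#' @param ratio Simulated guessing ratio in `[0, 1)`.
#' @param n_intrusions_observed Observed intrusion count(s).
#' @return Predicted source-error count(s), on the same scale as the
#'   observed counts.
#' @export
predict_source_errors <- function(ratio, n_intrusions_observed) {
  if (any(!is.na(ratio) & (ratio < 0 | ratio >= 1))) {
    abort_domain("`ratio` must lie in [0, 1); a ratio of 1 must be flagged upstream.")
  }
  if (any(n_intrusions_observed < 0)) abort_domain("intrusion counts must be >= 0.")
  n_intrusions_observed * ratio / (1 - ratio)
}

#' Guessing-null predictions for every participant cell
#'
#' Runs [simulate_guessing_ratio()] for each participant x task x condition
#' cell of a coded dataset and converts the ratios into predicted
#' source-error counts via [predict_source_errors()]. Cells where all
#' replicates are degenerate (or where the ratio reaches 1, leaving the
#' odds undefined) are flagged: degenerate cells predict 0, ratio-1 cells
#' predict `NA`, each with a warning.
#'
#' @param coded Result of [code_recall()].
#' @param prep Result of [prepare_encoding()].
#' @param norms A `frequency_norms` tibble, normally from
#'   [build_frequency_norms()] on *all* generation events.
#' @param n_reps Monte Carlo replicates per cell (default 500).
#' @param seed Integer seed; all cells draw from one seeded stream in a
#'   deterministic cell order, so identical inputs and seed give identical
#'   predictions.
#' @return A tibble with one row per cell: `participant_id`, `task`,
#'   `condition`, `ratio`, `n_reps`, `n_degenerate_reps`,
#'   `n_intrusions_observed`, `observed_source_errors`,
#'   `predicted_source_errors`, `flagged`, `seed`.
#' @export
guessing_predictions <- function(coded, prep, norms, n_reps = 500, seed = 1L) {
  counts <- dplyr::arrange(coded$counts, .data$participant_id, .data$task,
                           .data$condition)
  labels <- coded$labels
  reported <- labels[labels$report_status == "reported" &
                       labels$label != "excluded_duplicate", ]

  run_cell <- function(pid, task, condition) {
    shapes <- prep$conditions$shape_id[prep$conditions$participant_id == pid &
                                         prep$conditions$condition == condition]
    rep_i <- reported[reported$participant_id == pid &
                        reported$shape_id %in% shapes, ]
    per_shape <- tibble::tibble(shape_id = shapes) |>
      dplyr::left_join(dplyr::count(rep_i, .data$shape_id, name = "n_reported"),
                       by = "shape_id") |>
      dplyr::mutate(n_reported = tidyr::replace_na(.data$n_reported, 0L))
    info <- prep$roster[prep$roster$participant_id == pid, ]
    own <- prep$filtered[prep$filtered$participant_id == pid, ]
    partner <- prep$filtered[prep$filtered$participant_id == info$partner_id, ]
    simulate_guessing_ratio(per_shape, own, partner, norms, task,
                            n_reps = n_reps, seed = NULL)
  }

  sims <- with_seed_if(seed, purrr::pmap(
    list(counts$participant_id, counts$task, counts$condition), run_cell))

  ratio <- purrr::map_dbl(sims, "ratio")
  n_degen <- purrr::map_int(sims, "n_degenerate_reps")
  all_degen <- is.na(ratio)
  ratio_one <- !is.na(ratio) & ratio >= 1
  if (any(all_degen)) {
    rlang::warn(sprintf(
      "%d cell(s) had all replicates degenerate (no source-error or novel draws); predicted source errors set to 0.",
      sum(all_degen)))
  }
  if (any(ratio_one)) {
    rlang::warn(sprintf(
      "%d cell(s) reached ratio = 1 (no novel outcomes possible); predicted source errors undefined (NA).",
      sum(ratio_one)))
  }
  safe_ratio <- ifelse(all_degen, 0, ratio)
  predicted <- rep(NA_real_, length(ratio))
  ok <- !ratio_one
  predicted[ok] <- predict_source_errors(safe_ratio[ok], counts$n_intrusions[ok])

  tibble::tibble(
    participant_id = counts$participant_id,
    task = counts$task,
    condition = counts$condition,
    ratio = ifelse(all_degen, NA_real_, ratio),
    n_reps = as.integer(n_reps),
    n_degenerate_reps = n_degen,
    n_intrusions_observed = counts$n_intrusions,
    observed_source_errors = counts$n_source_errors,
    predicted_source_errors = predicted,
    flagged = all_degen | ratio_one,
    seed = as.integer(seed))
}
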