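#' Remove partner-duplicated actions and self-repeats from encoding sets
#'
#' Despite instructions, pair members sometimes duplicate an action the other
#' member has already performed for the same cue, or repeat one of their own.
#' Any coded action performed by *both* members of a pair is removed from the
#' retained encoding sets of both members (it no longer has a unique source);
#' a self-repeated action keeps its first occurrence as the canonical
#' encoding event.
#'
#' Duplication errors are attributed by the order of performance: within a
#' round the focal member performs first, so events are ordered by
#' `(trial_index, role)`. A row whose `(shape_id, action_code)` was performed
#' earlier by the other member is a partner duplication; a row repeating the
#' same member's earlier action is a self-repeat.
#'
#' @param events A data frame of generation events (one or more pairs).
#' @return A list with components
#'   * `events`: the retained encoding events (pair duplicates dropped from
#'     both members, self-repeats reduced to their first occurrence);
#'   * `removed`: distinct `(pair_id, shape_id, action_code)` removed as
#'     pair duplicates;
#'   * `summary`: one-row tibble with `pct_self_repeats`,
#'     `pct_partner_duplicates` (percent of all generated actions), and
#'     `n_removed_actions` (rows dropped).
#' @export
filter_pair_duplicates <- function(events) {
  events <- as_generation_events(events)
  if (nrow(events) == 0) {
    return(list(
      events = events,
      removed = events[c("pair_id", "shape_id", "action_code")],
      summary = tibble::tibble(pct_self_repeats = 0, pct_partner_duplicates = 0,
                               n_removed_actions = 0L, n_events = 0L)))
  }
  ev <- events
  ev$.row <- seq_len(nrow(ev))
  ord <- order(ev$pair_id, ev$trial_index, match(ev$role, role_levels))
  ev <- ev[ord, ]
  ev <- ev |>
    dplyr::group_by(.data$pair_id, .data$shape_id, .data$action_code) |>
    dplyr::mutate(
      .first_member = dplyr::first(.data$participant_id),
      .n_members = dplyr::n_distinct(.data$participant_id)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$pair_id, .data$participant_id, .data$shape_id,
                    .data$action_code) |>
    dplyr::mutate(.self_occ = dplyr::row_number()) |>
    dplyr::ungroup()

  is_pair_dup_action <- ev$.n_members > 1L
  is_partner_duplicate <- ev$participant_id != ev$.first_member
  is_self_repeat <- ev$.self_occ > 1L

  keep <- !is_pair_dup_action & !is_self_repeat
  removed <- ev[is_pair_dup_action, c("pair_id", "shape_id", "action_code")]
  removed <- dplyr::distinct(removed)

  retained <- ev[keep, ]
  retained <- retained[order(retained$.row), ]
  retained <- retained[names(events)]

  n <- nrow(ev)
  summary <- tibble::tibble(
    pct_self_repeats = 100 * sum(is_self_repeat) / n,
    pct_partner_duplicates = 100 * sum(is_partner_duplicate) / n,
    n_removed_actions = n - nrow(retained),
    n_events = n)
  list(events = retained, removed = removed, summary = summary)
}

#' Mark reported versus withheld recall events
#'
#' In the extended recall procedure participants produce everything that
#' comes to mind and then accept or reject each item as coming from the
#' target source; only accepted items count as reported. In standard free
#' report every produced item is reported.
#'
#' @param events A data frame of recall events.
#' @param mode `"free_report"` or `"extended"`.
#' @return The recall events with a `report_status` column
#'   (`"reported"`/`"withheld"`). Withheld events are retained for
#'   diagnostics; downstream coding counts reported events only.
#' @export
apply_extended_recall_filter <- function(events, mode = c("free_report", "extended")) {
  mode <- rlang::arg_match(mode)
  events <- as_recall_events(events)
  events$report_status <- if (mode == "extended") {
    ifelse(events$attributed_to_target, "reported", "withheld")
  } else {
    "reported"
  }
  events
}

#' Code one participant's recall into correct / source error / intrusion
#'
#' Each reported action is compared with the duplicate-filtered encoding
#' sets of the participant's pair. In the recall-own task a member of the
#' own set is a correct recall, a member of the partner's set is a source
#' error, and anything else is an intrusion; the roles swap for the
#' recall-partner task. A `(shape, action)` reported twice is counted once
#' (first report); reports of pair-duplicated (removed) actions are excluded
#' from all tallies.
#'
#' @param recall Recall events for one participant (optionally carrying a
#'   `report_status` column from [apply_extended_recall_filter()]).
#' @param own_set,partner_set Tibbles with `shape_id`, `action_code`: the
#'   duplicate-filtered encoding sets of the focal participant and their
#'   partner. Must be disjoint.
#' @param task `"recall_own"` or `"recall_partner"`.
#' @param removed Optional tibble with `shape_id`, `action_code` of actions
#'   removed as pair duplicates; reports of these are dropped from coding.
#' @return A list with `counts` (one-row tibble: `n_reported`, `n_correct`,
#'   `n_source_errors`, `n_intrusions`) and `labels` (the deduplicated
#'   events with a `label` column).
#' @export
code_recall_events <- function(recall, own_set, partner_set,
                               task = c("recall_own", "recall_partner"),
                               removed = NULL) {
  task <- rlang::arg_match(task)
  own_keys <- action_key(own_set$shape_id, own_set$action_code)
  partner_keys <- action_key(partner_set$shape_id, partner_set$action_code)
  if (length(intersect(own_keys, partner_keys)) > 0) {
    abort_integrity(paste0("own and partner encoding sets overlap; ",
                           "run filter_pair_duplicates() first."))
  }
  removed_keys <- if (is.null(removed)) character() else
    action_key(removed$shape_id, removed$action_code)

  recall <- tibble::as_tibble(recall)
  if (!"report_status" %in% names(recall)) recall$report_status <- "reported"
  rep <- recall[recall$report_status == "reported", , drop = FALSE]
  rep <- rep[order(rep$output_order), , drop = FALSE]
  rep <- rep[!duplicated(action_key(rep$shape_id, rep$action_code)), , drop = FALSE]

  keys <- action_key(rep$shape_id, rep$action_code)
  own_label <- if (task == "recall_own") "correct" else "source_error"
  partner_label <- if (task == "recall_own") "source_error" else "correct"
  label <- dplyr::case_when(
    is_novel_code(rep$action_code) ~ "intrusion",
    keys %in% removed_keys ~ "excluded_duplicate",
    keys %in% own_keys ~ own_label,
    keys %in% partner_keys ~ partner_label,
    TRUE ~ "intrusion")
  rep$label <- label
  counted <- label[label != "excluded_duplicate"]
  counts <- tibble::tibble(
    n_reported = length(counted),
    n_correct = sum(counted == "correct"),
    n_source_errors = sum(counted == "source_error"),
    n_intrusions = sum(counted == "intrusion"))
  list(counts = counts, labels = rep)
}

#' Derive pair structure, encoding sets and load conditions from generation data
#'
#' Convenience preprocessing shared by the coding and guessing stages:
#' filters duplicates, builds the pair roster (who is whose partner), and
#' maps each participant's shapes to the concurrent-load condition under
#' which that participant *observed* them (the `load_condition` of the
#' partner's performances of the shape).
#'
#' @param generation A data frame of generation events.
#' @return A list with `filtered`, `removed`, `dup_summary` (see
#'   [filter_pair_duplicates()]), `roster` (`participant_id`, `pair_id`,
#'   `partner_id`) and `conditions` (`participant_id`, `shape_id`,
#'   `condition`).
#' @export
prepare_encoding <- function(generation) {
  generation <- as_generation_events(generation)
  flt <- filter_pair_duplicates(generation)

  roster <- generation |>
    dplyr::distinct(.data$pair_id, .data$participant_id) |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::mutate(.n = dplyr::n()) |>
    dplyr::ungroup()
  if (any(roster$.n != 2L)) {
    abort_integrity("every pair_id must have exactly two participants.")
  }
  roster <- roster |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::mutate(partner_id = rev(.data$participant_id)) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "pair_id", "partner_id")

  # Condition map from the unfiltered events: the load this participant was
  # under while observing the partner perform the shape.
  conditions <- generation |>
    dplyr::distinct(.data$pair_id, performer = .data$participant_id,
                    .data$shape_id, .data$load_condition) |>
    dplyr::inner_join(roster, by = c(pair_id = "pair_id", performer = "partner_id")) |>
    dplyr::distinct(.data$participant_id, .data$shape_id,
                    condition = .data$load_condition)
  dup_cond <- duplicated(conditions[c("participant_id", "shape_id")])
  if (any(dup_cond)) {
    abort_integrity("a shape maps to more than one load condition for a participant.")
  }
  list(filtered = flt$events, removed = flt$removed, dup_summary = flt$summary,
       roster = roster, conditions = conditions)
}

#' Code a whole recall dataset into per-cell counts
#'
#' Applies the report/withhold filter, codes every participant's reported
#' actions against the duplicate-filtered encoding sets of their pair, and
#' tallies correct recalls, source errors and intrusions per participant,
#' retrieval task and concurrent-load condition (the condition of a reported
#' shape is the load under which the participant observed that shape).
#'
#' @param recall A data frame of recall events (whole experiment).
#' @param prep Result of [prepare_encoding()] on the matching generation data.
#' @param mode `"free_report"` or `"extended"`.
#' @return A list with `counts` (participant x task x condition tallies) and
#'   `labels` (per-event codes, including withheld/excluded events).
#' @export
code_recall <- function(recall, prep, mode = c("free_report", "extended")) {
  mode <- rlang::arg_match(mode)
  recall <- apply_extended_recall_filter(recall, mode)
  unknown <- setdiff(unique(recall$participant_id), prep$roster$participant_id)
  if (length(unknown) > 0) {
    abort_integrity(sprintf("recall events for unknown participant(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  task_of <- recall |> dplyr::distinct(.data$participant_id, .data$task)
  if (anyDuplicated(task_of$participant_id)) {
    abort_integrity("a participant appears under more than one retrieval task.")
  }

  per_participant <- function(pid) {
    info <- prep$roster[prep$roster$participant_id == pid, ]
    own <- prep$filtered[prep$filtered$participant_id == pid, ]
    partner <- prep$filtered[prep$filtered$participant_id == info$partner_id, ]
    removed <- prep$removed[prep$removed$pair_id == info$pair_id, ]
    rec <- recall[recall$participant_id == pid, ]
    task <- rec$task[1]
    coded <- code_recall_events(rec, own, partner, task, removed = removed)
    coded$labels
  }

  labels <- purrr::map(unique(recall$participant_id), per_participant) |>
    purrr::list_rbind()
  labels <- dplyr::left_join(
    labels, prep$conditions,
    by = c("participant_id", "shape_id"))
  labels$condition[is.na(labels$condition)] <- "none"

  counted <- labels[labels$report_status == "reported" &
                      labels$label != "excluded_duplicate", ]
  counts <- counted |>
    dplyr::group_by(.data$participant_id, .data$task, .data$condition) |>
    dplyr::summarise(
      n_reported = dplyr::n(),
      n_correct = sum(.data$label == "correct"),
      n_source_errors = sum(.data$label == "source_error"),
      n_intrusions = sum(.data$label == "intrusion"),
      .groups = "drop")
  # Participants (or cells) with zero reported events still form cells for
  # downstream averaging: complete against roster x observed conditions.
  cells <- labels |>
    dplyr::distinct(.data$participant_id, .data$task) |>
    dplyr::left_join(prep$conditions, by = "participant_id") |>
    dplyr::distinct(.data$participant_id, .data$task, .data$condition)
  counts <- cells |>
    dplyr::left_join(counts, by = c("participant_id", "task", "condition")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::arrange(.data$participant_id, .data$condition)
  list(counts = counts, labels = labels)
}
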