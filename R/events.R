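#' Read and validate generation-phase events
#'
#' The generation phase of the paired design is stored as one CSV row per
#' physical performance: who performed which coded action for which shape
#' cue, in what order, and under which concurrent load the *observing* pair
#' member stood while watching it. Performers themselves are never under
#' load; the design is unbalanced by construction.
#'
#' The required header is
#' `pair_id, participant_id, shape_id, action_code, trial_index, load_condition, actor_role`.
#' `actor_role` labels the performer's role within the pair (`focal` performs
#' first in every round, `partner` second); `trial_index` is 1-based within a
#' performer. On read, `actor_role` becomes the tibble column `role`.
#'
#' @param path Path to a `generation.csv` file.
#' @return A tibble of generation events, one row per performed action.
#' @seealso [read_recall_events()], [filter_pair_duplicates()]
#' @export
read_generation_events <- function(path) {
  df <- read_phase_csv(path, c("pair_id", "participant_id", "shape_id",
                               "action_code", "trial_index", "load_condition",
                               "actor_role"))
  df <- dplyr::rename(df, role = "actor_role")
  df$trial_index <- parse_index(df$trial_index, "trial_index")
  as_generation_events(df)
}

#' Read and validate test-phase (recall) events
#'
#' One CSV row per action a participant produced at test, in output order.
#' `action_code` is either a coded action from the experiment's inventory or
#' a `NOVEL:<token>` marker for an action outside it. `attributed_to_target`
#' is the participant's own source verdict in the extended (report/withhold)
#' recall procedure; in standard free report it is `TRUE` throughout.
#'
#' The required header is
#' `participant_id, task, shape_id, action_code, output_order, attributed_to_target`.
#'
#' @param path Path to a `recall.csv` file.
#' @return A tibble of recall events, one row per produced action.
#' @export
read_recall_events <- function(path) {
  df <- read_phase_csv(path, c("participant_id", "task", "shape_id",
                               "action_code", "output_order",
                               "attributed_to_target"))
  df$output_order <- parse_index(df$output_order, "output_order")
  att <- toupper(trimws(as.character(df$attributed_to_target)))
  if (!all(att %in% c("TRUE", "FALSE", "T", "F"))) {
    abort_schema("`attributed_to_target` must be logical (TRUE/FALSE).")
  }
  df$attributed_to_target <- att %in% c("TRUE", "T")
  as_recall_events(df)
}

#' @rdname read_generation_events
#' @param events A data frame of generation events to write.
#' @export
write_generation_events <- function(events, path) {
  events <- as_generation_events(events)
  out <- dplyr::rename(events, actor_role = "role")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_recall_events
#' @param events A data frame of recall events to write.
#' @export
write_recall_events <- function(events, path) {
  events <- as_recall_events(events)
  readr::write_csv(events, path)
  invisible(path)
}

#' Validate in-memory event tables
#'
#' Checks column presence, closed vocabularies (`load_condition`, `task`,
#' `role`), 1-based ordering indices, and per-participant uniqueness of
#' `trial_index` / `output_order`. Both the CSV readers and the synthetic
#' generator funnel through these validators, so a generated dataset and its
#' write-then-read round trip satisfy the same contract.
#'
#' @param df A data frame of events.
#' @return The validated tibble, invisibly coerced to canonical column types.
#' @export
as_generation_events <- function(df) {
  need <- c("pair_id", "participant_id", "shape_id", "action_code",
            "trial_index", "load_condition", "role")
  check_columns(df, need, "generation")
  df <- tibble::as_tibble(df)[need]
  for (col in c("pair_id", "participant_id", "shape_id", "action_code",
                "load_condition", "role")) {
    df[[col]] <- as.character(df[[col]])
  }
  check_vocab(df$load_condition, load_levels, "load_condition")
  check_vocab(df$role, role_levels, "role")
  check_index(df$trial_index, "trial_index")
  dup <- duplicated(df[c("participant_id", "trial_index")])
  if (any(dup)) {
    abort_integrity(sprintf(
      "duplicate (participant_id, trial_index) in generation events: e.g. (%s, %d)",
      df$participant_id[dup][1], df$trial_index[dup][1]))
  }
  one_pair <- stats::ave(df$pair_id, df$participant_id,
                         FUN = function(p) length(unique(p)))
  if (any(one_pair != "1")) {
    abort_integrity("a participant_id appears in more than one pair_id.")
  }
  df
}

#' @rdname as_generation_events
#' @export
as_recall_events <- function(df) {
  need <- c("participant_id", "task", "shape_id", "action_code",
            "output_order", "attributed_to_target")
  check_columns(df, need, "recall")
  df <- tibble::as_tibble(df)[need]
  for (col in c("participant_id", "task", "shape_id", "action_code")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (!is.logical(df$attributed_to_target) || anyNA(df$attributed_to_target)) {
    abort_schema("`attributed_to_target` must be logical with no missing values.")
  }
  check_vocab(df$task, task_levels, "task")
  check_index(df$output_order, "output_order")
  dup <- duplicated(df[c("participant_id", "output_order")])
  if (any(dup)) {
    abort_integrity(sprintf(
      "duplicate (participant_id, output_order) in recall events: e.g. (%s, %d)",
      df$participant_id[dup][1], df$output_order[dup][1]))
  }
  df
}

read_phase_csv <- function(path, need) {
  if (!file.exists(path)) {
    abort_schema(sprintf("file not found: %s", path))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  check_columns(df, setdiff(need, character()), "CSV")
  df
}

check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf("%s schema: missing column(s) %s", what,
                         paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(df)
}

check_vocab <- function(x, levels, name) {
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    abort_schema(sprintf("unknown %s value(s): %s (allowed: %s)", name,
                         paste0("\"", bad, "\"", collapse = ", "),
                         paste(levels, collapse = ", ")))
  }
  invisible(x)
}

parse_index <- function(x, name) {
  out <- suppressWarnings(as.integer(x))
  if (anyNA(out)) abort_schema(sprintf("`%s` must be integer.", name))
  out
}

check_index <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 1) || any(x != as.integer(x))) {
    abort_schema(sprintf("`%s` must be an integer >= 1.", name))
  }
  invisible(x)
}
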