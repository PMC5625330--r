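#' Generator configuration objects
#'
#' The synthetic experiment mirrors the paired generation/recall design:
#' 15 shape cues, each with 20-40 distinct coded actions of skewed
#' popularity; pairs alternating turns to produce 3 (or 4) exemplars per
#' cue each, with occasional self-repeats and partner duplications;
#' next-day recall of own or partner actions that mixes genuine retrieval
#' (with a source-confusion probability) and popularity-driven guessing.
#'
#' `action_space_config()` fixes the action inventory: number of shapes,
#' per-shape support-size range, and a popularity law — `zipf` gives
#' rank-`s` power-law probabilities (`s = 0` is uniform), `dirichlet`
#' draws a random simplex with concentration `alpha`.
#'
#' `encoding_config()` fixes the generation phase: exemplars per member per
#' cue, duplication error probabilities (defaults match the low
#' confederate-run rates: 0.5% self-repeats, 1.3% partner duplications;
#' naive pairs run an order of magnitude higher), an optional shape-to-load
#' schedule, and a multiplicative encoding penalty in `(0, 1]` applied to
#' the retrievability of actions observed under load.
#'
#' `recall_config()` fixes the test phase: per-item retrieval
#' probabilities for own and observed actions, the probability a retrieved
#' item is attributed to the wrong source, a Poisson rate of
#' popularity-driven guesses per shape, the probability a guess falls
#' outside the action inventory entirely, and — in extended-recall mode —
#' the probability that a would-be source error is caught and withheld.
#'
#' @param n_shapes,support_range,popularity,zipf_s,dirichlet_alpha,shapes
#'   Action-space parameters; `shapes` overrides the default 15 cue labels.
#' @param exemplars_per_shape,p_self_repeat,p_partner_duplicate,load_schedule,load_encoding_penalty
#'   Encoding parameters; `load_schedule` is a named character vector
#'   mapping every shape to a load condition (`NULL` = no load anywhere).
#' @param p_retrieve_own,p_retrieve_partner,p_source_confusion,guess_lambda,p_guess_outside_inventory,monitoring_strictness
#'   Recall parameters.
#' @return A named list of validated parameters.
#' @name generator-config
NULL

#' @rdname generator-config
#' @export
action_space_config <- function(n_shapes = 15, support_range = c(20L, 40L),
                                popularity = c("zipf", "dirichlet"),
                                zipf_s = 1, dirichlet_alpha = 1,
                                shapes = NULL) {
  popularity <- rlang::arg_match(popularity)
  if (length(support_range) != 2 || support_range[1] < 1 ||
      support_range[2] < support_range[1]) {
    abort_domain("`support_range` must be an increasing positive integer interval.")
  }
  shapes <- shapes %||%
    (if (n_shapes <= length(default_shapes)) default_shapes[seq_len(n_shapes)]
     else sprintf("shape%02d", seq_len(n_shapes)))
  if (length(shapes) != n_shapes) abort_domain("`shapes` must have length `n_shapes`.")
  list(n_shapes = as.integer(n_shapes),
       support_range = as.integer(support_range),
       popularity = popularity, zipf_s = zipf_s,
       dirichlet_alpha = dirichlet_alpha, shapes = shapes)
}

#' @rdname generator-config
#' @export
encoding_config <- function(exemplars_per_shape = 3, p_self_repeat = 0.005,
                            p_partner_duplicate = 0.013, load_schedule = NULL,
                            load_encoding_penalty = 1) {
  check_scalar_prob(p_self_repeat, "p_self_repeat")
  check_scalar_prob(p_partner_duplicate, "p_partner_duplicate")
  if (load_encoding_penalty <= 0 || load_encoding_penalty > 1) {
    abort_domain("`load_encoding_penalty` must lie in (0, 1].")
  }
  if (!is.null(load_schedule)) {
    check_vocab(unname(load_schedule), load_levels, "load_schedule")
    if (is.null(names(load_schedule))) {
      abort_schema("`load_schedule` must be named by shape_id.")
    }
  }
  list(exemplars_per_shape = as.integer(exemplars_per_shape),
       p_self_repeat = p_self_repeat,
       p_partner_duplicate = p_partner_duplicate,
       load_schedule = load_schedule,
       load_encoding_penalty = load_encoding_penalty)
}

#' @rdname generator-config
#' @export
recall_config <- function(p_retrieve_own = 0.65, p_retrieve_partner = 0.45,
                          p_source_confusion = 0.2, guess_lambda = 0.6,
                          p_guess_outside_inventory = 0.05,
                          monitoring_strictness = 0.7) {
  for (nm in c("p_retrieve_own", "p_retrieve_partner", "p_source_confusion",
               "p_guess_outside_inventory", "monitoring_strictness")) {
    check_scalar_prob(get(nm), nm)
  }
  if (guess_lambda < 0) abort_domain("`guess_lambda` must be >= 0.")
  list(p_retrieve_own = p_retrieve_own,
       p_retrieve_partner = p_retrieve_partner,
       p_source_confusion = p_source_confusion,
       guess_lambda = guess_lambda,
       p_guess_outside_inventory = p_guess_outside_inventory,
       monitoring_strictness = monitoring_strictness)
}

#' Build a synthetic action inventory with skewed popularity
#'
#' Draws a per-shape support size within the configured range and a
#' popularity vector under the configured law. The result plays the role of
#' the true (population) action space: generation draws, and
#' popularity-driven guesses at test, both sample from it.
#'
#' @param config An [action_space_config()].
#' @param seed Optional integer seed for a private RNG stream.
#' @return A tibble of class `action_space` (`shape_id`, `action_code`,
#'   `prob`), probabilities summing to 1 per shape.
#' @export
make_action_space <- function(config = action_space_config(), seed = NULL) {
  with_seed_if(seed, {
    sizes <- seq(config$support_range[1], config$support_range[2])
    rows <- purrr::map(config$shapes, function(shape) {
      size <- if (length(sizes) == 1) sizes else sample(sizes, 1)
      prob <- switch(config$popularity,
        zipf = {
          w <- seq_len(size)^(-config$zipf_s)
          w / sum(w)
        },
        dirichlet = {
          g <- stats::rgamma(size, shape = config$dirichlet_alpha)
          g / sum(g)
        })
      tibble::tibble(shape_id = shape,
                     action_code = sprintf("act%02d", seq_len(size)),
                     prob = prob)
    })
    space <- purrr::list_rbind(rows)
    structure(space, class = c("action_space", class(space)),
              config = config)
  })
}

#' Simulate the generation phase for one pair
#'
#' The two members alternate turns per cue (the focal member performs
#' first). Each draw is, with probability `p_partner_duplicate`, a re-draw
#' from the partner's already-used actions for that cue (a partner
#' duplication error), or with probability `p_self_repeat` a re-draw from
#' the member's own used actions; otherwise a fresh action is drawn from the
#' popularity distribution restricted to codes not yet used by the pair for
#' that cue. Each member performs `exemplars_per_shape` actions per cue.
#'
#' @param space An `action_space` tibble from [make_action_space()].
#' @param enc An [encoding_config()].
#' @param pair_id,participant_ids Identifiers; the first participant is the
#'   focal member.
#' @param seed Optional integer seed for a private RNG stream.
#' @return A validated tibble of generation events carrying
#'   `load_encoding_penalty` as an attribute.
#' @export
simulate_generation_phase <- function(space, enc = encoding_config(),
                                      pair_id = "pair01",
                                      participant_ids = NULL, seed = NULL) {
  shapes <- unique(space$shape_id)
  schedule <- enc$load_schedule %||%
    stats::setNames(rep("none", length(shapes)), shapes)
  missing_sched <- setdiff(shapes, names(schedule))
  if (length(missing_sched) > 0) {
    abort_domain(sprintf("load_schedule missing shape(s): %s",
                         paste(missing_sched, collapse = ", ")))
  }
  supports <- split(space, space$shape_id)
  min_support <- min(vapply(supports, nrow, integer(1)))
  if (2 * enc$exemplars_per_shape > min_support) {
    abort_domain("infeasible: 2 * exemplars_per_shape exceeds the smallest support.")
  }
  participant_ids <- participant_ids %||% paste0(pair_id, c("_a", "_b"))
  stopifnot(length(participant_ids) == 2)

  with_seed_if(seed, {
    out <- vector("list", length(shapes) * enc$exemplars_per_shape * 2)
    slot <- 0L
    trial_counter <- c(0L, 0L)
    for (shape in shapes) {
      sup <- supports[[shape]]
      used_pair <- character()
      used_member <- list(character(), character())
      for (round in seq_len(enc$exemplars_per_shape)) {
        for (m in 1:2) {
          other <- 3L - m
          u <- stats::runif(1)
          code <- if (u < enc$p_partner_duplicate &&
                      length(used_member[[other]]) > 0) {
            sample(used_member[[other]], 1)
          } else if (u < enc$p_partner_duplicate + enc$p_self_repeat &&
                     length(used_member[[m]]) > 0) {
            sample(used_member[[m]], 1)
          } else {
            avail <- !(sup$action_code %in% used_pair)
            sample(sup$action_code[avail], 1, prob = sup$prob[avail])
          }
          used_pair <- union(used_pair, code)
          used_member[[m]] <- union(used_member[[m]], code)
          trial_counter[m] <- trial_counter[m] + 1L
          slot <- slot + 1L
          out[[slot]] <- tibble::tibble(
            pair_id = pair_id,
            participant_id = participant_ids[m],
            shape_id = shape,
            action_code = code,
            trial_index = trial_counter[m],
            load_condition = unname(schedule[shape]),
            role = role_levels[m])
        }
      }
    }
    events <- as_generation_events(purrr::list_rbind(out))
    attr(events, "load_encoding_penalty") <- enc$load_encoding_penalty
    events
  })
}

#' Simulate the test phase for the participants of a generated dataset
#'
#' Every duplicate-filtered encoded item is retrieved independently with
#' its source's retrieval probability (observed items encoded under load
#' are attenuated by `load_encoding_penalty`); retrieved items are
#' attributed to the wrong source with `p_source_confusion`. In free
#' report, only items attributed to the task's target source are emitted.
#' In extended recall everything retrieved is emitted, flagged by the
#' participant's source verdict, and a would-be source error is caught
#' (rejected) with probability `monitoring_strictness`. On top of
#' retrieval, each shape attracts `Poisson(guess_lambda)` popularity-driven
#' guesses. Guesses are drawn from the *realized* generation-phase
#' frequency distribution of the whole dataset — ad-hoc solutions at test
#' follow the same frequency profile as solutions at generation — excluding
#' codes already produced, or are emitted as `NOVEL:` actions with
#' `p_guess_outside_inventory`.
#'
#' @param gen Generation events (whole pairs).
#' @param space The `action_space` the events were generated from.
#' @param rec A [recall_config()].
#' @param task Retrieval task assigned to these participants.
#' @param mode `"free_report"` or `"extended"`.
#' @param participants Participants to simulate (default: all in `gen`).
#' @param load_encoding_penalty Penalty in `(0, 1]`; defaults to the
#'   attribute set by [simulate_generation_phase()], else 1.
#' @param seed Optional integer seed for a private RNG stream.
#' @return A validated tibble of recall events.
#' @export
simulate_test_phase <- function(gen, space, rec = recall_config(),
                                task = c("recall_own", "recall_partner"),
                                mode = c("free_report", "extended"),
                                participants = NULL,
                                load_encoding_penalty = NULL, seed = NULL) {
  task <- rlang::arg_match(task)
  mode <- rlang::arg_match(mode)
  penalty <- load_encoding_penalty %||% attr(gen, "load_encoding_penalty") %||% 1
  gen <- as_generation_events(gen)
  prep <- prepare_encoding(gen)
  participants <- participants %||% unique(gen$participant_id)
  shapes <- unique(gen$shape_id)
  # ad-hoc guesses follow the generation-phase frequency profile
  guess_norms <- build_frequency_norms(gen)
  guess_dist <- split(guess_norms, guess_norms$shape_id)
  target <- if (task == "recall_own") "own" else "partner"

  one_participant <- function(pid) {
    info <- prep$roster[prep$roster$participant_id == pid, ]
    own <- prep$filtered[prep$filtered$participant_id == pid,
                         c("shape_id", "action_code")]
    partner <- prep$filtered[prep$filtered$participant_id == info$partner_id,
                             c("shape_id", "action_code")]
    conds <- prep$conditions[prep$conditions$participant_id == pid, ]
    cond_of <- stats::setNames(conds$condition, conds$shape_id)

    items <- dplyr::bind_rows(
      dplyr::mutate(own, true_source = "own"),
      dplyr::mutate(partner, true_source = "partner"))
    p_ret <- ifelse(items$true_source == "own", rec$p_retrieve_own,
                    rec$p_retrieve_partner *
                      ifelse(cond_of[items$shape_id] != "none", penalty, 1))
    retrieved <- items[stats::runif(nrow(items)) < p_ret, , drop = FALSE]

    confused <- stats::runif(nrow(retrieved)) < rec$p_source_confusion
    attributed <- ifelse(confused,
                         ifelse(retrieved$true_source == "own", "partner", "own"),
                         retrieved$true_source)
    claims_target <- attributed == target
    # monitoring: a claimed-target item whose true source is wrong may be
    # caught on explicit inspection (extended recall only)
    caught <- claims_target & retrieved$true_source != target &
      (mode == "extended") &
      stats::runif(nrow(retrieved)) < rec$monitoring_strictness
    accepts <- claims_target & !caught

    if (mode == "free_report") {
      emitted <- retrieved[accepts, , drop = FALSE]
      emitted$attributed_to_target <- rep(TRUE, nrow(emitted))
    } else {
      emitted <- retrieved
      emitted$attributed_to_target <- accepts
    }

    # popularity-driven guesses, excluding codes already produced
    produced <- action_key(emitted$shape_id, emitted$action_code)
    guess_rows <- list()
    novel_counter <- 0L
    for (shape in shapes) {
      n_g <- stats::rpois(1, rec$guess_lambda)
      if (n_g == 0) next
      sup <- guess_dist[[shape]]
      for (g in seq_len(n_g)) {
        if (stats::runif(1) < rec$p_guess_outside_inventory) {
          novel_counter <- novel_counter + 1L
          code <- sprintf("NOVEL:%s_%02d", shape, novel_counter)
        } else {
          avail <- !(action_key(shape, sup$action_code) %in% produced)
          if (!any(avail)) next
          code <- sample(sup$action_code[avail], 1, prob = sup$prob[avail])
        }
        produced <- c(produced, action_key(shape, code))
        guess_rows[[length(guess_rows) + 1L]] <- tibble::tibble(
          shape_id = shape, action_code = code, true_source = "guess",
          attributed_to_target = TRUE)
      }
    }
    guesses <- purrr::list_rbind(guess_rows)
    all_rows <- dplyr::bind_rows(
      emitted[c("shape_id", "action_code", "attributed_to_target")],
      if (nrow(guesses) > 0)
        guesses[c("shape_id", "action_code", "attributed_to_target")])
    if (nrow(all_rows) == 0) return(NULL)
    tibble::tibble(
      participant_id = pid,
      task = task,
      shape_id = all_rows$shape_id,
      action_code = all_rows$action_code,
      output_order = seq_len(nrow(all_rows)),
      attributed_to_target = all_rows$attributed_to_target)
  }

  with_seed_if(seed, {
    recall <- purrr::map(participants, one_participant) |> purrr::list_rbind()
    if (nrow(recall) == 0) {
      recall <- tibble::tibble(participant_id = character(), task = character(),
                               shape_id = character(), action_code = character(),
                               output_order = integer(),
                               attributed_to_target = logical())
    }
    as_recall_events(recall)
  })
}

#' Simulate a full paired generation/recall experiment
#'
#' End-to-end dataset in the pipeline's CSV schemas: an action space, a
#' generation phase for `n_pairs` pairs, and a test phase in which (by
#' default) the focal member of each pair performs the recall-own task and
#' the other member the recall-partner task. All randomness flows from one
#' seed; rerunning with the same configuration and seed reproduces the
#' dataset exactly.
#'
#' @param n_pairs Number of pairs.
#' @param space_config,enc,rec Generator configurations.
#' @param tasks `"both"` (default: one member per task), `"own"` or
#'   `"partner"` (both members the same task).
#' @param mode Recall mode.
#' @param seed Integer seed recorded in the ground-truth sidecar.
#' @param dir Optional output directory: writes `generation.csv`,
#'   `recall.csv` and a `truth.json` sidecar with every parameter.
#' @return A list with `generation`, `recall`, `space` and `truth`.
#' @export
simulate_experiment <- function(n_pairs = 20,
                                space_config = action_space_config(),
                                enc = encoding_config(),
                                rec = recall_config(),
                                tasks = c("both", "own", "partner"),
                                mode = c("free_report", "extended"),
                                seed = 1L, dir = NULL) {
  tasks <- rlang::arg_match(tasks)
  mode <- rlang::arg_match(mode)
  result <- withr::with_seed(as.integer(seed), {
    space <- make_action_space(space_config, seed = NULL)
    gen <- purrr::map(seq_len(n_pairs), function(i) {
      simulate_generation_phase(space, enc, pair_id = sprintf("pair%03d", i),
                                seed = NULL)
    }) |> purrr::list_rbind()
    gen <- as_generation_events(gen)
    attr(gen, "load_encoding_penalty") <- enc$load_encoding_penalty

    members <- gen |> dplyr::distinct(.data$participant_id, .data$role)
    own_ids <- switch(tasks,
                      both = members$participant_id[members$role == "focal"],
                      own = members$participant_id,
                      partner = character())
    partner_ids <- setdiff(members$participant_id, own_ids)
    recall <- dplyr::bind_rows(
      if (length(own_ids) > 0)
        simulate_test_phase(gen, space, rec, "recall_own", mode,
                            participants = own_ids, seed = NULL),
      if (length(partner_ids) > 0)
        simulate_test_phase(gen, space, rec, "recall_partner", mode,
                            participants = partner_ids, seed = NULL))
    list(generation = gen, recall = as_recall_events(recall), space = space)
  })
  truth <- list(seed = as.integer(seed), n_pairs = n_pairs, tasks = tasks,
                mode = mode, space_config = space_config[names(space_config) != "shapes"],
                shapes = space_config$shapes, encoding = enc, recall = rec)
  result$truth <- truth
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_generation_events(result$generation, file.path(dir, "generation.csv"))
    write_recall_events(result$recall, file.path(dir, "recall.csv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}
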