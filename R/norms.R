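#' Build per-shape frequency norms from generation events
#'
#' For every shape cue the probability of a coded action is its generation
#' count divided by the total generation count for that shape, across *all*
#' generation events of the experiment. Duplicated actions contribute each
#' occurrence: the norms describe the population action space, not the
#' deduplicated encoding sets.
#'
#' @param events A data frame of generation events.
#' @param shapes Optional character vector of expected shapes; shapes with
#'   zero events are excluded with a warning.
#' @return A tibble of class `frequency_norms` with columns `shape_id`,
#'   `action_code`, `n` (generation count) and `prob`. Per shape, `prob`
#'   is positive and sums to 1.
#' @export
build_frequency_norms <- function(events, shapes = NULL) {
  events <- as_generation_events(events)
  if (nrow(events) == 0) abort_domain("no generation events to build norms from.")
  if (!is.null(shapes)) {
    empty <- setdiff(shapes, unique(events$shape_id))
    if (length(empty) > 0) {
      rlang::warn(sprintf("shape(s) with zero generation events excluded from norms: %s",
                          paste(empty, collapse = ", ")))
    }
  }
  norms <- events |>
    dplyr::count(.data$shape_id, .data$action_code, name = "n") |>
    dplyr::group_by(.data$shape_id) |>
    dplyr::mutate(prob = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$shape_id, dplyr::desc(.data$n), .data$action_code)
  new_frequency_norms(norms)
}

new_frequency_norms <- function(norms) {
  stopifnot(all(c("shape_id", "action_code", "prob") %in% names(norms)))
  sums <- tapply(norms$prob, norms$shape_id, sum)
  if (any(abs(sums - 1) > 1e-12) || any(norms$prob <= 0)) {
    abort_domain("norms probabilities must be > 0 and sum to 1 per shape.")
  }
  structure(tibble::as_tibble(norms),
            class = c("frequency_norms", class(tibble::tibble())))
}

#' Turn a per-shape probability table into norms
#'
#' Utility for constructing small `frequency_norms` objects directly, e.g.
#' in tests or when norms come from an external source such as a
#' `norms.json` file.
#'
#' @param df Data frame with `shape_id`, `action_code`, `prob` (and
#'   optionally `n`).
#' @return A `frequency_norms` tibble.
#' @export
as_frequency_norms <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"n" %in% names(df)) df$n <- NA_integer_
  new_frequency_norms(df[c("shape_id", "action_code", "n", "prob")])
}

#' @export
write_norms_json <- function(norms, path) {
  by_shape <- split(norms, norms$shape_id)
  out <- lapply(by_shape, function(d) as.list(stats::setNames(d$prob, d$action_code)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
read_norms_json <- function(path) {
  raw <- jsonlite::read_json(path)
  df <- purrr::imap(raw, function(probs, shape) {
    tibble::tibble(shape_id = shape,
                   action_code = names(probs),
                   prob = unlist(probs, use.names = FALSE))
  }) |> purrr::list_rbind()
  as_frequency_norms(df)
}

shape_norms <- function(norms, shape_id) {
  d <- norms[norms$shape_id == shape_id, ]
  if (nrow(d) == 0) abort_domain(sprintf("no norms for shape \"%s\".", shape_id))
  stats::setNames(d$prob, d$action_code)
}

#' Draw a guessed set of actions for one shape
#'
#' Weighted sampling without replacement from a shape's frequency norms:
#' successive draws with renormalization of the remaining probability mass,
#' the scheme implemented by [base::sample()] with a `prob` argument.
#'
#' @param norms A `frequency_norms` tibble.
#' @param shape_id Shape to sample from.
#' @param k Number of distinct actions to draw; must not exceed the shape's
#'   support size.
#' @param seed Optional integer seed for a private RNG stream.
#' @return A character vector of `k` distinct action codes.
#' @export
draw_guess_set <- function(norms, shape_id, k, seed = NULL) {
  p <- shape_norms(norms, shape_id)
  if (k > length(p)) {
    abort_domain(sprintf("k = %d exceeds the support size (%d) of shape \"%s\".",
                         k, length(p), shape_id))
  }
  if (k == 0) return(character())
  with_seed_if(seed, names(p)[sample.int(length(p), k, prob = p)])
}

#' Exact distribution of the guessing draw on a small support
#'
#' Brute-force oracle for the weighted without-replacement sampler: sums the
#' probabilities of all ordered draw sequences (via a dynamic program over
#' subsets, equivalent to full factorial enumeration) to obtain the exact
#' per-action inclusion probabilities and, given the participant's encoding
#' sets, the expected category counts and the exact conditional expectation
#' of the per-replicate source-error ratio.
#'
#' @inheritParams draw_guess_set
#' @param own_set,partner_set Optional tibbles (`shape_id`, `action_code`)
#'   identifying which support actions the participant performed/observed.
#' @param task Which task defines a source error (`matched_partner` under
#'   `recall_own`, `matched_self` under `recall_partner`).
#' @return A list with `inclusion` (tibble `action_code`, `p_inclusion`),
#'   and — when sets are supplied — `expected_counts` (named: matched_self,
#'   matched_partner, novel), `p_degenerate` (probability of a 0/0
#'   replicate) and `expected_ratio` (conditional on non-degeneracy).
#' @export
enumerate_guess_distribution <- function(norms, shape_id, k,
                                         own_set = NULL, partner_set = NULL,
                                         task = c("recall_own", "recall_partner")) {
  task <- rlang::arg_match(task)
  p <- shape_norms(norms, shape_id)
  n <- length(p)
  if (n > 12) abort_domain("support size > 12: enumeration is factorial, refusing.")
  if (k > n) abort_domain("k exceeds the support size.")

  codes <- names(p)
  memo <- new.env(parent = emptyenv())
  # set_prob(S): probability that |S| successive renormalized draws yield
  # exactly the set S (in any order).
  set_prob <- function(idx) {
    if (length(idx) == 0) return(1)
    key <- paste(idx, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- 0
    for (j in seq_along(idx)) {
      rest <- idx[-j]
      val <- val + set_prob(rest) * p[idx[j]] / (1 - sum(p[rest]))
    }
    memo[[key]] <- val
    val
  }

  subsets <- utils::combn(n, k, simplify = FALSE)
  probs <- vapply(subsets, set_prob, numeric(1))
  stopifnot(abs(sum(probs) - 1) < 1e-9)

  inclusion <- numeric(n)
  for (s in seq_along(subsets)) {
    inclusion[subsets[[s]]] <- inclusion[subsets[[s]]] + probs[s]
  }
  out <- list(inclusion = tibble::tibble(action_code = codes,
                                         p_inclusion = inclusion))
  if (!is.null(own_set) || !is.null(partner_set)) {
    own_keys <- if (is.null(own_set)) character() else
      own_set$action_code[own_set$shape_id == shape_id]
    partner_keys <- if (is.null(partner_set)) character() else
      partner_set$action_code[partner_set$shape_id == shape_id]
    category <- ifelse(codes %in% own_keys, "matched_self",
                       ifelse(codes %in% partner_keys, "matched_partner", "novel"))
    src_cat <- if (task == "recall_own") "matched_partner" else "matched_self"
    exp_counts <- c(matched_self = 0, matched_partner = 0, novel = 0)
    p_degen <- 0
    ratio_num <- 0
    ratio_den <- 0
    for (s in seq_along(subsets)) {
      cats <- category[subsets[[s]]]
      cnt <- c(matched_self = sum(cats == "matched_self"),
               matched_partner = sum(cats == "matched_partner"),
               novel = sum(cats == "novel"))
      exp_counts <- exp_counts + probs[s] * cnt
      se <- cnt[[src_cat]]
      nv <- cnt[["novel"]]
      if (se + nv == 0) {
        p_degen <- p_degen + probs[s]
      } else {
        ratio_num <- ratio_num + probs[s] * se / (se + nv)
        ratio_den <- ratio_den + probs[s]
      }
    }
    out$expected_counts <- exp_counts
    out$p_degenerate <- p_degen
    out$expected_ratio <- if (ratio_den > 0) ratio_num / ratio_den else NA_real_
  }
  out
}
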