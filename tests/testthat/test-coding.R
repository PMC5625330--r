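two_member_events <- function(a_codes, b_codes, shape = "X") {
  rows <- dplyr::bind_rows(
    purrr::imap(a_codes, ~ gen_row("p1_a", "focal", shape, .x, .y)),
    purrr::imap(b_codes, ~ gen_row("p1_b", "partner", shape, .x, .y)))
  toy_generation(rows = rows)
}

test_that("actions performed by both members are removed from both encoding sets", {
  ev <- two_member_events(c("cross_forearms", "arms_up"),
                          c("cross_forearms", "legs_cross"))
  out <- filter_pair_duplicates(ev)
  expect_false("cross_forearms" %in% out$events$action_code)
  expect_setequal(out$events$action_code, c("arms_up", "legs_cross"))
  expect_equal(out$removed$action_code, "cross_forearms")
  expect_equal(out$summary$n_removed_actions, 2L)
})

test_that("filtering without overlap is a no-op and the filter is idempotent", {
  ev <- two_member_events(c("a1", "a2"), c("b1", "b2"))
  out <- filter_pair_duplicates(ev)
  expect_equal(as.data.frame(out$events), as.data.frame(ev))
  expect_equal(out$summary$pct_partner_duplicates, 0)

  # idempotence on data that does contain duplicates
  ev2 <- two_member_events(c("a1", "a1", "dup"), c("dup", "b1", "b2"))
  once <- filter_pair_duplicates(ev2)
  twice <- filter_pair_duplicates(once$events)
  expect_equal(as.data.frame(twice$events), as.data.frame(once$events))
  expect_equal(twice$summary$n_removed_actions, 0L)
})

test_that("self-repeats keep the first occurrence and are counted in the summary", {
  ev <- two_member_events(c("a1", "a1", "a2"), c("b1", "b2", "b3"))
  out <- filter_pair_duplicates(ev)
  kept_a <- out$events[out$events$participant_id == "p1_a", ]
  expect_equal(kept_a$action_code, c("a1", "a2"))
  expect_equal(kept_a$trial_index[kept_a$action_code == "a1"], 1L)
  expect_equal(out$summary$pct_self_repeats, 100 / 6)
})

test_that("partner-duplication rate in the generator matches its own parameter", {
  space <- make_action_space(action_space_config(), seed = 11)
  enc <- encoding_config(exemplars_per_shape = 4, p_partner_duplicate = 0.10,
                         p_self_repeat = 0)
  withr::with_seed(202, {
    gen <- purrr::map(1:60, function(i) {
      simulate_generation_phase(space, enc, pair_id = sprintf("pair%03d", i))
    }) |> purrr::list_rbind()
  })
  # a draw is eligible once the other member has performed for the shape;
  # with self-repeats off, a draw duplicates the partner iff its code is in
  # the other member's earlier codes for that shape
  n_eligible <- 0L
  n_dup <- 0L
  for (d in split(gen, paste(gen$pair_id, gen$shape_id))) {
    d <- d[order(d$trial_index, d$role == "partner"), ]
    seen <- list(focal = character(), partner = character())
    for (i in seq_len(nrow(d))) {
      other <- setdiff(c("focal", "partner"), d$role[i])
      if (length(seen[[other]]) > 0) {
        n_eligible <- n_eligible + 1L
        n_dup <- n_dup + (d$action_code[i] %in% seen[[other]])
      }
      seen[[d$role[i]]] <- c(seen[[d$role[i]]], d$action_code[i])
    }
  }
  phat <- n_dup / n_eligible
  band <- 2.58 * sqrt(0.1 * 0.9 / n_eligible)
  expect_lt(abs(phat - 0.10), band)
})

test_that("recall coding partitions reports into correct/source/intrusion", {
  own <- action_set("X", c("a", "b"))
  partner <- action_set("X", "c")
  rec <- toy_recall("p1_a", "recall_own", rep("X", 3), c("a", "c", "d"))
  coded <- code_recall_events(rec, own, partner, "recall_own")
  expect_equal(coded$counts$n_correct, 1L)
  expect_equal(coded$counts$n_source_errors, 1L)
  expect_equal(coded$counts$n_intrusions, 1L)

  # task symmetry: swap the sets and toggle the task
  rec_p <- toy_recall("p1_a", "recall_partner", rep("X", 3), c("a", "c", "d"))
  coded_sym <- code_recall_events(rec_p, partner, own, "recall_partner")
  expect_equal(coded_sym$counts, coded$counts)

  # counts partition the deduplicated reports
  rec_dup <- toy_recall("p1_a", "recall_own", rep("X", 5),
                        c("a", "a", "c", "d", "d"))
  coded_dup <- code_recall_events(rec_dup, own, partner, "recall_own")
  expect_equal(coded_dup$counts$n_reported, 3L)
  expect_equal(with(coded_dup$counts, n_correct + n_source_errors + n_intrusions),
               coded_dup$counts$n_reported)
})

test_that("overlapping encoding sets are rejected", {
  own <- action_set("X", c("a", "b"))
  partner <- action_set("X", c("b", "c"))
  rec <- toy_recall("p1_a", "recall_own", "X", "a")
  expect_error(code_recall_events(rec, own, partner, "recall_own"),
               class = "guessnull_integrity_error")
})

test_that("NOVEL codes and removed pair-duplicates are handled in coding", {
  own <- action_set("X", "a")
  partner <- action_set("X", "c")
  removed <- action_set("X", "z")
  rec <- toy_recall("p1_a", "recall_own", rep("X", 3),
                    c("NOVEL:tok1", "z", "a"))
  coded <- code_recall_events(rec, own, partner, "recall_own", removed = removed)
  expect_equal(coded$counts$n_intrusions, 1L)       # only the NOVEL item
  expect_equal(coded$counts$n_correct, 1L)
  expect_equal(coded$counts$n_reported, 2L)          # "z" excluded entirely
  expect_true("excluded_duplicate" %in% coded$labels$label)
})

test_that("the extended-recall filter splits reported from withheld", {
  rec <- toy_recall("p1_a", "recall_own", rep("X", 10), paste0("c", 1:10),
                    attributed = c(rep(TRUE, 4), rep(FALSE, 6)))
  ext <- apply_extended_recall_filter(rec, "extended")
  expect_equal(sum(ext$report_status == "reported"), 4L)
  expect_equal(sum(ext$report_status == "withheld"), 6L)
  free <- apply_extended_recall_filter(rec, "free_report")
  expect_true(all(free$report_status == "reported"))

  all_true <- apply_extended_recall_filter(
    toy_recall("p", "recall_own", "X", "a", attributed = TRUE), "extended")
  expect_true(all(all_true$report_status == "reported"))
  all_false <- apply_extended_recall_filter(
    toy_recall("p", "recall_own", "X", "a", attributed = FALSE), "extended")
  expect_true(all(all_false$report_status == "withheld"))
})

test_that("code_recall assigns load conditions from the observation schedule", {
  rows <- dplyr::bind_rows(
    gen_row("p1_a", "focal", "X", "a1", 1, load = "none"),
    gen_row("p1_a", "focal", "Y", "a2", 2, load = "action_planning"),
    gen_row("p1_b", "partner", "X", "b1", 1, load = "none"),
    gen_row("p1_b", "partner", "Y", "b2", 2, load = "action_planning"))
  gen <- toy_generation(rows = rows)
  prep <- prepare_encoding(gen)
  # p1_a observed p1_b's Y-action under action_planning load
  cond_a <- prep$conditions[prep$conditions$participant_id == "p1_a", ]
  expect_equal(cond_a$condition[cond_a$shape_id == "Y"], "action_planning")

  rec <- toy_recall("p1_a", "recall_own", c("X", "Y"), c("a1", "b2"))
  coded <- code_recall(rec, prep)
  expect_equal(nrow(coded$counts), 2L)  # one cell per condition
  y_cell <- coded$counts[coded$counts$condition == "action_planning", ]
  expect_equal(y_cell$n_source_errors, 1L)
})
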