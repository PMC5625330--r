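test_that("the default action space matches the design's inventory", {
  space <- make_action_space(seed = 1)
  sizes <- table(space$shape_id)
  expect_length(sizes, 15)
  expect_true(all(sizes >= 20 & sizes <= 40))
  sums <- tapply(space$prob, space$shape_id, sum)
  expect_equal(as.numeric(sums), rep(1, 15), tolerance = 1e-12)

  # zipf exponent 0 is the uniform limit
  flat <- make_action_space(action_space_config(zipf_s = 0), seed = 2)
  one_shape <- flat[flat$shape_id == flat$shape_id[1], ]
  expect_equal(one_shape$prob, rep(1 / nrow(one_shape), nrow(one_shape)))

  expect_identical(make_action_space(seed = 9), make_action_space(seed = 9))
})

test_that("each member generates exemplars_per_shape actions per cue", {
  space <- make_action_space(seed = 4)
  gen <- simulate_generation_phase(space, encoding_config(p_self_repeat = 0,
                                                          p_partner_duplicate = 0),
                                   seed = 10)
  per_member <- table(gen$participant_id)
  expect_equal(as.integer(per_member), c(45L, 45L))  # 15 cues x 3 exemplars
  expect_equal(max(gen$trial_index), 45L)
  # zero duplication: all actions distinct within the pair
  expect_equal(anyDuplicated(gen[c("shape_id", "action_code")]), 0L)

  four <- simulate_generation_phase(space, encoding_config(exemplars_per_shape = 4),
                                    seed = 11)
  expect_equal(as.integer(table(four$participant_id)), c(60L, 60L))
})

test_that("p_partner_duplicate = 1 makes every eligible draw a duplication", {
  space <- make_action_space(seed = 4)
  gen <- simulate_generation_phase(space,
                                   encoding_config(p_partner_duplicate = 1,
                                                   p_self_repeat = 0),
                                   seed = 12)
  # first performance per shape is fresh; every other draw copies the
  # partner, so each shape carries exactly one distinct action
  per_shape <- tapply(gen$action_code, gen$shape_id, dplyr::n_distinct)
  expect_true(all(per_shape == 1))
})

test_that("an infeasible support is rejected", {
  space <- make_action_space(action_space_config(support_range = c(4L, 5L)),
                             seed = 1)
  expect_error(simulate_generation_phase(space, encoding_config(exemplars_per_shape = 3)),
               class = "guessnull_domain_error")
})

test_that("test-phase boundary regimes are forced by the parameters", {
  space <- make_action_space(action_space_config(n_shapes = 4), seed = 6)
  enc <- encoding_config(p_self_repeat = 0, p_partner_duplicate = 0)
  gen <- simulate_generation_phase(space, enc, seed = 13)
  own_id <- unique(gen$participant_id[gen$role == "focal"])

  perfect <- recall_config(p_retrieve_own = 1, p_retrieve_partner = 1,
                           p_source_confusion = 0, guess_lambda = 0)
  rec <- simulate_test_phase(gen, space, perfect, "recall_own",
                             participants = own_id, seed = 14)
  own_set <- gen[gen$participant_id == own_id, c("shape_id", "action_code")]
  expect_setequal(action_key(rec$shape_id, rec$action_code),
                  action_key(own_set$shape_id, own_set$action_code))

  confused <- recall_config(p_retrieve_own = 1, p_retrieve_partner = 1,
                            p_source_confusion = 1, guess_lambda = 0)
  rec2 <- simulate_test_phase(gen, space, confused, "recall_own",
                              participants = own_id, seed = 15)
  partner_set <- gen[gen$participant_id != own_id, c("shape_id", "action_code")]
  expect_setequal(action_key(rec2$shape_id, rec2$action_code),
                  action_key(partner_set$shape_id, partner_set$action_code))

  # zero confusion and zero guessing leave no source errors or intrusions
  prep <- prepare_encoding(gen)
  coded <- code_recall(rec, prep)
  expect_true(all(coded$counts$n_source_errors == 0))
  expect_true(all(coded$counts$n_intrusions == 0))
})

test_that("simulated datasets validate, round-trip and are seed-deterministic", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sim1 <- simulate_experiment(n_pairs = 4, seed = 33, dir = dir1)
  sim2 <- simulate_experiment(n_pairs = 4, seed = 33, dir = dir2)
  expect_identical(readLines(file.path(dir1, "generation.csv")),
                   readLines(file.path(dir2, "generation.csv")))
  expect_identical(readLines(file.path(dir1, "recall.csv")),
                   readLines(file.path(dir2, "recall.csv")))
  expect_no_error(read_generation_events(file.path(dir1, "generation.csv")))
  expect_no_error(read_recall_events(file.path(dir1, "recall.csv")))
  truth <- jsonlite::read_json(file.path(dir1, "truth.json"))
  expect_equal(truth$seed, 33)
  expect_equal(truth$recall$p_source_confusion,
               sim1$truth$recall$p_source_confusion)

  sim3 <- simulate_experiment(n_pairs = 4, seed = 34)
  expect_false(identical(sim1$recall, sim3$recall))
})

test_that("monitoring in extended recall withholds would-be source errors", {
  space <- make_action_space(seed = 8)
  enc <- encoding_config(p_self_repeat = 0, p_partner_duplicate = 0)
  withr::with_seed(120, {
    gen <- purrr::map(1:15, function(i) {
      simulate_generation_phase(space, enc, pair_id = sprintf("pair%02d", i))
    }) |> purrr::list_rbind()
    own_ids <- unique(gen$participant_id[gen$role == "focal"])
    strict <- recall_config(monitoring_strictness = 0.9)
    lax <- recall_config(monitoring_strictness = 0)
    rec_strict <- simulate_test_phase(gen, space, strict, "recall_own",
                                      "extended", participants = own_ids)
    rec_lax <- simulate_test_phase(gen, space, lax, "recall_own",
                                   "extended", participants = own_ids)
  })
  prep <- prepare_encoding(gen)
  n_src <- function(rec) sum(code_recall(rec, prep, "extended")$counts$n_source_errors)
  expect_lt(n_src(rec_strict), n_src(rec_lax))
})

test_that("encoding load reduces partner recall but not the guessing prediction", {
  space <- make_action_space(seed = 16)
  schedule <- setNames(rep("motor_execution", 15), default_shapes)
  run_with_penalty <- function(penalty, seed) {
    enc <- encoding_config(load_schedule = schedule,
                           load_encoding_penalty = penalty)
    withr::with_seed(seed, {
      gen <- purrr::map(1:40, function(i) {
        simulate_generation_phase(space, enc, pair_id = sprintf("pair%02d", i))
      }) |> purrr::list_rbind()
      gen <- as_generation_events(gen)
      attr(gen, "load_encoding_penalty") <- penalty
      ids <- unique(gen$participant_id)
      own_ids <- unique(gen$participant_id[gen$role == "focal"])
      partner_ids <- setdiff(ids, own_ids)
      rec <- dplyr::bind_rows(
        simulate_test_phase(gen, space, recall_config(), "recall_own",
                            participants = own_ids),
        simulate_test_phase(gen, space, recall_config(), "recall_partner",
                            participants = partner_ids))
    })
    prep <- prepare_encoding(gen)
    coded <- code_recall(rec, prep)
    preds <- guessing_predictions(coded, prep, build_frequency_norms(gen),
                                  n_reps = 200, seed = seed)
    list(counts = coded$counts, preds = preds)
  }
  loaded <- run_with_penalty(0.5, seed = 60)
  control <- run_with_penalty(1, seed = 61)

  correct_partner <- function(x) {
    mean(x$counts$n_correct[x$counts$task == "recall_partner"])
  }
  expect_lt(correct_partner(loaded), 0.8 * correct_partner(control))

  # predicted (guessing-based) source errors are load-insensitive: the two
  # runs' per-participant predictions differ only by sampling noise
  pred_own <- function(x) x$preds$predicted_source_errors[x$preds$task == "recall_own"]
  tt <- t.test(pred_own(loaded), pred_own(control))
  expect_gt(tt$p.value, 0.01)
})

test_that("the pipeline's paired test holds its size under pure guessing", {
  # many replicate mini-experiments under the guessing null: reject at ~ alpha.
  # The reduction shrinks cues and pairs but keeps the per-cue support at the
  # real design's scale (>= 20): cramped supports make per-shape depletion
  # material and genuinely distort the guessing null.
  space_cfg <- action_space_config(n_shapes = 3, support_range = c(20L, 20L),
                                   shapes = c("X", "Y", "Z"))
  enc <- encoding_config(exemplars_per_shape = 2, p_self_repeat = 0,
                         p_partner_duplicate = 0)
  rec_cfg <- recall_config(p_retrieve_own = 0.6, p_retrieve_partner = 0,
                           p_source_confusion = 0, guess_lambda = 1,
                           p_guess_outside_inventory = 0)
  n_rep_experiments <- 500
  seeds <- 11000 + seq_len(n_rep_experiments)
  p_values <- vapply(seeds, function(s) {
    sim <- simulate_experiment(n_pairs = 9, space_config = space_cfg,
                               enc = enc, rec = rec_cfg, tasks = "own",
                               seed = s)
    an <- suppressWarnings(  # tiny cells may flag degenerate replicates
      run_analysis(sim$generation, sim$recall, n_reps = 150, seed = s,
                   anova = FALSE, effects = FALSE))
    an$tests$p.value[1]
  }, numeric(1))
  rejection <- mean(p_values < 0.05)
  band <- 2.58 * sqrt(0.05 * 0.95 / n_rep_experiments)
  expect_lt(abs(rejection - 0.05), band)
})
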