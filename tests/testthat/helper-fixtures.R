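# Small builders and independent oracles used across the suite.

# Norms with given per-shape probability vectors, e.g.
# toy_norms(S1 = c(a = 0.5, b = 0.25, c = 0.25))
toy_norms <- function(...) {
  shapes <- list(...)
  df <- purrr::imap(shapes, function(p, shape) {
    tibble::tibble(shape_id = shape, action_code = names(p), prob = unname(p))
  }) |> purrr::list_rbind()
  as_frequency_norms(df)
}

action_set <- function(shape_id, codes) {
  tibble::tibble(shape_id = shape_id, action_code = codes)
}

# Generation events for one pair written out by hand; trial indices follow
# the stated order, alternating focal/partner per round.
toy_generation <- function(pair = "p1",
                           a = "p1_a", b = "p1_b",
                           rows) {
  df <- tibble::as_tibble(rows)
  df$pair_id <- pair
  if (!"load_condition" %in% names(df)) df$load_condition <- "none"
  as_generation_events(df)
}

gen_row <- function(participant, role, shape, code, trial,
                    load = "none") {
  tibble::tibble(participant_id = participant, role = role, shape_id = shape,
                 action_code = code, trial_index = trial,
                 load_condition = load)
}

toy_recall <- function(participant, task, shapes, codes,
                       attributed = TRUE) {
  tibble::tibble(participant_id = participant, task = task,
                 shape_id = shapes, action_code = codes,
                 output_order = seq_along(codes),
                 attributed_to_target = rep_len(attributed, length(codes)))
}

# Classical sums-of-squares oracle for a balanced two-way mixed design
# (equal subjects per group, one observation per subject x within level).
# Independent of stats::aov: everything from cell means by hand.
mixed_anova_oracle <- function(d) {
  # d: data.frame with y, s, b, w
  G <- length(unique(d$b))
  C <- length(unique(d$w))
  n <- length(unique(d$s)) / G
  stopifnot(n == round(n))
  grand <- mean(d$y)
  m_g <- tapply(d$y, d$b, mean)
  m_c <- tapply(d$y, d$w, mean)
  m_gc <- tapply(d$y, list(d$b, d$w), mean)
  m_s <- tapply(d$y, d$s, mean)
  b_of_s <- tapply(as.character(d$b), d$s, function(x) x[1])

  ss_b <- C * n * sum((m_g - grand)^2)
  ss_subj <- C * sum((m_s - m_g[b_of_s])^2)
  ss_w <- G * n * sum((m_c - grand)^2)
  ss_bw <- n * sum((sweep(sweep(m_gc, 1, m_g), 2, m_c) + grand)^2)
  pred <- m_gc[cbind(as.character(d$b), as.character(d$w))] +
    m_s[as.character(d$s)] - m_g[as.character(d$b)]
  ss_err <- sum((d$y - pred)^2)

  df_subj <- G * (n - 1)
  df_err <- G * (n - 1) * (C - 1)
  list(
    F_b = (ss_b / (G - 1)) / (ss_subj / df_subj),
    F_w = (ss_w / (C - 1)) / (ss_err / df_err),
    F_bw = (ss_bw / ((G - 1) * (C - 1))) / (ss_err / df_err))
}

# Monte Carlo standard error of a mean ratio over retained replicates.
mc_se <- function(rep_ratios) {
  r <- rep_ratios[is.finite(rep_ratios)]
  stats::sd(r) / sqrt(length(r))
}
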