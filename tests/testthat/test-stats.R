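test_that("paired one-tailed t matches hand arithmetic", {
  res <- paired_t_onetailed(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2L)
  expect_equal(res$d_av, 2 / ((2 + 1) / 2), tolerance = 1e-10)
  expect_equal(res$p_one_tailed, pt(res$t, 2, lower.tail = FALSE))

  same <- paired_t_onetailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_one_tailed, 0.5)
  expect_equal(same$d_av, 0)
  expect_true(same$degenerate)

  shifted <- paired_t_onetailed(c(2, 3, 4), c(1, 2, 3))  # constant diff of 1
  expect_equal(shifted$t, Inf)
  expect_equal(shifted$p_one_tailed, 0)
  expect_true(shifted$degenerate)
  expect_equal(shifted$d_av, 1)  # SDs are 1 on both sides

  dz <- paired_t_onetailed(c(2, 4, 6), c(1, 2, 3), d_method = "d_z")
  expect_equal(dz$d_av, 2 / 1)
})

test_that("the paired test holds its one-tailed type-I error under the null", {
  n_runs <- 2000
  rejections <- withr::with_seed(314, {
    mean(replicate(n_runs, {
      obs <- rnorm(18)
      pred <- rnorm(18)
      paired_t_onetailed(obs, pred)$p_one_tailed < 0.05
    }))
  })
  band <- 2.58 * sqrt(0.05 * 0.95 / n_runs)
  expect_lt(abs(rejections - 0.05), band)
})

test_that("within-subject CIs remove subject offsets and scale as expected", {
  base <- matrix(c(1, 2, 3,
                   2, 3, 4,
                   3, 4, 5,
                   4, 5, 6), nrow = 4, byrow = TRUE)
  # pure subject offsets: identical condition differences for everyone
  ci <- within_subject_ci(base)
  expect_equal(ci$ci_half, rep(0, 3))

  m <- matrix(rnorm(20), nrow = 10, ncol = 2)
  ci2 <- within_subject_ci(m)
  d <- m[, 1] - m[, 2]
  paired_half <- qt(0.975, 9) * sd(d) / sqrt(10)
  expect_equal(ci2$ci_half, rep(paired_half / sqrt(2), 2), tolerance = 1e-10)

  # adding a per-subject constant leaves the half-widths unchanged
  shifted <- m + matrix(rnorm(10), nrow = 10, ncol = 2)
  expect_equal(within_subject_ci(shifted)$ci_half, ci2$ci_half,
               tolerance = 1e-10)

  expect_error(within_subject_ci(m[, 1, drop = FALSE]),
               class = "guessnull_domain_error")
})

test_that("mixed ANOVA matches the hand sums-of-squares oracle", {
  make_design <- function(seed, G = 2, C = 2, n = 4) {
    withr::with_seed(seed, {
      d <- expand.grid(s = seq_len(G * n), w = paste0("w", seq_len(C)))
      d$b <- paste0("g", ceiling(d$s / n))
      d$s <- paste0("s", d$s)
      d$y <- rnorm(nrow(d)) + as.integer(factor(d$b)) * 0.5 +
        as.integer(factor(d$w)) * 0.3 + rnorm(G * n)[as.integer(factor(d$s))]
      d
    })
  }
  for (seed in 1:12) {
    C <- sample(2:3, 1)
    d <- make_design(seed, C = C, n = 3 + seed %% 3)
    fit <- mixed_anova(d, dv = "y", subject = "s", between = "b", within = "w")
    oracle <- mixed_anova_oracle(d)
    F_of <- function(term) fit$table$statistic[fit$table$term == term]
    expect_equal(F_of("b"), unname(oracle$F_b), tolerance = 1e-8)
    expect_equal(F_of("w"), unname(oracle$F_w), tolerance = 1e-8)
    expect_equal(F_of("b:w"), unname(oracle$F_bw), tolerance = 1e-8)
  }
})

test_that("mixed ANOVA handles degenerate and invalid inputs", {
  d <- expand.grid(s = paste0("s", 1:8), w = c("w1", "w2"))
  d$b <- rep(c("g1", "g2"), each = 4)[match(d$s, paste0("s", 1:8))]
  d$y <- 1  # all values equal
  fit <- mixed_anova(d, "y", "s", "b", "w")
  expect_true(all(fit$table$statistic == 0))

  # identical permutation of within labels for every subject leaves the
  # within main effect unchanged
  d2 <- d
  d2$y <- rnorm(nrow(d2))
  fit_a <- mixed_anova(d2, "y", "s", "b", "w")
  d3 <- d2
  d3$w <- ifelse(d2$w == "w1", "w2", "w1")
  fit_b <- mixed_anova(d3, "y", "s", "b", "w")
  expect_equal(fit_a$table$statistic[fit_a$table$term == "w"],
               fit_b$table$statistic[fit_b$table$term == "w"])

  unbalanced <- d2[-1, ]
  expect_error(mixed_anova(unbalanced, "y", "s", "b", "w"),
               class = "guessnull_domain_error", regexp = "listwise")
})

test_that("half-normal Bayes factor: closed form, quadrature and limits agree", {
  grid <- expand.grid(mean = c(-2, -0.5, 0, 0.5, 2),
                      se = c(0.05, 0.2, 1),
                      prior = c(0.1, 1, 3))
  for (i in seq_len(nrow(grid))) {
    bf <- dienes_bf(grid$mean[i], grid$se[i], grid$prior[i])
    # relative error on the BF scale, stable even where exp() overflows
    expect_lt(abs(expm1(bf$log_bf10_numeric - bf$log_bf10)), 1e-6)
  }

  # collapsing the prior onto the null drives the BF to 1
  expect_equal(dienes_bf(0.4, 0.3, 1e-8)$bf10, 1, tolerance = 1e-4)

  # monotone in the data mean; below 1 at a zero mean
  bfs <- vapply(seq(-1, 2, by = 0.25),
                function(m) dienes_bf(m, 0.3, 1)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_lt(dienes_bf(0, 0.3, 1)$bf10, 1)

  expect_error(dienes_bf(0.1, 0, 1), class = "guessnull_domain_error")
  expect_error(dienes_bf(0.1, 0.2, -1), class = "guessnull_domain_error")
})
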