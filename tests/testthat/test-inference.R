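test_that("one-sample t matches its closed form and edge cases", {
  tt <- one_sample_t(c(9, 10, 11))
  expect_equal(tt$statistic, 10 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tt$df, 2)
  # symmetric sample around the null mean
  t0 <- one_sample_t(c(-2, -1, 1, 2), mu0 = 0)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_error(one_sample_t(5), "at least 2")
  expect_error(one_sample_t(c(3, 3, 3)), "zero variance")
})

test_that("Welch t matches its closed form and the pooled special case", {
  expect_equal(welch_t(1:5, 1:5)$statistic, 0)
  tt <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(tt$df, 4, tolerance = 1e-9)
  # equal variances and equal n: identical to the pooled-variance t
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10) + 0.5
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)   # force equal variance
  pooled <- stats::t.test(x, y, var.equal = TRUE)
  w <- welch_t(x, y)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-9)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("both t-tests agree with the reference implementation", {
  set.seed(77)
  for (i in 1:200) {
    x <- rnorm(sample(3:40, 1), mean = rnorm(1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:40, 1), mean = rnorm(1), sd = runif(1, 0.5, 3))
    mu <- rnorm(1)
    ref1 <- stats::t.test(x, mu = mu)
    got1 <- one_sample_t(x, mu0 = mu)
    expect_equal(got1$statistic, unname(ref1$statistic), tolerance = 1e-9)
    expect_equal(got1$p, ref1$p.value, tolerance = 1e-9)
    ref2 <- stats::t.test(x, y)
    got2 <- welch_t(x, y)
    expect_equal(got2$statistic, unname(ref2$statistic), tolerance = 1e-9)
    expect_equal(got2$df, unname(ref2$parameter), tolerance = 1e-9)
    expect_equal(got2$p, ref2$p.value, tolerance = 1e-9)
  }
  # one-sided p-values complement each other
  set.seed(78)
  x <- rnorm(12, 1)
  pg <- one_sample_t(x, sidedness = "greater")$p
  pl <- one_sample_t(x, sidedness = "less")$p
  expect_equal(pg + pl, 1, tolerance = 1e-12)
})

test_that("strong positive and negative responders are classified", {
  set.seed(41)
  expect_equal(classify_participant(rnorm(50, 15, 8))$label, "adapter")
  expect_equal(classify_participant(rnorm(50, -15, 8))$label, "follower")
})

test_that("classification counts partition the cohort", {
  co <- simulate_cohort(experiment_design(n_congruent = 3, n_incongruent = 3),
                        master_seed = 13)
  cls <- classify_cohort(co$trials, experiment_design()$perturbation)
  expect_equal(sum(cls$counts), 6)
  expect_equal(unname(rowSums(cls$counts)), c(3, 3))
  expect_setequal(colnames(cls$counts), c("adapter", "follower", "none"))
  expect_true(all(cls$classifications$label %in%
                    c("adapter", "follower", "none")))
})

test_that("identical groups produce a null group effect in the LMM", {
  base <- expand.grid(block = 3:7, trial_in_block = 1:10,
                      participant_id = sprintf("p%d", 1:6))
  set.seed(9)
  base$score <- 10 + 2 * base$block + rnorm(nrow(base), sd = 4) +
    rep(rnorm(6, sd = 2), each = 50)
  base$sentence_id <- base$trial_in_block
  two <- rbind(transform(base, group = "g1"),
               transform(base, group = "g2",
                         participant_id = paste0(participant_id, "b")))
  fit <- suppressWarnings(group_contrast_lmm(two))
  expect_lt(abs(fit$coefficients["groupg2", "Estimate"]), 1e-6)
  expect_gt(fit$interaction$p, 0.9)
})

test_that("the block-by-group interaction recovers the built-in asymmetry", {
  for (s in 1:3) {
    co <- simulate_cohort(experiment_design(n_congruent = 6,
                                            n_incongruent = 6),
                          master_seed = 100 + s)
    sc <- cohort_adaptation_scores(co$trials,
                                   experiment_design()$perturbation)
    fit <- suppressWarnings(group_contrast_lmm(sc))
    # adaptation builds up more slowly/less in the incongruent group
    expect_lt(fit$coefficients["block:groupincongruent", "Estimate"], 0)
  }
})

test_that("singular sentence intercepts are dropped with a warning", {
  base <- expand.grid(block = 3:7, trial_in_block = 1:8,
                      participant_id = sprintf("p%d", 1:4))
  set.seed(10)
  base$sentence_id <- base$trial_in_block
  # sentence effects cancel exactly across participants, so the sentence
  # variance component sits on the boundary
  sgn <- ifelse(base$participant_id %in% c("p1", "p2"), 1, -1)
  base$score <- 3 * base$block + rep(rnorm(4, sd = 3), each = 40) +
    sgn * 5 * base$sentence_id + rnorm(nrow(base), sd = 0.5)
  two <- rbind(transform(base, group = "g1"),
               transform(base, group = "g2",
                         participant_id = paste0(participant_id, "b")))
  expect_warning(fit <- group_contrast_lmm(two), "singular")
  expect_true(fit$simplified)
  expect_false("sentence_id" %in% names(lme4::ranef(fit$fit)))
})
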