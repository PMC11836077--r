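test_that("production change is the mean of sentence-matched differences", {
  base <- data.frame(sentence_id = c("a", "b"),
                     f1 = c(600, 610), f2 = c(1400, 1390))
  trials <- rbind(
    data.frame(participant_id = "p1", group = "congruent", block = 2,
               trial_in_block = 1:2, sentence_id = c("a", "b"),
               f1_mel = c(600, 610), f2_mel = c(1400, 1390), phase = "x"),
    data.frame(participant_id = "p1", group = "congruent", block = 6,
               trial_in_block = 1:2, sentence_id = c("a", "b"),
               f1_mel = c(590, 600), f2_mel = c(1410, 1420), phase = "x"))
  pc <- production_change(trials, "p1", 2, 6)
  expect_equal(c(pc$dF1, pc$dF2), c(-10, 20))
  expect_equal(pc$n_skipped, 0)
  expect_equal(pc$dF1, mean(pc$per_sentence$dF1))
})

test_that("identical and uniformly offset blocks give trivial changes", {
  base <- base_sentences(5)
  tr <- make_trials(base, list(`2` = c(0, 0), `6` = c(0, 0)))
  pc <- production_change(tr, "p1", 2, 6)
  expect_equal(c(pc$dF1, pc$dF2), c(0, 0))
  tr2 <- make_trials(base, list(`2` = c(0, 0), `6` = c(5, -3)))
  pc2 <- production_change(tr2, "p1", 2, 6)
  expect_equal(c(pc2$dF1, pc2$dF2), c(5, -3))
})

test_that("sentences missing from either block are skipped and counted", {
  base <- base_sentences(4)
  tr <- make_trials(base, list(`2` = c(0, 0), `6` = c(2, 2)))
  tr <- tr[!(tr$block == 6 & tr$sentence_id == 4), ]
  pc <- production_change(tr, "p1", 2, 6)
  expect_equal(nrow(pc$per_sentence), 3)
  expect_equal(pc$n_skipped, 1)
  # disjoint sentences: error
  tr_ref <- make_trials(base_sentences(2), list(`2` = c(0, 0)))
  tr_cmp <- make_trials(base_sentences(2), list(`6` = c(0, 0)))
  tr_cmp$sentence_id <- tr_cmp$sentence_id + 10
  expect_error(production_change(rbind(tr_ref, tr_cmp), "p1", 2, 6),
               "no overlapping sentences")
})

test_that("the projection statistic matches its documented anchor cases", {
  spec <- default_spec()
  expect_equal(adaptation_projection(-49.5, 49.5, spec), 70, tolerance = 1e-3)
  expect_equal(adaptation_projection(49.5, -49.5, spec), -70, tolerance = 1e-3)
  expect_equal(adaptation_projection(-10, 0, spec), 7.0711, tolerance = 1e-4)
  expect_equal(adaptation_projection(0, 0, spec), 0)
  expect_error(adaptation_projection(1, 1, perturbation_spec(shift_vector(0, 315))),
               "nonzero")
})

test_that("the projection equals the angle-based brute-force oracle", {
  set.seed(99)
  spec <- perturbation_spec(shift_vector(runif(1, 10, 200), runif(1, 0, 360)))
  for (i in 1:1000) {
    v <- rnorm(2, sd = 40)
    expect_equal(adaptation_projection(v[1], v[2], spec),
                 brute_force_projection(v[1], v[2], spec), tolerance = 1e-9)
  }
})

test_that("the projection is linear and bounded by the change magnitude", {
  set.seed(7)
  spec <- default_spec()
  for (i in 1:200) {
    u <- rnorm(2, sd = 30); v <- rnorm(2, sd = 30)
    al <- rnorm(1); be <- rnorm(1)
    w <- al * u + be * v
    expect_equal(adaptation_projection(w[1], w[2], spec),
                 al * adaptation_projection(u[1], u[2], spec) +
                   be * adaptation_projection(v[1], v[2], spec),
                 tolerance = 1e-9)
    expect_lte(abs(adaptation_projection(u[1], u[2], spec)),
               sqrt(sum(u^2)) + 1e-12)
  }
  # equality iff collinear with the perturbation axis
  d <- shift_components(spec$shift)
  expect_equal(abs(as.numeric(adaptation_projection(-2 * d[1], -2 * d[2], spec))),
               2 * spec$shift$magnitude, tolerance = 1e-9)
})

test_that("blockwise adaptation averages per-trial projections per block", {
  base <- base_sentences(6)
  tr <- make_trials(base, list(`2` = c(0, 0), `3` = c(0, 0), `4` = c(0, 0),
                               `5` = c(0, 0), `6` = c(0, 0), `7` = c(0, 0)))
  ba <- blockwise_adaptation(tr, "p1", default_spec())
  expect_equal(ba$block, 3:7)
  expect_equal(ba$adaptation, rep(0, 5))
  off <- list(`2` = c(0, 0), `3` = c(-49.5, 49.5), `4` = c(-49.5, 49.5),
              `5` = c(-49.5, 49.5), `6` = c(-49.5, 49.5), `7` = c(-49.5, 49.5))
  ba2 <- blockwise_adaptation(make_trials(base_sentences(6), off), "p1",
                              default_spec())
  expect_equal(ba2$adaptation, rep(70, 5), tolerance = 1e-3)
  expect_equal(ba2$n_trials, rep(6, 5))
})

test_that("trials whose sentence lacks a baseline are skipped with a count", {
  base <- base_sentences(5)
  tr <- make_trials(base, list(`2` = c(0, 0), `6` = c(1, 1)))
  tr <- tr[!(tr$block == 2 & tr$sentence_id == 5), ]
  sc <- trial_adaptation(tr, "p1", default_spec(), blocks = 6)
  expect_equal(nrow(sc), 4)
  expect_equal(attr(sc, "n_skipped"), 1)
})

test_that("convergence change is the baseline-window production change", {
  base <- base_sentences(4)
  tr <- make_trials(base, list(`1` = c(0, 0), `2` = c(-7.55, 10.51)))
  expect_equal(unname(convergence_change(tr, "p1")), c(-7.55, 10.51))
  tr0 <- make_trials(base, list(`1` = c(0, 0), `2` = c(0, 0)))
  expect_equal(unname(convergence_change(tr0, "p1")), c(0, 0))
})

test_that("the congruency score projects the baseline-window change", {
  spec <- default_spec()
  expect_equal(congruency_score(-7.55, 10.51, spec), 12.77, tolerance = 0.005)
  d <- shift_components(spec$shift)
  expect_equal(as.numeric(congruency_score(-d[1], -d[2], spec)),
               spec$shift$magnitude, tolerance = 1e-9)
  expect_equal(as.numeric(congruency_score(d[1], d[2], spec)),
               -spec$shift$magnitude, tolerance = 1e-9)
})

test_that("the eligibility screen matches the intended geometry", {
  con_acc <- c(524, 1435)
  inc_acc <- c(641, 1303)
  expect_true(screen_participant(c(623.89, 1368.31), con_acc, "congruent"))
  expect_true(screen_participant(c(593.63, 1339.06), inc_acc, "incongruent"))
  expect_false(screen_participant(c(500, 1500), con_acc, "congruent"))
  expect_false(screen_participant(c(700, 1250), inc_acc, "incongruent"))
  # ties are ineligible
  expect_false(screen_participant(c(524, 1300), con_acc, "congruent"))
  expect_error(screen_participant(c(600, 1400), con_acc, "solo"))
})

test_that("accompanist distance is the componentwise absolute difference", {
  expect_equal(unname(accompanist_distance(c(623.89, 1368.31), c(524, 1435))),
               c(99.89, 66.69))
  expect_equal(unname(accompanist_distance(c(593.63, 1339.06), c(641, 1303))),
               c(47.37, 36.06))
  expect_equal(unname(accompanist_distance(c(600, 1400), c(600, 1400))),
               c(0, 0))
})
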