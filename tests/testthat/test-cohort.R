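test_that("zero-SD sampling returns the group mean baseline", {
  p <- sample_participant("congruent", baseline_sd = c(0, 0), seed = 1)
  expect_equal(unname(p$baseline), c(623.89, 1368.31))
  q <- sample_participant("incongruent", baseline_sd = c(0, 0), seed = 1)
  expect_equal(unname(q$baseline), c(593.63, 1339.06))
})

test_that("sampled baselines are near the group distribution and screened", {
  set.seed(11)
  for (g in c("congruent", "incongruent")) {
    defs <- group_defaults(g)
    for (i in 1:25) {
      p <- sample_participant(g)
      expect_true(screen_participant(p$baseline, defs$accompanist$formants, g))
      expect_true(all(abs(p$baseline - defs$baseline_mean) <
                        5 * defs$baseline_sd))
    }
  }
})

test_that("a baseline distribution on the wrong side of the accompanist errors", {
  expect_error(
    sample_participant("congruent", baseline_mean = c(400, 1600),
                       baseline_sd = c(0, 0), seed = 1, max_redraws = 5),
    "no eligible baseline")
})

test_that("a simulated participant yields the full blocked trial structure", {
  p <- sample_participant("congruent", seed = 3)
  tr <- simulate_participant(p, seed = 4)
  expect_equal(nrow(tr), 350)
  expect_equal(sort(unique(tr$block)), 1:7)
  # every sentence exactly once per block
  counts <- table(tr$block, tr$sentence_id)
  expect_true(all(counts == 1))
  expect_equal(unique(tr$phase[tr$block == 1]), "baseline_solo")
  expect_equal(unique(tr$phase[tr$block == 7]), "after_effect")
})

test_that("the simulator is deterministic given a seed", {
  p <- sample_participant("incongruent", seed = 5)
  expect_identical(simulate_participant(p, seed = 6),
                   simulate_participant(p, seed = 6))
  co1 <- simulate_cohort(master_seed = 9,
                         design = experiment_design(n_congruent = 2,
                                                    n_incongruent = 2))
  co2 <- simulate_cohort(master_seed = 9,
                         design = experiment_design(n_congruent = 2,
                                                    n_incongruent = 2))
  expect_identical(co1$trials, co2$trials)
  expect_identical(co1$truth, co2$truth)
})

test_that("with no drive and no noise production sits at baseline", {
  p <- quiet_profile(conv_asymptote = 0)
  zdesign <- experiment_design(perturbation = perturbation_spec(shift_vector(0, 315)))
  tr <- simulate_participant(p, zdesign, seed = 1)
  expect_equal(tr$f1_mel, rep(600, 350))
  expect_equal(tr$f2_mel, rep(1400, 350))
})

test_that("under a sustained perturbation the state reaches the closed-form fixed point", {
  # long hold so the recursion converges: x* = -b p / (1 - a + b)
  spec <- perturbation_spec(shift_vector(70, 315), ramp_block = 2,
                            ramp_trials = 1, hold_end_block = 29,
                            off_block = 30)
  des <- experiment_design(n_sentences = 20, n_blocks = 30,
                           perturbation = spec)
  p <- quiet_profile(conv_asymptote = 0)
  tr <- simulate_participant(p, des, seed = 1)
  d <- shift_components(spec$shift)
  want <- -0.08 * unname(d) / (1 - 0.99 + 0.08)
  last_hold <- which(tr$block == 29)
  got <- c(tail(tr$state_f1_mel[last_hold], 1), tail(tr$state_f2_mel[last_hold], 1))
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("with convergence drive alone the state moves toward the accompanist", {
  # x* = b gamma (A - B) / (1 - a + b) once gamma has saturated
  spec <- perturbation_spec(shift_vector(0, 315))
  des <- experiment_design(n_sentences = 20, n_blocks = 30,
                           perturbation = spec)
  acc <- make_accompanist(formant_pair(550, 1430), shift_vector(0, 0))
  p <- quiet_profile(conv_asymptote = 1, conv_rate = 5)
  tr <- simulate_participant(p, des, acc, seed = 1)
  AB <- c(550 - 600, 1430 - 1400)
  want <- 0.08 * AB / 0.09
  n <- nrow(tr)
  expect_equal(c(tr$state_f1_mel[n], tr$state_f2_mel[n]), want,
               tolerance = 1e-3)
  expect_equal(tr$gamma[n], 1, tolerance = 1e-6)
})

test_that("unstable dynamics parameters are rejected", {
  expect_error(participant_profile("u", "congruent", c(600, 1400),
                                   retention = 1, learning_rate = 0),
               "unstable")
})

test_that("a default cohort has the published group sizes", {
  co <- simulate_cohort(master_seed = 2)
  n_per <- table(co$trials$participant_id)
  expect_length(n_per, 31)
  expect_true(all(n_per == 350))
  expect_equal(sum(table(unique(co$trials[c("participant_id", "group")])$group)),
               31)
  expect_equal(unname(table(co$trials$group) / 350), c(16, 15),
               ignore_attr = TRUE)
})

test_that("noiseless simulation reproduces the closed-form block adaptation", {
  for (g in c("congruent", "incongruent")) {
    p <- quiet_profile(group = g,
                       baseline = group_defaults(g)$baseline_mean)
    des <- experiment_design()
    tr <- simulate_participant(p, des, seed = 1)
    ba <- blockwise_adaptation(tr, "q", des$perturbation)
    an <- analytic_adaptation(p, des)
    expect_equal(ba$adaptation, unname(an$block_adaptation), tolerance = 1e-8)
  }
})

test_that("congruent cohorts out-adapt incongruent cohorts under defaults", {
  co <- simulate_cohort(master_seed = 7)
  spec <- experiment_design()$perturbation
  ids <- unique(co$trials$participant_id)
  b6 <- vapply(ids, function(id) {
    ba <- blockwise_adaptation(co$trials, id, spec)
    ba$adaptation[ba$block == 6]
  }, numeric(1))
  grp <- co$trials$group[match(ids, co$trials$participant_id)]
  means <- tapply(b6, grp, mean)
  expect_gt(means[["congruent"]], means[["incongruent"]])
})
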