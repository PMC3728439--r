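test_that("decide follows the perceived-value rule", {
  cfg <- cfg_std()
  a <- respondent_profile("r1", c("53555" = 0.5), decision_sd = 0,
                          indifference_tol = 0.1)
  expect_identical(decide(a, offer(12.5, 3L), "53555", cfg), "indifferent")
  b <- respondent_profile("r1", c("53555" = 0.5), decision_sd = 0,
                          indifference_tol = 0)
  expect_identical(decide(b, offer(15, 1L), "53555", cfg), "prefer_B")
  expect_identical(decide(b, offer(10, 2L), "53555", cfg), "prefer_A")
  expect_error(decide(b, offer(12.5, 3L), "11111", cfg), "no true utility")
})

test_that("framing and visual biases shift the effective utility and vanish in the 5+5 arm", {
  a <- respondent_profile("r1", c("53555" = 0.40), decision_sd = 0,
                          indifference_tol = 0, framing_coeff = 0.04)
  # LT/UT = 2: effective utility 0.40 - 0.04 = 0.36, off the 0.05 value grid,
  # so the search settles at the closest grid value
  rec <- run_task(a, "53555", cfg_std())$record
  expect_equal(rec$U, 0.35)
  # ratio 1: no shift, exact recovery
  rec5 <- run_task(a, "53555", cfg_exp5())$record
  expect_equal(rec5$U, 0.40)
  expect_false(rec5$censored)

  b <- respondent_profile("r1", c("53555" = 0.5), decision_sd = 0,
                          indifference_tol = 0, visual_error_coeff = 0.1)
  # 15-year bar: shift -0.1 * (15 - 10)/10 = -0.05, one grid step down
  expect_equal(run_task(b, "53555", cfg_std())$record$U, 0.45)
  expect_equal(run_task(b, "53555", cfg_exp5())$record$U, 0.5)
})

test_that("response times inflate only for engaged raised-bar refinement offers", {
  mk <- function(gamma) respondent_profile("r1", c("53555" = 0.2),
                                           time_sd = 0, engagement_gain = gamma,
                                           base_log_time = log(6))
  raised <- cfg_std("raised_bar"); aligned <- cfg_std()
  a1 <- mk(1)
  # refinement offer near dead: doubled under the raised bar
  expect_equal(response_time(a1, offer(11.25, 3L), raised), 12)
  expect_equal(response_time(a1, offer(11.25, 3L), aligned), 6)
  # opening offers and offers far from dead: never inflated
  expect_equal(response_time(a1, offer(15, 1L), raised), 6)
  expect_equal(response_time(a1, offer(10, 2L), raised), 6)
  expect_equal(response_time(a1, offer(13.75, 4L), raised), 6)  # value 0.75
  # gamma = 0: identical distribution across variants
  a0 <- mk(0)
  set.seed(1); t_r <- response_time(a0, offer(11.25, 3L), raised)
  set.seed(1); t_a <- response_time(a0, offer(11.25, 3L), aligned)
  expect_identical(t_r, t_a)
})

test_that("population sampling is reproducible and honours degenerate SDs", {
  design <- study_design(2)
  p1 <- sample_population(design, profile_params(), seed = 31)
  p2 <- sample_population(design, profile_params(), seed = 31)
  expect_identical(p1, p2)
  expect_equal(sort(table(p1$assignment$arm)), sort(table(p2$assignment$arm)))
  expect_equal(unname(table(p1$assignment$arm)["standard"]), 2)

  pp0 <- profile_params(state_sd = 0)
  pop <- sample_population(study_design(3), pp0, seed = 1)
  for (pr in pop$profiles) {
    expect_equal(unname(pr$true_utilities),
                 unname(pp0$state_means[names(pr$true_utilities)]))
  }
  expect_error(study_design(0), "positive count")
  expect_error(study_design(2, blocks = list(character(0), "11111")),
               "non-empty")
})

test_that("simulate_study yields one record per respondent-state, reproducibly", {
  recs <- simulate_study(study_design(1), profile_params(), seed = 3)
  expect_equal(nrow(recs), 10L)
  expect_equal(dplyr::n_distinct(recs$respondent_id), 2L)
  expect_identical(recs, simulate_study(study_design(1), profile_params(), seed = 3))
  # all-zero noise, grid utilities: exact recovery and no censoring
  pp <- profile_params(state_sd = 0, decision_sd = 0, indifference_tol = 0,
                       state_means = setNames(rep(0.25, 10),
                                              unlist(default_blocks())))
  recs0 <- simulate_study(study_design(4), pp, seed = 4)
  expect_true(all(recs0$U == 0.25))
  expect_true(!any(recs0$censored))
})

test_that("the fast simulation path is draw-for-draw identical to run_task", {
  design <- study_design(8)
  params <- profile_params(engagement_gain = 0.5)
  cfgs <- list(standard = cfg_std("raised_bar"), experimental = cfg_exp5())
  fast <- simulate_study(design, params, cfgs, seed = 99)
  set.seed(99)
  pop <- sample_population(design, params)
  slow <- dplyr::bind_rows(lapply(seq_along(pop$profiles), function(i) {
    agent <- pop$profiles[[i]]
    arm <- pop$assignment$arm[i]
    dplyr::bind_rows(lapply(design$blocks[[pop$assignment$block[i]]],
                            function(s) run_task(agent, s, cfgs[[arm]],
                                                 arm = arm)$record))
  }))
  expect_identical(fast$T, slow$T)
  expect_identical(fast$U, slow$U)
  expect_identical(fast$n_questions, slow$n_questions)
  expect_identical(fast$censored, slow$censored)
  expect_equal(fast$duration_s, slow$duration_s)
})

test_that("exhaustion frequency matches the truncated-normal mass below the bound", {
  # 5+5 arm in both arms: tradable time exhausts iff the true utility lies
  # below -1 - delta, where indifference at T = 0 is still reported within
  # the band. With sigma = 0, delta = 0.05 the threshold is -1.05.
  mu <- -0.8; s <- 0.6
  pp <- profile_params(state_means = setNames(rep(mu, 10), unlist(default_blocks())),
                       state_sd = s, decision_sd = 0, indifference_tol = 0.05)
  cfgs <- list(standard = cfg_exp5(), experimental = cfg_exp5())
  recs <- simulate_study(study_design(200), pp, cfgs, seed = 71)
  p_true <- (pnorm(-1.05, mu, s) - pnorm(-2, mu, s)) /
    (pnorm(1, mu, s) - pnorm(-2, mu, s))
  exhausted <- mean(recs$censored & recs$T == 0)
  n <- nrow(recs)
  expect_lt(abs(exhausted - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  # and those tasks are censored at the printed bound value
  expect_true(all(recs$U[recs$censored & recs$T == 0] == -1))
})

test_that("lead-time framing lowers the long-lead arm's values", {
  pp <- profile_params(framing_coeff = 0.15)
  recs <- simulate_study(study_design(150), pp, seed = 77)
  m <- tapply(recs$U, recs$arm, mean)
  expect_lt(m["standard"], m["experimental"])
})
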