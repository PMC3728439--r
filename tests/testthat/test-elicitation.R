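run_responses <- function(responses, offers, config) {
  tr <- new_trace("53555")
  tr$offers <- offers
  tr$responses <- responses
  tr$times_s <- rep(1, length(offers))
  next_offer(tr, config)
}

test_that("the offer sequence reproduces the printed anchors", {
  cfg <- cfg_std()
  first <- next_offer(new_trace("53555"), cfg)
  expect_equal(first$duration, 15)
  expect_equal(run_responses("prefer_B", 15, cfg)$duration, 10)
  expect_equal(run_responses(c("prefer_B", "prefer_A"), c(15, 10), cfg)$duration, 12.5)
  expect_equal(run_responses(c("prefer_B", "prefer_B"), c(15, 10), cfg)$duration, 5)

  cfg5 <- cfg_exp5()
  expect_equal(next_offer(new_trace("53555"), cfg5)$duration, 10)
  expect_equal(run_responses("prefer_B", 10, cfg5)$duration, 5)
  expect_equal(run_responses(c("prefer_B", "prefer_B"), c(10, 5), cfg5)$duration, 2.5)
  expect_equal(run_responses(c("prefer_B", "prefer_A"), c(10, 5), cfg5)$duration, 7.5)
})

test_that("inconsistent or finished traces raise protocol errors", {
  cfg <- cfg_std()
  tr <- new_trace("53555")
  tr$offers <- c(15, 10)
  tr$responses <- "prefer_B"
  expect_error(next_offer(tr, cfg), "protocol error")
  tr$responses <- c("prefer_B", "indifferent")
  expect_error(next_offer(tr, cfg), "already terminated")
})

test_that("error-free agents terminate at their exact utility", {
  cfg <- cfg_std()
  r <- run_task(error_free_agent(0.5), "53555", cfg)
  expect_equal(r$record$T, 12.5)
  expect_equal(r$record$U, 0.5)
  expect_equal(r$record$n_questions, 3L)
  expect_false(r$record$censored)
  expect_identical(r$trace$offers, c(15, 10, 12.5))
  expect_identical(r$trace$responses, c("prefer_B", "prefer_A", "indifferent"))

  r1 <- run_task(error_free_agent(1), "53555", cfg)$record
  expect_equal(r1$n_questions, 1L)
  expect_equal(r1$U, 1)

  # utility below the tradable bound: the grid is exhausted and the value is
  # censored at T = 0
  rc <- run_task(error_free_agent(-1.5), "53555", cfg_exp5())$record
  expect_true(rc$censored)
  expect_equal(rc$T, 0)
  expect_equal(rc$U, -1)
})

test_that("every grid utility is recovered exactly in both arm designs", {
  for (cfg in list(cfg_std(), cfg_exp5())) {
    g <- value_grid(cfg)
    for (u in g) {
      rec <- run_task(error_free_agent(u), "53555", cfg)$record
      expect_identical(rec$U, u)
      expect_false(rec$censored)
      expect_lte(rec$n_questions, 10L)
    }
  }
})

test_that("elicited values are monotone in the true utility", {
  cfg <- cfg_std()
  us <- seq(-2, 1, by = 0.01)
  Us <- vapply(us, function(u)
    run_task(error_free_agent(u), "53555", cfg)$record$U, numeric(1))
  expect_true(all(diff(Us) >= 0))
})

test_that("off-grid utilities settle at the closest grid value, flagged censored", {
  rec <- run_task(error_free_agent(0.36), "53555", cfg_std())$record
  expect_true(rec$censored)
  expect_equal(rec$U, 0.35)
})

test_that("the trace keeps offers and responses aligned on the grid", {
  set.seed(5)
  agent <- respondent_profile("r1", c("53555" = 0.2), decision_sd = 0.3,
                              indifference_tol = 0.05)
  for (i in 1:20) {
    tr <- run_task(agent, "53555", cfg_std())$trace
    expect_length(tr$responses, length(tr$offers))
    expect_identical(tr$offers, quarters_to_years(years_to_quarters(tr$offers)))
    expect_equal(tr$offers[1], 15)
    if (length(tr$offers) >= 2) expect_equal(tr$offers[2], 10)
    expect_lte(length(tr$offers), 64)
  }
})

test_that("the materialized offer tree matches the engine's schedule", {
  sched <- offer_schedule(cfg_exp5())
  root <- sched[sched$ordinal == 1 & sched$kind == "offer", ]
  expect_equal(root$x, 10)
  node5 <- sched[sched$kind == "offer" & !is.na(sched$x) & sched$x == 5, ]
  kids <- sched[!is.na(sched$parent) & sched$parent == node5$id &
                  sched$kind == "offer", ]
  expect_setequal(kids$x, c(2.5, 7.5))

  offers <- sched[sched$kind == "offer", ]
  expect_true(all(offers$x %in% quarters_to_years(0:cfg_exp5()$max_q)))
  expect_lte(max(sched$ordinal), 12)
  # every grid duration is reachable as an offer
  expect_setequal(unique(offers$x), quarters_to_years(0:cfg_exp5()$max_q))
})
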