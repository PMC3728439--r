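test_that("arm summaries count and average exactly", {
  recs <- dplyr::bind_rows(
    make_records(c(0.5, 0.7), state = "12112",
                 respondent_id = c("a", "b")),
    make_records(c(-0.4, 0.2, 0.2), state = "53555",
                 respondent_id = c("a", "b", "c")))
  s <- summarize_arm(recs)
  expect_equal(s$per_state$mean[s$per_state$state == "12112"], 0.6)
  expect_equal(s$per_state$n, c(2L, 3L))
  expect_equal(s$n_nonnegative, 4L)
  expect_equal(s$prop_nonnegative, 0.8)
  # grand mean is the unweighted mean of state means, not the record mean
  expect_equal(s$grand_mean, (0.6 + 0) / 2)
  expect_false(isTRUE(all.equal(s$grand_mean, mean(recs$U))))

  single <- summarize_arm(make_records(1))
  expect_equal(single$per_state$sd, 0)
  expect_equal(single$per_state$n, 1L)

  both <- dplyr::bind_rows(make_records(0.1, arm = "standard"),
                           make_records(0.2, arm = "experimental"))
  expect_error(summarize_arm(both), "more than one arm")
  expect_error(summarize_arm(recs[0, ]), "non-empty")
})

test_that("exhaustion is the censored floor of the offer grid", {
  recs <- make_records(c(-2, -2, 0.5), respondent_id = c("a", "b", "c"),
                       censored = c(TRUE, FALSE, FALSE))
  s <- summarize_arm(recs)
  expect_equal(s$exhausted_n, 1L)
  expect_equal(s$exhausted_prop, 1 / 3)
})

test_that("aggregate regression agrees with the normal equations", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- 0.8 * x + rnorm(n, sd = 0.2)
    r <- aggregate_arm_regression(x, y)
    X <- cbind(1, x)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(r$intercept, beta[1], tolerance = 1e-10)
    expect_equal(r$slope, beta[2], tolerance = 1e-10)
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (n - 2)
    se <- sqrt(s2 * diag(solve(crossprod(X))))
    tq <- qt(0.975, n - 2)
    expect_equal(r$ci_slope, beta[2] + c(-1, 1) * tq * se[2], tolerance = 1e-8)
    expect_equal(r$ci_intercept, beta[1] + c(-1, 1) * tq * se[1],
                 tolerance = 1e-8)
  }
})

test_that("aggregate regression handles perfect and degenerate inputs", {
  x <- c(0.1, 0.3, 0.5, 0.9)
  r <- suppressWarnings(aggregate_arm_regression(x, x))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(diff(r$ci_slope), 0, tolerance = 1e-8)
  expect_error(aggregate_arm_regression(rep(0.4, 5), x[c(1, 2, 3, 4, 1)]),
               "degenerate")
  expect_error(aggregate_arm_regression(c(1, 2), c(1, 2)), "at least 3")
})

test_that("the seven bins partition the value range with zero its own bin", {
  bins <- value_bins()
  expect_equal(nrow(bins), 7L)
  probe <- make_records(c(-2, -1.5, -1, -0.5, 0, 0.5, 1, -1.75, 0.05),
                        respondent_id = paste0("r", 1:9))
  lab <- as.character(bin_records(probe)$value_bin)
  expect_identical(lab, c("[-2,-1.5)", "[-1.5,-1)", "[-1,-0.5)", "[-0.5,0)",
                          "0", "(0,0.5]", "(0.5,1]", "[-2,-1.5)", "(0,0.5]"))
  # partition property over the full grid
  g <- value_grid(cfg_std())
  binned <- bin_records(make_records(g, respondent_id = seq_along(g)))
  expect_false(any(is.na(binned$value_bin)))
  expect_equal(sum(table(binned$value_bin)), length(g))
  bad <- make_records(0.5); bad$U <- 1.5
  expect_error(bin_records(bad), "outside the admissible range")
})

test_that("behaviour tables report empty bins and per-arm metrics", {
  recs <- dplyr::bind_rows(
    make_records(rep(0.25, 12), respondent_id = paste0("s", 1:12),
                 arm = "standard", n_questions = 4L, duration_s = 30),
    make_records(rep(0.25, 12), respondent_id = paste0("e", 1:12),
                 arm = "experimental", n_questions = 6L, duration_s = 60))
  b <- behavior_by_bin(recs, test = FALSE)
  expect_equal(nrow(b), 7L)
  row <- b[b$label == "(0,0.5]", ]
  expect_equal(row$n_standard, 12L)
  expect_equal(row$questions_mean_standard, 4)
  expect_equal(row$questions_mean_experimental, 6)
  expect_equal(row$minutes_mean_experimental, 1)
  expect_equal(b$n_standard[b$label == "0"], 0L)
  expect_true(all(is.na(b$p_minutes)))
})

test_that("identical arms give a null adjusted contrast", {
  one_arm <- make_records(seq(-0.5, 1, by = 0.25),
                          respondent_id = rep(c("x", "y"), length.out = 7),
                          state = rep(default_blocks()$block1, length.out = 7))
  recs <- dplyr::bind_rows(
    dplyr::mutate(one_arm, arm = "standard",
                  respondent_id = paste0("s", respondent_id)),
    dplyr::mutate(one_arm, arm = "experimental",
                  respondent_id = paste0("e", respondent_id)))
  cmp <- suppressWarnings(suppressMessages(compare_arms(recs, "U")))
  expect_equal(cmp$estimate, 0, tolerance = 1e-6)
  expect_gt(cmp$p_value, 0.99)
  expect_match(cmp$model, "random intercept")
})

test_that("binary outcomes are compared on the odds scale with clustering", {
  set.seed(9)
  recs <- simulate_study(study_design(40), profile_params(), seed = 12)
  recs$nonnegative <- recs$U >= 0
  cmp <- suppressWarnings(suppressMessages(compare_arms(recs, "nonnegative")))
  expect_true(cmp$estimate > 0)          # an odds ratio
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_match(cmp$model, "logistic")
  expect_error(compare_arms(recs[recs$arm == "standard", ], "nonnegative"),
               "exactly two arms")
})

test_that("covariates without variation are dropped from the adjustment set", {
  recs <- dplyr::bind_rows(
    make_records(seq(0, 0.75, 0.25), arm = "standard",
                 respondent_id = paste0("s", c(1, 1, 2, 2))),
    make_records(seq(0.25, 1, 0.25), arm = "experimental",
                 respondent_id = paste0("e", c(1, 1, 2, 2))))
  # single state, single education level etc.: all constant covariates drop
  cmp <- suppressWarnings(suppressMessages(compare_arms(recs, "U")))
  expect_length(cmp$covariates_used, 0)
  expect_equal(cmp$estimate, 0.25, tolerance = 1e-6)
})

test_that("histogram counts are conserved and bounded intervals behave", {
  recs <- make_records(rep(1, 10), respondent_id = 1:10)
  h <- value_histogram(recs, 0.25)
  expect_equal(h$count[nrow(h)], 10L)
  expect_equal(sum(h$count), 10L)
  set.seed(2)
  g <- sample(value_grid(cfg_std()), 200, replace = TRUE)
  for (w in c(0.1, 0.25, 0.5)) {
    h <- value_histogram(make_records(g, respondent_id = seq_along(g)), w)
    expect_equal(sum(h$count), length(g))
  }
  expect_error(value_histogram(recs, 0), "positive")
})
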