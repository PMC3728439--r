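#' Unadjusted summary of one study arm
#'
#' Per-state means and SDs of the TTO values, the proportion of non-negative
#' values, the grand mean (the unweighted arithmetic mean of the per-state
#' means), and the count of tasks in which tradable time was exhausted (the
#' search was censored at the bottom of the offer grid, T = 0).
#'
#' @param records QC-filtered long-format records from a single arm.
#' @return An object of class `tto_arm_summary` with elements `per_state`
#'   (tibble: `state`, `n`, `mean`, `sd`), `n_records`, `n_nonnegative`,
#'   `prop_nonnegative`, `grand_mean`, `exhausted_n`, `exhausted_prop`.
#' @export
summarize_arm <- function(records) {
  assert_records(records, cols = c("respondent_id", "state", "U"))
  if (dplyr::n_distinct(records$arm %||% "one") > 1L)
    stop("records span more than one arm; summarize each arm separately",
         call. = FALSE)
  per_state <- records |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$U),
      sd = ifelse(dplyr::n() > 1L, sd(.data$U), 0),
      .by = "state") |>
    dplyr::arrange(.data$state)
  exhausted_n <- if ("censored" %in% names(records))
    sum(records$censored & records$T == 0) else NA_integer_
  structure(
    list(per_state = per_state,
         n_records = nrow(records),
         n_nonnegative = sum(records$U >= 0),
         prop_nonnegative = mean(records$U >= 0),
         grand_mean = mean(per_state$mean),
         exhausted_n = exhausted_n,
         exhausted_prop = exhausted_n / nrow(records)),
    class = "tto_arm_summary"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.tto_arm_summary <- function(x, ...) {
  cat("Arm summary (unadjusted)\n")
  print(dplyr::mutate(x$per_state, mean = round(.data$mean, 2),
                      sd = round(.data$sd, 2)))
  cat(sprintf("  records            : %d\n", x$n_records))
  cat(sprintf("  non-negative       : %d (%.1f%%)\n",
              x$n_nonnegative, 100 * x$prop_nonnegative))
  cat(sprintf("  grand mean         : %.2f\n", x$grand_mean))
  if (!is.na(x$exhausted_n))
    cat(sprintf("  trade time exhausted: %d (%.2f%%)\n",
                x$exhausted_n, 100 * x$exhausted_prop))
  invisible(x)
}

#' Aggregate cross-arm regression of per-state mean values
#'
#' Ordinary least squares of one arm's per-state mean values on the other's
#' (one point per health state), with 95% confidence intervals from the t
#' distribution on n - 2 degrees of freedom. A slope near 1 and intercept near
#' 0 indicate no aggregate-level difference between the arms.
#'
#' @param x Per-state means of the reference (predictor) arm.
#' @param y Per-state means of the comparison (response) arm.
#' @return A list of class `tto_aggregate_regression`: `slope`, `intercept`,
#'   `ci_slope`, `ci_intercept`, `n`, `fit` (the underlying `lm`).
#' @examples
#' aggregate_arm_regression(c(0.1, 0.4, 0.8), c(0.05, 0.42, 0.78))
#' @export
aggregate_arm_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must pair per-state means of equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 state-mean pairs", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x), 0)))
    stop("degenerate predictor: per-state means are all equal", call. = FALSE)
  fit <- lm(y ~ x)
  ci <- suppressWarnings(confint(fit, level = 0.95))
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         ci_slope = unname(ci[2, ]), ci_intercept = unname(ci[1, ]),
         n = length(x), fit = fit),
    class = "tto_aggregate_regression"
  )
}

#' @export
print.tto_aggregate_regression <- function(x, ...) {
  cat(sprintf(
    "Aggregate regression on %d state-mean pairs\n  y = %.3f x %+.3f\n",
    x$n, x$slope, x$intercept))
  cat(sprintf("  95%% CI slope    : %.3f to %.3f\n",
              x$ci_slope[1], x$ci_slope[2]))
  cat(sprintf("  95%% CI intercept: %.3f to %.3f\n",
              x$ci_intercept[1], x$ci_intercept[2]))
  invisible(x)
}

#' The seven value bins of the behaviour analysis
#'
#' The partition of the value range `[-2, 1]` used to analyse valuation
#' behaviour by resultant value: four half-open negative bins, the singleton
#' `{0}`, and two positive bins closed above.
#'
#' @return A tibble with columns `label`, `lower`, `upper`, `lower_closed`,
#'   `upper_closed`, in increasing order of value.
#' @export
value_bins <- function() {
  tibble::tibble(
    label = factor(
      c("[-2,-1.5)", "[-1.5,-1)", "[-1,-0.5)", "[-0.5,0)", "0",
        "(0,0.5]", "(0.5,1]"),
      levels = c("[-2,-1.5)", "[-1.5,-1)", "[-1,-0.5)", "[-0.5,0)", "0",
                 "(0,0.5]", "(0.5,1]"), ordered = TRUE),
    lower = c(-2, -1.5, -1, -0.5, 0, 0, 0.5),
    upper = c(-1.5, -1, -0.5, 0, 0, 0.5, 1),
    lower_closed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    upper_closed = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Assign each record to its value bin
#'
#' The bin boundaries (multiples of 0.5 and the exact zero) are exactly
#' representable for grid values, so membership uses exact comparisons; every
#' value in `[-2, 1]` lands in exactly one bin, with 0 its own bin.
#'
#' @param records Long-format records with a `U` column.
#' @return `records` with an ordered-factor column `value_bin` appended.
#' @export
bin_records <- function(records) {
  assert_records(records, cols = "U")
  U <- records$U
  if (any(U < -2 | U > 1))
    stop("value ", format(U[U < -2 | U > 1][1]),
         " outside the admissible range [-2, 1]", call. = FALSE)
  bins <- value_bins()
  lab <- dplyr::case_when(
    U == 0 ~ "0",
    U >= -2 & U < -1.5 ~ "[-2,-1.5)",
    U >= -1.5 & U < -1 ~ "[-1.5,-1)",
    U >= -1 & U < -0.5 ~ "[-1,-0.5)",
    U >= -0.5 & U < 0 ~ "[-0.5,0)",
    U > 0 & U <= 0.5 ~ "(0,0.5]",
    TRUE ~ "(0.5,1]"
  )
  records$value_bin <- factor(lab, levels = levels(bins$label), ordered = TRUE)
  records
}

#' Valuation behaviour by resultant value bin and arm
#'
#' For each of the seven value bins and each arm: number of tasks, mean (SD)
#' of the number of questions used, and mean (SD) of the task duration in
#' minutes. When both arms are populated in a bin, per-bin arm differences in
#' both metrics are tested with [compare_arms()] (respondent-level random
#' intercept, covariate-adjusted).
#'
#' @param records QC-filtered long-format records from both arms, with
#'   `n_questions` and `duration_s` columns.
#' @param covariates Covariates passed to [compare_arms()] for the per-bin
#'   tests.
#' @param test Set `FALSE` to skip the per-bin model fits (descriptives only).
#' @return A tibble with one row per bin: per-arm `n`, `questions_mean/sd`,
#'   `minutes_mean/sd`, and `p_questions`, `p_minutes` (NA when untestable or
#'   `test = FALSE`). Bins with no records report `n = 0` and `NA` metrics.
#' @export
behavior_by_bin <- function(records,
                            covariates = c("age_group", "gender", "education"),
                            test = TRUE) {
  assert_records(records,
                 cols = c("respondent_id", "arm", "U", "n_questions",
                          "duration_s"))
  arms <- sort(unique(records$arm))
  if (length(arms) != 2L)
    stop("records must contain exactly two arms", call. = FALSE)
  binned <- bin_records(records)
  desc <- binned |>
    dplyr::summarise(
      n = dplyr::n(),
      questions_mean = mean(.data$n_questions),
      questions_sd = ifelse(dplyr::n() > 1, sd(.data$n_questions), 0),
      minutes_mean = mean(.data$duration_s) / 60,
      minutes_sd = ifelse(dplyr::n() > 1, sd(.data$duration_s) / 60, 0),
      .by = c("value_bin", "arm")) |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("n", "questions_mean", "questions_sd",
                                       "minutes_mean", "minutes_sd"))
  out <- dplyr::left_join(value_bins()["label"], desc,
                          by = c(label = "value_bin"))
  for (a in arms) {
    ncol_a <- paste0("n_", a)
    out[[ncol_a]][is.na(out[[ncol_a]])] <- 0L
  }
  out$p_questions <- NA_real_
  out$p_minutes <- NA_real_
  if (test) {
    for (i in seq_len(nrow(out))) {
      sub <- binned[binned$value_bin == out$label[i], , drop = FALSE]
      if (dplyr::n_distinct(sub$arm) == 2L && nrow(sub) >= 10L) {
        out$p_questions[i] <- tryCatch(
          compare_arms(sub, "n_questions", covariates)$p_value,
          error = function(e) NA_real_)
        out$p_minutes[i] <- tryCatch(
          compare_arms(sub, "duration_s", covariates)$p_value,
          error = function(e) NA_real_)
      }
    }
  }
  out
}

#' Covariate-adjusted arm comparison with respondent clustering
#'
#' The paper-style arm contrast: because each respondent contributes several
#' values, models include a respondent-level random intercept. Continuous
#' outcomes use a linear mixed model (Satterthwaite p-value); binary outcomes
#' use a mixed-effects logistic model, falling back to an ordinary logistic
#' model with cluster-robust (respondent-level) standard errors if the random
#' -intercept fit fails or does not converge. Covariates with fewer than two
#' observed levels are dropped automatically.
#'
#' @param records Long-format records containing both arms.
#' @param outcome Name of the outcome column. Logical or 0/1 columns are
#'   treated as binary.
#' @param covariates Character vector of adjustment covariate columns
#'   (default: age group, gender, education and health state).
#' @return An object of class `tto_arm_comparison`: `outcome`, `estimate`
#'   (adjusted difference, or odds ratio for binary outcomes), `p_value`,
#'   `model`, `estimator`, `covariates_used`, `n`, `fit`.
#' @export
compare_arms <- function(records, outcome,
                         covariates = c("age_group", "gender", "education",
                                        "state")) {
  assert_records(records, cols = c("respondent_id", "arm", outcome))
  if (dplyr::n_distinct(records$arm) != 2L)
    stop("records must contain exactly two arms", call. = FALSE)
  y <- records[[outcome]]
  binary <- is.logical(y) || all(y %in% c(0, 1))
  covariates <- covariates[covariates %in% names(records)]
  covariates <- covariates[vapply(covariates, function(v)
    dplyr::n_distinct(records[[v]]) >= 2L, logical(1))]
  dat <- records
  dat$.y <- as.numeric(y)
  dat$arm <- factor(dat$arm)
  if ("standard" %in% levels(dat$arm))
    dat$arm <- stats::relevel(dat$arm, "standard")
  rhs <- paste(c("arm", covariates), collapse = " + ")
  fml <- stats::as.formula(paste0(".y ~ ", rhs, " + (1 | respondent_id)"))
  arm_coef_name <- paste0("arm", levels(dat$arm)[2])

  if (!binary) {
    fit <- lmerTest::lmer(fml, data = dat)
    co <- coef(summary(fit))
    est <- co[arm_coef_name, "Estimate"]
    p <- co[arm_coef_name, "Pr(>|t|)"]
    res <- list(model = "linear mixed (random intercept per respondent)",
                estimator = "REML + Satterthwaite", estimate = est, p_value = p,
                fit = fit)
  } else {
    fit <- tryCatch(
      lme4::glmer(fml, data = dat, family = stats::binomial()),
      error = function(e) NULL, warning = function(w) NULL)
    converged <- !is.null(fit) &&
      length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
    if (converged) {
      co <- coef(summary(fit))
      res <- list(model = "logistic mixed (random intercept per respondent)",
                  estimator = "Laplace ML",
                  estimate = exp(co[arm_coef_name, "Estimate"]),
                  p_value = co[arm_coef_name, "Pr(>|z|)"], fit = fit)
    } else {
      glm_fml <- stats::as.formula(paste0(".y ~ ", rhs))
      fit <- stats::glm(glm_fml, data = dat, family = stats::binomial())
      vc <- sandwich::vcovCL(fit, cluster = dat$respondent_id)
      ct <- lmtest::coeftest(fit, vcov. = vc)
      res <- list(model = "logistic with cluster-robust SE (per respondent)",
                  estimator = "ML + CR0 sandwich",
                  estimate = exp(ct[arm_coef_name, "Estimate"]),
                  p_value = ct[arm_coef_name, "Pr(>|z|)"], fit = fit)
    }
  }
  structure(
    c(list(outcome = outcome, covariates_used = covariates, n = nrow(dat),
           arms = levels(dat$arm), reference_arm = levels(dat$arm)[1]),
      res),
    class = "tto_arm_comparison"
  )
}

#' @export
print.tto_arm_comparison <- function(x, ...) {
  cat(sprintf("Arm comparison for '%s' (%s vs %s)\n", x$outcome,
              x$arms[2], x$reference_arm))
  cat(sprintf("  model    : %s [%s]\n", x$model, x$estimator))
  cat(sprintf("  adjusted : %s\n",
              paste(x$covariates_used, collapse = ", ")))
  cat(sprintf("  estimate : %.4f   p = %.4g\n", x$estimate, x$p_value))
  invisible(x)
}

#' Histogram counts of TTO values
#'
#' Counts of values in consecutive intervals `[lo, lo + w)`, the topmost
#' interval closed above, spanning `[lower, upper]`.
#'
#' @param records Long-format records with a `U` column.
#' @param bin_width Positive interval width.
#' @param lower,upper Range spanned (defaults to the widest admissible value
#'   range `[-2, 1]`).
#' @return Tibble with `lower`, `upper`, `count`; counts sum to the number of
#'   records.
#' @export
value_histogram <- function(records, bin_width = 0.25, lower = -2, upper = 1) {
  assert_records(records, cols = "U")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number", call. = FALSE)
  U <- records$U
  if (any(U < lower | U > upper))
    stop("values outside [", lower, ", ", upper, "]", call. = FALSE)
  breaks <- seq(lower, upper, by = bin_width)
  if (breaks[length(breaks)] < upper) breaks <- c(breaks, upper)
  idx <- findInterval(U, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  tibble::tibble(
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    count = tabulate(idx, nbins = nb)
  )
}
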