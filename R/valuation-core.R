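#' @importFrom rlang .data
#' @importFrom stats lm confint coef pnorm qnorm rnorm runif sd setNames qbinom
#' @importFrom utils read.csv write.csv packageVersion
NULL

# One grid unit: 3 months. All task durations live on this grid, held
# internally as integer quarter-year counts so that bracket arithmetic in the
# elicitation engine is exact.
QUARTER_YEARS <- 0.25

years_to_quarters <- function(x) {
  q <- x / QUARTER_YEARS
  qi <- round(q)
  if (any(abs(q - qi) > 1e-9)) {
    bad <- x[abs(q - qi) > 1e-9][1]
    stop("duration ", format(bad), " years is not a multiple of 3 months (0.25 years)",
         call. = FALSE)
  }
  as.integer(qi)
}

quarters_to_years <- function(q) q * QUARTER_YEARS

#' Validate an EQ-5D-5L health-state code
#'
#' An EQ-5D-5L state is written as a 5-digit code, one digit per dimension
#' (mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression), each digit a severity level from 1 (no problems) to 5
#' (extreme problems). `"11111"` denotes full health.
#'
#' @param code Character vector of candidate state codes.
#' @return The input, invisibly unchanged, if every code is valid; otherwise an
#'   error naming the first offending code.
#' @examples
#' health_state("53555")
#' @export
health_state <- function(code) {
  ok <- is.character(code) & grepl("^[1-5]{5}$", code)
  if (!all(ok)) {
    stop("invalid EQ-5D-5L state code: '", code[!ok][1],
         "' (need 5 characters, each in 1-5)", call. = FALSE)
  }
  code
}

#' Define a lead-time TTO task configuration
#'
#' A lead-time TTO task asks the respondent to compare Life A — `lead_time`
#' (LT) years in full health followed by `unhealthy_time` (UT) years in the
#' health state under valuation — against Life B, `x` years in full health.
#' The indifference duration T maps to a value `U = (T - LT)/UT`, so the
#' attainable value range is `[-LT/UT, 1]`.
#'
#' @param lead_time Years of full health preceding the unhealthy period (LT).
#' @param unhealthy_time Years spent in the state being valued (UT).
#' @param min_step Finest change in the Life-B duration, in years. The default
#'   3 months is the finest step used by the EQ-VT iteration.
#' @param visual_variant `"aligned"` (lead-time and unhealthy-time bars on one
#'   line) or `"raised_bar"` (the unhealthy-time bar raised to highlight where
#'   the lead time ends, i.e. the point equivalent to dead).
#' @return An object of class `tto_task_config`.
#' @examples
#' task_config(10, 5)              # standard arm: value range [-2, 1]
#' task_config(5, 5)               # short lead time: value range [-1, 1]
#' task_config(10, 5, visual_variant = "raised_bar")
#' @export
task_config <- function(lead_time, unhealthy_time, min_step = 0.25,
                        visual_variant = c("aligned", "raised_bar")) {
  visual_variant <- match.arg(visual_variant)
  if (!is.numeric(lead_time) || length(lead_time) != 1L || lead_time <= 0)
    stop("lead_time must be a single positive number of years", call. = FALSE)
  if (!is.numeric(unhealthy_time) || length(unhealthy_time) != 1L || unhealthy_time <= 0)
    stop("unhealthy_time must be a single positive number of years", call. = FALSE)
  if (!is.numeric(min_step) || length(min_step) != 1L || min_step <= 0)
    stop("min_step must be a single positive number of years", call. = FALSE)
  if (abs(min_step - QUARTER_YEARS) > 1e-12)
    stop("the engine's offer grid is fixed at 3-month (0.25-year) resolution; ",
         "min_step must be 0.25", call. = FALSE)
  lt_q <- years_to_quarters(lead_time)
  ut_q <- years_to_quarters(unhealthy_time)
  structure(
    list(
      lead_time = lead_time,
      unhealthy_time = unhealthy_time,
      min_step = min_step,
      visual_variant = visual_variant,
      max_offer = lead_time + unhealthy_time,
      value_range = c(-lead_time / unhealthy_time, 1),
      lt_q = lt_q,
      ut_q = ut_q,
      max_q = lt_q + ut_q
    ),
    class = "tto_task_config"
  )
}

#' @export
print.tto_task_config <- function(x, ...) {
  cat("Lead-time TTO task configuration\n")
  cat(sprintf("  lead time       : %g years\n", x$lead_time))
  cat(sprintf("  unhealthy time  : %g years\n", x$unhealthy_time))
  cat(sprintf("  offer grid      : 0 .. %g years, step %g\n", x$max_offer, x$min_step))
  cat(sprintf("  value range     : [%g, %g]\n", x$value_range[1], x$value_range[2]))
  cat(sprintf("  visual variant  : %s\n", x$visual_variant))
  invisible(x)
}

is_task_config <- function(x) inherits(x, "tto_task_config")

assert_config <- function(config) {
  if (!is_task_config(config))
    stop("config must be created with task_config()", call. = FALSE)
  invisible(config)
}

#' TTO value of an indifference duration
#'
#' Maps the Life-B duration `T` at which the respondent is indifferent to the
#' value of the health state: `U = (T - LT)/UT`. `T = LT` gives 0 (the state is
#' equivalent to dead: all lead time traded away), `T = LT + UT` gives 1 (full
#' health), and `T < LT` gives negative values (worse than dead), down to
#' `-LT/UT` at `T = 0`.
#'
#' @param T Indifference duration(s) in years, in `[0, LT + UT]`.
#' @param config A [task_config()].
#' @return Dimensionless value(s) in the configuration's value range.
#' @examples
#' cfg <- task_config(10, 5)
#' compute_value(12.5, cfg)  # 0.5
#' compute_value(0, cfg)     # -2, the lower bound
#' @export
compute_value <- function(T, config) {
  assert_config(config)
  if (!is.numeric(T)) stop("T must be numeric (years)", call. = FALSE)
  if (any(T < 0))
    stop("indifference time T = ", format(T[T < 0][1]),
         " is below the lower offer bound 0", call. = FALSE)
  if (any(T > config$max_offer))
    stop("indifference time T = ", format(T[T > config$max_offer][1]),
         " exceeds the upper offer bound ", format(config$max_offer),
         " (= LT + UT)", call. = FALSE)
  (T - config$lead_time) / config$unhealthy_time
}

#' Indifference duration implied by a TTO value
#'
#' Inverse of [compute_value()]: `T = LT + U * UT`. Results that fall within
#' numerical round-off of the 3-month offer grid are snapped onto it, so
#' grid values round-trip exactly.
#'
#' @param U Dimensionless value(s) within the configuration's value range.
#' @param config A [task_config()].
#' @return Duration(s) in years.
#' @examples
#' invert_value(-0.5, task_config(5, 5))  # 2.5 years
#' @export
invert_value <- function(U, config) {
  assert_config(config)
  if (!is.numeric(U)) stop("U must be numeric", call. = FALSE)
  lo <- config$value_range[1]
  if (any(U < lo - 1e-12))
    stop("value U = ", format(U[U < lo - 1e-12][1]),
         " is below the lower bound ", format(lo), " (= -LT/UT)", call. = FALSE)
  if (any(U > 1 + 1e-12))
    stop("value U = ", format(U[U > 1 + 1e-12][1]),
         " exceeds the upper bound 1", call. = FALSE)
  Tq <- config$lt_q + U * config$ut_q
  snapped <- round(Tq)
  on_grid <- abs(Tq - snapped) < 1e-9
  Tq[on_grid] <- snapped[on_grid]
  quarters_to_years(Tq)
}

#' Smallest detectable value difference
#'
#' The value resolution of the iteration is the smallest offer step divided by
#' the unhealthy time: with a 3-month step and 10 years of unhealthy time a
#' difference in value of 0.025 (3/120) can be detected; with 5 years of
#' unhealthy time the same step resolves only 0.05.
#'
#' @param config A [task_config()].
#' @return The smallest value difference distinguishable on the offer grid.
#' @examples
#' detectable_resolution(task_config(10, 10))  # 0.025
#' @export
detectable_resolution <- function(config) {
  assert_config(config)
  config$min_step / config$unhealthy_time
}

#' All values representable on the offer grid
#'
#' @param config A [task_config()].
#' @return Numeric vector of the values of every grid offer 0, 0.25, ...,
#'   LT + UT, in increasing order.
#' @export
value_grid <- function(config) {
  assert_config(config)
  compute_value(quarters_to_years(0:config$max_q), config)
}
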