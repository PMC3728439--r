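#' Exclusion accounting for the QC filters
#'
#' Bookkeeping identity for the two cleaning rules: respondents giving all
#' states the same value are dropped first (whole respondent), then individual
#' tasks completed within 1 second are dropped, so
#' `n_records_retained = (n_participants_in - n_allsame_excluded) *
#' states_per_respondent - n_fast_tasks_excluded`.
#'
#' @param n_participants_in Participants entering QC.
#' @param n_allsame_excluded Participants whose values were all identical.
#' @param n_fast_tasks_excluded Individual tasks completed within 1 s.
#' @param states_per_respondent Tasks per participant (5 in the standard
#'   design).
#' @return An object of class `tto_exclusion_report`.
#' @examples
#' exclusion_report(406, 38, 6)  # 1834 records retained
#' @export
exclusion_report <- function(n_participants_in, n_allsame_excluded,
                             n_fast_tasks_excluded,
                             states_per_respondent = 5L) {
  stopifnot(n_participants_in >= 0, n_allsame_excluded >= 0,
            n_fast_tasks_excluded >= 0,
            n_allsame_excluded <= n_participants_in)
  retained_p <- n_participants_in - n_allsame_excluded
  structure(
    list(n_participants_in = as.integer(n_participants_in),
         n_allsame_excluded = as.integer(n_allsame_excluded),
         n_fast_tasks_excluded = as.integer(n_fast_tasks_excluded),
         n_participants_retained = as.integer(retained_p),
         n_records_retained =
           as.integer(retained_p * states_per_respondent -
                        n_fast_tasks_excluded),
         states_per_respondent = as.integer(states_per_respondent)),
    class = "tto_exclusion_report"
  )
}

#' @export
print.tto_exclusion_report <- function(x, ...) {
  cat("TTO data-cleaning report\n")
  cat(sprintf("  participants in           : %d\n", x$n_participants_in))
  cat(sprintf("  all-same-value excluded   : %d\n", x$n_allsame_excluded))
  cat(sprintf("  participants retained     : %d\n", x$n_participants_retained))
  cat(sprintf("  fast tasks (<=1 s) dropped: %d\n", x$n_fast_tasks_excluded))
  cat(sprintf("  records retained          : %d\n", x$n_records_retained))
  invisible(x)
}

assert_records <- function(records, cols = c("respondent_id", "U")) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame", call. = FALSE)
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

#' Exclude respondents who gave every state the same value
#'
#' A respondent whose recorded values are all identical is taken not to have
#' understood the task and is removed entirely. Equality is exact: values
#' originate on the quarter-year offer grid, so identical indifference points
#' give bit-identical values.
#'
#' @param records Long-format record tibble (one row per task) with at least
#'   `respondent_id` and `U`.
#' @return A list: `records` (retained rows), `excluded_respondents`
#'   (character vector of dropped ids).
#' @export
filter_allsame <- function(records) {
  assert_records(records)
  if (any(is.na(records$U)))
    stop("records contain missing values in U", call. = FALSE)
  flagged <- records |>
    dplyr::summarise(allsame = dplyr::n_distinct(.data$U) == 1L,
                     .by = "respondent_id")
  bad <- flagged$respondent_id[flagged$allsame]
  list(records = dplyr::filter(records, !.data$respondent_id %in% bad),
       excluded_respondents = bad)
}

#' Exclude tasks completed within one second
#'
#' Values from tasks finished in at most 1 s are regarded as unreliable and
#' dropped record-by-record. Applied after [filter_allsame()].
#'
#' @param records Long-format record tibble with a `duration_s` column.
#' @return A list: `records` (retained rows), `excluded` (the dropped rows).
#' @export
filter_fast_tasks <- function(records) {
  assert_records(records, cols = c("respondent_id", "duration_s"))
  if (any(is.na(records$duration_s) | records$duration_s < 0))
    stop("records contain missing or negative duration_s", call. = FALSE)
  fast <- records$duration_s <= 1.0
  list(records = records[!fast, , drop = FALSE],
       excluded = records[fast, , drop = FALSE])
}

#' Apply both cleaning rules and account for the exclusions
#'
#' Runs [filter_allsame()] then [filter_fast_tasks()] and returns the retained
#' records together with an [exclusion_report()] whose arithmetic identity can
#' be audited against the record counts.
#'
#' @param records Long-format record tibble.
#' @return A list: `records` (clean rows), `report` (`tto_exclusion_report`),
#'   `excluded_respondents`, `excluded_tasks`.
#' @export
qc_records <- function(records) {
  assert_records(records, cols = c("respondent_id", "U", "duration_s"))
  n_in <- dplyr::n_distinct(records$respondent_id)
  per_resp <- nrow(records) / n_in
  s1 <- filter_allsame(records)
  s2 <- filter_fast_tasks(s1$records)
  report <- exclusion_report(
    n_participants_in = n_in,
    n_allsame_excluded = length(s1$excluded_respondents),
    n_fast_tasks_excluded = nrow(s2$excluded),
    states_per_respondent = per_resp)
  list(records = s2$records, report = report,
       excluded_respondents = s1$excluded_respondents,
       excluded_tasks = s2$excluded)
}
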