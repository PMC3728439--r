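#' Published arm-level reference values from the EQ-VT pilot valuation study
#'
#' Packaged transcriptions of the arm-level summary statistics published by
#' the multinational EQ-VT pilot valuation study for its China site (lead
#' time 10 vs 5 years) and Singapore site (aligned vs raised-bar visual aid):
#' per-state mean (SD) TTO values, arm-level counts (records, non-negative
#' values, exhaustion of tradable time), and exclusion accounting. These are
#' used as fixtures for the deterministic checks in [check_reference()] and
#' as realistic anchors for simulation scenarios; no respondent-level data
#' are included (none are public).
#'
#' @param site Optional filter, `"china"` or `"singapore"`.
#' @return A tibble.
#' @export
eqvt_pilot_means <- function(site = NULL) {
  out <- read_extdata("eqvt_pilot_state_means.csv")
  if (!is.null(site)) out <- out[out$site == match.arg(site, c("china", "singapore")), ]
  tibble::as_tibble(out)
}

#' @rdname eqvt_pilot_means
#' @export
eqvt_pilot_counts <- function(site = NULL) {
  out <- read_extdata("eqvt_pilot_counts.csv")
  if (!is.null(site)) out <- out[out$site == match.arg(site, c("china", "singapore")), ]
  tibble::as_tibble(out)
}

#' @rdname eqvt_pilot_means
#' @export
eqvt_pilot_exclusions <- function(site = NULL) {
  out <- read_extdata("eqvt_pilot_exclusions.csv")
  if (!is.null(site)) out <- out[out$site == match.arg(site, c("china", "singapore")), ]
  tibble::as_tibble(out)
}

read_extdata <- function(name) {
  path <- system.file("extdata", name, package = "leadtto", mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  # state codes contain no zeros, so integer -> character is lossless
  if ("state" %in% names(out)) out$state <- health_state(as.character(out$state))
  out
}

#' Recompute the published arm-level results from the packaged fixtures
#'
#' Runs the package's own analysis operations on the packaged published
#' summaries: the unweighted grand mean of each arm's per-state means, the
#' proportion of non-negative values and the exhaustion fraction from the
#' published counts, the record-count identity implied by the published
#' exclusion numbers, and — for the China site — the aggregate OLS regression
#' of the standard arm's per-state means on the experimental arm's.
#'
#' @param site `"china"` or `"singapore"`.
#' @return A list of class `tto_reference_check` with elements `site`,
#'   `grand_mean` (named, per arm), `prop_nonnegative` (named, percent),
#'   `exhausted_pct` (named, percent), `n_records_retained`, and for China
#'   `regression` (a `tto_aggregate_regression`).
#' @examples
#' check_reference("china")
#' @export
check_reference <- function(site = c("china", "singapore")) {
  site <- match.arg(site)
  means <- eqvt_pilot_means(site)
  counts <- eqvt_pilot_counts(site)
  excl <- eqvt_pilot_exclusions(site)

  wide <- tidyr::pivot_wider(means[c("state", "arm", "mean")],
                             names_from = "arm", values_from = "mean")
  grand <- c(standard = mean(wide$standard),
             experimental = mean(wide$experimental))
  prop <- setNames(100 * counts$n_nonnegative / counts$n_records, counts$arm)
  exh <- setNames(100 * counts$n_exhausted / counts$n_records, counts$arm)
  report <- exclusion_report(excl$n_participants_in,
                             excl$n_allsame_excluded,
                             excl$n_fast_tasks_excluded)
  out <- list(site = site, grand_mean = grand, prop_nonnegative = prop,
              exhausted_pct = exh,
              n_records_retained = report$n_records_retained,
              exclusion = report)
  if (site == "china")
    out$regression <- aggregate_arm_regression(wide$experimental, wide$standard)
  structure(out, class = "tto_reference_check")
}

#' @export
print.tto_reference_check <- function(x, ...) {
  cat(sprintf("Recomputed published arm-level results (%s site)\n", x$site))
  cat(sprintf("  grand mean        : standard %.2f, experimental %.2f\n",
              x$grand_mean["standard"], x$grand_mean["experimental"]))
  cat(sprintf("  %% non-negative    : standard %.1f, experimental %.1f\n",
              x$prop_nonnegative["standard"], x$prop_nonnegative["experimental"]))
  cat(sprintf("  %% exhausted       : standard %.2f, experimental %.2f\n",
              x$exhausted_pct["standard"], x$exhausted_pct["experimental"]))
  cat(sprintf("  records retained  : %d\n", x$n_records_retained))
  if (!is.null(x$regression)) print(x$regression)
  invisible(x)
}
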