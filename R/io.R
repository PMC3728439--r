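RECORD_COLUMNS <- c("respondent_id", "arm", "block", "state", "T", "U",
                    "n_questions", "duration_s", "censored")

#' Write valuation records to delimited text
#'
#' One row per completed task, in the long format consumed by the QC filters
#' and the analysis pipeline. Extra columns (demographics, true utilities) are
#' preserved.
#'
#' @param records Record tibble with at least the core columns
#'   `respondent_id`, `arm`, `block`, `state`, `T`, `U`, `n_questions`,
#'   `duration_s`, `censored`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  assert_records(records, cols = RECORD_COLUMNS)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate valuation records
#'
#' Reads a long-format record CSV, checks the header, coerces types, and
#' validates every row against the value algebra: state codes must be valid
#' EQ-5D-5L codes, question counts at least 1, durations non-negative, and —
#' when the arm task configurations are supplied — `T` must lie within the
#' arm's offer range and `U` must equal `(T - LT)/UT` to within 1e-9.
#' Validation failures report the offending data line number.
#'
#' @param path CSV path as written by [write_records()].
#' @param configs Optional named list of [task_config()] objects keyed by arm
#'   label, enabling the `U`-vs-`T` consistency check.
#' @return A tibble of validated records.
#' @export
read_records <- function(path, configs = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing))
    stop("record file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  raw$state <- as.character(raw$state)
  raw$censored <- as.logical(raw$censored)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  fail <- function(bad, what) {
    if (any(bad))
      stop("invalid record at line ", line[bad][1], " of ", path, ": ", what,
           call. = FALSE)
  }
  fail(!grepl("^[1-5]{5}$", raw$state), "unknown health-state code")
  fail(is.na(raw$T) | is.na(raw$U), "missing T or U")
  fail(raw$n_questions < 1, "n_questions below 1")
  fail(is.na(raw$duration_s) | raw$duration_s < 0,
       "missing or negative duration_s")
  if (!is.null(configs)) {
    for (a in unique(raw$arm)) {
      cfg <- configs[[a]]
      if (is.null(cfg))
        stop("no task configuration supplied for arm '", a, "'", call. = FALSE)
      assert_config(cfg)
      in_arm <- raw$arm == a
      fail(in_arm & (raw$T < 0 | raw$T > cfg$max_offer),
           paste0("T outside [0, ", cfg$max_offer, "] for arm '", a, "'"))
      expect_U <- (raw$T - cfg$lead_time) / cfg$unhealthy_time
      fail(in_arm & abs(raw$U - expect_U) > 1e-9,
           paste0("U inconsistent with T under arm '", a,
                  "' (expected (T - LT)/UT)"))
    }
  }
  tibble::as_tibble(raw)
}
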