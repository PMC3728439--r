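#' Construct a single offer
#'
#' An offer is one Life-B proposal: live `duration` years in full health and
#' then die. `ordinal` is the 1-based question index within the task.
#'
#' @param duration Years of full health offered as Life B; must lie on the
#'   3-month grid within `[0, LT + UT]`.
#' @param ordinal Question index within the valuation task.
#' @return An object of class `tto_offer`.
#' @export
offer <- function(duration, ordinal) {
  stopifnot(is.numeric(duration), length(duration) == 1L,
            is.numeric(ordinal), length(ordinal) == 1L, ordinal >= 1)
  structure(list(duration = duration, ordinal = as.integer(ordinal)),
            class = "tto_offer")
}

#' Start an empty elicitation trace
#'
#' A trace records the ordered offers, responses and per-question times of one
#' valuation task, plus the terminal indifference duration and whether it was
#' forced (censored) rather than reported.
#'
#' @param state EQ-5D-5L state code being valued.
#' @return An object of class `tto_trace`.
#' @export
new_trace <- function(state) {
  health_state(state)
  structure(
    list(state = state, offers = numeric(0), responses = character(0),
         times_s = numeric(0), terminal_T = NA_real_, censored = FALSE,
         elapsed_s = 0),
    class = "tto_trace"
  )
}

#' @export
print.tto_trace <- function(x, ...) {
  cat(sprintf("Elicitation trace for state %s: %d offer(s)\n",
              x$state, length(x$offers)))
  if (length(x$offers))
    print(trace_tibble(x))
  if (!is.na(x$terminal_T))
    cat(sprintf("  terminal T = %g years%s\n", x$terminal_T,
                if (x$censored) " (censored)" else ""))
  invisible(x)
}

#' Tabulate a trace, one row per offer
#'
#' @param trace A `tto_trace`.
#' @param respondent_id Optional id to stamp on every row.
#' @return A tibble with columns `respondent_id`, `state`, `ordinal`, `x`,
#'   `response`, `cumulative_seconds`.
#' @export
trace_tibble <- function(trace, respondent_id = NA) {
  stopifnot(inherits(trace, "tto_trace"))
  tibble::tibble(
    respondent_id = respondent_id,
    state = trace$state,
    ordinal = seq_along(trace$offers),
    x = trace$offers,
    response = trace$responses,
    cumulative_seconds = cumsum(trace$times_s)
  )
}

# Replay a trace to recover the current search bracket in quarter units.
# lo_q: largest offer answered "prefer_A" (-1 before any); hi_q: smallest
# offer answered "prefer_B" (max_q + 1 before any). Every proposed offer is
# strictly inside the bracket, so the bracket shrinks monotonically and noisy
# (inconsistent-looking) response sequences still keep lo_q < hi_q.
trace_bracket <- function(trace, config) {
  lo_q <- -1L
  hi_q <- config$max_q + 1L
  offers_q <- years_to_quarters(trace$offers)
  for (i in seq_along(offers_q)) {
    if (trace$responses[i] == "prefer_A") lo_q <- offers_q[i]
    else if (trace$responses[i] == "prefer_B") hi_q <- offers_q[i]
  }
  list(lo_q = lo_q, hi_q = hi_q)
}

#' Next offer of the iterative lead-time TTO search
#'
#' Implements the EQ-VT-style offer sequence. The first offer is the full
#' duration `LT + UT` (Life B worth value 1); the second is `LT` (value 0,
#' i.e. equivalent to dead). Subsequent offers bisect the current preference
#' bracket on the 3-month grid: after answers Life B at `LT + UT` and Life A
#' at `LT`, the third offer is the midpoint of `(LT, LT + UT)` — 12.5 years in
#' the 10 + 5 design; after Life B at `LT` the search moves to `LT/2` — 5
#' years in the 10 + 5 design, 2.5 in the 5 + 5 design.
#'
#' @param trace A `tto_trace` whose last response is `prefer_A` or `prefer_B`.
#' @param config A [task_config()].
#' @return A `tto_offer`, or a terminal signal of class `tto_terminal` when no
#'   unoffered grid point remains inside the bracket. The terminal carries the
#'   grid durations (`candidates`, years) at which the respondent must settle,
#'   mirroring the instruction to indicate indifference at the offer closest
#'   to the true indifference point.
#' @export
next_offer <- function(trace, config) {
  assert_config(config)
  stopifnot(inherits(trace, "tto_trace"))
  n <- length(trace$offers)
  if (length(trace$responses) != n)
    stop("protocol error: ", n, " offer(s) but ", length(trace$responses),
         " response(s)", call. = FALSE)
  if (n > 0 && trace$responses[n] == "indifferent")
    stop("protocol error: task already terminated at indifference", call. = FALSE)
  if (n == 0) return(offer(config$max_offer, 1L))

  b <- trace_bracket(trace, config)
  if (b$lo_q >= config$max_q) {
    # Life A preferred even when Life B equals the full span: settle at the top.
    return(structure(list(candidates = config$max_offer), class = "tto_terminal"))
  }
  if (n == 1) return(offer(config$lead_time, 2L))

  lo_int <- b$lo_q + 1L
  hi_int <- b$hi_q - 1L
  if (lo_int > hi_int) {
    cand <- c(if (b$lo_q >= 0L) quarters_to_years(b$lo_q),
              if (b$hi_q <= config$max_q) quarters_to_years(b$hi_q))
    return(structure(list(candidates = cand), class = "tto_terminal"))
  }
  mid <- (max(b$lo_q, 0L) + b$hi_q) %/% 2L
  mid <- min(max(mid, lo_int), hi_int)
  offer(quarters_to_years(mid), n + 1L)
}

#' Run one complete valuation task
#'
#' Drives the iterative search against a respondent model: poses offers via
#' [next_offer()], obtains each answer from [decide()], accumulates response
#' times from [response_time()], and terminates at reported indifference or,
#' when the offer grid is exhausted without indifference, at the forced
#' (censored) grid duration closest to the respondent's indifference point.
#'
#' @param agent A [respondent_profile()].
#' @param state EQ-5D-5L state code to value.
#' @param config A [task_config()].
#' @param arm Optional arm label stamped on the record.
#' @param block Optional block label stamped on the record.
#' @param seed Optional seed for this task's random draws.
#' @return A list with elements `record` (one-row tibble: `respondent_id`,
#'   `arm`, `block`, `state`, `T`, `U`, `n_questions`, `duration_s`,
#'   `censored`) and `trace` (the full `tto_trace`).
#' @examples
#' agent <- respondent_profile("r1", true_utilities = c("53555" = 0.5),
#'                             decision_sd = 0, indifference_tol = 0)
#' run_task(agent, "53555", task_config(10, 5))$record
#' @export
run_task <- function(agent, state, config, arm = NA_character_,
                     block = NA_character_, seed = NULL) {
  assert_config(config)
  stopifnot(inherits(agent, "tto_respondent"))
  if (!is.null(seed)) set.seed(seed)
  trace <- new_trace(state)
  repeat {
    nxt <- next_offer(trace, config)
    if (inherits(nxt, "tto_terminal")) {
      trace$terminal_T <- settle(agent, nxt$candidates, state, config)
      trace$censored <- TRUE
      break
    }
    resp <- decide(agent, nxt, state, config)
    dt <- response_time(agent, nxt, config)
    trace$offers <- c(trace$offers, nxt$duration)
    trace$responses <- c(trace$responses, resp)
    trace$times_s <- c(trace$times_s, dt)
    if (resp == "indifferent") {
      trace$terminal_T <- nxt$duration
      break
    }
    if (length(trace$offers) >= 64L)
      stop("protocol error: offer cap (64) reached without termination",
           call. = FALSE)
  }
  trace$elapsed_s <- sum(trace$times_s)
  record <- tibble::tibble(
    respondent_id = agent$respondent_id,
    arm = arm,
    block = block,
    state = state,
    T = trace$terminal_T,
    U = compute_value(trace$terminal_T, config),
    n_questions = length(trace$offers),
    duration_s = trace$elapsed_s,
    censored = trace$censored
  )
  list(record = record, trace = trace)
}

#' Materialize the full offer decision tree
#'
#' Enumerates every reachable offer of the iterative search for a task design,
#' for inspection and testing. Each row is a node: the offer posed (`x`,
#' years) at question `ordinal`, reached from its parent via `via_response`,
#' or a terminal node (`kind != "offer"`) where the search settles.
#'
#' @param config A [task_config()].
#' @return A tibble with columns `id`, `parent`, `ordinal`, `via_response`,
#'   `kind` (`"offer"`, `"terminal"`), `x` (offer duration in years, `NA` for
#'   terminals), `candidates` (list-column of settle durations for terminals).
#' @export
offer_schedule <- function(config) {
  assert_config(config)
  rows <- list()
  id <- 0L
  emit <- function(parent, ordinal, via, kind, x, candidates = NULL) {
    id <<- id + 1L
    rows[[id]] <<- tibble::tibble(
      id = id, parent = parent, ordinal = ordinal, via_response = via,
      kind = kind, x = x, candidates = list(candidates))
    id
  }
  # Mirrors next_offer(): state is (lo_q, hi_q, n). Indifference at any offer
  # is a valid termination and is not expanded.
  grow <- function(lo_q, hi_q, n, parent, via) {
    if (lo_q >= config$max_q) {
      emit(parent, n + 1L, via, "terminal", NA_real_, config$max_offer)
      return(invisible())
    }
    if (n == 0L) x_q <- config$max_q
    else if (n == 1L) x_q <- config$lt_q
    else {
      lo_int <- lo_q + 1L
      hi_int <- hi_q - 1L
      if (lo_int > hi_int) {
        cand <- c(if (lo_q >= 0L) quarters_to_years(lo_q),
                  if (hi_q <= config$max_q) quarters_to_years(hi_q))
        emit(parent, n + 1L, via, "terminal", NA_real_, cand)
        return(invisible())
      }
      x_q <- min(max((max(lo_q, 0L) + hi_q) %/% 2L, lo_int), hi_int)
    }
    me <- emit(parent, n + 1L, via, "offer", quarters_to_years(x_q))
    grow(x_q, hi_q, n + 1L, me, "prefer_A")
    grow(lo_q, x_q, n + 1L, me, "prefer_B")
  }
  grow(-1L, config$max_q + 1L, 0L, NA_integer_, NA_character_)
  dplyr::bind_rows(rows)
}
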