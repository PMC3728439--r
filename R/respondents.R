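#' Define a synthetic respondent
#'
#' A respondent model for lead-time TTO simulation. Each agent holds true
#' (latent) utilities for the states it values plus behavioural parameters:
#'
#' * `decision_sd` (sigma): SD of the zero-mean noise added to the perceived
#'   value of each offer.
#' * `indifference_tol` (delta): half-width of the "A and B are about the
#'   same" band around the perceived match.
#' * `framing_coeff` (kappa): extra trading per unit excess of the LT/UT ratio
#'   over 1 — people tend to trade more time just because more lead time is
#'   available, pushing elicited values down in high-ratio designs.
#' * `visual_error_coeff` (nu): downward bias growing with total bar length
#'   beyond 10 years — with longer bars the length contrast at indifference is
#'   less striking, so respondents trade a little more to sense it.
#' * `engagement_gain` (gamma): raised-bar variant only — when the search is
#'   refining offers near the point equivalent to dead (absolute offer value
#'   below 0.5), the highlighted bar prompts more careful deliberation: the
#'   indifference band shrinks by `1/(1 + gamma)` and per-question time
#'   inflates by `1 + gamma`.
#'
#' Both framing and visual-contrast biases are normalized to vanish in the
#' 5-year-lead-time, 5-year-unhealthy-time design (ratio 1, 10-year bar), so
#' they are identified as contrasts against that arm.
#'
#' @param respondent_id Identifier.
#' @param true_utilities Named numeric vector, state code -> true utility in
#'   `[-2, 1]`.
#' @param decision_sd,indifference_tol,framing_coeff,visual_error_coeff,engagement_gain
#'   Non-negative behavioural parameters described above.
#' @param base_log_time,time_sd Per-question response time is lognormal with
#'   these log-scale parameters (log-seconds).
#' @param age_group,gender,education Demographic covariates carried into the
#'   analysis models.
#' @return An object of class `tto_respondent`.
#' @export
respondent_profile <- function(respondent_id, true_utilities,
                               decision_sd = 0.15, indifference_tol = 0.05,
                               framing_coeff = 0, visual_error_coeff = 0,
                               engagement_gain = 0,
                               base_log_time = log(5.5), time_sd = 0.35,
                               age_group = NA_character_,
                               gender = NA_character_,
                               education = NA_character_) {
  stopifnot(is.numeric(true_utilities), !is.null(names(true_utilities)))
  health_state(names(true_utilities))
  if (any(true_utilities < -2 - 1e-12 | true_utilities > 1 + 1e-12))
    stop("true utilities must lie in [-2, 1]", call. = FALSE)
  for (p in c(decision_sd, indifference_tol, framing_coeff,
              visual_error_coeff, engagement_gain))
    if (!is.numeric(p) || length(p) != 1L || p < 0)
      stop("behavioural parameters must be single non-negative numbers",
           call. = FALSE)
  structure(
    list(respondent_id = respondent_id,
         true_utilities = true_utilities,
         decision_sd = decision_sd, indifference_tol = indifference_tol,
         framing_coeff = framing_coeff, visual_error_coeff = visual_error_coeff,
         engagement_gain = engagement_gain,
         base_log_time = base_log_time, time_sd = time_sd,
         age_group = age_group, gender = gender, education = education),
    class = "tto_respondent"
  )
}

#' @export
print.tto_respondent <- function(x, ...) {
  cat(sprintf("Synthetic TTO respondent '%s' (%d state(s))\n",
              as.character(x$respondent_id), length(x$true_utilities)))
  cat(sprintf("  sigma=%g delta=%g kappa=%g nu=%g gamma=%g\n",
              x$decision_sd, x$indifference_tol, x$framing_coeff,
              x$visual_error_coeff, x$engagement_gain))
  invisible(x)
}

# Effective utility the agent acts on under a given task design: the latent
# utility shifted down by the framing bias (linear in the LT/UT ratio excess
# over 1) and the visual-contrast bias (linear in total bar length beyond 10
# years). Both vanish at the 5+5 design.
effective_utility <- function(agent, state, config) {
  if (!state %in% names(agent$true_utilities))
    stop("agent has no true utility for state ", state, call. = FALSE)
  u <- agent$true_utilities[[state]]
  u - agent$framing_coeff * (config$lead_time / config$unhealthy_time - 1) -
    agent$visual_error_coeff * (config$max_offer - 10) / 10
}

# Is this offer subject to the raised-bar engagement effect? Only refinement
# offers (ordinal >= 3; the two fixed openers at values 1 and 0 are routine)
# whose value lies strictly within (-0.5, 0.5), i.e. deliberation in the
# proximity of dead.
engaged_offer <- function(agent, v, ordinal, config) {
  config$visual_variant == "raised_bar" && agent$engagement_gain > 0 &&
    ordinal >= 3L && abs(v) < 0.5
}

#' One preference decision
#'
#' The agent compares the offered Life-B value `v` with its effective utility
#' for the state under this task design, perturbed by decision noise
#' `epsilon ~ N(0, sigma)`: it reports indifference when
#' `|v - u_eff + epsilon|` falls within the (possibly engagement-shrunk)
#' indifference band, otherwise prefers Life B exactly when the perturbed
#' offer value exceeds the effective utility.
#'
#' @param agent A [respondent_profile()].
#' @param offer A [offer()].
#' @param state State code being valued.
#' @param config A [task_config()].
#' @return One of `"prefer_A"`, `"prefer_B"`, `"indifferent"`.
#' @export
decide <- function(agent, offer, state, config) {
  stopifnot(inherits(agent, "tto_respondent"), inherits(offer, "tto_offer"))
  v <- compute_value(offer$duration, config)
  u_eff <- effective_utility(agent, state, config)
  eps <- rnorm(1L, 0, agent$decision_sd)
  delta <- agent$indifference_tol
  if (engaged_offer(agent, v, offer$ordinal, config))
    delta <- delta / (1 + agent$engagement_gain)
  perceived <- v - u_eff + eps
  if (abs(perceived) <= delta) "indifferent"
  else if (perceived > 0) "prefer_B"
  else "prefer_A"
}

# Forced settle when the grid is exhausted: the agent indicates indifference
# at the candidate duration whose value is closest to its (noisy) effective
# utility; ties resolve to the shorter duration.
settle <- function(agent, candidates, state, config) {
  if (length(candidates) == 1L) return(candidates)
  u_eff <- effective_utility(agent, state, config) -
    rnorm(1L, 0, agent$decision_sd)
  v <- compute_value(candidates, config)
  candidates[which.min(abs(v - u_eff))]
}

#' Per-question response time
#'
#' Time for one question is lognormal on the agent's log-time scale. Under the
#' raised-bar variant, refinement questions near the point equivalent to dead
#' (absolute offer value below 0.5, ordinal >= 3) take `1 + gamma` times
#' longer, reflecting the extra deliberation the highlighted bar provokes.
#'
#' @param agent A [respondent_profile()].
#' @param offer A [offer()].
#' @param config A [task_config()].
#' @return Seconds (single draw).
#' @export
response_time <- function(agent, offer, config) {
  stopifnot(inherits(agent, "tto_respondent"), inherits(offer, "tto_offer"))
  v <- compute_value(offer$duration, config)
  t <- exp(rnorm(1L, agent$base_log_time, agent$time_sd))
  if (engaged_offer(agent, v, offer$ordinal, config))
    t <- t * (1 + agent$engagement_gain)
  t
}

#' The two standard 5-state blocks
#'
#' The ten EQ-5D-5L states used in the valuation design, split into the two
#' fixed blocks of five; each respondent values exactly one block.
#'
#' @return Named list of two character vectors of state codes.
#' @export
default_blocks <- function() {
  list(
    block1 = c("12112", "52221", "33133", "44113", "53555"),
    block2 = c("21111", "11221", "52324", "55523", "11145")
  )
}

#' Define the randomized study design
#'
#' @param n_per_arm Respondents per arm.
#' @param blocks Named list of two character vectors of state codes; each
#'   respondent is randomized to one block.
#' @return An object of class `tto_design`.
#' @export
study_design <- function(n_per_arm, blocks = default_blocks()) {
  if (!is.numeric(n_per_arm) || length(n_per_arm) != 1L || n_per_arm < 1)
    stop("n_per_arm must be a positive count", call. = FALSE)
  if (!is.list(blocks) || length(blocks) != 2L ||
      any(!lengths(blocks)))
    stop("blocks must be a list of two non-empty state-code vectors",
         call. = FALSE)
  lapply(blocks, health_state)
  if (is.null(names(blocks))) names(blocks) <- c("block1", "block2")
  structure(list(n_per_arm = as.integer(n_per_arm), blocks = blocks),
            class = "tto_design")
}

#' Default simulation parameters for the respondent population
#'
#' State-level mean true utilities and a common between-respondent SD, the
#' behavioural parameters shared by all agents, and demographic category
#' frequencies. The defaults are illustrative, chosen to produce a plausible
#' value distribution (most mass between 0.5 and 1 with secondary mass at the
#' bounds); they are not fitted to any data set.
#'
#' @param state_means Named numeric vector of per-state mean true utilities.
#' @param state_sd Between-respondent SD of true utilities (common to all
#'   states); draws are truncated to `[-2, 1]`.
#' @param decision_sd,indifference_tol,framing_coeff,visual_error_coeff,engagement_gain
#'   Behavioural parameters, as in [respondent_profile()].
#' @param base_log_time,time_sd Response-time model (log-seconds).
#' @param demographics Named list of category-probability vectors for
#'   `age_group`, `gender`, `education`.
#' @return A list of class `tto_profile_params`.
#' @export
profile_params <- function(state_means = NULL, state_sd = 0.5,
                           decision_sd = 0.15, indifference_tol = 0.05,
                           framing_coeff = 0, visual_error_coeff = 0,
                           engagement_gain = 0,
                           base_log_time = log(5.5), time_sd = 0.35,
                           demographics = list(
                             age_group = c("18-34" = 0.45, "35-54" = 0.40,
                                           "55+" = 0.15),
                             gender = c(female = 0.53, male = 0.47),
                             education = c(tertiary = 0.55,
                                           secondary_or_lower = 0.45))) {
  if (is.null(state_means)) {
    state_means <- c(
      "12112" = 0.55, "52221" = 0.45, "33133" = 0.40, "44113" = 0.35,
      "53555" = 0.25, "21111" = 0.60, "11221" = 0.55, "52324" = 0.30,
      "55523" = 0.20, "11145" = 0.40)
  }
  health_state(names(state_means))
  structure(
    list(state_means = state_means, state_sd = state_sd,
         decision_sd = decision_sd, indifference_tol = indifference_tol,
         framing_coeff = framing_coeff, visual_error_coeff = visual_error_coeff,
         engagement_gain = engagement_gain,
         base_log_time = base_log_time, time_sd = time_sd,
         demographics = demographics),
    class = "tto_profile_params"
  )
}

# Inverse-CDF draws from Normal(mean, sd) truncated to [lo, hi].
rtrunc_norm <- function(n, mean, sd, lo = -2, hi = 1) {
  if (sd == 0) return(rep(mean, n))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

sample_category <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Draw a respondent population for a study design
#'
#' Randomizes respondents to arms (balanced: exactly `n_per_arm` each) and
#' blocks, draws per-state true utilities from truncated normal distributions
#' and demographics from the stated category frequencies. Fully reproducible
#' under `seed`.
#'
#' @param design A [study_design()].
#' @param params A [profile_params()].
#' @param seed Optional integer seed.
#' @return A list with `profiles` (list of [respondent_profile()] objects) and
#'   `assignment` (tibble: `respondent_id`, `arm`, `block`).
#' @export
sample_population <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "tto_design"), inherits(params, "tto_profile_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * design$n_per_arm
  ids <- sprintf("r%04d", seq_len(n))
  arm <- sample(rep(c("standard", "experimental"), each = design$n_per_arm))
  block <- sample(names(design$blocks), n, replace = TRUE)
  demo <- lapply(params$demographics, sample_category, n = n)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    states <- design$blocks[[block[i]]]
    missing <- setdiff(states, names(params$state_means))
    if (length(missing))
      stop("no state mean supplied for state(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    u <- vapply(states, function(s)
      rtrunc_norm(1L, params$state_means[[s]], params$state_sd), numeric(1))
    profiles[[i]] <- respondent_profile(
      ids[i], true_utilities = u,
      decision_sd = params$decision_sd,
      indifference_tol = params$indifference_tol,
      framing_coeff = params$framing_coeff,
      visual_error_coeff = params$visual_error_coeff,
      engagement_gain = params$engagement_gain,
      base_log_time = params$base_log_time, time_sd = params$time_sd,
      age_group = demo$age_group[i], gender = demo$gender[i],
      education = demo$education[i])
  }
  list(profiles = profiles,
       assignment = tibble::tibble(respondent_id = ids, arm = arm, block = block))
}

#' Simulate a full two-arm valuation study
#'
#' End-to-end driver: draws the population, then runs every respondent through
#' the elicitation engine on the five states of their block under their arm's
#' task configuration. Output is the long-format record table consumed by the
#' QC filters and the analysis pipeline (one row per respondent x state),
#' including the agents' realized true utilities and demographics.
#'
#' @param design A [study_design()].
#' @param params A [profile_params()].
#' @param configs Named list of two [task_config()] objects, names `standard`
#'   and `experimental`.
#' @param seed Integer seed; identical inputs and seed give identical records.
#' @return A tibble with columns `respondent_id`, `arm`, `block`, `state`,
#'   `T`, `U`, `n_questions`, `duration_s`, `censored`, `true_utility`,
#'   `age_group`, `gender`, `education`.
#' @examples
#' recs <- simulate_study(study_design(5), profile_params(),
#'                        configs = list(standard = task_config(10, 5),
#'                                       experimental = task_config(5, 5)),
#'                        seed = 1)
#' @export
simulate_study <- function(design, params,
                           configs = list(standard = task_config(10, 5),
                                          experimental = task_config(5, 5)),
                           seed = 1L) {
  stopifnot(inherits(design, "tto_design"))
  if (!all(c("standard", "experimental") %in% names(configs)))
    stop("configs must be a named list with elements 'standard' and 'experimental'",
         call. = FALSE)
  lapply(configs, assert_config)
  set.seed(seed)
  pop <- sample_population(design, params)
  n_tasks <- sum(lengths(design$blocks)[match(pop$assignment$block,
                                              names(design$blocks))])
  col_id <- character(n_tasks); col_arm <- character(n_tasks)
  col_block <- character(n_tasks); col_state <- character(n_tasks)
  col_T <- numeric(n_tasks); col_n <- integer(n_tasks)
  col_dur <- numeric(n_tasks); col_cens <- logical(n_tasks)
  col_u <- numeric(n_tasks); col_age <- character(n_tasks)
  col_gen <- character(n_tasks); col_edu <- character(n_tasks)
  k <- 0L
  for (i in seq_along(pop$profiles)) {
    agent <- pop$profiles[[i]]
    arm_i <- pop$assignment$arm[i]
    cfg <- configs[[arm_i]]
    states <- design$blocks[[pop$assignment$block[i]]]
    for (s in states) {
      res <- fast_task(effective_utility(agent, s, cfg), agent, cfg)
      k <- k + 1L
      col_id[k] <- agent$respondent_id; col_arm[k] <- arm_i
      col_block[k] <- pop$assignment$block[i]; col_state[k] <- s
      col_T[k] <- res$T; col_n[k] <- res$n
      col_dur[k] <- res$dur; col_cens[k] <- res$cens
      col_u[k] <- agent$true_utilities[[s]]
      col_age[k] <- agent$age_group; col_gen[k] <- agent$gender
      col_edu[k] <- agent$education
    }
  }
  tibble::tibble(
    respondent_id = col_id, arm = col_arm, block = col_block,
    state = col_state, T = col_T,
    U = (col_T - vapply(col_arm, function(a) configs[[a]]$lead_time,
                        numeric(1), USE.NAMES = FALSE)) /
      vapply(col_arm, function(a) configs[[a]]$unhealthy_time, numeric(1),
             USE.NAMES = FALSE),
    n_questions = col_n, duration_s = col_dur, censored = col_cens,
    true_utility = col_u, age_group = col_age, gender = col_gen,
    education = col_edu)
}

# Fast inner loop of one valuation task: identical draws, decisions and
# termination to run_task() (an equivalence the test suite asserts), without
# per-offer object construction. The search bracket (lo_q, hi_q) is carried
# incrementally in quarter units.
fast_task <- function(u_eff, agent, config) {
  lt_q <- config$lt_q; ut_q <- config$ut_q; max_q <- config$max_q
  sigma <- agent$decision_sd; delta0 <- agent$indifference_tol
  gamma <- agent$engagement_gain
  raised <- config$visual_variant == "raised_bar" && gamma > 0
  lo_q <- -1L; hi_q <- max_q + 1L
  n <- 0L; total_t <- 0
  censored <- FALSE; term_q <- NA_integer_
  repeat {
    if (n == 0L) x_q <- max_q
    else if (lo_q >= max_q) {
      censored <- TRUE; term_q <- max_q; break
    } else if (n == 1L) x_q <- lt_q
    else {
      lo_int <- lo_q + 1L; hi_int <- hi_q - 1L
      if (lo_int > hi_int) {
        censored <- TRUE
        cands <- c(if (lo_q >= 0L) lo_q, if (hi_q <= max_q) hi_q)
        if (length(cands) == 1L) term_q <- cands
        else {
          vs <- (cands - lt_q) / ut_q
          ue <- u_eff - rnorm(1L, 0, sigma)
          term_q <- cands[which.min(abs(vs - ue))]
        }
        break
      }
      x_q <- (max(lo_q, 0L) + hi_q) %/% 2L
      if (x_q < lo_int) x_q <- lo_int else if (x_q > hi_int) x_q <- hi_int
    }
    n <- n + 1L
    v <- (x_q - lt_q) / ut_q
    engaged <- raised && n >= 3L && abs(v) < 0.5
    d <- if (engaged) delta0 / (1 + gamma) else delta0
    perceived <- v - u_eff + rnorm(1L, 0, sigma)
    t1 <- exp(rnorm(1L, agent$base_log_time, agent$time_sd))
    if (engaged) t1 <- t1 * (1 + gamma)
    total_t <- total_t + t1
    if (abs(perceived) <= d) { term_q <- x_q; break }
    if (perceived > 0) hi_q <- x_q else lo_q <- x_q
    if (n >= 64L)
      stop("protocol error: offer cap (64) reached without termination",
           call. = FALSE)
  }
  list(T = quarters_to_years(term_q), n = n, dur = total_t, cens = censored)
}
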