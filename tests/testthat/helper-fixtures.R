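# Shared builders for tests. All fixtures are constructed in code.

cfg_std <- function(visual = "aligned") {
  task_config(10, 5, visual_variant = visual)
}

cfg_exp5 <- function() task_config(5, 5)

# Deterministic agent: no decision noise, no indifference band, no biases.
error_free_agent <- function(u, states = "53555", id = "r1", ...) {
  respondent_profile(id, setNames(rep(u, length(states)), states),
                     decision_sd = 0, indifference_tol = 0, ...)
}

# Hand-built long-format records with sensible defaults.
make_records <- function(U, respondent_id = paste0("r", seq_along(U)),
                         arm = "standard", block = "block1", state = "53555",
                         config = cfg_std(), n_questions = 3L,
                         duration_s = 30, censored = FALSE,
                         age_group = "18-34", gender = "female",
                         education = "tertiary") {
  tibble::tibble(
    respondent_id = respondent_id, arm = arm, block = block, state = state,
    T = invert_value(U, config), U = U, n_questions = n_questions,
    duration_s = duration_s, censored = censored,
    age_group = age_group, gender = gender, education = education)
}

default_configs <- function() {
  list(standard = task_config(10, 5), experimental = task_config(5, 5))
}
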