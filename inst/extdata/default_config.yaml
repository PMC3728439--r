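# Default study configuration for the simulate-clean-analyse pipeline.
# Two randomized arms differing in lead time (10 vs 5 years over the same
# 5 years of unhealthy time), two fixed 5-state blocks, and a synthetic
# respondent population with decision noise, an indifference band, and the
# lead-time framing / visual-contrast biases normalized to vanish in the
# 5 + 5 arm.
seed: 1
n_per_arm: 200
arms:
  standard:
    lead_time: 10
    unhealthy_time: 5
    visual_variant: aligned
  experimental:
    lead_time: 5
    unhealthy_time: 5
    visual_variant: aligned
profile:
  state_means:
    "12112": 0.55
    "52221": 0.45
    "33133": 0.40
    "44113": 0.35
    "53555": 0.25
    "21111": 0.60
    "11221": 0.55
    "52324": 0.30
    "55523": 0.20
    "11145": 0.40
  state_sd: 0.5
  decision_sd: 0.15
  indifference_tol: 0.05
  framing_coeff: 0.04
  visual_error_coeff: 0.02
  engagement_gain: 0.0
  base_log_time: 1.7047     # log(5.5 s) per question
  time_sd: 0.35
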