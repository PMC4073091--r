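# Fixture builders shared across test files. Everything is generated in
# code; no data files.

default_stop_config <- function(n = 52L) {
  task_config("stop", trials_per_block = n)
}

default_params <- function(prior_sd = 30, evidence_sd = 30, perf_sd = 40,
                           ...) {
  observer_params(prior_sd_px = prior_sd, evidence_sd_px = evidence_sd,
                  performance_sd_px = perf_sd, ...)
}

# a self block plus its agent replay, with distinct generative params
two_condition_trials <- function(n_per_cond = 200, seed = 1,
                                 self_prior = 30, self_ev = 30,
                                 agent_prior = 45, agent_ev = 35,
                                 perf_sd = 40) {
  cfg <- default_stop_config(n_per_cond)
  self_tr <- simulate_stop_block(
    cfg, default_params(self_prior, self_ev, perf_sd), seed = seed)
  agent_tr <- simulate_agent_replay(
    self_tr, cfg,
    default_params(agent_prior, agent_ev, perf_sd), seed = seed + 1)
  rbind(self_tr, agent_tr)
}

# hand-made minimal trial frame (veridical or otherwise synthetic reports)
manual_trials <- function(true_stop, estimate, target = 500,
                          condition = "self", direction = 1L,
                          est_time = 1.0, rt = NA_real_) {
  n <- length(true_stop)
  data.frame(
    participant_id = "t01", condition = condition, phase = "before",
    block_index = 1L, direction = as.integer(direction),
    feedback_level = "none", target_x_px = target,
    true_stop_x_px = true_stop, estimate_x_px = estimate,
    sweeps = 1L, reaction_time_s = rep_len(rt, n),
    estimation_time_s = rep_len(est_time, n),
    excluded = FALSE, excluded_reason = "",
    stringsAsFactors = FALSE
  )
}
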