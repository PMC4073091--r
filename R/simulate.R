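#' Draw a synthetic cohort of observers
#'
#' Realizes the population structure the group analyses assume. For each
#' participant: a motor performance SD drawn from `performance_sd_dist`; a
#' self prior SD equal to an exaggeration ratio times the performance SD
#' (ratios below 1 give "optimistic" priors narrower than true performance);
#' an agent prior that either tracks the performance SD or is flat with
#' probability `agent_flat_prob`; and a trait-optimism score in `[0, 24]`
#' constructed so that, in expectation over large cohorts, the partial
#' correlation between self prior SD and optimism controlling for performance
#' SD equals `optimism_partial_rho`.
#'
#' Optimism is generated from the residual of the log exaggeration ratio
#' after regressing out the performance SD, mixed with independent noise to
#' hit the target partial correlation, then affine-mapped and clipped to the
#' questionnaire range.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `participants` (one row per participant:
#'   `participant_id`, `performance_sd_px`, `self_prior_sd_px`,
#'   `agent_prior_sd_px`, `agent_prior_flat`, `optimism_score`,
#'   `exaggeration`) and `params` (named list of per-participant generative
#'   [observer_params()] for the self and agent conditions).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(derive_seed(spec$seed, "cohort"), {
    perf_sd <- rnorm_pos(n, spec$performance_sd_dist[["mean"]],
                         spec$performance_sd_dist[["sd"]])
    exagg <- rnorm_pos(n, spec$self_exaggeration_dist[["mean"]],
                       spec$self_exaggeration_dist[["sd"]])
    self_prior_sd <- exagg * perf_sd
    if (spec$agent_prior_mode == "matched") {
      agent_flat <- rep(FALSE, n)
    } else {
      agent_flat <- stats::runif(n) < spec$agent_flat_prob
    }
    agent_prior_sd <- perf_sd * exp(stats::rnorm(n, 0, spec$agent_match_sdlog))
    agent_prior_sd[agent_flat] <- FLAT_PRIOR_GENERATIVE_SD

    # optimism: target partial correlation with self prior SD given perf SD
    log_ex <- log(exagg)
    resid <- stats::residuals(stats::lm(log_ex ~ perf_sd))
    z <- if (stats::sd(resid) > 0) as.numeric(scale(resid)) else rep(0, n)
    rho <- spec$optimism_partial_rho
    y <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    optimism <- pmin(24, pmax(0, round(12 + 4.5 * y)))
  })
  ids <- sprintf("p%03d", seq_len(n))
  participants <- data.frame(
    participant_id = ids,
    performance_sd_px = perf_sd,
    self_prior_sd_px = self_prior_sd,
    agent_prior_sd_px = agent_prior_sd,
    agent_prior_flat = agent_flat,
    optimism_score = optimism,
    exaggeration = exagg,
    stringsAsFactors = FALSE
  )
  ev_ratio <- spec$evidence_sd_ratio
  params <- lapply(seq_len(n), function(i) {
    list(
      self = observer_params(prior_sd_px = self_prior_sd[i],
                             evidence_sd_px = ev_ratio * perf_sd[i],
                             performance_sd_px = perf_sd[i]),
      agent = observer_params(prior_sd_px = agent_prior_sd[i],
                              evidence_sd_px = ev_ratio * perf_sd[i] *
                                spec$agent_evidence_inflation,
                              performance_sd_px = perf_sd[i])
    )
  })
  names(params) <- ids
  list(participants = participants, params = params, spec = spec)
}

# generative stand-in SD for a flat prior; far above the 1e7 classification
# threshold, still finite so the weighting formula stays defined
FLAT_PRIOR_GENERATIVE_SD <- 1e9

# positive truncated normal draws (resample until positive)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (iter in 1:100) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop_config("performance/exaggeration distribution yields no positive draws")
}

# reliability-weighted report for a vector of true final positions
gen_estimates <- function(true_stop, direction, prior_mean, prior_sd,
                          evidence_sd, prior_shift = 0, evidence_shift = 0) {
  w <- posterior_weight(prior_sd, evidence_sd)
  noisy_evidence <- true_stop + direction * evidence_shift +
    stats::rnorm(length(true_stop), 0, evidence_sd)
  w * (prior_mean + prior_shift) + (1 - w) * noisy_evidence
}

# log-normal timing draws with occasional inflated outliers
gen_timing <- function(n, meanlog, sdlog, outlier_prob) {
  t <- stats::rlnorm(n, meanlog, sdlog)
  out <- stats::runif(n) < outlier_prob
  t[out] <- t[out] * 4
  t
}

new_trial_frame <- function(participant_id, condition, phase, block_index,
                            direction, feedback_level, target, true_stop,
                            estimate, sweeps, reaction_time, estimation_time) {
  n <- length(true_stop)
  data.frame(
    participant_id = rep_len(participant_id, n),
    condition = rep_len(condition, n),
    phase = rep_len(phase, n),
    block_index = rep_len(as.integer(block_index), n),
    direction = rep_len(as.integer(direction), n),
    feedback_level = rep_len(feedback_level, n),
    target_x_px = rep_len(as.numeric(target), n),
    true_stop_x_px = true_stop,
    estimate_x_px = estimate,
    sweeps = as.integer(sweeps),
    reaction_time_s = reaction_time,
    estimation_time_s = estimation_time,
    excluded = rep(FALSE, n),
    excluded_reason = rep("", n),
    stringsAsFactors = FALSE
  )
}

#' Simulate one block of the stop task
#'
#' True stopping positions are Normal around the target with the generative
#' performance SD; each report is the reliability-weighted mix of the prior
#' mean and noisy evidence, so reports carry residual SD
#' `(1 - w) * evidence_sd` around their conditional mean. Timing fields are
#' drawn log-normal with occasional outliers so timing-based exclusions have
#' something to find.
#'
#' @param config a stop-variant [task_config()].
#' @param params generative [observer_params()] (must carry
#'   `performance_sd_px`).
#' @param condition `"self"` or `"agent"`.
#' @param phase `"before"`, `"during"` or `"after"`.
#' @param seed integer seed.
#' @param participant_id id string recorded on each row.
#' @param block_index block number within the phase.
#' @param directions `1`, `-1`, a length-`trials_per_block` vector, or
#'   `"random"` for a per-trial coin flip.
#' @param target_x_px target override (defaults to the config's first target).
#' @param timing_outlier_prob probability of an inflated timing draw.
#' @return A trial data frame (one row per trial).
#' @export
simulate_stop_block <- function(config, params, condition = "self",
                                phase = "before", seed = 1L,
                                participant_id = "p001", block_index = 1L,
                                directions = 1L,
                                target_x_px = NULL,
                                timing_outlier_prob = 0.02) {
  stopifnot(inherits(config, "task_config"), inherits(params, "observer_params"))
  if (!config$task_kind %in% c("stop", "multi_target_stop",
                               "implicit_target_stop")) {
    stop_config("simulate_stop_block requires a stop-variant task")
  }
  if (is.null(params$performance_sd_px)) {
    stop_config("generative params must include performance_sd_px")
  }
  n <- config$trials_per_block
  target <- target_x_px %||% config$target_x_px[[1]]
  with_seed(seed, {
    dir <- if (identical(directions, "random")) {
      sample(c(-1L, 1L), n, replace = TRUE)
    } else rep_len(as.integer(directions), n)
    true_stop <- stats::rnorm(n, target, params$performance_sd_px)
    prior_mean <- if (is.finite(params$prior_mean_px)) params$prior_mean_px else target
    est <- gen_estimates(true_stop, dir, prior_mean,
                         params$prior_sd_px, params$evidence_sd_px[[1]],
                         params$prior_shift_px, params$evidence_shift_px)
    sweeps <- sample(1:6, n, replace = TRUE,
                     prob = c(0.40, 0.30, 0.15, 0.08, 0.05, 0.02))
    est_time <- gen_timing(n, log(1.5), 0.3, timing_outlier_prob)
  })
  new_trial_frame(participant_id, condition, phase, block_index, dir, "none",
                  target, true_stop, est, sweeps, NA_real_, est_time)
}

#' Replay self trials as an agent (observation) block
#'
#' The computer "performs" the task by replaying the participant's own
#' stopping positions in a permuted order. To mask outliers the replayed
#' positions are truncated (clamped) to within 2 SD of the self-set mean and
#' the number of screen sweeps is resampled into 1–4. Reports are regenerated
#' from the agent-condition observer parameters, and reaction times to the
#' computer's stop are emitted for the attention-based exclusion rule.
#'
#' @param self_trials trial data frame of self-condition trials (>= 2 rows).
#' @param config the [task_config()] the self block was generated from.
#' @param agent_params [observer_params()] for the agent condition.
#' @param seed integer seed.
#' @param timing_outlier_prob probability of an inflated timing draw.
#' @return A trial data frame with `condition = "agent"`.
#' @export
simulate_agent_replay <- function(self_trials, config, agent_params,
                                  seed = 1L, timing_outlier_prob = 0.02) {
  if (!is.data.frame(self_trials) || nrow(self_trials) < 2L) {
    stop_input("need at least 2 self trials to define the replay bounds")
  }
  if (!all(self_trials$condition == "self")) {
    stop_input("all replay source trials must have condition = 'self'")
  }
  x <- self_trials$true_stop_x_px
  m <- mean(x)
  s <- stats::sd(x)
  clamped <- pmin(pmax(x, m - 2 * s), m + 2 * s)
  n <- length(x)
  with_seed(seed, {
    replay <- clamped[sample.int(n)]
    dir <- self_trials$direction[sample.int(n)]
    prior_mean <- if (is.finite(agent_params$prior_mean_px)) {
      agent_params$prior_mean_px
    } else self_trials$target_x_px
    est <- gen_estimates(replay, dir, prior_mean,
                         agent_params$prior_sd_px,
                         agent_params$evidence_sd_px[[1]],
                         agent_params$prior_shift_px,
                         agent_params$evidence_shift_px)
    sweeps <- sample(1:4, n, replace = TRUE)
    rt <- gen_timing(n, log(0.35), 0.25, timing_outlier_prob)
    est_time <- gen_timing(n, log(1.5), 0.3, timing_outlier_prob)
  })
  new_trial_frame(self_trials$participant_id[1], "agent",
                  self_trials$phase[1], self_trials$block_index[1], dir,
                  self_trials$feedback_level[1], self_trials$target_x_px,
                  replay, est, sweeps, rt, est_time)
}

#' Simulate one block of the release task
#'
#' The ball is released above the target plane and falls for
#' `fall_frames` refreshes while moving laterally, landing a fixed
#' displacement downstream of the release point (see [release_geometry()]).
#' The three feedback levels (low/medium/high uncertainty about the landing
#' point) are interleaved with equal counts per block, and reports use the
#' level-specific evidence SD, which must be strictly increasing from low to
#' high.
#'
#' @param config a release [task_config()].
#' @param params generative [observer_params()] whose `evidence_sd_px` is a
#'   named vector with entries `low`, `medium`, `high`.
#' @inheritParams simulate_stop_block
#' @return A trial data frame; `true_stop_x_px` holds the landing position.
#' @export
simulate_release_block <- function(config, params, condition = "self",
                                   phase = "before", seed = 1L,
                                   participant_id = "p001", block_index = 1L,
                                   timing_outlier_prob = 0.02) {
  stopifnot(inherits(config, "task_config"), inherits(params, "observer_params"))
  if (config$task_kind != "release") {
    stop_config("simulate_release_block requires task_kind = 'release'")
  }
  lv <- config$feedback_levels
  ev <- params$evidence_sd_px
  if (is.null(names(ev)) || !all(lv %in% names(ev))) {
    stop_config("evidence_sd_px must be named by feedback level: ",
                paste(lv, collapse = ", "))
  }
  ordered_ev <- ev[c("low", "medium", "high")[c("low", "medium", "high") %in% lv]]
  if (any(diff(ordered_ev) <= 0)) {
    stop_config("evidence SDs must be strictly increasing low < medium < high")
  }
  n <- config$trials_per_block
  if (n %% length(lv) != 0) {
    stop_config("trials_per_block must be divisible by the number of ",
                "feedback levels for equal counts")
  }
  target <- config$target_x_px[[1]]
  disp <- release_geometry(config)$lateral_displacement_px
  with_seed(seed, {
    level <- sample(rep(lv, each = n / length(lv)))
    landing <- stats::rnorm(n, target, params$performance_sd_px)
    prior_mean <- if (is.finite(params$prior_mean_px)) params$prior_mean_px else target
    est <- numeric(n)
    for (l in lv) {
      idx <- level == l
      est[idx] <- gen_estimates(landing[idx], 1L, prior_mean,
                                params$prior_sd_px, ev[[l]],
                                params$prior_shift_px,
                                params$evidence_shift_px)
    }
    est_time <- gen_timing(n, log(1.5), 0.3, timing_outlier_prob)
  })
  tr <- new_trial_frame(participant_id, condition, phase, block_index, 1L,
                        level, target, landing, est, 1L, NA_real_, est_time)
  attr(tr, "release_x_px") <- landing - disp
  tr
}

#' Simulate one block of a no-target task
#'
#' With no goal to form a prior around, stopping positions are uniform over
#' the screen and reports are the true position plus a direction-coupled
#' forward shift (representational momentum) and evidence noise — no prior
#' term enters.
#'
#' @inheritParams simulate_stop_block
#' @export
simulate_no_target_block <- function(config, params, condition = "self",
                                     phase = "before", seed = 1L,
                                     participant_id = "p001", block_index = 1L,
                                     directions = "random",
                                     timing_outlier_prob = 0.02) {
  stopifnot(inherits(config, "task_config"), inherits(params, "observer_params"))
  if (!config$task_kind %in% c("no_target_stop", "no_target_release")) {
    stop_config("simulate_no_target_block requires a no-target task")
  }
  n <- config$trials_per_block
  with_seed(seed, {
    dir <- if (identical(directions, "random")) {
      sample(c(-1L, 1L), n, replace = TRUE)
    } else rep_len(as.integer(directions), n)
    true_stop <- stats::runif(n, 0, config$screen_width_px)
    est <- true_stop + dir * params$momentum_shift_px +
      stats::rnorm(n, 0, params$evidence_sd_px[[1]])
    sweeps <- sample(1:6, n, replace = TRUE,
                     prob = c(0.40, 0.30, 0.15, 0.08, 0.05, 0.02))
    est_time <- gen_timing(n, log(1.5), 0.3, timing_outlier_prob)
  })
  new_trial_frame(participant_id, condition, phase, block_index, dir, "none",
                  NA_real_, true_stop, est, sweeps, NA_real_, est_time)
}

#' Simulate a full session for a synthetic cohort
#'
#' Runs the phase/block design for every participant: within each phase, each
#' self block is immediately followed by its agent replay (the fixed order
#' that lets the computer mirror the participant's own performance). The
#' `during` and `after` phases apply the cohort's feedback factors
#' multiplicatively to the performance and evidence SDs — never to the prior
#' SD, whose generative value is identical across phases.
#'
#' @param cohort result of [make_cohort()].
#' @param config a stop-variant [task_config()]; its `n_blocks_per_phase`
#'   names the phases run.
#' @param root_seed integer root seed; per-participant/block substreams are
#'   derived by stable hashing so participant order is immaterial.
#' @param conditions conditions to run (`"self"` always; `"agent"` adds a
#'   replay after each self block).
#' @return A list with `trials` (all trials), `participants`, and
#'   `generative` (per participant × phase generative SDs actually used).
#' @export
simulate_session <- function(cohort, config, root_seed = 1L,
                             conditions = c("self", "agent")) {
  stopifnot(is.list(cohort), !is.null(cohort$participants))
  phases <- names(config$n_blocks_per_phase)
  if (is.null(phases)) stop_config("n_blocks_per_phase must be named by phase")
  spec <- cohort$spec
  out <- vector("list", 0L)
  gen <- vector("list", 0L)
  for (pid in cohort$participants$participant_id) {
    pp <- cohort$params[[pid]]
    for (phase in phases) {
      f_perf <- if (phase == "before") 1 else spec$feedback_perf_sd_factor
      f_evid <- if (phase == "before") 1 else spec$feedback_evid_sd_factor
      self_par <- pp$self
      self_par$performance_sd_px <- self_par$performance_sd_px * f_perf
      self_par$evidence_sd_px <- self_par$evidence_sd_px * f_evid
      agent_par <- pp$agent
      agent_par$evidence_sd_px <- agent_par$evidence_sd_px * f_evid
      gen[[length(gen) + 1L]] <- data.frame(
        participant_id = pid, phase = phase,
        performance_sd_px = self_par$performance_sd_px,
        evidence_sd_px = self_par$evidence_sd_px[[1]],
        self_prior_sd_px = self_par$prior_sd_px,
        agent_prior_sd_px = agent_par$prior_sd_px,
        stringsAsFactors = FALSE
      )
      for (b in seq_len(config$n_blocks_per_phase[[phase]])) {
        s_self <- derive_seed(root_seed,
                              sprintf("%s/%s/self/%d", pid, phase, b))
        self_tr <- simulate_stop_block(
          config, self_par, condition = "self", phase = phase,
          seed = s_self, participant_id = pid, block_index = b,
          timing_outlier_prob = spec$timing_outlier_prob)
        out[[length(out) + 1L]] <- self_tr
        if ("agent" %in% conditions) {
          s_ag <- derive_seed(root_seed,
                              sprintf("%s/%s/agent/%d", pid, phase, b))
          out[[length(out) + 1L]] <- simulate_agent_replay(
            self_tr, config, agent_par, seed = s_ag,
            timing_outlier_prob = spec$timing_outlier_prob)
        }
      }
    }
  }
  list(trials = do.call(rbind, out),
       participants = cohort$participants,
       generative = do.call(rbind, gen))
}
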