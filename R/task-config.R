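#' Task configuration for a visuomotor ball task
#'
#' Describes one task variant: the classic "stop" task (press a button to stop
#' a ball sweeping at constant speed under a target), the "release" task (drop
#' the ball onto a target on the floor of the screen; the ball falls for a
#' fixed number of screen refreshes while still moving laterally), and their
#' no-target / multi-target / implicit-target variants.
#'
#' Screen coordinates are in pixels, x = 0 at the left edge and increasing
#' rightward; all signed errors are rightward-positive.
#'
#' @param task_kind one of `"stop"`, `"release"`, `"no_target_stop"`,
#'   `"no_target_release"`, `"multi_target_stop"`, `"implicit_target_stop"`.
#' @param screen_width_px screen width in pixels.
#' @param refresh_hz display refresh rate (Hz).
#' @param sweep_speed_px_s horizontal ball speed during the sweep (px/s).
#' @param target_x_px target position(s), px. A vector for multi-target tasks;
#'   ignored (may be `NA`) for no-target tasks.
#' @param fall_frames number of screen refreshes the ball falls for after
#'   release (release tasks only).
#' @param fall_lateral_speed_px_s horizontal speed during the fall (px/s,
#'   release tasks only).
#' @param trials_per_block trials per block.
#' @param n_blocks_per_phase named integer vector of blocks per phase
#'   (e.g. `c(before = 2, during = 2, after = 2)`).
#' @param feedback_levels feedback-uncertainty levels used by release tasks,
#'   subset of `c("low", "medium", "high")`.
#' @param seed integer seed associated with the task.
#' @return A validated `task_config` list.
#' @export
task_config <- function(task_kind = "stop",
                        screen_width_px = 1024,
                        refresh_hz = 85,
                        sweep_speed_px_s = 1200,
                        target_x_px = screen_width_px / 2,
                        fall_frames = NULL,
                        fall_lateral_speed_px_s = NULL,
                        trials_per_block = 52,
                        n_blocks_per_phase = c(before = 2, during = 2, after = 2),
                        feedback_levels = NULL,
                        seed = 1L) {
  kinds <- c("stop", "release", "no_target_stop", "no_target_release",
             "multi_target_stop", "implicit_target_stop")
  if (!is.character(task_kind) || length(task_kind) != 1L ||
      !task_kind %in% kinds) {
    stop_config("task_kind must be one of: ", paste(kinds, collapse = ", "))
  }
  if (!is.finite(refresh_hz) || refresh_hz <= 0) {
    stop_config("refresh_hz must be strictly positive")
  }
  if (!is.finite(sweep_speed_px_s) || sweep_speed_px_s <= 0) {
    stop_config("sweep_speed_px_s must be strictly positive")
  }
  if (!is.finite(screen_width_px) || screen_width_px <= 0) {
    stop_config("screen_width_px must be strictly positive")
  }
  if (!is.finite(trials_per_block) || trials_per_block < 1) {
    stop_config("trials_per_block must be >= 1")
  }
  is_release <- task_kind %in% c("release", "no_target_release")
  if (is_release) {
    fall_frames <- fall_frames %||% 4L
    fall_lateral_speed_px_s <- fall_lateral_speed_px_s %||% 2400
    if (!is.finite(fall_frames) || fall_frames < 1) {
      stop_config("fall_frames must be >= 1 for release tasks")
    }
    if (!is.finite(fall_lateral_speed_px_s) || fall_lateral_speed_px_s <= 0) {
      stop_config("fall_lateral_speed_px_s must be strictly positive")
    }
    feedback_levels <- feedback_levels %||% c("low", "medium", "high")
    if (!all(feedback_levels %in% c("low", "medium", "high"))) {
      stop_config("feedback_levels must be a subset of low/medium/high")
    }
  } else {
    if (!is.null(fall_frames)) {
      stop_config("fall_frames only applies to release tasks")
    }
  }
  has_target <- !task_kind %in% c("no_target_stop", "no_target_release")
  if (has_target) {
    if (any(!is.finite(target_x_px)) ||
        any(target_x_px < 0 | target_x_px > screen_width_px)) {
      stop_config("every target position must lie within [0, screen_width_px]")
    }
  } else {
    target_x_px <- NA_real_
  }
  structure(list(
    task_kind = task_kind,
    screen_width_px = screen_width_px,
    refresh_hz = refresh_hz,
    sweep_speed_px_s = sweep_speed_px_s,
    target_x_px = target_x_px,
    fall_frames = if (is_release) as.integer(fall_frames) else NULL,
    fall_lateral_speed_px_s = if (is_release) fall_lateral_speed_px_s else NULL,
    trials_per_block = as.integer(trials_per_block),
    n_blocks_per_phase = n_blocks_per_phase,
    feedback_levels = if (is_release) feedback_levels else NULL,
    seed = as.integer(seed)
  ), class = "task_config")
}

#' Horizontal displacement of the ball per screen refresh
#'
#' During the sweep the ball advances `sweep_speed_px_s / refresh_hz` pixels
#' per refresh (e.g. 1200 px/s at 85 Hz is about 14.1 px per refresh).
#'
#' @param config a [task_config()].
#' @return Displacement in pixels per refresh.
#' @export
per_refresh_displacement <- function(config) {
  config$sweep_speed_px_s / config$refresh_hz
}

#' Fall duration and lateral displacement of a released ball
#'
#' A released ball falls to the target plane over `fall_frames` screen
#' refreshes while continuing to move horizontally, so it lands
#' `fall_frames / refresh_hz * fall_lateral_speed_px_s` pixels downstream of
#' the release point (about 112.9 px for 4 frames at 85 Hz and 2400 px/s).
#'
#' @param config a release-task [task_config()].
#' @return A list with `fall_duration_s` and `lateral_displacement_px`.
#' @export
release_geometry <- function(config) {
  if (is.null(config$fall_frames)) {
    stop_config("release_geometry requires a release task config")
  }
  dur <- config$fall_frames / config$refresh_hz
  list(fall_duration_s = dur,
       lateral_displacement_px = dur * config$fall_lateral_speed_px_s)
}

#' Generative / fitted observer parameters
#'
#' The observer's report of the ball's final position combines a Gaussian
#' prior centred on the goal with Gaussian-noisy sensory evidence centred on
#' the true final position. `prior_sd_px` and `evidence_sd_px` set their
#' spreads; the optional shifts displace the two means (the evidence shift is
#' applied with the sign of the motion direction). Fields used only when
#' generating synthetic trials: `performance_sd_px` (spread of true stops
#' around the target) and `momentum_shift_px` (forward displacement of
#' reports in no-target tasks, i.e. representational momentum).
#'
#' @param prior_mean_px prior mean (px); `NA` means "centred on the trial's
#'   target".
#' @param prior_sd_px prior SD (px, > 0); flat priors are represented by very
#'   large finite values (see [classify_flat()]).
#' @param evidence_sd_px evidence SD (px, > 0); a scalar or a named vector
#'   keyed by feedback level (`low`/`medium`/`high`).
#' @param prior_shift_px offset of the prior mean from the target (px).
#' @param evidence_shift_px direction-coupled offset of the evidence mean (px).
#' @param performance_sd_px generative SD of true stops around the target.
#' @param momentum_shift_px generative directional report shift for no-target
#'   tasks (px).
#' @return A validated `observer_params` list.
#' @export
observer_params <- function(prior_mean_px = NA_real_,
                            prior_sd_px,
                            evidence_sd_px,
                            prior_shift_px = 0,
                            evidence_shift_px = 0,
                            performance_sd_px = NULL,
                            momentum_shift_px = 0) {
  if (any(!is.finite(prior_sd_px)) || any(prior_sd_px <= 0)) {
    stop_config("prior_sd_px must be finite and > 0")
  }
  if (any(!is.finite(evidence_sd_px)) || any(evidence_sd_px <= 0)) {
    stop_config("evidence_sd_px must be finite and > 0")
  }
  if (!is.null(performance_sd_px) &&
      (!is.finite(performance_sd_px) || performance_sd_px <= 0)) {
    stop_config("performance_sd_px must be finite and > 0")
  }
  structure(list(
    prior_mean_px = prior_mean_px,
    prior_sd_px = prior_sd_px,
    evidence_sd_px = evidence_sd_px,
    prior_shift_px = prior_shift_px,
    evidence_shift_px = evidence_shift_px,
    performance_sd_px = performance_sd_px,
    momentum_shift_px = momentum_shift_px
  ), class = "observer_params")
}

#' Population-level settings for a synthetic cohort
#'
#' Defines the generative population the synthetic participants are drawn
#' from: per-participant motor performance SD; the ratio of self prior SD to
#' performance SD (values below 1 mean "optimistic" priors narrower than true
#' performance); how agent (observation) priors behave (tracking performance,
#' or flat with some probability); the target partial correlation between
#' self prior SD and trait optimism controlling for performance SD; and the
#' multiplicative reductions that feedback phases apply to performance and
#' evidence SDs (never to prior SDs).
#'
#' @param n_participants number of participants (>= 2).
#' @param performance_sd_dist `c(mean, sd)` of the per-participant performance
#'   SD (px).
#' @param self_exaggeration_dist `c(mean, sd)` of the self prior SD /
#'   performance SD ratio.
#' @param agent_prior_mode `"matched"` or `"flat_with_prob"`.
#' @param agent_flat_prob probability an agent prior is flat (only used with
#'   `agent_prior_mode = "flat_with_prob"`).
#' @param agent_match_sdlog log-scale SD of the matched agent prior around the
#'   performance SD.
#' @param optimism_partial_rho target partial correlation between self prior
#'   SD and optimism score, controlling for performance SD (usually negative).
#' @param feedback_perf_sd_factor multiplicative factor on performance SD in
#'   the `during`/`after` phases.
#' @param feedback_evid_sd_factor same, for the evidence SD.
#' @param evidence_sd_ratio evidence SD as a fraction of performance SD (or a
#'   named vector by feedback level for release tasks).
#' @param agent_evidence_inflation multiplicative factor on the evidence SD
#'   in the agent condition (observation carries slightly noisier evidence
#'   than one's own action, which also has proprioceptive support).
#' @param timing_outlier_prob probability a trial gets an inflated timing
#'   value (so timing-based exclusion rules are exercised).
#' @param seed integer seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 20,
                        performance_sd_dist = c(mean = 40, sd = 10),
                        self_exaggeration_dist = c(mean = 0.6, sd = 0.15),
                        agent_prior_mode = c("flat_with_prob", "matched"),
                        agent_flat_prob = 0.25,
                        agent_match_sdlog = 0.2,
                        optimism_partial_rho = -0.5,
                        feedback_perf_sd_factor = 0.85,
                        feedback_evid_sd_factor = 0.8,
                        evidence_sd_ratio = 0.75,
                        agent_evidence_inflation = 1.15,
                        timing_outlier_prob = 0.02,
                        seed = 1L) {
  agent_prior_mode <- match.arg(agent_prior_mode)
  if (!is.finite(n_participants) || n_participants < 2) {
    stop_config("n_participants must be >= 2")
  }
  for (nm in c("performance_sd_dist", "self_exaggeration_dist")) {
    d <- get(nm)
    if (length(d) != 2L || any(!is.finite(d)) || d[[1]] <= 0 || d[[2]] < 0) {
      stop_config(nm, " must be c(mean > 0, sd >= 0)")
    }
  }
  if (agent_flat_prob < 0 || agent_flat_prob > 1) {
    stop_config("agent_flat_prob must lie in [0, 1]")
  }
  if (timing_outlier_prob < 0 || timing_outlier_prob > 1) {
    stop_config("timing_outlier_prob must lie in [0, 1]")
  }
  if (!is.finite(optimism_partial_rho) || abs(optimism_partial_rho) > 1) {
    stop_config("optimism_partial_rho must lie in [-1, 1]")
  }
  if (any(evidence_sd_ratio <= 0)) {
    stop_config("evidence_sd_ratio must be > 0")
  }
  if (!is.finite(agent_evidence_inflation) || agent_evidence_inflation <= 0) {
    stop_config("agent_evidence_inflation must be > 0")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    performance_sd_dist = c(mean = unname(performance_sd_dist[[1]]),
                            sd = unname(performance_sd_dist[[2]])),
    self_exaggeration_dist = c(mean = unname(self_exaggeration_dist[[1]]),
                               sd = unname(self_exaggeration_dist[[2]])),
    agent_prior_mode = agent_prior_mode,
    agent_flat_prob = agent_flat_prob,
    agent_match_sdlog = agent_match_sdlog,
    optimism_partial_rho = optimism_partial_rho,
    feedback_perf_sd_factor = feedback_perf_sd_factor,
    feedback_evid_sd_factor = feedback_evid_sd_factor,
    evidence_sd_ratio = evidence_sd_ratio,
    agent_evidence_inflation = agent_evidence_inflation,
    timing_outlier_prob = timing_outlier_prob,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}
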