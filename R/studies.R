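# Simulation studies that calibrate the pipeline: parameter recovery, model
# selection, bootstrap coverage, and type-I error of the headline contrast.
# These are the computations behind the package's claims that the fitting
# machinery works at the study's scale.

#' Parameter-recovery study for the observer fit
#'
#' Simulates a cohort at study scale (by default 20 participants, four
#' 52-trial self blocks each with their agent replays, ~208 trials per
#' condition), fits the full single-direction model per participant, and
#' summarizes how well self prior SDs are recovered: the median relative
#' error of the fitted self prior SD, and the fraction of participants for
#' whom the sign of (self prior SD - performance SD) — is the prior
#' optimistic or not — matches the generative truth.
#'
#' @param seed integer seed.
#' @param n_participants cohort size.
#' @param n_blocks self blocks per participant.
#' @return A list: `median_rel_err`, `sign_rate`, `n`, and the per-participant
#'   `table`.
#' @export
recovery_study <- function(seed, n_participants = 20, n_blocks = 4) {
  spec <- cohort_spec(n_participants = n_participants, seed = seed)
  cohort <- make_cohort(spec)
  cfg <- task_config("stop",
                     n_blocks_per_phase = c(before = n_blocks))
  ses <- simulate_session(cohort, cfg, root_seed = seed)
  trials <- apply_exclusions(ses$trials)
  g <- cohort$participants
  rows <- lapply(seq_len(nrow(g)), function(i) {
    pid <- g$participant_id[i]
    tr <- trials[trials$participant_id == pid, ]
    fit <- fit_model(tr, model_preset("exp1_full"),
                     seed = derive_seed(seed, paste0("rec/", pid)))
    self_tr <- tr[tr$condition == "self" & !tr$excluded, ]
    perf_hat <- stats::sd(self_tr$true_stop_x_px - self_tr$target_x_px)
    prior_hat <- fit$params[["prior_sd.self"]]
    data.frame(
      participant_id = pid,
      prior_sd_true = g$self_prior_sd_px[i],
      prior_sd_hat = prior_hat,
      rel_err = abs(prior_hat - g$self_prior_sd_px[i]) / g$self_prior_sd_px[i],
      sign_true = g$self_prior_sd_px[i] < g$performance_sd_px[i],
      sign_hat = prior_hat < perf_hat,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  list(median_rel_err = stats::median(tab$rel_err),
       sign_rate = mean(tab$sign_true == tab$sign_hat),
       n = n_participants, table = tab)
}

#' Model-selection study: does BIC find the generating family?
#'
#' Two arms. Parsimony: `n_shared` replicate datasets generated with the
#' evidence SD tied across conditions are fitted under the tied and the full
#' model; the tied model should win on mean BIC. Discrimination: a cohort of
#' `n_participants` generated with well-separated per-condition evidence SDs
#' is fitted under both; the full model should win in the majority of
#' participants.
#'
#' @param seed integer seed.
#' @param n_shared replicates for the parsimony arm.
#' @param n_participants cohort size for the discrimination arm.
#' @param n_per_cond trials per condition in each dataset.
#' @return A list: `mean_bic_shared_minus_full` (negative favors the tied
#'   model on tied data), `full_win_fraction`, and the arm sizes.
#' @export
selection_study <- function(seed, n_shared = 200, n_participants = 20,
                            n_per_cond = 100) {
  cfg <- task_config("stop", trials_per_block = n_per_cond)
  gen_pair <- function(s, self_ev, agent_ev) {
    self_tr <- simulate_stop_block(
      cfg, observer_params(prior_sd_px = 30, evidence_sd_px = self_ev,
                           performance_sd_px = 40), seed = s)
    agent_tr <- simulate_agent_replay(
      self_tr, cfg,
      observer_params(prior_sd_px = 45, evidence_sd_px = agent_ev),
      seed = s + 1L)
    rbind(self_tr, agent_tr)
  }
  d <- vapply(seq_len(n_shared), function(i) {
    s <- derive_seed(seed, paste0("shared/", i))
    tr <- gen_pair(s, self_ev = 30, agent_ev = 30)
    shared <- fit_model(tr, model_preset("exp1_shared_evidence"),
                        n_restarts = 2, seed = s)
    full <- fit_model(tr, model_preset("exp1_full"), n_restarts = 2, seed = s)
    shared$bic - full$bic
  }, numeric(1))

  wins <- vapply(seq_len(n_participants), function(i) {
    s <- derive_seed(seed, paste0("full/", i))
    tr <- gen_pair(s, self_ev = 25, agent_ev = 50)
    shared <- fit_model(tr, model_preset("exp1_shared_evidence"),
                        n_restarts = 2, seed = s)
    full <- fit_model(tr, model_preset("exp1_full"), n_restarts = 2, seed = s)
    full$bic < shared$bic
  }, logical(1))

  list(mean_bic_shared_minus_full = mean(d),
       full_win_fraction = mean(wins),
       n_shared = n_shared, n_participants = n_participants)
}

#' Bootstrap coverage study for the evidence SD
#'
#' Generates `n_rep` independent datasets from a known observer, bootstraps a
#' 95% percentile interval for the evidence SD on each, and reports the
#' fraction of intervals covering the generative value.
#'
#' @param seed integer seed.
#' @param n_rep number of datasets.
#' @param B bootstrap replicates per dataset.
#' @param n_trials trials per dataset.
#' @param prior_sd,evidence_sd generative SDs.
#' @return A list: `coverage`, `n_rep`, `B`.
#' @export
coverage_study <- function(seed, n_rep = 200, B = 500, n_trials = 100,
                           prior_sd = 30, evidence_sd = 30) {
  cfg <- task_config("stop", trials_per_block = n_trials)
  par <- observer_params(prior_sd_px = prior_sd, evidence_sd_px = evidence_sd,
                         performance_sd_px = 40)
  hits <- vapply(seq_len(n_rep), function(i) {
    s <- derive_seed(seed, paste0("cov/", i))
    tr <- simulate_stop_block(cfg, par, seed = s)
    ci <- bootstrap_cis(tr, model_preset("exp1_full"), B = B, seed = s,
                        n_restarts = 1)$ci
    row <- ci[ci$param == "evidence_sd.self", ]
    row$lower <= evidence_sd && evidence_sd <= row$upper
  }, logical(1))
  list(coverage = mean(hits), n_rep = n_rep, B = B)
}

#' Type-I error of the self-prior-vs-performance contrast
#'
#' Generates null cohorts in which self prior SDs scatter around the
#' performance SD with no systematic exaggeration (ratio centred on 1), runs
#' the one-sample contrast of (self prior SD - performance SD) against zero
#' on each cohort, and reports the 5%-level rejection rate.
#'
#' @param seed integer seed.
#' @param n_cohorts number of simulated cohorts.
#' @param n_participants cohort size.
#' @param alpha nominal level.
#' @return A list: `rejection_rate`, `n_cohorts`, `n_participants`.
#' @export
type1_study <- function(seed, n_cohorts = 1000, n_participants = 20,
                        alpha = 0.05) {
  rej <- vapply(seq_len(n_cohorts), function(i) {
    spec <- cohort_spec(n_participants = n_participants,
                        self_exaggeration_dist = c(mean = 1, sd = 0.15),
                        seed = derive_seed(seed, paste0("null/", i)))
    g <- make_cohort(spec)$participants
    t_test_one(g$self_prior_sd_px - g$performance_sd_px)$p < alpha
  }, logical(1))
  list(rejection_rate = mean(rej), n_cohorts = n_cohorts,
       n_participants = n_participants)
}
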