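test_that("degenerate exaggeration ratio of 1 makes self priors equal performance SDs", {
  spec <- cohort_spec(n_participants = 10,
                      self_exaggeration_dist = c(mean = 1, sd = 0),
                      seed = 3)
  cohort <- make_cohort(spec)
  expect_equal(cohort$participants$self_prior_sd_px,
               cohort$participants$performance_sd_px)
})

test_that("flat-agent-prior fraction sits inside binomial bounds", {
  spec <- cohort_spec(n_participants = 400, agent_flat_prob = 0.25, seed = 7)
  cohort <- make_cohort(spec)
  n_flat <- sum(cohort$participants$agent_prior_flat)
  bounds <- qbinom(c(0.005, 0.995), 400, 0.25)
  expect_gte(n_flat, bounds[1])
  expect_lte(n_flat, bounds[2])
  expect_true(all(
    cohort$participants$agent_prior_sd_px[cohort$participants$agent_prior_flat] > 1e7))
})

test_that("optimism scores hit the target partial correlation and stay in range", {
  spec <- cohort_spec(n_participants = 1000, optimism_partial_rho = -0.5,
                      seed = 11)
  g <- make_cohort(spec)$participants
  expect_true(all(g$optimism_score >= 0 & g$optimism_score <= 24))
  expect_true(all(g$exaggeration > 0))
  # independent closed-form partial-correlation oracle
  r_xy <- cor(g$self_prior_sd_px, g$optimism_score)
  r_xz <- cor(g$self_prior_sd_px, g$performance_sd_px)
  r_zy <- cor(g$performance_sd_px, g$optimism_score)
  partial <- (r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))
  expect_lt(abs(partial - (-0.5)), 0.1)
})

test_that("stop blocks emit the configured number of trials with plausible fields", {
  tr <- simulate_stop_block(default_stop_config(), default_params(), seed = 1)
  expect_equal(nrow(tr), 52L)
  expect_true(all(tr$estimation_time_s > 0))
  expect_true(all(tr$direction == 1L))
  expect_false(any(tr$excluded))
  # determinism: identical seed, identical table
  expect_identical(tr, simulate_stop_block(default_stop_config(),
                                           default_params(), seed = 1))
})

test_that("veridical limit: flat prior and vanishing noise reproduce true stops", {
  par <- observer_params(prior_sd_px = 1e9, evidence_sd_px = 1e-6,
                         performance_sd_px = 40)
  tr <- simulate_stop_block(default_stop_config(100), par, seed = 2)
  expect_lt(max(abs(tr$estimate_x_px - tr$true_stop_x_px)), 1e-4)
})

test_that("sample SD of performance errors matches the generative value", {
  cfg <- task_config("stop", trials_per_block = 10000)
  tr <- simulate_stop_block(cfg, default_params(perf_sd = 40), seed = 5)
  s <- sd(tr$true_stop_x_px - tr$target_x_px)
  expect_lt(abs(s - 40) / 40, 0.03)
})

test_that("generated self blocks obey the slope and residual-variance identities", {
  # population regression slope of estimation on performance error == -w,
  # and the regression residual variance equals (1-w)^2 sigma_evidence^2
  cfg <- task_config("stop", trials_per_block = 10000)
  for (pars in list(c(prior = 30, ev = 30), c(prior = 20, ev = 45))) {
    w <- posterior_weight(pars[["prior"]], pars[["ev"]])
    tr <- simulate_stop_block(cfg, default_params(pars[["prior"]], pars[["ev"]]),
                              seed = 17)
    reg <- fit_error_regression(tr)
    expect_lt(abs(reg$weighting - w), 0.02)
    expect_lt(abs(reg$residual_sd_px^2 / ((1 - w)^2 * pars[["ev"]]^2) - 1), 0.05)
  }
})

test_that("agent replay permutes clamped self positions and bounds sweeps", {
  cfg <- default_stop_config(60)
  self_tr <- simulate_stop_block(cfg, default_params(), seed = 9)
  ag <- simulate_agent_replay(self_tr, cfg, default_params(45, 35), seed = 10)
  m <- mean(self_tr$true_stop_x_px)
  s <- sd(self_tr$true_stop_x_px)
  clamped <- pmin(pmax(self_tr$true_stop_x_px, m - 2 * s), m + 2 * s)
  expect_equal(sort(ag$true_stop_x_px), sort(clamped))
  expect_true(all(ag$sweeps %in% 1:4))
  expect_true(all(ag$condition == "agent"))
  expect_true(all(is.finite(ag$reaction_time_s)))
})

test_that("an extreme self position is replayed at the nearer 2-SD bound", {
  tr <- manual_trials(true_stop = c(500, 502, 498, 501, 499, 700),
                      estimate = rep(500, 6))
  m <- mean(tr$true_stop_x_px); s <- sd(tr$true_stop_x_px)
  ag <- simulate_agent_replay(tr, default_stop_config(), default_params(),
                              seed = 4)
  expect_true((m + 2 * s) %in% ag$true_stop_x_px)
  expect_false(700 %in% ag$true_stop_x_px)
})

test_that("replay refuses fewer than two self trials", {
  tr <- manual_trials(500, 500)
  expect_error(simulate_agent_replay(tr, default_stop_config(),
                                     default_params(), seed = 1),
               class = "selfpriors_input_error")
})

test_that("release blocks partition feedback levels equally and displace the fall", {
  cfg <- task_config("release", trials_per_block = 48)
  par <- observer_params(prior_sd_px = 30,
                         evidence_sd_px = c(low = 15, medium = 30, high = 60),
                         performance_sd_px = 40)
  tr <- simulate_release_block(cfg, par, seed = 3)
  expect_equal(unname(table(tr$feedback_level)[c("low", "medium", "high")]),
               rep(16L, 3), ignore_attr = TRUE)
  geom <- release_geometry(cfg)
  expect_equal(geom$lateral_displacement_px, 4 / 85 * 2400)
  expect_equal(tr$true_stop_x_px - attr(tr, "release_x_px"),
               rep(geom$lateral_displacement_px, 48))
  # unordered evidence SDs are a configuration error
  bad <- observer_params(prior_sd_px = 30,
                         evidence_sd_px = c(low = 30, medium = 20, high = 60),
                         performance_sd_px = 40)
  expect_error(simulate_release_block(cfg, bad, seed = 3),
               class = "selfpriors_config_error")
})

test_that("release weighting rises with the uncertainty level", {
  cfg <- task_config("release", trials_per_block = 6000)
  par <- observer_params(prior_sd_px = 30,
                         evidence_sd_px = c(low = 15, medium = 30, high = 60),
                         performance_sd_px = 40)
  tr <- simulate_release_block(cfg, par, seed = 21)
  w <- vapply(c("low", "medium", "high"), function(l) {
    fit_error_regression(tr[tr$feedback_level == l, ])$weighting
  }, numeric(1))
  expect_true(all(diff(w) > 0))
  w_true <- posterior_weight(30, c(15, 30, 60))
  expect_lt(max(abs(w - w_true)), 0.05)
})

test_that("no-target blocks shift reports along the motion direction only", {
  cfg <- task_config("no_target_stop", trials_per_block = 8000)
  par0 <- observer_params(prior_sd_px = 30, evidence_sd_px = 25,
                          momentum_shift_px = 0)
  tr0 <- simulate_no_target_block(cfg, par0, seed = 6)
  err0 <- tr0$estimate_x_px - tr0$true_stop_x_px
  expect_lt(abs(mean(err0)), 1.5)

  par20 <- observer_params(prior_sd_px = 30, evidence_sd_px = 25,
                           momentum_shift_px = 20)
  tr <- simulate_no_target_block(cfg, par20, seed = 6)
  err <- tr$estimate_x_px - tr$true_stop_x_px
  expect_lt(abs(mean(err[tr$direction > 0]) - 20), 2)
  expect_lt(abs(mean(err[tr$direction < 0]) + 20), 2)
  # no positional anchor: slope of error on screen position is ~0
  slope <- coef(lm(err ~ tr$true_stop_x_px))[[2]]
  expect_lt(abs(slope), 0.01)
})

test_that("session phases rescale performance and evidence SDs but never the prior", {
  spec <- cohort_spec(n_participants = 3, feedback_perf_sd_factor = 0.8,
                      feedback_evid_sd_factor = 0.7, seed = 2)
  cohort <- make_cohort(spec)
  cfg <- task_config("stop", trials_per_block = 400,
                     n_blocks_per_phase = c(before = 1, during = 1))
  ses <- simulate_session(cohort, cfg, root_seed = 31)
  gen <- ses$generative
  for (pid in unique(gen$participant_id)) {
    g <- gen[gen$participant_id == pid, ]
    expect_equal(g$performance_sd_px[g$phase == "during"],
                 0.8 * g$performance_sd_px[g$phase == "before"])
    expect_equal(g$evidence_sd_px[g$phase == "during"],
                 0.7 * g$evidence_sd_px[g$phase == "before"])
    expect_equal(g$self_prior_sd_px[g$phase == "during"],
                 g$self_prior_sd_px[g$phase == "before"])
  }
  # sample SDs track the rescaling
  self_tr <- ses$trials[ses$trials$condition == "self", ]
  sds <- tapply(self_tr$true_stop_x_px - self_tr$target_x_px,
                list(self_tr$participant_id, self_tr$phase), sd)
  expect_lt(abs(mean(sds[, "during"] / sds[, "before"]) - 0.8), 0.08)

  # no-learning limit: factors of 1 leave generative SDs identical
  spec1 <- cohort_spec(n_participants = 2, feedback_perf_sd_factor = 1,
                       feedback_evid_sd_factor = 1, seed = 2)
  ses1 <- simulate_session(make_cohort(spec1), cfg, root_seed = 31)
  g1 <- ses1$generative
  expect_equal(g1$performance_sd_px[g1$phase == "during"],
               g1$performance_sd_px[g1$phase == "before"])
})

test_that("session generation is deterministic and participant-order stable", {
  spec <- cohort_spec(n_participants = 3, seed = 5)
  cfg <- task_config("stop", trials_per_block = 20,
                     n_blocks_per_phase = c(before = 1))
  a <- simulate_session(make_cohort(spec), cfg, root_seed = 13)
  b <- simulate_session(make_cohort(spec), cfg, root_seed = 13)
  expect_identical(a$trials, b$trials)
})
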