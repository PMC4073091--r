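test_that("identical estimation times produce zero exclusions", {
  tr <- manual_trials(rnorm(20, 500, 30), rnorm(20, 500, 30), est_time = 1.0)
  out <- apply_exclusions(tr)
  expect_false(any(out$excluded))
})

test_that("a single extreme estimation time is the only flagged trial", {
  times <- c(rep(1.0, 49), 10.0)
  tr <- manual_trials(rnorm(50, 500, 30), rnorm(50, 500, 30),
                      est_time = times)
  # oracle on the raw values: only the 10 s trial exceeds mean +/- 2 SD
  expect_equal(which(abs(times - mean(times)) > 2 * sd(times)), 50L)
  out <- apply_exclusions(tr)
  expect_equal(which(out$excluded), 50L)
  expect_equal(out$excluded_reason[50], "est_time")
})

test_that("the reaction-time rule touches agent trials only", {
  rt <- c(rep(0.3, 29), 3.0)
  self_tr <- manual_trials(rnorm(30, 500, 30), rnorm(30, 500, 30), rt = rt)
  agent_tr <- manual_trials(rnorm(30, 500, 30), rnorm(30, 500, 30),
                            condition = "agent", rt = rt)
  out <- apply_exclusions(rbind(self_tr, agent_tr))
  expect_false(any(grepl("agent_rt", out$excluded_reason[out$condition == "self"])))
  expect_equal(out$excluded_reason[out$condition == "agent"][30], "agent_rt")
})

test_that("exclusion flagging is idempotent", {
  tr <- two_condition_trials(100, seed = 3)
  once <- apply_exclusions(tr)
  twice <- apply_exclusions(once)
  expect_identical(once, twice)
})

test_that("missing timing columns are an input error", {
  tr <- two_condition_trials(20, seed = 4)
  tr$estimation_time_s <- NULL
  expect_error(apply_exclusions(tr), class = "selfpriors_input_error")
})

test_that("regression recovers the limiting reporters exactly", {
  x <- rnorm(50, 500, 40)
  # veridical reporter: estimate == true stop
  r0 <- fit_error_regression(manual_trials(x, x))
  expect_equal(r0$slope, 0)
  expect_equal(r0$weighting, 0)
  expect_equal(r0$residual_sd_px, 0)
  # prior-only reporter: estimate == target, so estimation error == -(performance error)
  r1 <- fit_error_regression(manual_trials(x, rep(500, 50)))
  expect_equal(r1$slope, -1)
  expect_equal(r1$weighting, 1)
})

test_that("weighting is the negated slope, exactly, and n_used honors exclusions", {
  tr <- two_condition_trials(60, seed = 5)
  tr <- apply_exclusions(tr)
  self_tr <- tr[tr$condition == "self", ]
  r <- fit_error_regression(self_tr)
  expect_identical(r$weighting, -r$slope)
  expect_equal(r$n_used, sum(!self_tr$excluded))
})

test_that("empirical weighting recovers the generative w", {
  cfg <- task_config("stop", trials_per_block = 10000)
  # w = 0.3 needs sigma_prior^2/sigma_ev^2 = 7/3
  sd_ev <- 30
  sd_prior <- sd_ev * sqrt(0.7 / 0.3)
  tr <- simulate_stop_block(cfg, default_params(sd_prior, sd_ev), seed = 23)
  r <- fit_error_regression(tr)
  expect_lt(abs(r$weighting - 0.3), 0.02)
  # and it agrees with the model-based weighting of the generative SDs
  expect_lt(abs(r$weighting - posterior_weight(sd_prior, sd_ev)), 0.02)
})

test_that("degenerate regressions are statistic errors", {
  tr <- manual_trials(rep(500, 10), rnorm(10, 500, 5))
  expect_error(fit_error_regression(tr), class = "selfpriors_stat_error")
  expect_error(fit_error_regression(manual_trials(500, 500)),
               class = "selfpriors_stat_error")
})
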