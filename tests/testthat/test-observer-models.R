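test_that("posterior weighting follows the variance ratio", {
  expect_equal(posterior_weight(1, 1), 0.5)
  expect_equal(posterior_weight(1, 2), 0.8)
  expect_lt(posterior_weight(1e8, 1), 1e-15)
  expect_error(posterior_weight(0, 1), class = "selfpriors_config_error")
  expect_error(posterior_weight(1, -1), class = "selfpriors_config_error")
  # monotone in both arguments
  expect_true(all(diff(posterior_weight(1, c(0.5, 1, 2, 4))) > 0))
  expect_true(all(diff(posterior_weight(c(0.5, 1, 2, 4), 1)) < 0))
})

test_that("predicted report collapses to the prior or the evidence in the limits", {
  p_strong <- observer_params(prior_mean_px = 500, prior_sd_px = 1e-6,
                              evidence_sd_px = 50)
  expect_equal(predict_estimate(p_strong, true_stop = 900)$mean, 500,
               tolerance = 1e-6)
  p_weak <- observer_params(prior_mean_px = 500, prior_sd_px = 1e9,
                            evidence_sd_px = 50)
  expect_equal(predict_estimate(p_weak, true_stop = 900)$mean, 900,
               tolerance = 1e-4)
})

test_that("predicted report mean equals the gridded posterior maximum", {
  # dense-grid oracle: the posterior of position x given noisy evidence at
  # its mean is Normal(prior) x Normal(likelihood); its argmax should equal
  # the reliability-weighted mean to within the grid step
  set.seed(42)
  grid_step <- 0.05
  for (i in 1:100) {
    mu_p <- runif(1, 300, 700)
    sd_p <- runif(1, 5, 80)
    sd_e <- runif(1, 5, 80)
    x_e <- runif(1, 300, 700)
    params <- observer_params(prior_mean_px = mu_p, prior_sd_px = sd_p,
                              evidence_sd_px = sd_e)
    pred <- predict_estimate(params, true_stop = x_e)
    grid <- seq(min(mu_p, x_e) - 20, max(mu_p, x_e) + 20, by = grid_step)
    post <- dnorm(grid, mu_p, sd_p, log = TRUE) +
      dnorm(x_e, grid, sd_e, log = TRUE)
    expect_lt(abs(pred$mean - grid[which.max(post)]), grid_step)
  }
})

test_that("negative log-likelihood has the right value, additivity and optimum", {
  # a single trial reported exactly at the predicted mean with sd 1:
  # density is the standard normal mode, NLL = 0.5 * log(2*pi)
  tr <- manual_trials(true_stop = 500, estimate = 500)
  params <- c("prior_sd.self" = 1e9, "evidence_sd.self" = 1)
  # with a flat prior, w ~ 0 and the predicted sd is ~ evidence sd = 1
  nll <- neg_log_likelihood(params, model_preset("exp1_full"), tr[1, ])
  expect_equal(as.numeric(nll), 0.5 * log(2 * pi), tolerance = 1e-6)

  # additivity over concatenated trial sets
  a <- two_condition_trials(40, seed = 6)
  b <- two_condition_trials(40, seed = 7)
  p4 <- c("prior_sd.self" = 30, "prior_sd.agent" = 45,
          "evidence_sd.self" = 30, "evidence_sd.agent" = 35)
  spec <- model_preset("exp1_full")
  expect_equal(as.numeric(neg_log_likelihood(p4, spec, rbind(a, b))),
               as.numeric(neg_log_likelihood(p4, spec, a)) +
                 as.numeric(neg_log_likelihood(p4, spec, b)),
               tolerance = 1e-8)

  # likelihood dominance: generative params beat a distorted prior at n = 1e4
  cfg <- task_config("stop", trials_per_block = 10000)
  tr_big <- simulate_stop_block(cfg, default_params(30, 30), seed = 8)
  good <- c("prior_sd.self" = 30, "evidence_sd.self" = 30)
  bad <- c("prior_sd.self" = 60, "evidence_sd.self" = 30)
  expect_lt(as.numeric(neg_log_likelihood(good, spec, tr_big)),
            as.numeric(neg_log_likelihood(bad, spec, tr_big)))
})

test_that("free-parameter counts reproduce the preset model sizes", {
  lv1 <- list(condition = c("agent", "self"), direction = 1L,
              feedback_level = "none")
  expect_equal(count_free_params(model_preset("exp1_full"), lv1), 4L)
  expect_equal(count_free_params(model_preset("exp1_shared_evidence"), lv1), 3L)
  expect_equal(count_free_params(model_preset("exp1_shared_prior"), lv1), 3L)
  lv2 <- list(condition = c("agent", "self"), direction = c(-1L, 1L),
              feedback_level = "none")
  expect_equal(count_free_params(model_preset("exp2_full_shift"), lv2), 10L)
  expect_equal(count_free_params(model_preset("exp2_shared_direction"), lv2), 8L)
  # single-condition data shrinks the counts accordingly
  lv_self <- list(condition = "self", direction = 1L, feedback_level = "none")
  expect_equal(count_free_params(model_preset("exp1_full"), lv_self), 2L)
  expect_error(count_free_params(model_preset("exp1_full"),
                                 list(condition = character())),
               class = "selfpriors_config_error")
})

test_that("BIC formula and domain errors", {
  expect_equal(compute_bic(0, 0, 1), 0)
  expect_equal(compute_bic(50, 4, 100), 4 * log(100) + 100)
  expect_error(compute_bic(10, 2, 0), class = "selfpriors_config_error")
})

test_that("fit_model recovers generative parameters and matches the regression", {
  cfg <- task_config("stop", trials_per_block = 2000)
  tr <- simulate_stop_block(cfg, default_params(30, 30), seed = 12)
  fit <- fit_model(tr, model_preset("exp1_full"), seed = 12)
  expect_true(fit$converged)
  w_hat <- posterior_weight(fit$params[["prior_sd.self"]],
                            fit$params[["evidence_sd.self"]])
  expect_lt(abs(w_hat - 0.5), 0.05)
  # regression slope as the independent oracle for the fitted weighting
  reg <- fit_error_regression(tr)
  expect_lt(abs(w_hat - reg$weighting), 0.03)
})

test_that("a flat generative prior never yields a spuriously narrow fit", {
  # with no generative prior influence the fitted prior SD is either pushed
  # to the boundary (flagged flat) or lands at a large finite value set by
  # sampling noise in the slope -- far above the performance scale either way
  cfg <- task_config("stop", trials_per_block = 1000)
  par <- observer_params(prior_sd_px = 1e9, evidence_sd_px = 30,
                         performance_sd_px = 40)
  fits <- lapply(1:20, function(i) {
    tr <- simulate_stop_block(cfg, par, seed = 130 + i)
    fit_model(tr, model_preset("exp1_full"), n_restarts = 2, seed = i)
  })
  prior_sds <- vapply(fits, function(f) f$params[["prior_sd.self"]], 1)
  # never narrower than twice the performance SD (that would need a 5-sigma
  # chance slope), and typically orders of magnitude wider
  expect_true(all(prior_sds > 2 * 40))
  expect_gt(median(prior_sds), 1e3)
  expect_gte(sum(vapply(fits, function(f) classify_flat(f)[["self"]],
                        logical(1))), 1)
})

test_that("degenerate zero-variance trials raise a fit error", {
  tr <- manual_trials(rep(500, 20), rep(500, 20))
  expect_error(fit_model(tr, model_preset("exp1_full")),
               class = "selfpriors_fit_error")
})

test_that("flat classification is strict at the threshold", {
  expect_false(classify_flat(1e7))
  expect_true(classify_flat(1e7 + 1))
  expect_true(classify_flat(1e9))
  # a generative flat prior leaves essentially no weight on the prior
  expect_lt(posterior_weight(1e9, 1e3), 1e-11)
})

test_that("log-SD and natural-SD parameterizations reach the same optimum", {
  tr <- two_condition_trials(150, seed = 14)
  spec <- model_preset("exp1_full")
  fit <- fit_model(tr, spec, seed = 14)
  # independent route: optimize the NLL over natural-scale SDs
  use <- tr[!tr$excluded, ]
  nll_nat <- function(p) {
    as.numeric(neg_log_likelihood(
      c("prior_sd.self" = p[1], "prior_sd.agent" = p[2],
        "evidence_sd.self" = p[3], "evidence_sd.agent" = p[4]), spec, use))
  }
  opt <- optim(c(30, 30, 30, 30), nll_nat, method = "L-BFGS-B",
               lower = rep(0.5, 4), upper = rep(1e4, 4),
               control = list(maxit = 1000, factr = 10))
  expect_lt(abs(opt$value - fit$neg_log_lik), 1e-4)
})

test_that("adding freedom never worsens the in-sample likelihood", {
  tr <- two_condition_trials(120, seed = 15)
  full <- fit_model(tr, model_preset("exp1_full"), seed = 15)
  for (m in c("exp1_shared_evidence", "exp1_shared_prior")) {
    reduced <- fit_model(tr, model_preset(m), seed = 15)
    expect_lte(full$neg_log_lik, reduced$neg_log_lik + 1e-4)
  }
})

test_that("direction-coupled evidence shifts are recovered with the right sign", {
  cfg <- task_config("stop", trials_per_block = 1000)
  par <- observer_params(prior_sd_px = 30, evidence_sd_px = 30,
                         performance_sd_px = 40, evidence_shift_px = 15)
  spec <- model_preset("exp2_full_shift")
  hits <- 0L
  n_sim <- 100L
  for (i in seq_len(n_sim)) {
    tr <- simulate_stop_block(cfg, par, seed = 1000 + i, directions = "random")
    fit <- fit_model(tr, spec, n_restarts = 2, seed = i)
    if (fit$params[["evidence_shift.self"]] > 0) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("model comparison reports winners, margins and the strong-evidence rule", {
  mk <- function(bic) structure(list(bic = bic), class = "fit_result")
  fits <- list(
    p1 = list(a = mk(100), b = mk(100)),
    p2 = list(a = mk(100), b = mk(100))
  )
  cmp <- compare_models(fits)
  expect_equal(cmp$pairs[["a vs b"]]$mean_bic_diff, 0)
  expect_equal(cmp$pairs[["a vs b"]]$verdict, "indistinguishable")

  fits59 <- list(p1 = list(a = mk(105.9), b = mk(100)))
  expect_false(compare_models(fits59)$pairs[["a vs b"]]$strong_evidence)
  fits60 <- list(p1 = list(a = mk(106), b = mk(100)))
  cmp60 <- compare_models(fits60)
  expect_true(cmp60$pairs[["a vs b"]]$strong_evidence)
  expect_equal(cmp60$pairs[["a vs b"]]$favors, "b")

  ragged <- list(p1 = list(a = mk(1), b = mk(2)), p2 = list(a = mk(1)))
  expect_error(compare_models(ragged), class = "selfpriors_input_error")
})

test_that("parsimony: the generating tied model wins on average BIC", {
  # data generated under shared evidence SDs should prefer the 3-parameter
  # model over the 4-parameter full model on average
  n_rep <- 40L
  d <- vapply(seq_len(n_rep), function(i) {
    tr <- two_condition_trials(100, seed = 3000 + i, self_ev = 30,
                               agent_ev = 30)
    shared <- fit_model(tr, model_preset("exp1_shared_evidence"),
                        n_restarts = 2, seed = i)
    full <- fit_model(tr, model_preset("exp1_full"), n_restarts = 2, seed = i)
    shared$bic - full$bic
  }, numeric(1))
  expect_lt(mean(d), 0)
})

test_that("bootstrap intervals cover the point estimate and respect the seed", {
  tr <- simulate_stop_block(task_config("stop", trials_per_block = 120),
                            default_params(30, 30), seed = 19)
  b1 <- bootstrap_cis(tr, model_preset("exp1_full"), B = 50, seed = 77,
                      n_restarts = 1)
  b2 <- bootstrap_cis(tr, model_preset("exp1_full"), B = 50, seed = 77,
                      n_restarts = 1)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci$lower <= b1$ci$estimate + 1e-8))
  expect_true(all(b1$ci$upper >= b1$ci$estimate - 1e-8))
  expect_equal(b1$n_failed, 0L)
})
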