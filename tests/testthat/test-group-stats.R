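test_that("t contrasts match the hand formula and degenerate cases", {
  expect_equal(t_test_one(c(1, 2, 3), mu = 2)$t, 0)
  same <- c(1.2, 3.4, 5.6, 7.8)
  paired <- t_test_one(same, y = same)
  expect_equal(paired$t, 0)
  expect_equal(paired$p, 1)
  r <- t_test_one(c(2, 4, 6), mu = 0)
  expect_equal(r$t, mean(c(2, 4, 6)) / (sd(c(2, 4, 6)) / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_error(t_test_one(c(3, 3, 3), mu = 0),
               class = "selfpriors_stat_error")
})

test_that("correlations distinguish linear and monotone association", {
  x <- 1:20
  expect_equal(correlations(x, 2 * x + 1)$r, 1)
  r_exp <- correlations(x, exp(x / 3))
  expect_lt(r_exp$r, 1)
  expect_equal(correlations(x, exp(x / 3), method = "spearman")$r, 1)
  expect_error(correlations(x, rep(1, 20)), class = "selfpriors_stat_error")
})

test_that("self priors scale with performance in a synthetic cohort", {
  g <- make_cohort(cohort_spec(n_participants = 200, seed = 21))$participants
  expect_gt(correlations(g$self_prior_sd_px, g$performance_sd_px)$r, 0)
})

test_that("partial correlation matches the closed form and flags collinearity", {
  set.seed(31)
  x <- rnorm(50); z <- rnorm(50); y <- 0.5 * x + 0.3 * z + rnorm(50)
  got <- partial_correlation(x, y, z)$r
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_zy <- cor(z, y)
  expected <- (r_xy - r_xz * r_zy) / sqrt((1 - r_xz^2) * (1 - r_zy^2))
  expect_equal(got, expected, tolerance = 1e-10)
  # covariate independent of both: partial ~ plain
  big_x <- rnorm(4000); big_y <- 0.6 * big_x + rnorm(4000)
  big_z <- rnorm(4000)
  expect_lt(abs(partial_correlation(big_x, big_y, big_z)$r -
                  cor(big_x, big_y)), 0.03)
  expect_error(partial_correlation(z, y, z), class = "selfpriors_stat_error")
})

test_that("repeated-measures ANOVA matches the reference implementation", {
  skip_if_not_installed("car")
  set.seed(41)
  mat <- matrix(rnorm(30, mean = rep(c(0, 0.5, 1), each = 10)), 10, 3)
  got <- rm_anova_gg(mat)
  # reference route: multivariate lm + car's repeated-measures machinery
  idata <- data.frame(level = factor(paste0("l", 1:3)))
  mlm <- lm(mat ~ 1)
  ref <- suppressWarnings(summary(car::Anova(mlm, idata = idata,
                                             idesign = ~level, type = 3),
                                  multivariate = FALSE))
  ref_tab <- ref$univariate.tests
  ref_F <- ref_tab["level", "F value"]
  ref_eps <- ref$pval.adjustments["level", "GG eps"]
  ref_pgg <- ref$pval.adjustments["level", "Pr(>F[GG])"]
  expect_equal(got$F, unname(ref_F), tolerance = 1e-8)
  expect_equal(got$epsilon, unname(ref_eps), tolerance = 1e-8)
  expect_equal(got$p_gg, unname(ref_pgg), tolerance = 1e-8)
})

test_that("ANOVA edge cases: two levels and constant scores", {
  set.seed(43)
  m2 <- matrix(rnorm(20), 10, 2)
  expect_equal(rm_anova_gg(m2)$epsilon, 1)
  flat <- matrix(rep(rnorm(8), 2), 8, 2)
  expect_equal(rm_anova_gg(flat)$F, 0)
  m_bad <- m2; m_bad[1, 1] <- NA
  expect_error(rm_anova_gg(m_bad), class = "selfpriors_input_error")
})

test_that("bonferroni caps at one and never shrinks a p-value", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1)
  p <- runif(10)
  expect_true(all(bonferroni(p, m = 12) >= p))
  expect_error(bonferroni(1.2), class = "selfpriors_config_error")
})

test_that("prior accuracy contrast separates exaggerated from matched priors", {
  g0 <- data.frame(
    participant_id = sprintf("p%02d", 1:10),
    performance_sd_px = seq(30, 48, by = 2),
    self_prior_sd_px = seq(30, 48, by = 2),
    agent_prior_sd_px = seq(30, 48, by = 2),
    agent_prior_flat = FALSE
  )
  r0 <- prior_accuracy_contrast(g0)
  expect_equal(r0$self_vs_performance$t, 0)
  expect_equal(r0$deviations$agent_dev, rep(0, 10))

  g <- make_cohort(cohort_spec(n_participants = 40,
                               self_exaggeration_dist = c(mean = 0.5, sd = 0.1),
                               seed = 47))$participants
  r <- prior_accuracy_contrast(g)
  keep <- !g$agent_prior_flat
  expect_gt(mean(r$deviations$self_dev[keep]),
            mean(r$deviations$agent_dev[keep]))
  expect_lt(r$self_vs_performance$t, 0)
})

test_that("median split builds equal groups and detects nothing under the null", {
  g <- data.frame(
    participant_id = sprintf("p%02d", 1:20),
    self_prior_sd_px = rnorm(20, 30, 8),
    learning_score = rep(-2, 20)
  )
  r <- median_split_learning(g)
  expect_equal(r$n_low, 10)
  expect_equal(r$n_high, 10)
  expect_equal(r$group_test$t, 0)
})

test_that("median-split group difference is well calibrated when learning is independent of prior width", {
  set.seed(53)
  p_vals <- replicate(200, {
    g <- data.frame(
      participant_id = sprintf("p%02d", 1:20),
      self_prior_sd_px = rnorm(20, 30, 8),
      learning_score = rnorm(20, -2, 1)
    )
    median_split_learning(g)$group_test$p
  })
  expect_lt(abs(mean(p_vals < 0.05) - 0.05), 0.05)
  # p-values roughly uniform: mean near 0.5
  expect_lt(abs(mean(p_vals) - 0.5), 0.1)
})
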