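#!/usr/bin/env Rscript
# Step 4: the group-level inferential battery over the full pipeline run:
# prior-vs-performance contrasts, correlations (incl. the trait-optimism
# partial correlation), feedback-phase repeated-measures ANOVAs, and the
# median-split learning analysis. Uses run_experiment() so every statistic
# is computed from a single coherent pipeline pass.

library(selfpriors)

seed <- 20140627L
report <- run_experiment(run_config("exp1", seed = seed,
                                    output_dir = "results/exp1/run"))
s <- report$statistics

cat("== priors vs performance ==\n")
pa <- s$prior_accuracy
cat(sprintf("self prior - performance SD: t(%d) = %.2f, p = %.2g (negative = optimistic)\n",
            pa$self_vs_performance$df, pa$self_vs_performance$t,
            pa$self_vs_performance$p))
if (!is.null(pa$self_vs_agent_deviation)) {
  cat(sprintf("|dev| self vs agent (flat excluded, n excl = %d): t(%d) = %.2f, p = %.2g\n",
              pa$n_flat_excluded, pa$self_vs_agent_deviation$df,
              pa$self_vs_agent_deviation$t, pa$self_vs_agent_deviation$p))
}
if (!is.null(s$agent_prior_vs_performance)) {
  cat(sprintf("agent prior vs performance (flat excluded): t(%d) = %.2f, p = %.2g\n",
              s$agent_prior_vs_performance$df, s$agent_prior_vs_performance$t,
              s$agent_prior_vs_performance$p))
}

cat("\n== correlation structure ==\n")
cat(sprintf("self prior ~ performance: r = %.3f, p = %.2g\n",
            s$corr_self_prior_vs_performance$r,
            s$corr_self_prior_vs_performance$p))
cat(sprintf("self ~ agent prior (Spearman, flat included): rho = %.3f, p = %.2g\n",
            s$corr_self_vs_agent_prior_spearman$r,
            s$corr_self_vs_agent_prior_spearman$p))
cat(sprintf("self ~ agent prior | performance (partial Spearman): rho = %.3f, p = %.2g\n",
            s$partial_self_vs_agent_prior$r, s$partial_self_vs_agent_prior$p))
cat(sprintf("self prior ~ optimism | performance: r = %.3f, p = %.2g\n",
            s$partial_optimism$r, s$partial_optimism$p))

cat("\n== feedback phases (repeated-measures ANOVA, GG-corrected) ==\n")
for (nm in c("feedback_anova_performance", "feedback_anova_evidence",
             "feedback_anova_prior")) {
  a <- s[[nm]]
  cat(sprintf("%-28s F(%.2f, %.2f) = %.2f, eps = %.2f, p_gg = %.3g\n",
              sub("feedback_anova_", "", nm), a$df1_gg, a$df2_gg, a$F,
              a$epsilon, a$p_gg))
}

cat("\n== learning and prior width ==\n")
ms <- s$median_split_learning
cat(sprintf("median split (n = %d vs %d): t(%d) = %.2f, p = %.2g\n",
            ms$n_low, ms$n_high, ms$group_test$df, ms$group_test$t,
            ms$group_test$p))

cat("\n== qualitative pattern checklist ==\n")
print(report)
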