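#!/usr/bin/env Rscript
# Step 2: apply the timing-based trial exclusions and fit the
# estimation-error-vs-performance-error regression per participant and
# condition on the baseline (pre-feedback) blocks. The negated slope is the
# empirical prior weighting.

library(selfpriors)

trials <- read_trials("results/exp1/trials.csv")
trials <- apply_exclusions(trials)
write_trials(trials, "results/exp1/trials_flagged.csv")

cat(sprintf("excluded %d of %d trials (%.1f per participant)\n",
            sum(trials$excluded), nrow(trials),
            sum(trials$excluded) / length(unique(trials$participant_id))))
print(table(trials$excluded_reason[trials$excluded]))

before <- trials[trials$phase == "before", ]
reg <- regress_by_cell(before)
utils::write.csv(reg, "results/exp1/regressions.csv", row.names = FALSE)

self_slope <- reg$slope[reg$condition == "self"]
agent_slope <- reg$slope[reg$condition == "agent"]
t_self <- t_test_one(self_slope)
t_agent <- t_test_one(agent_slope)
t_diff <- t_test_one(self_slope, y = agent_slope)
cat(sprintf("self slopes:  mean %.3f, t(%d) = %.2f, p = %.2g\n",
            t_self$mean, t_self$df, t_self$t, t_self$p))
cat(sprintf("agent slopes: mean %.3f, t(%d) = %.2f, p = %.2g\n",
            t_agent$mean, t_agent$df, t_agent$t, t_agent$p))
cat(sprintf("self vs agent: t(%d) = %.2f, p = %.2g\n",
            t_diff$df, t_diff$t, t_diff$p))
cat("reports are biased toward the target in both conditions,",
    "more strongly for one's own actions\n")
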