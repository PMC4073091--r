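#!/usr/bin/env Rscript
# Step 1: draw the synthetic cohort and simulate the full stop-task session
# (self + agent-replay conditions, before/during/after feedback phases).
# Writes the trial and participant tables under results/exp1/.

library(selfpriors)

seed <- 20140627L
out_dir <- "results/exp1"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(n_participants = 20, seed = seed)
cohort <- make_cohort(spec)
cfg <- task_config("stop", seed = seed)
session <- simulate_session(cohort, cfg, root_seed = seed)

write_trials(session$trials, file.path(out_dir, "trials.csv"))
write_participants(cohort$participants, file.path(out_dir, "participants.csv"))
write_cohort_spec(spec, file.path(out_dir, "cohort_spec.json"))
utils::write.csv(session$generative, file.path(out_dir, "generative_sds.csv"),
                 row.names = FALSE)

g <- cohort$participants
cat(sprintf("cohort: %d participants, %d with flat agent priors\n",
            nrow(g), sum(g$agent_prior_flat)))
cat(sprintf("performance SD: %.1f px (mean), self prior SD: %.1f px (mean)\n",
            mean(g$performance_sd_px), mean(g$self_prior_sd_px)))
cat(sprintf("mean exaggeration ratio (self prior / performance): %.2f\n",
            mean(g$exaggeration)))
cat(sprintf("trials simulated: %d (%d per participant)\n",
            nrow(session$trials), nrow(session$trials) / nrow(g)))
cat("ball advances", round(per_refresh_displacement(cfg), 1),
    "px per refresh at", cfg$sweep_speed_px_s, "px/s,", cfg$refresh_hz, "Hz\n")
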