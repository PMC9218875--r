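#!/usr/bin/env Rscript
# Ideal-observer vs Q-learning comparison: reward rates and the
# block-reversal RPE signature (inference shrinks the trial-2 post-switch
# RPE) on the deterministic 100/0 and the probabilistic 70/10 hazard
# tasks. Writes results/observer_q_comparison.csv.

library(creditseq)

dir.create("results", showWarnings = FALSE)
set.seed(6)

rows <- lapply(c("bromberg", "ours"), function(task) {
  cfg <- observer_config(task, hazard = 0.05)
  comp <- reversal_rpe_comparison(cfg, n_trials = 20000)
  cbind(task = task, comp)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/observer_q_comparison.csv", row.names = FALSE)
print(tab, row.names = FALSE)

b <- tab[tab$task == "bromberg", ]
cat(sprintf(
  "\n100/0 task: rewarded post-switch trial-2 RPE %.3f (observer) vs %.3f (Q-learner)\n",
  b$trial2_switch_rpe[b$agent == "observer"],
  b$trial2_switch_rpe[b$agent == "q"]))
cat("The observer infers the reversal from a single omission, so by the\n",
    "second trial of a block the new contingency is already expected and\n",
    "its RPE collapses; the incremental Q-learner still carries the old\n",
    "low value and reports a large positive surprise.\n")
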