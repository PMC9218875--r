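# creditseq

Simulation and analysis toolkit for studying how **choice-selective
sequential activity** in cortical inputs to the nucleus accumbens can
support trial-by-trial reinforcement learning in a probabilistic reversal
task.

A mouse presses one of two levers; one pays with probability 0.7, the
other 0.1, and the assignment reverses after ten rewarded trials plus a
geometric number of extra trials. The decision is made seconds before the
outcome, so the circuit must solve *temporal credit assignment*. Cortical
neurons projecting to the ventral striatum fire in choice-selective
sequences that bridge that gap. This package implements, on synthetic
sequences, the two circuit-level models of how such sequences support
learning, plus the statistics used around them:

* **Task engine** — the 70/10 reversal task in three variants
  (reward-counted, geometric, per-trial hazard), stay probabilities,
  reversal-aligned choice curves.
* **Synthetic data** — single-trial choice-selective population sequences
  (cortical-like `pl_like`, thalamic-like `mth_like`, onset-only
  `early_only` presets), optogenetic-like stimulation, and event-locked
  fluorescence generated from known ground-truth kernels.
* **Synaptic-plasticity TD circuit** — value as a weighted sum of sequence
  basis functions, dopamine RPE via a delayed inhibitory pathway
  (`delta(t) = r(t) + (gamma V(t) - V(t - Delta)) / Delta`,
  `gamma = exp(-Delta/tau)`), eligibility-trace weight updates
  (`dw/dt = alpha delta E`, non-negative weights), and probabilistic
  action readout from sequence-onset neurons.
* **Actor-critic neural dynamics model** — critic and actor LSTMs trained
  with advantage actor-critic and frozen for testing, so reversal
  learning runs on network dynamics alone; actor-geometry analyses
  (PCA, readout alignment, choice x RPE history regression).
* **Encoding model** — 25-df cubic B-spline event kernels (81 samples per
  window), lasso or OLS fits, nested F-tests against circular-shift
  permutation nulls, choice/outcome selectivity classification.
* **Decoders** — sequence-type-weighted logistic decoding of choice and
  outcome, piecewise trial time-warping, binned time-course decoding.
* **History regressions** — rewarded/unrewarded choice-history logistic
  models with stimulation interactions; dopamine outcome-history
  regression.
* **Ideal observer vs Q-learning** — exact Bayesian block-state inference
  vs incremental value updates, and their diverging RPE signatures at
  block reversals.

## Worked example

```r
library(creditseq)
set.seed(1)

run <- run_plasticity_session(make_profile_preset("pl_like"),
                              n_trials = 5000)
run
#> <cs_plasticity_run> 5000 trials, reward rate 48.0%, mean block 24.4 trials

stay_probability(run$session)
#>   prev_outcome      stay    n
#> 1            0 0.8316032 2601
#> 2            1 1.0000000 2398

round(dopamine_history_regression(run$stats$rpe_fb,
                                  run$session$outcome)$beta, 3)
#>   lag0   lag1   lag2   lag3   lag4   lag5
#>  0.394 -0.108 -0.071 -0.044 -0.038 -0.030
```

The circuit earns ~47–50% reward (chance is 40%, an omniscient oracle
67–70%) in ~23-trial blocks, repeats rewarded choices far more often than
unrewarded ones, and its simulated dopamine signal depends positively on
the current outcome and negatively on recent past outcomes — the
trial-history signature of a reward prediction error.

The numbered scripts under `analysis/` run the full set of analyses
(task baselines, the three plasticity-model input variants, desk-scale
actor-critic training and geometry, encoding/decoding validation, and the
observer-vs-Q comparison) and write their tables under `results/`.

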