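---
title: "Choice-selective sequences and reinforcement learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choice-selective sequences and reinforcement learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(creditseq)
```

# The scientific problem

In a probabilistic reversal task, a mouse pokes a central port, presses a
left or right lever, and around a second later hears a tone announcing
reward or omission. One lever pays with probability 0.7 and the other with
0.1, and the assignment reverses without warning after ten rewarded trials
plus a geometric number of extra trials. Solving this task requires
*temporal credit assignment*: the decision is made near the nose poke,
seconds before the outcome arrives, and its consequences must steer choices
for several subsequent trials.

Prelimbic-cortex neurons projecting to the nucleus accumbens (the
cortical-like population here) fire in choice-selective *sequences*:
neurons preferring one lever activate in a reliable temporal order that
tiles the seconds between the decision and well past the outcome. This
package implements, on synthetic data, the two circuit models that explain
how such sequences support reinforcement learning — a synaptic-plasticity
temporal-difference (TD) circuit and an actor-critic recurrent-network
model — together with the statistical machinery used around them: a
spline-basis event-kernel encoding model with circular-shift permutation
tests, sequence-type-weighted population decoders with piecewise trial
time-warping, choice- and dopamine-history regressions, and Bayesian
ideal-observer versus Q-learning comparisons.

# The task engine

`task_config()` / `run_session()` simulate the task under three reversal
rules: the behavioral `reward_counted` rule (10 rewards plus a geometric
extension with success probability 0.4, support starting at one trial — a
reversal can never coincide with the tenth reward), a pure `geometric_only`
rule, and a `per_trial_hazard` rule (i.i.d. 5% flips) used by the
ideal-observer analyses. Useful closed forms: a side-blind policy earns
`(0.7 + 0.1) / 2 = 40%`, and an oracle playing the block lever produces
blocks of `10 / 0.7 + 1 / 0.4 = 16.8` trials. Imperfect agents stretch the
blocks — reversals wait for the tenth reward — which is why the published
operating point pairs a ~47% reward rate with ~23-trial blocks.

Within-trial event times use the task's jitters: nose poke at
N(−2.5, 0.2²) s relative to the press, a 0.1–1 s levers-out delay on a
0.1 s grid, a uniform 0–1 s press-to-tone delay. Abandoned trials are
representable (`choice = "none"`) but only the dynamics model's
"do nothing" action produces them.

# The synthetic sequence generator

`sequence_profile()` parameterizes `2 * n_per_side` model neurons whose
Gaussian rate bumps (sd 0.3 s) tile −2..+3 s around the press; per trial,
the chosen side's neurons emit their bumps with peak-time jitter and
truncated-normal multiplicative amplitude noise, the unchosen side emits
the same pattern scaled by `selectivity`, and everything is smoothed with a
0.2 s Gaussian. Smoothing is applied analytically (a Gaussian bump
convolved with a Gaussian kernel is again Gaussian); a discrete-convolution
reference implementation backs this in the tests. The time grid puts t = 0
at the lever press with left-edge-labeled, half-open bins.

Three presets emulate the recorded input classes:

* `pl_like` — the full span, low jitter (0.05 s), strong selectivity
  (unchosen side at 10%), amplitude noise 0.2: split-half peak-time
  consistency exceeds the recorded-data benchmark of R² = 0.80.
* `mth_like` — same span, jitter 0.6 s, amplitude noise 0.6, selectivity
  0.5: the inconsistent, weakly selective thalamic-like input.
* `early_only` — all peaks compressed into 0.5 s at the sequence onset
  (−2.5 to −2.0 s): only decision-time neurons are active.

**The amplitude scale.** The recorded inputs were z-scored inferred spike
rates, whose transients peak well above 1, and the scale matters: the TD
circuit's per-trial learning speed grows with the square of the input
amplitude. With unit-peak bumps the circuit reverses in ~12 trials and
cannot reach the published operating point; `peak_amplitude` (default 1.4)
was therefore calibrated once — against the target operating point of
~47% reward and ~23-trial blocks under the full study conditions — and is
fixed in the presets. It is not adjusted per analysis.

What the generator does *not* emulate: calcium-indicator kinetics, photon
noise, source cross-talk, non-Gaussian rate profiles, or correlated noise
across neurons. Passing tests therefore validate the models and statistics
on idealized sequences, not the full measurement chain of the recordings.

# The synaptic-plasticity TD circuit

The model (`run_plasticity_session()`) learns, at every moment, an
estimate V(t) of discounted future reward as a weighted sum of the input
basis functions: V_L and V_R are the weighted sums over left- and
right-preferring neurons and V = V_L + V_R. Dopamine neurons compute the
reward prediction error through a fast discounted value pathway and a
delayed (Δ = 0.01 s) sign-inverted copy via inhibitory interneurons:

    delta(t) = r(t) + (gamma V(t) - V(t - Delta)) / Delta,
    gamma = exp(-Delta / tau),  tau = 0.7 s.

Each synapse carries an eligibility trace E (decay 0.8 s) of its recent
presynaptic activity, and weights update as dw/dt = alpha delta E with
alpha = 0.009 and a non-negativity constraint (Dale's principle). Updates
run from the nose poke (t_start ~ N(−2.5, 0.2²)) to +3 s after the press
at dt = 0.01 s; the eligibility trace resets at each trial start and the
weights carry across trials. Reward arrives as a truncated Gaussian
(sd 0.3 s, peak uniform 0.2–1.2 s post press, zero earlier than 0.2 s
before its peak); note the truncation removes a fixed 25% of the Gaussian
mass, so a fully surprising reward integrates to ~0.75, not 1.

Choice is read out *before* the sequence starts: a 50 ms probe of
non-negative truncated-normal noise (mean 0.05, sd 0.0025/dt taken
literally as printed, i.e. 0.25) drives the earliest ~18.5% of neurons per
side; the probe-averaged weighted sums d_left/d_right feed a softmax with
gain 7000 plus a 0.15 stay bonus. The probe reads the weights from the end
of the previous trial, so stimulation of the input during a trial cannot
affect that trial's own choice.

Numerical choices worth knowing:

* The inner integration loop is compiled; Gaussian bumps are evaluated by
  an exact two-term recurrence on the uniform grid, and a pure-R reference
  integrator reproduces the compiled path to 1e−9 in the tests.
* The delayed value V(t − Δ) is taken from the current trial's stored
  trace and is zero before the trial start, consistent with the
  eligibility reset.
* The weight accumulator is floored at zero after each step (exposed as
  `floor_each_step`). With an unfloored accumulator the onset-only control
  collapses: the negative RPE at the value-bump offset drives onset
  weights monotonically negative, the probe reads zero, and the control
  performs at chance instead of the published above-chance rate produced
  by single-trial eligibility-trace learning. The flooring restores that
  mechanism; the `update_weights()` primitive still exposes accumulator
  semantics.
* Stimulation trials clamp a random 70% of neurons (both sides pooled) to
  rate 0.2 from the nose poke to the end of the update window. Ending the
  clamp inside the window would collapse the value signal in a single
  10 ms step and produce an RPE transient that is an artifact of the hard
  offset; the published stimulation outlasts the window on average (it
  runs to ~2 s after reward consumption begins).

With the three presets and the published parameters the model reproduces
the reported behavior: the cortical-like input sustains ~47–49% reward and
~23–25-trial blocks; the thalamic-like input tracks reversals more slowly
and earns near chance; the onset-only control (alpha = 0.003, softmax gain
1000) reaches ~43% with clearly slower reversals. A known divergence: in
this implementation the asymptotic side preference is sharper, and the
baseline stay probability after omissions correspondingly higher, than in
the published model at the same average reward rate. One consequence is
that input stimulation on unrewarded trials — which pushes preferences
toward the softmax indifference point — *lowers* next-trial stay here
instead of raising it; the rewarded-trial reduction and the absence of any
current-trial effect do reproduce.

# The actor-critic neural dynamics model

The alternative model replaces fast plasticity with recurrent dynamics:
during testing all weights are frozen and reversal learning happens only
through network activity. A critic LSTM reads the choice-selective
sequence input (restricted to −2..+2 s, at 0.1 s steps) plus the reward
signal and emits value V(t); the dopamine RPE
`delta = r + gamma V(t) - V(t - dt)` (gamma = exp(−0.1/2.5) ≈ 0.96) feeds
an actor LSTM together with an efference copy of the previous action and a
one-hot temporal context, and the actor emits a 3-way policy (left, right,
do nothing). Each 4 s trial spans 42 steps: a decision-registration step,
40 sequence steps, and an end-of-trial step whose return discount is zero
(reconciling the printed 630-step episodes with 15 four-second trials).
Acting at the wrong time costs −1. The per-step reward is the truncated
Gaussian kernel amplitude itself, so a rewarded trial delivers pulses of
order one against the unit penalty.

Training uses advantage actor-critic: the critic descends
`0.5 beta_v (R_t - V_t)^2` against the k-step bootstrapped return (the
printed form, which discounts the immediate reward by the current step's
factor; a conventional form is available via `return_form`), and the actor
descends `-log pi(a_t) A_t - beta_e H_t` with beta_v = beta_e = 0.05,
RMSprop at 0.001 per step, and backpropagation through the full episode.
Both gradients are verified against finite differences in the tests. The
advantage and the RPE input to the actor are treated as constants with
respect to the actor's parameters (standard A2C semantics).

Design decisions that required judgment:

* The gate nonlinearity is the logistic sigmoid; the source text's
  "softmax" for the gates is read as its one-dimensional case.
* Training blocks reverse with a 10% per-trial hazard (mean 10-trial
  blocks). The printed geometric parameter, read literally in the Eq-1
  parameterization, would give mean 1.1-trial blocks, under which reward
  history carries no usable information and a trained agent provably sits
  at chance (we verified this); the hazard reading matches the stated
  purpose of making reversals unpredictable on the mice's ~4-trial memory
  timescale.
* Forget-gate biases initialize to 1 (the standard unit forget bias used
  by the framework the source model was built in); all other biases start
  at 0, input weights orthogonal, recurrent weights Glorot-uniform. With
  all-zero biases, memory decays 1000-fold between outcome and the next
  decision and the gradient that would teach the network to remember
  vanishes.
* Desk scale: the package defaults train 8 units with 8 input neurons
  per side for 10,000 episodes at a 0.002 optimizer step, instead of 128
  units, 153 per side, 62,000 episodes at 0.001. The choice was driven by
  when the policy's coupling to its stored reward history emerges: the
  actor state comes to encode the previous outcome, choice and block
  state long before the policy readout learns to use them,
  and the desk scale was chosen so that this coupling emerges
  within the training budget; larger desk networks required substantially
  longer training. The objective hyperparameters (loss scalings, entropy
  bonus, discounts, penalty, grammar) are unchanged at desk scale.

* A known desk-scale limitation: the large-scale finding that a critic
  fed *persistent* choice-selective input fails to train within the same
  number of episodes does not reproduce here — with a small network the
  constant choice trace is an easier credit-assignment target than the
  sparse transient sequence, and the ordering reverses at the matched
  desk budget. The frozen-weight block tracking, the above-chance test
  performance, and the actor-geometry signatures (readout aligned with
  PC1; PC1 history regression dominated by choice × RPE terms decaying
  over ~3 trials) do reproduce.

Actor-geometry analyses (`actor_geometry_analysis()`) run the frozen agent
on fixed 30-trial blocks, extract the actor state at the decision step,
and summarize: principal-component variance shares, the cosine between the
left-minus-right policy readout axis and each component, and a linear
regression of the PC1 score on the previous seven trials' choice, RPE
(0–2 s post-press average) and their product — the choice × RPE
accumulation signature.

# Encoding model

`build_spline_basis()` evaluates 25 cubic B-splines (equally spaced
interior knots, partition-of-unity normalization; knot placement is not
dictated by the source and is fixed here) on 81-sample windows: −2..6 s
for action events, 0..8 s for stimulus events, at 10 Hz.
`build_design_matrix()` convolves binary event trains with the basis —
kernel sample 1 aligned to the window start — and `fit_kernel_model()`
fits lasso (penalty chosen by 5-fold cross-validated MSE, via glmnet) or
ordinary least squares. Response kernels are the spline reconstructions
per event.

Significance uses a nested-model comparison: an F statistic between the
full OLS model and a reduced model lacking the target event's predictors,
calibrated against 500 circular shifts of the trace (shifts smaller than
one kernel length excluded, to avoid near-identity nulls), Bonferroni
corrected over the events tested. Choice and outcome selectivity use the
event set with choice- and outcome-blind regressors (`all_press`,
`all_cs`) so that dropping `ipsi_press`, or `cs_plus` +
`reward_consumption` jointly, isolates the information of interest. The
simulated press-only control reproduces the key artifact: event-locked
averages of press-only neurons show spurious structure at correlated
events, while fitted kernels do not.

# Decoders

`decode_labels()` implements the weighted logistic decoder: each trial is
typed by its previous-current-future label triplet and weighted by the
inverse type frequency, removing the autocorrelation leak by which a
decoder can read neighboring trials' labels; accuracy is the unweighted
fraction of correctly classified held-out trials over 5 folds and random
ensembles of 1–10 neurons. Fits use an explicit IRLS with a minimal ridge
(1e−6) so separation cannot break them.

`time_warp_trials()` reconstructs the piecewise-linear trial
normalization: the 2 s before the nose poke and 3 s after the next trial's
nose poke pass through unwarped; the nose-poke-to-press and
press-to-next-nose-poke epochs rescale linearly to their across-trial
medians, with the adjusted clock continuous at the anchors. (The printed
formula for this map is typographically garbled in the source; this
continuity-anchored reconstruction is the documented choice.)
`timecourse_decoding()` then decodes labels at trial lags −2..+1 from
500 ms bins of the warped traces.

# History regressions

`choice_history_regression()` fits the signed rewarded-choice /
unrewarded-choice logistic model (lags count completed trials; abandoned
trials are removed before lagging), `stim_choice_regression()` adds
stimulation main effects and interactions and reports the combined
stimulated traces, and `dopamine_history_regression()` regresses the
0.2–1.2 s post-feedback RPE average on the current and previous five
outcomes. Standard errors come from the observed information matrix;
single-session estimates are the unit and any across-subject averaging is
left to the caller.

# Ideal observer and Q-learning

The observer knows the transition matrix (0.95/0.05 hazard) and the reward
matrix (100/0 or 70/10) and updates its block-state posterior by exact
Bayes; action selection is greedy on the one-step-ahead expected reward
(the belief is propagated through the transition matrix before being
scored). The Q-learner updates only the chosen action's value
(alpha = 0.612) and acts through a softmax (gain 0.99, stay bias 0.95) —
the parameter values previously fitted to mouse behavior. Per-trial RPE is
the outcome minus the chosen action's expectation. The reversal signature:
on second trials of a block whose choice switched, the observer — having
inferred the reversal from a single omission — shows a collapsed RPE
(~0.05 on the 100/0 task) while the Q-learner still reports a large
surprise (~0.94).

# Problem sizes and reproducibility

All simulations are seeded and bit-reproducible (every random draw,
including inside compiled code, goes through R's RNG). The analysis
scripts and the test suite use desk-scale problem sizes chosen as the
package's defaults: 5000-trial plasticity sessions (a few seeds), 8-unit
/ 10,000-episode dynamics training, hundreds of trials for the encoding
and decoding fixtures. Paper-scale runs (62,000 episodes, 128 units, 184
neurons per side) are configuration changes, not code changes.
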