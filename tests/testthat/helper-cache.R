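# Shared expensive fixtures for the acceptance tests: plasticity-model
# sessions at the study conditions and a trained scaled-down dynamics
# agent. Computed once per test run and reused across test blocks.

.cs_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .cs_cache)) assign(key, builder(),
                                              envir = .cs_cache)
  get(key, envir = .cs_cache)
}

# five seeded 5000-trial sessions per input variant at the published
# circuit parameters
get_plasticity_runs <- function() {
  cache_get("plasticity_runs", function() {
    run_one <- function(profile, params, seed) {
      set.seed(seed)
      run <- run_plasticity_session(profile, params = params,
                                    n_trials = 5000L)
      list(rate = 100 * mean(run$session$outcome),
           block = mean_block_length(run$session),
           session = run$session, stats = run$stats)
    }
    list(
      pl = lapply(1:5, function(s)
        run_one(make_profile_preset("pl_like"), plasticity_params(), s)),
      eo = lapply(11:15, function(s)
        run_one(make_profile_preset("early_only"),
                plasticity_params(alpha = 0.003, beta_value = 1000), s)))
  })
}

# scaled-down actor-critic agent trained once at the desk-scale defaults
get_dynamics_agent <- function() {
  cache_get("dynamics_agent", function() {
    train_dynamics_model(dynamics_config(), seed = 1)
  })
}

# matched-budget sequence vs persistent training runs (desk scale)
get_input_comparison <- function() {
  cache_get("input_comparison", function() {
    lapply(1:5, function(sd) {
      seq_ag <- if (sd == 1) get_dynamics_agent() else
        train_dynamics_model(dynamics_config(), seed = sd)
      per_ag <- train_dynamics_model(dynamics_config(input = "persistent"),
                                     seed = sd)
      list(seq = seq_ag$learning_curve, per = per_ag$learning_curve)
    })
  })
}
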