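# Shared fixtures: small, fast parameterisations of the generative model.

# deterministic-limit parameters: no noise anywhere (overridable)
deterministic_params <- function(...) {
  args <- list(
    effector_noise_sd = 0, stop_sd = 0, restart_delay_sd = 0,
    p_trigger_fail = 0, p_decouple_fail = 0, p_wrong_effector = 0,
    em_jitter_sd = 0, between_mu_sd = 0, between_stop_sd = 0
  )
  args[names(list(...))] <- list(...)
  do.call(restart_params, args)
}

# a quick mix session for pipeline-level tests
quick_mix_trials <- function(n_trials = 600, seed = 1,
                             params = restart_preset("mix"),
                             participant_id = "p1") {
  cfg <- session_config(n_trials = n_trials, condition = "mix")
  simulate_session(cfg, params, seed = seed, participant_id = participant_id)
}

# stop trials of one version, presentation order, burn-in removed
stop_cell <- function(trials, version, burn_in = 10) {
  cell <- trials[trials$trial_type == "stop" &
                   trials$stop_version == version, ]
  drop_burn_in(cell[order(cell$trial_index), ], burn_in)
}
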