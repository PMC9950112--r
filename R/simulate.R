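#' Sample coupled Go latencies for the two effectors
#'
#' Draws the latent muscle-onset times implied by the shared Go process:
#' `wrist = G + e_w`, `foot = G + foot_offset + e_f`, with `G` ex-Gaussian
#' and the `e` independent `N(0, effector_noise_sd)`. The shared component
#' makes the two latencies strongly positively correlated (the
#' variance-ratio prediction is
#' `(sigma^2 + tau^2) / (sigma^2 + tau^2 + noise_sd^2)`).
#'
#' @param n number of trials.
#' @param params a [restart_params()].
#' @return a data frame with columns `wrist` and `foot`, ms from the Go
#'   Signal.
#' @export
sample_go_latencies <- function(n, params = restart_params()) {
  stopifnot(inherits(params, "restart_params"))
  g <- rexgauss(n, params$go_mu, params$go_sigma, params$go_tau)
  data.frame(
    wrist = g + stats::rnorm(n, 0, params$effector_noise_sd),
    foot = g + params$foot_offset + stats::rnorm(n, 0, params$effector_noise_sd)
  )
}

# step labels used in the latent ground truth
STEP_LABELS <- c("no_stop", "first_step_error", "restart_error",
                 "stop_success", "trigger_fail")

# Resolve one stop trial given pre-drawn random material.
# Returns list(mus_w, mus_f, stop_finish, label).
resolve_stop_trial <- function(gw, gf, ssd, s_draw, d_draw, u_trigger,
                               u_branch, version, p_trigger_fail,
                               p_decouple_fail, p_wrong_effector) {
  if (u_trigger < p_trigger_fail) {
    return(list(mus_w = gw, mus_f = gf, stop_finish = NA_real_,
                label = "trigger_fail"))
  }
  sf <- ssd + s_draw
  w_escaped <- gw < sf
  f_escaped <- gf < sf
  stopped_escaped <- switch(version,
    stop_both = w_escaped || f_escaped,
    stop_wrist = w_escaped,
    stop_foot = f_escaped
  )
  if (stopped_escaped) {
    return(list(mus_w = if (w_escaped) gw else NA_real_,
                mus_f = if (f_escaped) gf else NA_real_,
                stop_finish = sf, label = "first_step_error"))
  }
  if (version == "stop_both") {
    return(list(mus_w = NA_real_, mus_f = NA_real_, stop_finish = sf,
                label = "stop_success"))
  }
  # selective: the first step caught the to-be-stopped effector
  mover_escaped <- if (version == "stop_wrist") f_escaped else w_escaped
  mover_go <- if (version == "stop_wrist") gf else gw
  if (mover_escaped) {
    # the moving effector beat the global inhibition; no restart needed
    mus <- c(NA_real_, NA_real_)
    if (version == "stop_wrist") mus[2] <- mover_go else mus[1] <- mover_go
    return(list(mus_w = mus[1], mus_f = mus[2], stop_finish = sf,
                label = "stop_success"))
  }
  # the restart relaunches the paused Go command at sf + D, but a restarted
  # effector can never respond before its own Go process would have finished
  restart_w <- max(gw, sf + d_draw)
  restart_f <- max(gf, sf + d_draw)
  if (u_branch < p_decouple_fail) {
    # decoupling failed: both effectors restart together
    return(list(mus_w = restart_w, mus_f = restart_f, stop_finish = sf,
                label = "restart_error"))
  }
  if (u_branch < p_decouple_fail + p_wrong_effector) {
    # the wrong (to-be-stopped) effector restarts alone
    mus <- c(NA_real_, NA_real_)
    if (version == "stop_wrist") mus[1] <- restart_w else mus[2] <- restart_f
    return(list(mus_w = mus[1], mus_f = mus[2], stop_finish = sf,
                label = "restart_error"))
  }
  mus <- c(NA_real_, NA_real_)
  if (version == "stop_wrist") mus[2] <- restart_f else mus[1] <- restart_w
  list(mus_w = mus[1], mus_f = mus[2], stop_finish = sf,
       label = "stop_success")
}

#' Simulate a single stop trial of the two-step restart model
#'
#' With probability `p_trigger_fail` the Stop process never starts and the
#' trial resolves as a race-free Go trial. Otherwise the Stop process
#' finishes at `ssd + N(stop_mean, stop_sd)` (truncated at 0) and globally
#' inhibits every effector still short of its Go finish; effectors that beat
#' it move at their Go finish. If the first step catches all to-be-stopped
#' effectors, a selective version restarts the moving effector after the
#' context-dependent restart delay, with possible decoupling or
#' wrong-effector failures (restart errors).
#'
#' Random draws come from the current RNG stream; seed it with `set.seed()`
#' for reproducibility.
#'
#' @param params a [restart_params()].
#' @param ssd stop-signal delay, ms (>= 0).
#' @param version one of [stop_versions()].
#' @param condition `"block"` or `"mix"`; selects the context-dependent
#'   restart parameters when `params` carries per-condition values.
#' @return a list with the per-effector latent Go finishes
#'   (`latent_go`), the Stop finish (`latent_stop_finish`, `NA` on trigger
#'   failure), the per-effector muscle onsets of moved effectors
#'   (`mus_rt`, `NA` where the effector never moved) and the latent
#'   `step_label`.
#' @export
simulate_stop_trial <- function(params, ssd, version,
                                condition = c("block", "mix")) {
  stopifnot(inherits(params, "restart_params"), is.finite(ssd), ssd >= 0)
  version <- match.arg(version, stop_versions())
  condition <- match.arg(condition)
  go <- sample_go_latencies(1, params)
  res <- resolve_stop_trial(
    gw = go$wrist, gf = go$foot, ssd = ssd,
    s_draw = rtnorm0(1, params$stop_mean, params$stop_sd),
    d_draw = rtnorm0(1, param_for(params, "restart_delay_mean", condition),
                     params$restart_delay_sd),
    u_trigger = stats::runif(1), u_branch = stats::runif(1),
    version = version,
    p_trigger_fail = params$p_trigger_fail,
    p_decouple_fail = param_for(params, "p_decouple_fail", condition),
    p_wrong_effector = params$p_wrong_effector
  )
  list(
    latent_go = c(wrist = go$wrist, foot = go$foot),
    latent_stop_finish = res$stop_finish,
    mus_rt = c(wrist = res$mus_w, foot = res$mus_f),
    step_label = res$label
  )
}

#' Simulate a full session of the selective stop-signal task
#'
#' Wires together the exact-count trial allocation, the per-version SSD
#' staircases (three independent staircases in a Mix session), the two-step
#' restart race for stop trials, and the behavioural outcome rules. Overt
#' reaction times are the muscle onsets plus the per-effector
#' electromechanical delay with a small Gaussian jitter. Staircases advance
#' only on Stop Correct / Stop Error outcomes.
#'
#' @param config a [session_config()].
#' @param params a [restart_params()].
#' @param seed optional integer seed; the same seed reproduces the session
#'   exactly.
#' @param participant_id identifier stored in the table.
#' @return a data frame, one row per trial, with the observable columns
#'   `participant_id`, `condition`, `trial_index`, `trial_type`,
#'   `stop_version`, `ssd`, per-effector `*_moved`, `*_mus_rt`, `*_rt`, and
#'   `outcome`, plus the latent ground-truth columns `step_label`,
#'   `latent_go_wrist`, `latent_go_foot`, `latent_stop_finish`.
#' @export
simulate_session <- function(config, params = restart_params(), seed = NULL,
                             participant_id = "p1") {
  stopifnot(inherits(config, "session_config"),
            inherits(params, "restart_params"))
  with_local_seed(seed, {
    n <- config$n_trials
    alloc <- allocate_trials(config)
    go <- sample_go_latencies(n, params)
    s_draws <- rtnorm0(n, params$stop_mean, params$stop_sd)
    d_draws <- rtnorm0(
      n, param_for(params, "restart_delay_mean", config$condition),
      params$restart_delay_sd
    )
    u_trig <- stats::runif(n)
    u_branch <- stats::runif(n)
    em_w <- params$em_delay[["wrist"]] + stats::rnorm(n, 0, params$em_jitter_sd)
    em_f <- params$em_delay[["foot"]] + stats::rnorm(n, 0, params$em_jitter_sd)
    pdc <- param_for(params, "p_decouple_fail", config$condition)
    pwr <- params$p_wrong_effector
    ptf <- params$p_trigger_fail

    stair <- list()
    for (v in stop_versions()) {
      stair[[v]] <- staircase_state(config$staircase_start,
                                    config$staircase_step,
                                    floor = 0, ceiling = config$upper_rt_limit)
    }

    ssd <- rep(NA_real_, n)
    mus_w <- rep(NA_real_, n)
    mus_f <- rep(NA_real_, n)
    label <- character(n)
    stop_fin <- rep(NA_real_, n)
    outcome <- character(n)

    for (i in seq_len(n)) {
      if (alloc$trial_type[i] == "no_stop") {
        mus_w[i] <- go$wrist[i]
        mus_f[i] <- go$foot[i]
        label[i] <- "no_stop"
        outcome[i] <- classify_trial(
          NA_character_, TRUE, TRUE,
          mus_w[i] + em_w[i], mus_f[i] + em_f[i], config
        )
      } else {
        v <- alloc$stop_version[i]
        ssd[i] <- stair[[v]]$current_ssd
        res <- resolve_stop_trial(go$wrist[i], go$foot[i], ssd[i],
                                  s_draws[i], d_draws[i], u_trig[i],
                                  u_branch[i], v, ptf, pdc, pwr)
        mus_w[i] <- res$mus_w
        mus_f[i] <- res$mus_f
        stop_fin[i] <- res$stop_finish
        label[i] <- res$label
        outcome[i] <- classify_trial(
          v, !is.na(mus_w[i]), !is.na(mus_f[i]),
          if (is.na(mus_w[i])) NA_real_ else mus_w[i] + em_w[i],
          if (is.na(mus_f[i])) NA_real_ else mus_f[i] + em_f[i],
          config
        )
        if (outcome[i] != "aborted") {
          stair[[v]] <- next_ssd(stair[[v]], outcome[i])
        }
      }
    }

    data.frame(
      participant_id = participant_id,
      condition = config$condition,
      trial_index = alloc$trial_index,
      trial_type = alloc$trial_type,
      stop_version = alloc$stop_version,
      ssd = ssd,
      wrist_moved = !is.na(mus_w),
      foot_moved = !is.na(mus_f),
      wrist_mus_rt = mus_w,
      foot_mus_rt = mus_f,
      wrist_rt = ifelse(is.na(mus_w), NA_real_, mus_w + em_w),
      foot_rt = ifelse(is.na(mus_f), NA_real_, mus_f + em_f),
      outcome = outcome,
      step_label = label,
      latent_go_wrist = go$wrist,
      latent_go_foot = go$foot,
      latent_stop_finish = stop_fin,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a full study design for one participant
#'
#' Reproduces the study layout: three Block sessions (one per stop version)
#' and one Mix session in which the three versions are intermingled with
#' independent staircases.
#'
#' @param params a [restart_params()] (already individualised if simulating
#'   a group).
#' @param participant_id identifier stored in the tables.
#' @param n_block_trials trials per Block session (default 300; 0 skips
#'   the Block sessions).
#' @param n_mix_trials trials in the Mix session (default 600; 0 skips the
#'   Mix session).
#' @param ... further arguments passed to [session_config()].
#' @return a single trial table covering the simulated sessions.
#' @export
simulate_participant <- function(params = restart_params(),
                                 participant_id = "p1",
                                 n_block_trials = 300, n_mix_trials = 600,
                                 ...) {
  stopifnot(n_block_trials > 0 || n_mix_trials > 0)
  blocks <- if (n_block_trials > 0) {
    lapply(stop_versions(), function(v) {
      cfg <- session_config(n_trials = n_block_trials, condition = "block",
                            stop_version = v, ...)
      simulate_session(cfg, params, participant_id = participant_id)
    })
  } else list()
  mix <- if (n_mix_trials > 0) {
    mix_cfg <- session_config(n_trials = n_mix_trials, condition = "mix", ...)
    list(simulate_session(mix_cfg, params, participant_id = participant_id))
  } else list()
  out <- do.call(rbind, c(blocks, mix))
  rownames(out) <- NULL
  out
}

#' Simulate a group of participants
#'
#' Individualises the generative parameters per participant by drawing
#' `go_mu` and `stop_mean` offsets from the between-participant
#' distributions in `params`, then simulates each participant's full design.
#'
#' @param n_participants number of participants (default 9).
#' @param params a [restart_params()].
#' @param seed optional integer seed for the whole group.
#' @param ... passed to [simulate_participant()].
#' @return a trial table stacking all participants.
#' @export
simulate_group <- function(n_participants = 9, params = restart_params(),
                           seed = NULL, ...) {
  with_local_seed(seed, {
    out <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      p_i <- params
      p_i$go_mu <- params$go_mu + stats::rnorm(1, 0, params$between_mu_sd)
      p_i$stop_mean <- max(
        50, params$stop_mean + stats::rnorm(1, 0, params$between_stop_sd)
      )
      out[[i]] <- simulate_participant(
        p_i, participant_id = sprintf("p%02d", i), ...
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
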