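#' Synthetic EMG parameters
#'
#' Settings for the synthetic surface-EMG traces: a stationary Gaussian
#' baseline whose amplitude envelope ramps up at the latent muscle onset and
#' stays elevated for the rest of the trace.
#'
#' @param sampling_rate sampling frequency, Hz (default 6104, matching a
#'   typical high-rate surface-EMG acquisition).
#' @param baseline_sd standard deviation of the resting signal, in signal
#'   units.
#' @param burst_gain multiplier on `baseline_sd` reached by the burst
#'   envelope (signal-to-noise ratio of the burst; default 8).
#' @param burst_rise ramp duration from baseline to full burst amplitude,
#'   ms (default 10).
#' @param trace_pre_go,trace_post_go trace extent before and after the Go
#'   Signal, ms.
#' @return an object of class `emg_params`.
#' @export
emg_params <- function(sampling_rate = 6104, baseline_sd = 1,
                       burst_gain = 8, burst_rise = 10,
                       trace_pre_go = 200, trace_post_go = 1500) {
  stopifnot(sampling_rate > 0, baseline_sd >= 0, burst_gain > 1,
            burst_rise > 0, trace_pre_go > 0, trace_post_go > 0)
  structure(
    list(sampling_rate = sampling_rate, baseline_sd = baseline_sd,
         burst_gain = burst_gain, burst_rise = burst_rise,
         trace_pre_go = trace_pre_go, trace_post_go = trace_post_go),
    class = "emg_params"
  )
}

#' Parameters of the two-step restart race model
#'
#' The generative model behind the simulator. A trial's Go activation is a
#' shared ex-Gaussian process `G` driving both effectors: the wrist finishes
#' at `G + e_w` and the foot at `G + foot_offset + e_f`, with independent
#' Gaussian effector noise, so the two muscle onsets are strongly coupled
#' and the foot lags the wrist by `foot_offset` on average. On a stop trial
#' an independent Stop process finishes `N(stop_mean, stop_sd)` ms (truncated
#' at 0) after the Stop Signal; with probability `p_trigger_fail` it is never
#' triggered. The first step is a global race: any effector whose Go
#' activation completes before the Stop process moves at its Go finish. If
#' the first step catches all to-be-stopped effectors, a selective stop
#' requires a second step that restarts the moving effector after a
#' context-dependent delay `N(restart_delay_mean, restart_delay_sd)`; with
#' probability `p_decouple_fail` the stopped effector restarts coupled with
#' it (a restart error), and with probability `p_wrong_effector` only the
#' wrong effector restarts.
#'
#' `restart_delay_mean` and `p_decouple_fail` are the two parameters that
#' encode the task context: with foreknowledge of the effector to stop
#' (Block) the restart is fast and decoupling reliable; without it (Mix) the
#' restart is slow and decoupling error-prone. Supply either scalars or
#' vectors named `block` / `mix`.
#'
#' @param go_mu,go_sigma,go_tau ex-Gaussian parameters of the shared Go
#'   process, ms.
#' @param foot_offset mean extra latency of the foot relative to the wrist,
#'   ms (default 46).
#' @param effector_noise_sd sd of the independent per-effector latency
#'   noise, ms.
#' @param stop_mean,stop_sd Stop-process finish time distribution, ms after
#'   the Stop Signal.
#' @param p_trigger_fail probability that the Stop process never starts.
#' @param restart_delay_mean,restart_delay_sd second-step restart delay, ms;
#'   the mean may be a named per-condition vector.
#' @param p_decouple_fail probability that the stopped effector restarts
#'   coupled with the moving one; may be a named per-condition vector.
#' @param p_wrong_effector probability that, after a successful first step,
#'   only the to-be-stopped effector restarts.
#' @param em_delay named per-effector electromechanical delay between muscle
#'   onset and overt movement, ms (defaults wrist 90, foot 140).
#' @param em_jitter_sd sd of the trial-to-trial jitter on the
#'   electromechanical delay, ms.
#' @param between_mu_sd,between_stop_sd between-participant sds of `go_mu`
#'   and `stop_mean`, ms, used when simulating groups.
#' @param emg an [emg_params()] bundle for synthetic traces.
#' @return an object of class `restart_params`.
#' @seealso [restart_preset()] for the shipped Block/Mix bundles.
#' @export
restart_params <- function(go_mu = 410, go_sigma = 70, go_tau = 40,
                           foot_offset = 46, effector_noise_sd = 25,
                           stop_mean = 150, stop_sd = 30,
                           p_trigger_fail = 0.02,
                           restart_delay_mean = c(block = 120, mix = 400),
                           restart_delay_sd = 60,
                           p_decouple_fail = c(block = 0.05, mix = 0.25),
                           p_wrong_effector = 0.03,
                           em_delay = c(wrist = 90, foot = 140),
                           em_jitter_sd = 5,
                           between_mu_sd = 90, between_stop_sd = 40,
                           emg = emg_params()) {
  probs <- c(p_trigger_fail, p_decouple_fail, p_wrong_effector)
  stopifnot(
    go_sigma > 0, go_tau > 0, effector_noise_sd >= 0,
    stop_sd >= 0, restart_delay_sd >= 0, em_jitter_sd >= 0,
    between_mu_sd >= 0, between_stop_sd >= 0,
    all(probs >= 0 & probs <= 1),
    setequal(names(em_delay), effectors()),
    inherits(emg, "emg_params")
  )
  p <- structure(
    list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
         foot_offset = foot_offset, effector_noise_sd = effector_noise_sd,
         stop_mean = stop_mean, stop_sd = stop_sd,
         p_trigger_fail = p_trigger_fail,
         restart_delay_mean = restart_delay_mean,
         restart_delay_sd = restart_delay_sd,
         p_decouple_fail = p_decouple_fail,
         p_wrong_effector = p_wrong_effector,
         em_delay = em_delay[effectors()], em_jitter_sd = em_jitter_sd,
         between_mu_sd = between_mu_sd, between_stop_sd = between_stop_sd,
         emg = emg),
    class = "restart_params"
  )
  rd <- c(param_for(p, "restart_delay_mean", "block"),
          param_for(p, "restart_delay_mean", "mix"))
  if (rd[2] < rd[1]) {
    stop("restart_delay_mean in mix must be >= restart_delay_mean in block")
  }
  p
}

#' Shipped parameter bundles for the two task contexts
#'
#' Returns [restart_params()] with `restart_delay_mean` and
#' `p_decouple_fail` resolved for one context. The bundles differ only in
#' those two fields: with foreknowledge of the effector to stop (`"block"`)
#' the restart is fast (120 ms) and decoupling failures rare (5%); without
#' it (`"mix"`) the restart is slow (400 ms) and decoupling failures common
#' (25%).
#'
#' @param condition `"block"` or `"mix"`.
#' @param ... further arguments passed to [restart_params()].
#' @return a `restart_params` object with scalar context fields.
#' @export
restart_preset <- function(condition = c("block", "mix"), ...) {
  condition <- match.arg(condition)
  base <- restart_params(...)
  base$restart_delay_mean <- param_for(base, "restart_delay_mean", condition)
  base$p_decouple_fail <- param_for(base, "p_decouple_fail", condition)
  base
}

# resolve a possibly per-condition parameter to a scalar
param_for <- function(params, field, condition) {
  v <- params[[field]]
  if (length(v) == 1 && is.null(names(v))) return(unname(v))
  if (!is.null(names(v)) && condition %in% names(v)) return(unname(v[[condition]]))
  if (length(v) == 1) return(unname(v))
  stop(sprintf("parameter '%s' has no value for condition '%s'", field, condition))
}

#' @export
print.restart_params <- function(x, ...) {
  fmt <- function(v) if (length(v) > 1) {
    paste(sprintf("%s=%g", names(v), v), collapse = ", ")
  } else as.character(v)
  cat("<restart_params>\n")
  cat(sprintf("  Go (shared ex-Gaussian): mu=%g sigma=%g tau=%g ms; foot offset %g ms; effector noise sd %g ms\n",
              x$go_mu, x$go_sigma, x$go_tau, x$foot_offset, x$effector_noise_sd))
  cat(sprintf("  Stop: N(%g, %g) ms; trigger failure %g\n",
              x$stop_mean, x$stop_sd, x$p_trigger_fail))
  cat(sprintf("  Restart: delay mean {%s} sd %g ms; decouple failure {%s}; wrong effector %g\n",
              fmt(x$restart_delay_mean), x$restart_delay_sd,
              fmt(x$p_decouple_fail), x$p_wrong_effector))
  cat(sprintf("  Electromechanical delay: wrist %g, foot %g (jitter sd %g) ms\n",
              x$em_delay[["wrist"]], x$em_delay[["foot"]], x$em_jitter_sd))
  invisible(x)
}

#' Ex-Gaussian random deviates
#'
#' Sum of a Gaussian and an independent exponential component, the standard
#' positively skewed family for reaction-time latencies.
#'
#' @param n number of draws.
#' @param mu,sigma Gaussian component mean and sd.
#' @param tau exponential component mean.
#' @return numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

# Normal draws truncated below at zero (negative durations are clipped)
rtnorm0 <- function(n, mean, sd) {
  pmax(stats::rnorm(n, mean, sd), 0)
}
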