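#' Drop staircase burn-in trials
#'
#' Removes the first `burn_in` stop trials of a cell so that averages are
#' not dragged toward the fixed staircase starting value.
#'
#' @param stop_trials data frame of stop trials, in presentation order.
#' @param burn_in number of leading stop trials to drop (default 10).
#' @return the trimmed data frame.
#' @export
drop_burn_in <- function(stop_trials, burn_in = 10) {
  if (nrow(stop_trials) <= burn_in) return(stop_trials[0, , drop = FALSE])
  stop_trials[-seq_len(burn_in), , drop = FALSE]
}

new_ssrt_estimate <- function(ssrt, method, mean_ssd, n_stop_trials, valid,
                              participant_id = NA_character_,
                              condition = NA_character_,
                              version = NA_character_) {
  structure(
    list(participant_id = participant_id, condition = condition,
         version = version, ssrt = ssrt, method = method,
         mean_ssd = mean_ssd, n_stop_trials = n_stop_trials, valid = valid),
    class = "ssrt_estimate"
  )
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf("<ssrt_estimate> %.1f ms (%s method; mean SSD %.1f ms; n=%d%s)\n",
              x$ssrt, x$method, x$mean_ssd, x$n_stop_trials,
              if (x$valid) "" else "; INVALID"))
  invisible(x)
}

#' SSRT by the mean method
#'
#' With a one-up/one-down staircase tracking 50% stopping failure, the Stop
#' process finishes on average at the going distribution's centre, so
#' `SSRT = mean(No Stop MusRT) - mean(SSD)`. Requires at least `min_trials`
#' stop trials (after burn-in removal, which is the caller's
#' responsibility); with fewer the estimate is returned but flagged
#' invalid.
#'
#' @param no_stop_musrts No Stop muscle reaction times, ms from Go.
#' @param ssds realized stop-signal delays of the cell's stop trials, ms.
#' @param min_trials minimum number of stop trials (default 20).
#' @param ... metadata (`participant_id`, `condition`, `version`) stored on
#'   the estimate.
#' @return an `ssrt_estimate`.
#' @export
mean_method_ssrt <- function(no_stop_musrts, ssds, min_trials = 20, ...) {
  stopifnot(length(no_stop_musrts) > 0)
  valid <- length(ssds) >= min_trials
  if (!valid) {
    warning(sprintf("only %d stop trials (< %d); SSRT flagged invalid",
                    length(ssds), min_trials))
  }
  new_ssrt_estimate(
    ssrt = mean(no_stop_musrts) - mean(ssds), method = "mean",
    mean_ssd = mean(ssds), n_stop_trials = length(ssds), valid = valid, ...
  )
}

#' SSRT by the integration method
#'
#' Assumes the Stop process finishes at the `p_respond` quantile of the
#' going distribution: `SSRT = quantile(No Stop MusRT, p_respond) -
#' mean(SSD)`. Provided as a cross-check of the mean method, and as the
#' estimator underlying the compliant-subset re-estimation.
#'
#' @param no_stop_musrts No Stop muscle reaction times, ms from Go.
#' @param p_respond probability of responding on a stop trial (0 < p < 1).
#' @param mean_ssd mean realized stop-signal delay, ms.
#' @param ... metadata stored on the estimate.
#' @return an `ssrt_estimate`.
#' @export
integration_ssrt <- function(no_stop_musrts, p_respond, mean_ssd, ...) {
  stopifnot(length(no_stop_musrts) > 1, p_respond > 0, p_respond < 1,
            is.finite(mean_ssd))
  if (stats::sd(no_stop_musrts) == 0) {
    stop("degenerate No Stop distribution: all MusRTs identical")
  }
  q <- unname(stats::quantile(no_stop_musrts, p_respond, type = 7))
  new_ssrt_estimate(
    ssrt = q - mean_ssd, method = "integration",
    mean_ssd = mean_ssd, n_stop_trials = NA_integer_, valid = TRUE, ...
  )
}

#' Race-model independence test
#'
#' The independence assumption of the race model requires Stop Error
#' responses to be faster on average than No Stop responses (errors are the
#' fast tail of the going distribution that escaped inhibition). The test
#' is a two-tailed paired t test on per-participant mean MusRTs; the
#' assumption counts as violated only when errors are significantly
#' *slower*.
#'
#' @param stop_error_means per-participant mean Stop Error MusRTs, ms.
#' @param no_stop_means per-participant mean No Stop MusRTs, ms (same
#'   participant order).
#' @param alpha significance level (default 0.05).
#' @return a list with the test (`t`, `df`, `p_value`), the group means,
#'   `direction` (`"error_faster"` / `"error_slower"`) and `violated`.
#' @export
independence_test <- function(stop_error_means, no_stop_means, alpha = 0.05) {
  stopifnot(length(stop_error_means) == length(no_stop_means))
  if (length(stop_error_means) < 2) {
    stop("independence test needs at least 2 participants")
  }
  tt <- paired_t(stop_error_means, no_stop_means)
  direction <- if (tt$mean_diff > 0) "error_slower" else "error_faster"
  list(
    stop_error_mean = mean(stop_error_means),
    no_stop_mean = mean(no_stop_means),
    t = tt$t, df = tt$df, p_value = tt$p,
    direction = direction,
    violated = direction == "error_slower" && tt$p < alpha,
    alpha = alpha,
    n = length(stop_error_means)
  )
}

#' Stop-interference effect on the moving effector
#'
#' In correct selective stop trials the effector that keeps moving pays the
#' cost of the preceding global inhibition: its MusRT is delayed relative
#' to No Stop trials. The interference is the difference of means.
#'
#' @param stop_correct_moving_musrts MusRTs of the moving effector in
#'   selective Stop Correct trials, ms.
#' @param no_stop_musrts same-effector No Stop MusRTs, ms.
#' @return the delay in ms (positive = interference).
#' @export
interference_effect <- function(stop_correct_moving_musrts, no_stop_musrts) {
  stopifnot(length(stop_correct_moving_musrts) > 0,
            length(no_stop_musrts) > 0)
  mean(stop_correct_moving_musrts) - mean(no_stop_musrts)
}

#' Between-effector coupling of No Stop latencies
#'
#' Spearman rank correlation between the wrist and foot MusRTs of the same
#' No Stop trials; a strong positive correlation is the signature of a
#' shared Go process driving both effectors.
#'
#' @param wrist_musrts,foot_musrts paired same-trial MusRTs (n >= 10).
#' @return as [spearman_cor()] (`r = NA` for constant input).
#' @export
coupling_correlation <- function(wrist_musrts, foot_musrts) {
  stopifnot(length(wrist_musrts) == length(foot_musrts),
            length(wrist_musrts) >= 10)
  spearman_cor(wrist_musrts, foot_musrts)
}
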