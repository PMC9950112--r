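#' Effector and stop-version vocabulary
#'
#' The task engages exactly two effectors: a wrist rotation and a foot lift,
#' performed simultaneously on every Go trial. Stop trials come in three
#' versions: a non-selective version in which both movements must be
#' cancelled, and two selective versions in which only one effector must be
#' held while the other completes its movement.
#'
#' @return `effectors()` returns `c("wrist", "foot")`; `stop_versions()`
#'   returns `c("stop_both", "stop_wrist", "stop_foot")`.
#' @export
effectors <- function() c("wrist", "foot")

#' @rdname effectors
#' @export
stop_versions <- function() c("stop_both", "stop_wrist", "stop_foot")

#' Is a stop version selective?
#'
#' @param version one of [stop_versions()].
#' @return `TRUE` for `stop_wrist` / `stop_foot`, `FALSE` for `stop_both`.
#' @export
is_selective <- function(version) {
  version <- match.arg(version, stop_versions(), several.ok = TRUE)
  version != "stop_both"
}

#' The effector a selective stop version requires to be stopped
#'
#' @param version `"stop_wrist"` or `"stop_foot"`.
#' @return `"wrist"` or `"foot"`.
#' @export
stopped_effector <- function(version) {
  switch(version,
    stop_wrist = "wrist",
    stop_foot = "foot",
    stop(sprintf("'%s' has no single stopped effector", version))
  )
}

#' Session design configuration
#'
#' Describes one experimental session: how many trials it contains, whether
#' it is a Block session (a single stop version throughout, so the effector
#' to be stopped is known in advance) or a Mix session (all three stop
#' versions intermingled, with the effector revealed only by the Stop
#' Signal), the outcome limits, and the staircase settings.
#'
#' @param n_trials total number of trials in the session.
#' @param condition `"block"` or `"mix"`.
#' @param stop_version for Block sessions, the single stop version presented.
#' @param stop_fraction proportion of stop trials (default 0.30, i.e. 70%
#'   No Stop trials).
#' @param mix_version_fractions named proportions of stop trials allotted to
#'   each stop version in a Mix session (default one third each).
#' @param upper_rt_limit maximum allowed reaction time, ms from the Go
#'   Signal (default 1300).
#' @param max_intereffector_delay maximum allowed delay between the two
#'   effectors' responses in a No Stop trial, ms (default 200).
#' @param hold_after_stop time the stopped effector(s) must be held after
#'   the Stop Signal, ms (default 1300).
#' @param staircase_start initial stop-signal delay, ms (default 50).
#' @param staircase_step staircase step, ms (default 50).
#' @return an object of class `session_config`.
#' @export
session_config <- function(n_trials = 300,
                           condition = c("block", "mix"),
                           stop_version = "stop_both",
                           stop_fraction = 0.30,
                           mix_version_fractions = c(stop_both = 1 / 3,
                                                     stop_wrist = 1 / 3,
                                                     stop_foot = 1 / 3),
                           upper_rt_limit = 1300,
                           max_intereffector_delay = 200,
                           hold_after_stop = 1300,
                           staircase_start = 50,
                           staircase_step = 50) {
  condition <- match.arg(condition)
  stop_version <- match.arg(stop_version, stop_versions())
  stopifnot(
    n_trials >= 1,
    stop_fraction > 0, stop_fraction < 1,
    upper_rt_limit > 0, max_intereffector_delay > 0, hold_after_stop > 0,
    staircase_start >= 0, staircase_step > 0
  )
  if (condition == "mix") {
    if (is.null(names(mix_version_fractions)) ||
        !setequal(names(mix_version_fractions), stop_versions())) {
      stop("mix_version_fractions must be named by the three stop versions")
    }
    mix_version_fractions <- mix_version_fractions[stop_versions()]
    if (abs(sum(mix_version_fractions) - 1) > 1e-8) {
      stop("mix_version_fractions must sum to 1")
    }
  }
  structure(
    list(
      n_trials = as.integer(n_trials),
      condition = condition,
      stop_version = stop_version,
      stop_fraction = stop_fraction,
      mix_version_fractions = mix_version_fractions,
      upper_rt_limit = upper_rt_limit,
      max_intereffector_delay = max_intereffector_delay,
      hold_after_stop = hold_after_stop,
      staircase_start = staircase_start,
      staircase_step = staircase_step
    ),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "<session_config> %d trials, %s condition%s; %.0f%% stop trials; SSD staircase %g/%g ms\n",
    x$n_trials, x$condition,
    if (x$condition == "block") paste0(" (", x$stop_version, ")") else "",
    100 * x$stop_fraction, x$staircase_start, x$staircase_step
  ))
  invisible(x)
}

#' Adaptive stop-signal-delay staircase
#'
#' One-up/one-down tracking of the stop-signal delay (SSD): a correct stop
#' makes the next stop harder (SSD + step) and a failed stop makes it easier
#' (SSD - step), so the realized stop-error rate converges to 50%. Aborted
#' trials do not move the staircase. The SSD is clipped to
#' `[floor, ceiling]`.
#'
#' @param current_ssd current SSD, ms.
#' @param step staircase step, ms.
#' @param floor,ceiling clipping bounds, ms. The ceiling defaults to the
#'   upper RT limit so that the Stop Signal always falls inside the response
#'   window.
#' @return an object of class `staircase_state`.
#' @export
staircase_state <- function(current_ssd = 50, step = 50,
                            floor = 0, ceiling = 1300) {
  stopifnot(is.finite(current_ssd), is.finite(step), step > 0,
            floor <= ceiling)
  current_ssd <- min(max(current_ssd, floor), ceiling)
  structure(
    list(current_ssd = current_ssd, step = step,
         floor = floor, ceiling = ceiling),
    class = "staircase_state"
  )
}

#' Advance the staircase after a stop trial
#'
#' @param state a [staircase_state()].
#' @param outcome `"correct"` (SSD increases) or `"error"` (SSD decreases).
#' @return the updated `staircase_state`.
#' @export
next_ssd <- function(state, outcome) {
  stopifnot(inherits(state, "staircase_state"))
  outcome <- match.arg(outcome, c("correct", "error"))
  if (!is.finite(state$current_ssd)) stop("invalid staircase state: non-finite SSD")
  delta <- if (outcome == "correct") state$step else -state$step
  state$current_ssd <- min(max(state$current_ssd + delta, state$floor),
                           state$ceiling)
  state
}

#' Classify the outcome of a single trial
#'
#' Applies the behavioural outcome rules. In a No Stop trial both effectors
#' must move, each within the upper RT limit and within
#' `max_intereffector_delay` of one another; otherwise the trial is aborted.
#' In the non-selective stop version any movement is a Stop Error. In a
#' selective version, moving the to-be-stopped effector is a Stop Error;
#' holding it while the other effector moves within the RT limit is a Stop
#' Correct; holding both (the required effector never moved in time) aborts
#' the trial.
#'
#' @param stop_version one of [stop_versions()], or `NA` for a No Stop trial.
#' @param wrist_moved,foot_moved logical movement flags.
#' @param wrist_rt,foot_rt reaction times, ms from the Go Signal; required
#'   for every moved effector.
#' @param config a [session_config()] supplying the limits.
#' @return one of `"correct"`, `"error"`, `"aborted"`.
#' @export
classify_trial <- function(stop_version, wrist_moved, foot_moved,
                           wrist_rt = NA_real_, foot_rt = NA_real_,
                           config = session_config()) {
  stopifnot(inherits(config, "session_config"),
            is.logical(wrist_moved), is.logical(foot_moved))
  if ((wrist_moved && is.na(wrist_rt)) || (foot_moved && is.na(foot_rt))) {
    stop("malformed trial: moved effector without a reaction time")
  }
  lim <- config$upper_rt_limit
  if (is.na(stop_version)) {
    ok <- wrist_moved && foot_moved &&
      wrist_rt <= lim && foot_rt <= lim &&
      abs(wrist_rt - foot_rt) <= config$max_intereffector_delay
    return(if (ok) "correct" else "aborted")
  }
  stop_version <- match.arg(stop_version, stop_versions())
  if (stop_version == "stop_both") {
    return(if (wrist_moved || foot_moved) "error" else "correct")
  }
  held <- if (stop_version == "stop_wrist") !wrist_moved else !foot_moved
  mover_moved <- if (stop_version == "stop_wrist") foot_moved else wrist_moved
  mover_rt <- if (stop_version == "stop_wrist") foot_rt else wrist_rt
  if (!held) return("error")
  if (mover_moved && mover_rt <= lim) return("correct")
  "aborted"
}

#' Allocate trial types and stop versions for a session
#'
#' Deterministic, exact-count allocation: the numbers of No Stop and stop
#' trials (and, in Mix, of each stop version) match the configured fractions
#' exactly, with any fractional remainder assigned by largest remainder in
#' the fixed order of [stop_versions()]. The presentation order is a single
#' seeded permutation, so the same seed always yields the same sequence.
#'
#' @param config a [session_config()].
#' @param seed optional integer; when given, the permutation is drawn from a
#'   local RNG stream and the caller's RNG state is untouched.
#' @return a data frame with columns `trial_index`, `trial_type`
#'   (`"no_stop"`/`"stop"`) and `stop_version` (`NA` for No Stop trials).
#' @export
allocate_trials <- function(config, seed = NULL) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_trials
  n_stop <- round(n * config$stop_fraction)
  if (config$condition == "block") {
    versions <- rep(config$stop_version, n_stop)
  } else {
    counts <- largest_remainder(n_stop * config$mix_version_fractions)
    versions <- rep(names(counts), counts)
  }
  type <- c(rep("no_stop", n - n_stop), rep("stop", n_stop))
  version <- c(rep(NA_character_, n - n_stop), versions)
  ord <- with_local_seed(seed, sample.int(n))
  data.frame(
    trial_index = seq_len(n),
    trial_type = type[ord],
    stop_version = version[ord],
    stringsAsFactors = FALSE
  )
}

# largest-remainder rounding of real-valued counts to integers preserving sum
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    take <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[take] <- fl[take] + 1
  }
  fl
}

# evaluate expr under a temporary RNG seed (or the current stream if NULL)
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}
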