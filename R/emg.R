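#' EMG trace container
#'
#' A sampled surface-EMG signal for one effector on one trial, together
#' with its sampling rate and the sample index of the Go Signal. Synthetic
#' traces additionally carry the latent true burst onset.
#'
#' @param samples numeric vector of signal values.
#' @param sampling_rate sampling frequency, Hz.
#' @param go_index sample index (1-based) of the Go Signal onset.
#' @param effector `"wrist"` or `"foot"`.
#' @param trial_index trial the trace belongs to.
#' @param latent_onset_ms latent burst onset, ms from Go (synthetic traces
#'   only; `NA` if the effector never moved).
#' @return an object of class `emg_trace`.
#' @export
emg_trace <- function(samples, sampling_rate, go_index,
                      effector = "wrist", trial_index = 1L,
                      latent_onset_ms = NA_real_) {
  stopifnot(is.numeric(samples), sampling_rate > 0,
            go_index >= 1, go_index <= length(samples))
  effector <- match.arg(effector, effectors())
  structure(
    list(samples = as.numeric(samples), sampling_rate = sampling_rate,
         go_index = as.integer(go_index), effector = effector,
         trial_index = as.integer(trial_index),
         latent_onset_ms = latent_onset_ms),
    class = "emg_trace"
  )
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf(
    "<emg_trace> trial %d, %s: %d samples @ %g Hz, Go at sample %d%s\n",
    x$trial_index, x$effector, length(x$samples), x$sampling_rate,
    x$go_index,
    if (is.na(x$latent_onset_ms)) "" else
      sprintf(", latent onset %.1f ms", x$latent_onset_ms)
  ))
  invisible(x)
}

#' Full-wave rectification
#'
#' @param x numeric signal vector.
#' @return `abs(x)`, length preserved.
#' @export
rectify <- function(x) abs(x)

#' Centred moving-average smoothing
#'
#' Smooths with a centred window of `window_ms`; at the edges the window is
#' truncated to the available samples, so the length is preserved. The
#' window is realised as `2h + 1` samples with
#' `h = floor(window_ms * rate / 1000 / 2)`.
#'
#' @param x numeric signal vector.
#' @param window_ms window length, ms (> 0).
#' @param sampling_rate sampling frequency, Hz.
#' @return the smoothed signal, same length as `x`.
#' @export
smooth_trace <- function(x, window_ms, sampling_rate) {
  stopifnot(window_ms > 0, sampling_rate > 0)
  n <- length(x)
  w <- max(1L, round(window_ms * sampling_rate / 1000))
  if (w > n) stop("smoothing window longer than the trace")
  h <- (w - 1L) %/% 2L
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect the muscle onset (MusRT) in a processed EMG trace
#'
#' Implements baseline-referenced threshold detection: the threshold is the
#' mean plus `k` standard deviations of the processed signal over the
#' `baseline_ms` window immediately preceding the Go Signal, and the muscle
#' reaction time is the time (ms from Go) of the first post-Go sample that
#' exceeds the threshold and stays above it for at least `sustain_ms`. The
#' search is restricted to the post-Go segment; a sustained pre-Go crossing
#' marks the trace as contaminated instead of yielding a negative onset.
#'
#' @param trace an [emg_trace()] whose samples have already been rectified
#'   and smoothed (see [process_emg_trace()] for the full chain).
#' @param baseline_ms baseline window length, ms (default 100).
#' @param k threshold in baseline standard deviations (default 2.5).
#' @param sustain_ms minimum suprathreshold duration, ms (default 10).
#' @return a list with `mus_rt` (ms from Go, `NA` if no crossing),
#'   `threshold`, and `contaminated` (logical).
#' @export
detect_onset <- function(trace, baseline_ms = 100, k = 2.5, sustain_ms = 10) {
  stopifnot(inherits(trace, "emg_trace"), baseline_ms > 0, k >= 0,
            sustain_ms >= 0)
  x <- trace$samples
  fs <- trace$sampling_rate
  gi <- trace$go_index
  nb <- max(1L, round(baseline_ms * fs / 1000))
  if (gi - 1L < nb) stop("insufficient pre-Go samples for the baseline window")
  base <- x[(gi - nb):(gi - 1L)]
  threshold <- mean(base) + k * stats::sd(base)
  ns <- max(1L, round(sustain_ms * fs / 1000))

  first_sustained <- function(above) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= ns)
    if (length(hit) == 0) NA_integer_ else starts[hit[1L]]
  }

  contaminated <- FALSE
  if (gi > 1L) {
    pre_hit <- first_sustained(x[seq_len(gi - 1L)] > threshold)
    contaminated <- !is.na(pre_hit)
  }
  post <- x[gi:length(x)]
  idx <- first_sustained(post > threshold)
  mus_rt <- if (is.na(idx)) NA_real_ else (idx - 1L) / fs * 1000
  list(mus_rt = mus_rt, threshold = threshold, contaminated = contaminated)
}

#' Rectify, smooth and detect the onset of a raw EMG trace
#'
#' The standard processing chain: full-wave rectification, centred
#' moving-average smoothing, then baseline-referenced onset detection on
#' the processed signal (the baseline statistics are computed on the
#' processed signal too, matching the processing order).
#'
#' @param trace an [emg_trace()] with raw samples.
#' @param window_ms smoothing window, ms (default 10).
#' @inheritParams detect_onset
#' @return as [detect_onset()], with the processed trace added as
#'   `processed`.
#' @export
process_emg_trace <- function(trace, window_ms = 10, baseline_ms = 100,
                              k = 2.5, sustain_ms = 10) {
  stopifnot(inherits(trace, "emg_trace"))
  proc <- trace
  proc$samples <- smooth_trace(rectify(trace$samples), window_ms,
                               trace$sampling_rate)
  out <- detect_onset(proc, baseline_ms = baseline_ms, k = k,
                      sustain_ms = sustain_ms)
  out$processed <- proc
  out
}

#' Synthesize a surface-EMG trace with a known burst onset
#'
#' Builds a Gaussian-noise trace whose amplitude envelope is flat at
#' `baseline_sd` until the latent onset, ramps linearly over `burst_rise`
#' ms to `burst_gain * baseline_sd`, and stays elevated until the end of
#' the trace. With `onset_ms = NA` (a non-moving effector) the trace is
#' stationary baseline noise throughout.
#'
#' @param onset_ms latent muscle onset, ms from the Go Signal, or `NA`.
#' @param emg an [emg_params()].
#' @param effector,trial_index metadata stored on the trace.
#' @return an [emg_trace()] carrying the latent onset.
#' @export
synthesize_emg <- function(onset_ms, emg = emg_params(),
                           effector = "wrist", trial_index = 1L) {
  stopifnot(inherits(emg, "emg_params"))
  fs <- emg$sampling_rate
  n_pre <- round(emg$trace_pre_go * fs / 1000)
  n_post <- round(emg$trace_post_go * fs / 1000)
  n <- n_pre + n_post
  go_index <- n_pre + 1L
  sd_env <- rep(emg$baseline_sd, n)
  if (!is.na(onset_ms)) {
    t_ms <- (seq_len(n) - go_index) / fs * 1000
    ramp <- pmin(pmax((t_ms - onset_ms) / emg$burst_rise, 0), 1)
    sd_env <- emg$baseline_sd * (1 + (emg$burst_gain - 1) * ramp)
  }
  emg_trace(
    samples = stats::rnorm(n, 0, 1) * sd_env,
    sampling_rate = fs, go_index = go_index,
    effector = effector, trial_index = trial_index,
    latent_onset_ms = onset_ms
  )
}

#' Synthesize the EMG traces for every moved effector of a trial table
#'
#' @param trials a trial table from [simulate_session()].
#' @param emg an [emg_params()].
#' @return a list of [emg_trace()] objects, one per moved effector per
#'   trial.
#' @export
synthesize_session_emg <- function(trials, emg = emg_params()) {
  traces <- list()
  for (i in seq_len(nrow(trials))) {
    for (eff in effectors()) {
      mus <- trials[[paste0(eff, "_mus_rt")]][i]
      if (!is.na(mus)) {
        traces[[length(traces) + 1L]] <- synthesize_emg(
          mus, emg, effector = eff, trial_index = trials$trial_index[i]
        )
      }
    }
  }
  traces
}

#' Fill the MusRT columns of a trial table from EMG traces
#'
#' Processes each trace with [process_emg_trace()] and merges the detected
#' onsets into the table by `(trial_index, effector)`. Trials whose moved
#' flag is set but whose onset could not be detected (or whose baseline was
#' contaminated) are flagged for exclusion in the `musrt_excluded` column.
#'
#' @param traces list of [emg_trace()] objects.
#' @param trials a trial table with `trial_index` and per-effector
#'   `*_moved` columns.
#' @param ... detection settings passed to [process_emg_trace()].
#' @return `trials` with `wrist_mus_rt` / `foot_mus_rt` replaced by the
#'   detected onsets and a logical `musrt_excluded` column added.
#' @export
build_musrt_table <- function(traces, trials, ...) {
  if (nrow(trials) == 0) {
    trials$musrt_excluded <- logical(0)
    return(trials)
  }
  key <- function(ti, eff) paste(ti, eff, sep = "/")
  detected <- new.env(parent = emptyenv())
  for (tr in traces) {
    res <- process_emg_trace(tr, ...)
    assign(key(tr$trial_index, tr$effector),
           if (res$contaminated) NA_real_ else res$mus_rt,
           envir = detected)
  }
  trials$musrt_excluded <- FALSE
  missing_traces <- integer(0)
  for (eff in effectors()) {
    moved_col <- paste0(eff, "_moved")
    mus_col <- paste0(eff, "_mus_rt")
    trials[[mus_col]] <- NA_real_
    for (i in seq_len(nrow(trials))) {
      if (!isTRUE(trials[[moved_col]][i])) next
      k <- key(trials$trial_index[i], eff)
      if (!exists(k, envir = detected, inherits = FALSE)) {
        missing_traces <- c(missing_traces, trials$trial_index[i])
        next
      }
      v <- get(k, envir = detected)
      if (is.na(v)) trials$musrt_excluded[i] <- TRUE
      trials[[mus_col]][i] <- v
    }
  }
  if (length(missing_traces) > 0) {
    stop("missing EMG trace for moved effector on trial(s): ",
         paste(sort(unique(missing_traces)), collapse = ", "))
  }
  trials
}
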