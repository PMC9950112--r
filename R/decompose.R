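#' Estimated end of the global inhibition step (Stop End)
#'
#' The first, non-selective step of the restart model is assumed to finish
#' SSRT ms after the Stop Signal. Anchored to the Go Signal, its average
#' completion in a selective cell is `SSRT + mean(SSD)`, where the SSRT is
#' the participant's non-selective (stop-both) estimate from the matching
#' task condition and the mean SSD is taken over the participant's
#' selective stop trials of that cell.
#'
#' @param ssrt_nonselective the participant's stop-both SSRT, ms (an
#'   `ssrt_estimate` or a number). An invalid estimate is an error: the
#'   decomposition for that participant must be skipped.
#' @param mean_ssd_selective mean SSD of the selective cell, ms.
#' @return Stop End, ms from the Go Signal.
#' @export
compute_stop_end <- function(ssrt_nonselective, mean_ssd_selective) {
  if (inherits(ssrt_nonselective, "ssrt_estimate")) {
    if (!ssrt_nonselective$valid) {
      stop("non-selective SSRT is invalid; cannot anchor the Stop End")
    }
    ssrt_nonselective <- ssrt_nonselective$ssrt
  }
  stopifnot(is.finite(ssrt_nonselective), is.finite(mean_ssd_selective))
  ssrt_nonselective + mean_ssd_selective
}

#' Partition selective Stop Errors at the Stop End
#'
#' Stop Errors whose MusRT completes before the Stop End are Compliant with
#' the race model (they plausibly lost the first-step race); errors
#' completing at or after the Stop End are Non-Compliant (they belong to
#' the restart step). The cut is strict: an error exactly at the Stop End
#' is Non-Compliant.
#'
#' @param error_musrts MusRTs of the cell's Stop Error trials, ms
#'   (nonempty).
#' @param stop_end Stop End, ms from Go.
#' @param ssds optional per-trial SSDs aligned with `error_musrts`, used to
#'   compute the per-subset mean SSDs.
#' @param ... metadata (`participant_id`, `condition`, `version`) stored on
#'   the result.
#' @return an object of class `compliance_split` with the two MusRT
#'   subsets, `p_compliant`, and per-subset mean SSDs.
#' @export
split_errors <- function(error_musrts, stop_end, ssds = NULL, ...) {
  if (length(error_musrts) == 0) stop("no Stop Error MusRTs to split")
  stopifnot(is.finite(stop_end))
  if (!is.null(ssds)) stopifnot(length(ssds) == length(error_musrts))
  compliant <- error_musrts < stop_end
  meta <- list(...)
  structure(
    list(
      participant_id = meta$participant_id %||% NA_character_,
      condition = meta$condition %||% NA_character_,
      version = meta$version %||% NA_character_,
      stop_end = stop_end,
      compliant_musrts = error_musrts[compliant],
      noncompliant_musrts = error_musrts[!compliant],
      p_compliant = mean(compliant),
      n_errors = length(error_musrts),
      mean_ssd_compliant = if (is.null(ssds)) NA_real_ else
        mean(ssds[compliant]),
      mean_ssd_noncompliant = if (is.null(ssds)) NA_real_ else
        mean(ssds[!compliant]),
      compliant_ssds = if (is.null(ssds)) NULL else ssds[compliant]
    ),
    class = "compliance_split"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.compliance_split <- function(x, ...) {
  cat(sprintf(
    "<compliance_split> Stop End %.1f ms: %d/%d errors compliant (%.0f%%)\n",
    x$stop_end, length(x$compliant_musrts), x$n_errors, 100 * x$p_compliant
  ))
  invisible(x)
}

#' Independence re-test on the Compliant subset
#'
#' Same contract as [independence_test()], applied to the per-participant
#' mean Compliant Stop Error MusRTs. Participants with an empty compliant
#' subset contribute `NA` means and are excluded pairwise (their ids are
#' reported in `excluded`).
#'
#' @param compliant_means per-participant mean Compliant Stop Error MusRTs.
#' @param no_stop_means per-participant mean No Stop MusRTs, same order.
#' @param alpha significance level.
#' @param participant_ids optional ids used to report exclusions.
#' @return as [independence_test()], plus `excluded`.
#' @export
compliant_independence_retest <- function(compliant_means, no_stop_means,
                                          alpha = 0.05,
                                          participant_ids = NULL) {
  stopifnot(length(compliant_means) == length(no_stop_means))
  keep <- !is.na(compliant_means) & !is.na(no_stop_means)
  excluded <- if (is.null(participant_ids)) which(!keep) else
    participant_ids[!keep]
  res <- independence_test(compliant_means[keep], no_stop_means[keep], alpha)
  res$excluded <- excluded
  res
}

#' SSRT re-estimated from the Compliant Stop Errors
#'
#' In a selective cell the full stop-error rate overstates how often the Go
#' process truly won the first-step race, because restart errors also count
#' as Stop Errors. Using the proportion of Compliant errors, the
#' probability of a genuine race loss is
#' `p_respond = p(stop error) * p(compliant)`, and the integration method
#' applied at that probability re-estimates the first-step SSRT
#' (`method = "integration"`, the default). `method = "mean"` instead
#' applies the mean method to the SSDs of the compliant trials only; it is
#' retained for sensitivity analysis but inherits the selective staircase's
#' below-50% tracking of the first-step race.
#'
#' @param split a [split_errors()] result.
#' @param no_stop_musrts the cell's No Stop MusRTs (same effector), ms.
#' @param p_stop_error the cell's overall stop-error rate (errors / stop
#'   trials, after burn-in).
#' @param mean_ssd_all mean SSD over all the cell's stop trials, ms
#'   (integration method).
#' @param method `"integration"` (default) or `"mean"`.
#' @param min_trials minimum compliant-trial count for a valid mean-method
#'   estimate.
#' @return an `ssrt_estimate` with method tag
#'   `"integration/compliant"` or `"mean/compliant"`.
#' @export
compliant_ssrt <- function(split, no_stop_musrts, p_stop_error = NULL,
                           mean_ssd_all = NULL,
                           method = c("integration", "mean"),
                           min_trials = 20) {
  stopifnot(inherits(split, "compliance_split"))
  method <- match.arg(method)
  if (length(split$compliant_musrts) == 0) {
    stop("empty compliant subset; cannot re-estimate the SSRT")
  }
  meta <- list(participant_id = split$participant_id,
               condition = split$condition, version = split$version)
  if (method == "integration") {
    stopifnot(!is.null(p_stop_error), !is.null(mean_ssd_all))
    p_respond <- p_stop_error * split$p_compliant
    est <- do.call(integration_ssrt,
                   c(list(no_stop_musrts, p_respond, mean_ssd_all), meta))
    est$method <- "integration/compliant"
    est$n_stop_trials <- length(split$compliant_musrts)
    return(est)
  }
  if (is.null(split$compliant_ssds)) {
    stop("mean-method compliant SSRT needs the per-trial SSDs in the split")
  }
  est <- suppressWarnings(do.call(
    mean_method_ssrt,
    c(list(no_stop_musrts, split$compliant_ssds, min_trials), meta)
  ))
  est$method <- "mean/compliant"
  est
}
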