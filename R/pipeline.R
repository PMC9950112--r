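#' Read and write trial tables
#'
#' Trial tables are plain comma-separated text, one row per trial, with the
#' column names produced by [simulate_session()]; missing values are empty
#' fields. `read_trial_table()` validates the schema and names the first
#' missing column in its error.
#'
#' @param trials a trial table.
#' @param path file path.
#' @return `read_trial_table()` returns the trial table;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  required <- c("participant_id", "condition", "trial_index", "trial_type",
                "stop_version", "ssd", "wrist_moved", "foot_moved",
                "wrist_mus_rt", "foot_mus_rt", "wrist_rt", "foot_rt",
                "outcome")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop(sprintf("malformed trial table: missing column '%s'", missing[1]))
  }
  out$wrist_moved <- as.logical(out$wrist_moved)
  out$foot_moved <- as.logical(out$foot_moved)
  out
}

# The no-stop comparator and stop-error MusRT relevant to a cell's race.
# For the non-selective version the race is decided by the earliest
# effector, so both sides use the per-trial minimum; selective versions use
# the to-be-stopped effector.
cell_error_musrts <- function(stop_trials, version) {
  if (version == "stop_both") {
    pmin(stop_trials$wrist_mus_rt, stop_trials$foot_mus_rt, na.rm = TRUE)
  } else if (version == "stop_wrist") {
    stop_trials$wrist_mus_rt
  } else {
    stop_trials$foot_mus_rt
  }
}

no_stop_comparator <- function(no_stop_trials, version) {
  if (version == "stop_both") {
    pmin(no_stop_trials$wrist_mus_rt, no_stop_trials$foot_mus_rt)
  } else if (version == "stop_wrist") {
    no_stop_trials$wrist_mus_rt
  } else {
    no_stop_trials$foot_mus_rt
  }
}

# Correct No Stop trials of a participant x condition
no_stop_of <- function(trials, pid, cond) {
  trials[trials$participant_id == pid & trials$condition == cond &
           trials$trial_type == "no_stop" & trials$outcome == "correct", ,
         drop = FALSE]
}

# Stop trials of a cell, in presentation order, burn-in removed
stop_cell_of <- function(trials, pid, cond, version, burn_in) {
  cell <- trials[trials$participant_id == pid & trials$condition == cond &
                   trials$trial_type == "stop" &
                   trials$stop_version == version, , drop = FALSE]
  drop_burn_in(cell[order(cell$trial_index), , drop = FALSE], burn_in)
}

#' Race-model analysis of a trial table
#'
#' Computes, for every participant x condition x stop version cell: the
#' stop-error rate and mean SSD (after burn-in), the mean Stop Error MusRT,
#' the matching No Stop comparator mean, and SSRT estimates by the mean and
#' integration methods. Group-level independence tests (paired across
#' participants) are run per condition x version, and cells belonging to a
#' violated condition are flagged invalid. Also reports the per-participant
#' wrist-foot coupling correlation and the stop-interference effect of the
#' selective versions.
#'
#' For the non-selective version the race is decided by the earliest
#' effector, so its Stop Error MusRT and No Stop comparator are per-trial
#' minima over the two effectors; selective versions use the to-be-stopped
#' effector.
#'
#' @param trials a trial table (simulated, or read and MusRT-filled).
#' @param alpha significance level of the independence tests.
#' @param burn_in stop trials discarded per cell before averaging
#'   (default 10).
#' @return a list with data frames `cells`, `independence`, `coupling` and
#'   `interference`.
#' @export
analyze_study <- function(trials, alpha = 0.05, burn_in = 10) {
  pids <- unique(trials$participant_id)
  conds <- unique(trials$condition)
  cells <- list()
  for (pid in pids) {
    for (cond in conds) {
      ns <- no_stop_of(trials, pid, cond)
      for (v in stop_versions()) {
        cell <- stop_cell_of(trials, pid, cond, v, burn_in)
        if (nrow(cell) == 0) next
        scored <- cell[cell$outcome != "aborted", , drop = FALSE]
        errs <- scored[scored$outcome == "error", , drop = FALSE]
        cmp <- no_stop_comparator(ns, v)
        p_err <- mean(scored$outcome == "error")
        m_est <- suppressWarnings(mean_method_ssrt(
          cmp, scored$ssd, participant_id = pid, condition = cond,
          version = v
        ))
        i_est <- if (p_err > 0 && p_err < 1) {
          integration_ssrt(cmp, p_err, mean(scored$ssd),
                           participant_id = pid, condition = cond,
                           version = v)
        } else NULL
        cells[[length(cells) + 1L]] <- data.frame(
          participant_id = pid, condition = cond, version = v,
          n_stop = nrow(scored), n_error = nrow(errs), p_error = p_err,
          mean_ssd = mean(scored$ssd),
          error_musrt_mean = if (nrow(errs) > 0)
            mean(cell_error_musrts(errs, v)) else NA_real_,
          no_stop_mean = mean(cmp),
          ssrt_mean = m_est$ssrt,
          ssrt_integration = if (is.null(i_est)) NA_real_ else i_est$ssrt,
          ssrt_valid = m_est$valid,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cells <- do.call(rbind, cells)

  independence <- list()
  for (cond in conds) {
    for (v in unique(cells$version)) {
      sub <- cells[cells$condition == cond & cells$version == v &
                     !is.na(cells$error_musrt_mean), , drop = FALSE]
      if (nrow(sub) < 2) next
      it <- independence_test(sub$error_musrt_mean, sub$no_stop_mean, alpha)
      independence[[length(independence) + 1L]] <- data.frame(
        condition = cond, version = v, n = it$n,
        stop_error_mean = it$stop_error_mean,
        no_stop_mean = it$no_stop_mean,
        t = it$t, df = it$df, p_value = it$p_value,
        direction = it$direction, violated = it$violated,
        stringsAsFactors = FALSE
      )
      if (it$violated) {
        hit <- cells$condition == cond & cells$version == v
        cells$ssrt_valid[hit] <- FALSE
      }
    }
  }
  independence <- do.call(rbind, independence)

  coupling <- list()
  for (pid in pids) {
    for (cond in conds) {
      ns <- no_stop_of(trials, pid, cond)
      if (nrow(ns) < 10) next
      cc <- coupling_correlation(ns$wrist_mus_rt, ns$foot_mus_rt)
      coupling[[length(coupling) + 1L]] <- data.frame(
        participant_id = pid, condition = cond, n = nrow(ns),
        r = cc$r, p_value = cc$p, stringsAsFactors = FALSE
      )
    }
  }
  coupling <- do.call(rbind, coupling)

  interference <- list()
  for (pid in pids) {
    for (cond in conds) {
      ns <- no_stop_of(trials, pid, cond)
      for (v in c("stop_wrist", "stop_foot")) {
        cell <- stop_cell_of(trials, pid, cond, v, burn_in)
        correct <- cell[cell$outcome == "correct", , drop = FALSE]
        if (nrow(correct) == 0) next
        mover_col <- if (v == "stop_wrist") "foot_mus_rt" else "wrist_mus_rt"
        moving <- correct[[mover_col]][!is.na(correct[[mover_col]])]
        ns_same <- if (v == "stop_wrist") ns$foot_mus_rt else ns$wrist_mus_rt
        if (length(moving) == 0 || length(ns_same) == 0) next
        interference[[length(interference) + 1L]] <- data.frame(
          participant_id = pid, condition = cond, version = v,
          n_stop_correct = length(moving),
          delta = interference_effect(moving, ns_same),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  interference <- do.call(rbind, interference)

  list(cells = cells, independence = independence, coupling = coupling,
       interference = interference)
}

#' Compliant / Non-Compliant decomposition of a trial table
#'
#' For every participant x condition x selective version cell, computes the
#' Stop End from the participant's non-selective SSRT of the matching
#' condition and the cell's mean SSD, partitions the Stop Error MusRTs at
#' it, re-tests independence on the compliant subset, re-estimates the
#' SSRT from the compliant proportion, and compares compliant proportions
#' between the Block and Mix conditions with two-proportion z tests
#' (pooled over participants by default, with a per-participant paired t
#' test alongside).
#'
#' Participants whose non-selective SSRT is unavailable or invalid are
#' skipped and listed in `skipped`.
#'
#' @param trials a trial table covering at least one selective version.
#' @param analysis optional result of [analyze_study()] on the same table
#'   (recomputed if omitted).
#' @param alpha significance level.
#' @param burn_in stop trials discarded per cell (default 10).
#' @return a list with data frames `splits` (per-cell decomposition and
#'   compliant SSRT), `retests`, `ztests`, `ssrt_comparison`, and the
#'   character vector `skipped`.
#' @export
decompose_study <- function(trials, analysis = NULL, alpha = 0.05,
                            burn_in = 10) {
  if (is.null(analysis)) analysis <- analyze_study(trials, alpha, burn_in)
  cells <- analysis$cells
  pids <- unique(cells$participant_id)
  conds <- unique(cells$condition)
  splits <- list()
  skipped <- character(0)

  for (pid in pids) {
    for (cond in conds) {
      anchor <- cells[cells$participant_id == pid & cells$condition == cond &
                        cells$version == "stop_both", , drop = FALSE]
      if (nrow(anchor) != 1 || !anchor$ssrt_valid) {
        has_sel <- any(cells$participant_id == pid &
                         cells$condition == cond &
                         cells$version != "stop_both")
        if (has_sel) skipped <- c(skipped, sprintf("%s/%s", pid, cond))
        next
      }
      ns <- no_stop_of(trials, pid, cond)
      for (v in c("stop_wrist", "stop_foot")) {
        cell <- stop_cell_of(trials, pid, cond, v, burn_in)
        scored <- cell[cell$outcome != "aborted", , drop = FALSE]
        errs <- scored[scored$outcome == "error", , drop = FALSE]
        if (nrow(errs) == 0) next
        stop_end <- compute_stop_end(anchor$ssrt_mean, mean(scored$ssd))
        sp <- split_errors(cell_error_musrts(errs, v), stop_end,
                           ssds = errs$ssd, participant_id = pid,
                           condition = cond, version = v)
        cmp <- no_stop_comparator(ns, v)
        p_err <- mean(scored$outcome == "error")
        cs <- if (length(sp$compliant_musrts) > 0 && p_err * sp$p_compliant > 0 &&
                    p_err * sp$p_compliant < 1) {
          compliant_ssrt(sp, cmp, p_stop_error = p_err,
                         mean_ssd_all = mean(scored$ssd))
        } else NULL
        splits[[length(splits) + 1L]] <- data.frame(
          participant_id = pid, condition = cond, version = v,
          stop_end = stop_end, n_errors = sp$n_errors,
          n_compliant = length(sp$compliant_musrts),
          p_compliant = sp$p_compliant,
          compliant_mean = if (length(sp$compliant_musrts) > 0)
            mean(sp$compliant_musrts) else NA_real_,
          noncompliant_mean = if (length(sp$noncompliant_musrts) > 0)
            mean(sp$noncompliant_musrts) else NA_real_,
          mean_ssd_compliant = sp$mean_ssd_compliant,
          mean_ssd_noncompliant = sp$mean_ssd_noncompliant,
          no_stop_mean = mean(cmp),
          compliant_ssrt = if (is.null(cs)) NA_real_ else cs$ssrt,
          nonselective_ssrt = anchor$ssrt_mean,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  splits <- do.call(rbind, splits)
  if (is.null(splits)) {
    return(list(splits = NULL, retests = NULL, ztests = NULL,
                ssrt_comparison = NULL, skipped = skipped))
  }

  retests <- list()
  for (cond in unique(splits$condition)) {
    for (v in unique(splits$version)) {
      sub <- splits[splits$condition == cond & splits$version == v, ,
                    drop = FALSE]
      if (nrow(sub) < 2) next
      rt <- compliant_independence_retest(sub$compliant_mean,
                                          sub$no_stop_mean, alpha,
                                          sub$participant_id)
      retests[[length(retests) + 1L]] <- data.frame(
        condition = cond, version = v, n = rt$n,
        compliant_mean = rt$stop_error_mean, no_stop_mean = rt$no_stop_mean,
        t = rt$t, df = rt$df, p_value = rt$p_value,
        direction = rt$direction, violated = rt$violated,
        n_excluded = length(rt$excluded), stringsAsFactors = FALSE
      )
    }
  }
  retests <- do.call(rbind, retests)

  ztests <- list()
  if (all(c("block", "mix") %in% splits$condition)) {
    for (v in unique(splits$version)) {
      blk <- splits[splits$condition == "block" & splits$version == v, ]
      mix <- splits[splits$condition == "mix" & splits$version == v, ]
      if (nrow(blk) == 0 || nrow(mix) == 0) next
      zt <- proportion_ztest(sum(blk$n_compliant), sum(blk$n_errors),
                             sum(mix$n_compliant), sum(mix$n_errors))
      shared <- intersect(blk$participant_id, mix$participant_id)
      tt <- if (length(shared) >= 2) {
        paired_t(blk$p_compliant[match(shared, blk$participant_id)],
                 mix$p_compliant[match(shared, mix$participant_id)])
      } else NULL
      ztests[[length(ztests) + 1L]] <- data.frame(
        version = v, p_compliant_block = zt$p1, p_compliant_mix = zt$p2,
        z = zt$z, p_value = zt$p,
        t_participants = if (is.null(tt)) NA_real_ else tt$t,
        p_participants = if (is.null(tt)) NA_real_ else tt$p,
        stringsAsFactors = FALSE
      )
    }
  }
  ztests <- do.call(rbind, ztests)

  # Are the compliant selective SSRTs distinguishable from the
  # non-selective ones? Cells are pooled as independent groups per
  # condition (between-groups one-way ANOVA).
  comparisons <- list()
  for (cond in unique(splits$condition)) {
    sub <- splits[splits$condition == cond & !is.na(splits$compliant_ssrt), ]
    nsel <- cells[cells$condition == cond & cells$version == "stop_both" &
                    cells$ssrt_valid, , drop = FALSE]
    if (nrow(sub) < 2 || nrow(nsel) < 2) next
    vals <- c(sub$compliant_ssrt, nsel$ssrt_mean)
    grp <- c(paste(sub$version, "compliant", sep = "_"),
             rep("stop_both", nrow(nsel)))
    aov1 <- oneway_anova(vals, grp)
    comparisons[[length(comparisons) + 1L]] <- cbind(
      data.frame(condition = cond, stringsAsFactors = FALSE), aov1
    )
  }
  ssrt_comparison <- do.call(rbind, comparisons)

  list(splits = splits, retests = retests, ztests = ztests,
       ssrt_comparison = ssrt_comparison, skipped = unique(skipped))
}

#' Run the full synthetic study
#'
#' Simulates a group under the Block and Mix presets, analyses it, and
#' decomposes the selective Stop Errors: simulation, race analysis, and
#' restart decomposition in the order of the empirical workflow. The
#' summary tables are per-cell group means and SDs over participants and
#' are labelled synthetic.
#'
#' @param n_participants number of simulated participants (default 9).
#' @param params a [restart_params()].
#' @param seed integer seed for the whole study.
#' @param n_block_trials,n_mix_trials session lengths (defaults 300 / 600).
#' @param alpha significance level.
#' @return a list with the `trials` table, the [analyze_study()] result
#'   (`analysis`), the [decompose_study()] result (`decomposition`), and
#'   group `summary` tables (`musrt`, `ssrt`, `ssd_by_compliance`).
#' @export
run_full_study <- function(n_participants = 9, params = restart_params(),
                           seed = NULL, n_block_trials = 300,
                           n_mix_trials = 600, alpha = 0.05) {
  trials <- simulate_group(n_participants, params, seed = seed,
                           n_block_trials = n_block_trials,
                           n_mix_trials = n_mix_trials)
  analysis <- analyze_study(trials, alpha = alpha)
  decomposition <- decompose_study(trials, analysis, alpha = alpha)

  msd <- function(x) sprintf("%.0f (± %.0f) ms", mean(x, na.rm = TRUE),
                             stats::sd(x, na.rm = TRUE))
  # No Stop MusRT per effector and condition (synthetic analogue of the
  # descriptive group table)
  ns <- trials[trials$trial_type == "no_stop" & trials$outcome == "correct", ]
  agg <- stats::aggregate(
    cbind(wrist_mus_rt, foot_mus_rt) ~ participant_id + condition,
    data = ns, FUN = mean
  )
  musrt <- do.call(rbind, lapply(split(agg, agg$condition), function(d) {
    data.frame(condition = d$condition[1],
               wrist_musrt = msd(d$wrist_mus_rt),
               foot_musrt = msd(d$foot_mus_rt),
               stringsAsFactors = FALSE)
  }))
  rownames(musrt) <- NULL

  cells <- analysis$cells
  ssrt <- do.call(rbind, lapply(
    split(cells, list(cells$condition, cells$version)), function(d) {
      if (nrow(d) == 0) return(NULL)
      data.frame(
        condition = d$condition[1], version = d$version[1],
        ssrt = if (all(d$ssrt_valid)) msd(d$ssrt_mean) else "not respected",
        stringsAsFactors = FALSE
      )
    }
  ))
  rownames(ssrt) <- NULL

  sp <- decomposition$splits
  ssd_by_compliance <- if (!is.null(sp)) {
    out <- do.call(rbind, lapply(
      split(sp, list(sp$condition, sp$version)), function(d) {
        if (nrow(d) == 0) return(NULL)
        data.frame(
          condition = d$condition[1], version = d$version[1],
          ssd_compliant = msd(d$mean_ssd_compliant),
          ssd_noncompliant = msd(d$mean_ssd_noncompliant),
          stringsAsFactors = FALSE
        )
      }
    ))
    rownames(out) <- NULL
    out
  } else NULL

  list(
    trials = trials, analysis = analysis, decomposition = decomposition,
    summary = list(label = "synthetic", musrt = musrt, ssrt = ssrt,
                   ssd_by_compliance = ssd_by_compliance)
  )
}
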