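test_that("Stop End is the non-selective SSRT plus the selective mean SSD", {
  expect_equal(compute_stop_end(150, 300), 450)
  expect_equal(compute_stop_end(0, 280), 280)
  est <- mean_method_ssrt(rep(450, 30), rep(300, 30))
  expect_equal(compute_stop_end(est, 310), 460)
  est$valid <- FALSE
  expect_error(compute_stop_end(est, 310), "invalid")
})

test_that("simulated Stop End sits near the latent stop completion", {
  # averaged over sessions to quiet the staircase's random-walk noise in a
  # single cell's mean SSD
  errs <- sapply(1:5, function(i) {
    s <- quick_mix_trials(n_trials = 4000, seed = 40 + i)
    cell_b <- stop_cell(s, "stop_both")
    cell_b <- cell_b[cell_b$outcome != "aborted", ]
    ns <- s[s$trial_type == "no_stop" & s$outcome == "correct", ]
    ssrt_b <- mean_method_ssrt(pmin(ns$wrist_mus_rt, ns$foot_mus_rt),
                               cell_b$ssd)
    cell_w <- stop_cell(s, "stop_wrist")
    cell_w <- cell_w[cell_w$outcome != "aborted", ]
    se <- compute_stop_end(ssrt_b, mean(cell_w$ssd))
    se - (mean(cell_w$ssd) + 150)
  })
  expect_lt(abs(mean(errs)), 15)
})

test_that("the split partitions errors strictly at the Stop End", {
  sp <- split_errors(c(340, 350, 360), stop_end = 450, ssds = c(300, 310, 320))
  expect_equal(sp$p_compliant, 1)
  expect_equal(sp$mean_ssd_compliant, 310)
  # exact ties are Non-Compliant
  sp2 <- split_errors(c(440, 450, 460), stop_end = 450)
  expect_equal(sort(sp2$noncompliant_musrts), c(450, 460))
  expect_equal(sp2$compliant_musrts, 440)
  expect_error(split_errors(numeric(0), 450), "no Stop Error")
})

test_that("the partition conserves every error and is monotone in the Stop End", {
  set.seed(42)
  mus <- rexgauss(200, 410, 70, 40)
  prev <- -1
  for (se in c(300, 400, 450, 500, 700)) {
    sp <- split_errors(mus, se)
    expect_equal(length(sp$compliant_musrts) + length(sp$noncompliant_musrts),
                 200)
    expect_gte(sp$p_compliant, prev)
    prev <- sp$p_compliant
    if (length(sp$compliant_musrts) > 0) {
      expect_true(all(sp$compliant_musrts < se))
    }
    if (length(sp$noncompliant_musrts) > 0) {
      expect_true(all(sp$noncompliant_musrts >= se))
    }
  }
})

test_that("pooled z test matches the chi-square oracle and flags clear differences", {
  expect_equal(proportion_ztest(40, 100, 80, 200)$z, 0)
  res <- proportion_ztest(82, 100, 64, 100)
  # oracle: Pearson chi-square without continuity correction equals z^2
  chi <- suppressWarnings(
    stats::prop.test(c(82, 64), c(100, 100), correct = FALSE)
  )
  expect_equal(res$z^2, unname(chi$statistic), tolerance = 1e-10)
  expect_lt(res$p, 0.01)
  expect_gt(res$z, 2.8)
  # extreme separation
  ext <- proportion_ztest(500, 500, 0, 500)
  expect_gt(abs(ext$z), 20)
  expect_lt(ext$p, 1e-10)
  expect_error(proportion_ztest(11, 10, 5, 10), "exceed")
})

test_that("compliant labels are pure and restart errors are caught, at long restart delays", {
  # with restart_delay_mean >= 200 ms, restart errors finish well after the
  # Stop End: nearly every compliant-labelled error is a latent first-step
  # race loss, and nearly every latent restart error is labelled
  # non-compliant
  s <- quick_mix_trials(n_trials = 4000, seed = 43)
  d <- decompose_study(s)
  for (v in c("stop_wrist", "stop_foot")) {
    cell <- stop_cell(s, v)
    errs <- cell[cell$outcome == "error", ]
    se <- d$splits$stop_end[d$splits$version == v]
    mus <- if (v == "stop_wrist") errs$wrist_mus_rt else errs$foot_mus_rt
    comp <- mus < se
    lab <- errs$step_label
    expect_gt(mean(lab[comp] == "first_step_error"), 0.9)
    expect_gt(mean(!comp[lab == "restart_error"]), 0.9)
  }
})

test_that("compliant subset re-test restores independence in the mix context", {
  set.seed(44)
  g <- simulate_group(9, restart_preset("mix"), seed = 44,
                      n_block_trials = 0, n_mix_trials = 2000)
  a <- analyze_study(g)
  viol <- a$independence[a$independence$version != "stop_both", ]
  expect_true(all(viol$violated))
  both <- a$independence[a$independence$version == "stop_both", ]
  expect_false(any(both$violated))
  d <- decompose_study(g, a)
  expect_false(any(d$retests$violated))
  expect_true(all(d$retests$direction == "error_faster"))
})

test_that("compliant SSRT equals the full-cell integration estimate when all errors comply", {
  set.seed(45)
  mus <- rexgauss(500, 410, 70, 40)
  sp <- split_errors(c(300, 320, 340), stop_end = 1000,
                     ssds = c(250, 300, 350))
  cs <- compliant_ssrt(sp, mus, p_stop_error = 0.5, mean_ssd_all = 300)
  full <- integration_ssrt(mus, 0.5, 300)
  expect_equal(cs$ssrt, full$ssrt)
  expect_equal(cs$method, "integration/compliant")
})

test_that("mean-method compliant SSRT flags small compliant subsets invalid", {
  sp <- split_errors(c(300, 320, 340), stop_end = 1000,
                     ssds = c(250, 300, 350))
  cs <- compliant_ssrt(sp, rep(450, 30), method = "mean")
  expect_false(cs$valid)
  expect_equal(cs$method, "mean/compliant")
  expect_equal(cs$ssrt, 450 - 300)
})

test_that("participants with an empty compliant subset are excluded from the re-test", {
  res <- compliant_independence_retest(
    c(400, NA, 420, 410), c(470, 480, 460, 465),
    participant_ids = c("p1", "p2", "p3", "p4")
  )
  expect_equal(res$excluded, "p2")
  expect_equal(res$n, 3)
  expect_equal(res$direction, "error_faster")
})
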