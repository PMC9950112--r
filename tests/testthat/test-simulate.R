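test_that("zero effector noise makes the foot lag the wrist by exactly the offset", {
  set.seed(1)
  go <- sample_go_latencies(200, deterministic_params())
  expect_equal(go$foot - go$wrist, rep(46, 200))
})

test_that("effector coupling matches the variance-ratio prediction", {
  # shared variance sigma^2 + tau^2 = 6400, effector noise variance 625:
  # Pearson r should be 6400 / 7025 ~ 0.911
  set.seed(2)
  p <- restart_params(go_sigma = 60, go_tau = sqrt(6400 - 60^2),
                      effector_noise_sd = 25)
  go <- sample_go_latencies(1e5, p)
  expect_equal(cor(go$wrist, go$foot), 6400 / 7025, tolerance = 0.01 / 0.911)
})

test_that("mean foot-wrist lag matches the configured offset", {
  set.seed(3)
  go <- sample_go_latencies(1e5, restart_params())
  expect_equal(mean(go$foot) - mean(go$wrist), 46, tolerance = 1 / 46)
})

test_that("a guaranteed trigger failure resolves as a race-free Go trial", {
  set.seed(4)
  p <- restart_params(p_trigger_fail = 1)
  tr <- simulate_stop_trial(p, ssd = 300, version = "stop_both",
                            condition = "block")
  expect_equal(tr$step_label, "trigger_fail")
  expect_equal(unname(tr$mus_rt), unname(tr$latent_go))
  expect_true(is.na(tr$latent_stop_finish))
})

test_that("the deterministic limit exposes the restart cost", {
  # stop finishes well before the go processes, the restart is
  # deterministic and slower than the go finish: the moving effector's
  # onset is exactly ssd + stop_mean + restart_delay
  set.seed(5)
  p <- deterministic_params(go_mu = 400, go_sigma = 1e-3, go_tau = 1e-3,
                            restart_delay_mean = c(block = 120, mix = 400))
  tr <- simulate_stop_trial(p, ssd = 100, version = "stop_wrist",
                            condition = "mix")
  expect_equal(tr$step_label, "stop_success")
  expect_true(is.na(tr$mus_rt[["wrist"]]))
  expect_equal(tr$mus_rt[["foot"]], 100 + 150 + 400)
})

test_that("a race lost on both effectors is a first-step error at the go finishes", {
  set.seed(6)
  p <- restart_params(stop_mean = 5000, stop_sd = 0, p_trigger_fail = 0)
  tr <- simulate_stop_trial(p, ssd = 0, version = "stop_both",
                            condition = "block")
  expect_equal(tr$step_label, "first_step_error")
  expect_equal(unname(tr$mus_rt), unname(tr$latent_go))
})

test_that("decoupling failure restarts both effectors together", {
  set.seed(7)
  p <- deterministic_params(go_mu = 400, go_sigma = 1e-3, go_tau = 1e-3,
                            p_decouple_fail = 1,
                            restart_delay_mean = c(block = 120, mix = 400))
  tr <- simulate_stop_trial(p, ssd = 200, version = "stop_wrist",
                            condition = "block")
  expect_equal(tr$step_label, "restart_error")
  expect_equal(tr$mus_rt[["wrist"]], tr$mus_rt[["foot"]])
  expect_equal(tr$mus_rt[["wrist"]], 200 + 150 + 120)
})

test_that("a simulated Block session has the exact design fractions", {
  cfg <- session_config(300, "block", "stop_both")
  s <- simulate_session(cfg, restart_params(), seed = 11)
  expect_equal(sum(s$trial_type == "no_stop"), 210)
  expect_equal(sum(s$trial_type == "stop"), 90)
})

test_that("the same seed reproduces the session exactly", {
  cfg <- session_config(300, "mix")
  a <- simulate_session(cfg, restart_params(), seed = 12)
  b <- simulate_session(cfg, restart_params(), seed = 12)
  expect_identical(a, b)
})

test_that("step labels partition the stop trials and match the latent times", {
  s <- quick_mix_trials(seed = 13)
  stopped <- s[s$trial_type == "stop", ]
  expect_true(all(stopped$step_label %in%
                    c("first_step_error", "restart_error", "stop_success",
                      "trigger_fail")))
  expect_true(all(s$step_label[s$trial_type == "no_stop"] == "no_stop"))
  # first-step errors respond at their latent go finish
  fse <- stopped[stopped$step_label == "first_step_error", ]
  moved_w <- fse[fse$wrist_moved, ]
  expect_equal(moved_w$wrist_mus_rt, moved_w$latent_go_wrist)
  # restart errors respond after the latent stop finish
  re <- stopped[stopped$step_label == "restart_error", ]
  re_mus <- pmin(re$wrist_mus_rt, re$foot_mus_rt, na.rm = TRUE)
  expect_true(all(re_mus > re$latent_stop_finish))
})

test_that("muscle onsets precede overt movement by the electromechanical delay", {
  s <- quick_mix_trials(seed = 14)
  w <- s[s$wrist_moved, ]
  f <- s[s$foot_moved, ]
  expect_true(all(w$wrist_rt > w$wrist_mus_rt))
  expect_true(all(f$foot_rt > f$foot_mus_rt))
  expect_equal(mean(w$wrist_rt - w$wrist_mus_rt), 90, tolerance = 0.05)
  expect_equal(mean(f$foot_rt - f$foot_mus_rt), 140, tolerance = 0.05)
})

test_that("session staircases converge to 50% stop errors per version", {
  s <- quick_mix_trials(n_trials = 4000, seed = 15)
  for (v in stop_versions()) {
    cell <- stop_cell(s, v)
    cell <- cell[cell$outcome != "aborted", ]
    expect_equal(mean(cell$outcome == "error"), 0.5, tolerance = 0.05 / 0.5)
  }
})

test_that("group simulation individualises participants deterministically", {
  g1 <- simulate_group(3, restart_preset("mix"), seed = 16,
                       n_block_trials = 0, n_mix_trials = 100)
  g2 <- simulate_group(3, restart_preset("mix"), seed = 16,
                       n_block_trials = 0, n_mix_trials = 100)
  expect_identical(g1, g2)
  expect_equal(length(unique(g1$participant_id)), 3)
  means <- tapply(g1$latent_go_wrist, g1$participant_id, mean)
  expect_gt(max(means) - min(means), 1)  # participants genuinely differ
})
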