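test_that("mean-method SSRT is the mean No Stop latency minus the mean SSD", {
  est <- mean_method_ssrt(rep(464, 30), rep(310, 30))
  expect_equal(est$ssrt, 154)
  expect_true(est$valid)
  expect_equal(mean_method_ssrt(rep(500, 25), rep(500, 25))$ssrt, 0)
})

test_that("mean-method SSRT is translation equivariant", {
  set.seed(31)
  mus <- rexgauss(200, 410, 70, 40)
  ssd <- runif(50, 200, 400)
  base <- mean_method_ssrt(mus, ssd)$ssrt
  for (c in c(-50, 25, 100)) {
    expect_equal(mean_method_ssrt(mus + c, ssd)$ssrt, base + c)
  }
})

test_that("too few stop trials flag the estimate invalid", {
  expect_warning(est <- mean_method_ssrt(rep(450, 30), rep(300, 5)),
                 "invalid")
  expect_false(est$valid)
})

test_that("integration SSRT uses the responding quantile of the No Stop distribution", {
  mus <- seq(400, 500, length.out = 101)  # uniform grid: quantiles exact
  expect_equal(integration_ssrt(mus, 0.5, 300)$ssrt, 150)
  # p near 0 with the SSD at the distribution minimum: SSRT near 0
  expect_lt(abs(integration_ssrt(mus, 0.001, 400)$ssrt), 0.5)
  expect_error(integration_ssrt(rep(450, 30), 0.5, 300), "degenerate")
})

test_that("mean and integration methods agree on converged staircase data", {
  s <- quick_mix_trials(n_trials = 4000, seed = 32,
                        params = restart_preset("block"))
  cell <- stop_cell(s, "stop_both")
  cell <- cell[cell$outcome != "aborted", ]
  ns <- s[s$trial_type == "no_stop" & s$outcome == "correct", ]
  cmp <- pmin(ns$wrist_mus_rt, ns$foot_mus_rt)
  m <- mean_method_ssrt(cmp, cell$ssd)$ssrt
  i <- integration_ssrt(cmp, mean(cell$outcome == "error"),
                        mean(cell$ssd))$ssrt
  expect_lt(abs(m - i), 10)
})

test_that("identical paired means give t = 0 and no violation", {
  x <- c(450, 470, 430, 500, 480)
  res <- independence_test(x, x)
  expect_equal(res$t, 0)
  expect_false(res$violated)
  res2 <- independence_test(rep(450, 5), rep(450, 5))
  expect_equal(res2$t, 0)
})

test_that("systematically slower errors violate independence, confirmed by a permutation oracle", {
  set.seed(33)
  ns_means <- rnorm(9, 470, 40)
  err_means <- ns_means + 100 + rnorm(9, 0, 30)
  res <- independence_test(err_means, ns_means)
  expect_equal(res$direction, "error_slower")
  expect_lt(res$p_value, 0.01)
  expect_true(res$violated)
  # exhaustive sign-flip permutation of the paired differences
  d <- err_means - ns_means
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm_means <- signs %*% d / n
  p_perm <- mean(abs(perm_means) >= abs(mean(d)))
  expect_lt(p_perm, 0.01)
})

test_that("independence direction follows the sign of the difference", {
  ns_means <- c(470, 480, 460, 455, 490, 500, 430, 470, 480)
  res <- independence_test(ns_means - 50, ns_means)
  expect_equal(res$direction, "error_faster")
  expect_false(res$violated)
  expect_error(independence_test(450, 470), "at least 2")
})

test_that("interference is zero for identical samples and nonnegative without a restart stage", {
  x <- rnorm(100, 470, 50)
  expect_equal(interference_effect(x, x), 0)
  # no restart delay, instantaneous stop: the moving effector can only be
  # delayed, never sped up
  set.seed(34)
  p <- deterministic_params(restart_delay_mean = 0)
  s <- simulate_session(session_config(800, "block", "stop_wrist"), p,
                        seed = 34)
  cell <- stop_cell(s, "stop_wrist")
  correct <- cell[cell$outcome == "correct" & !is.na(cell$foot_mus_rt), ]
  ns <- s[s$trial_type == "no_stop" & s$outcome == "correct", ]
  delta <- interference_effect(correct$foot_mus_rt, ns$foot_mus_rt)
  expect_gte(delta, 0)
  # and bounded by the stop residual: stop_mean at most, since the restart
  # itself is free
  expect_lte(delta, 150 + 25)
})

test_that("the simulated restart delay surfaces in the interference effect", {
  set.seed(35)
  p <- restart_preset("mix")  # restart delay 400 ms
  s <- simulate_session(session_config(2000, "mix"), p, seed = 35)
  cell <- stop_cell(s, "stop_wrist")
  correct <- cell[cell$outcome == "correct" & !is.na(cell$foot_mus_rt), ]
  ns <- s[s$trial_type == "no_stop" & s$outcome == "correct", ]
  delta <- interference_effect(correct$foot_mus_rt, ns$foot_mus_rt)
  # latent-truth replay: a correct trial's moving effector either escaped
  # the first step (onset = its go finish) or restarted at the stop finish
  # plus the mean restart delay
  predicted <- ifelse(
    correct$latent_go_foot < correct$latent_stop_finish,
    correct$latent_go_foot, correct$latent_stop_finish + 400
  )
  expected <- mean(predicted) - mean(ns$foot_mus_rt)
  expect_lt(abs(delta - expected), 25)
})

test_that("perfectly coupled effectors correlate at 1, independent ones near 0", {
  w <- rexgauss(100, 410, 70, 40)
  expect_equal(coupling_correlation(w, w + 46)$r, 1)
  set.seed(36)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(coupling_correlation(a, b)$r), 0.1)
})

test_that("coupling strength tracks the shared-variance prediction", {
  set.seed(37)
  p <- restart_params(go_sigma = 60, go_tau = sqrt(6400 - 60^2),
                      effector_noise_sd = 25)
  go <- sample_go_latencies(5000, p)
  r <- coupling_correlation(go$wrist, go$foot)$r
  expect_equal(r, 6400 / 7025, tolerance = 0.1 / 0.911)
})
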