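test_that("the psychometric function has the right floor, midpoint and ceiling", {
  p <- observer_params(threshold = 0.45, slope = 0.1,
                       guess_rate = 0.02, lapse_rate = 0.03)
  expect_equal(psychometric_p(0.45, p), 0.02 + (1 - 0.02 - 0.03) / 2)
  expect_equal(psychometric_p(0, p), 0.02)            # control -> guess rate
  expect_equal(psychometric_p(1e-9, p), 0.02, tolerance = 1e-6)
  expect_equal(psychometric_p(1e9, p), 1 - 0.03, tolerance = 1e-6)
  expect_error(observer_params(threshold = 0, slope = 1), "threshold")
  expect_error(observer_params(0.4, 0.1, guess_rate = 0.5), "guess")
})

test_that("simulation is reproducible and honours the step-observer limit", {
  d <- simulation_design("resolution", n_individuals = 6)
  pars <- resolution_observer()
  s1 <- simulate_trials(d, pars, seed = 99)
  s2 <- simulate_trials(d, pars, seed = 99)
  expect_identical(s1$trials, s2$trials)
  s3 <- simulate_trials(d, pars, seed = 100)
  expect_false(identical(s1$trials, s3$trials))
  # near-step observer with no guess/lapse: responds iff level > theta
  step <- observer_params(threshold = 0.45, slope = 1e-6, guess_rate = 0,
                          lapse_rate = 0, individual_sd = 0)
  sim <- simulate_trials(d, step, seed = 5)
  tab <- build_response_table(sim$trials, sim$manifest, "resolution")
  expect_true(all(tab$k[tab$level > 0.45] == tab$n[tab$level > 0.45]))
  expect_true(all(tab$k[tab$level <= 0.45] == 0))
  # zero guess rate -> control never responds at any n
  expect_equal(tab$k[tab$is_control], 0L)
})

test_that("simulated response frequencies converge to the psychometric function", {
  pars <- observer_params(threshold = 0.45, slope = 0.15, individual_sd = 0)
  d <- simulation_design("resolution", levels = c(0.3, 0.45, 1.6),
                         n_individuals = 2500, repeats = 2)
  sim <- simulate_trials(d, pars, seed = 8)
  tab <- build_response_table(sim$trials, sim$manifest, "resolution")
  for (lev in d$levels) {
    p_true <- psychometric_p(lev, pars)
    p_obs <- tab$p_hat[tab$level == lev]
    se <- sqrt(p_true * (1 - p_true) / 5000)
    expect_lt(abs(p_obs - p_true), 4 * se + 1e-9)
  }
  expect_lt(abs(tab$p_hat[tab$is_control] - pars$guess_rate),
            4 * sqrt(0.02 * 0.98 / 5000))
})

test_that("simulated event sequences follow the ethogram ordering and the loom timeline", {
  d <- simulation_design("resolution", n_individuals = 8)
  sim <- simulate_trials(d, resolution_observer(), seed = 21)
  tr <- sim$trials
  sev <- match(tr$event_category, transition_categories())
  key <- interaction(tr[c("individual_id", "stimulus_id", "repeat_index")],
                     drop = TRUE)
  for (k in split(seq_len(nrow(tr)), key)) {
    s <- sev[k]; t <- tr$event_time_s[k]
    expect_true(all(diff(s[!is.na(s)]) > 0))    # severity strictly escalates
    expect_true(all(diff(t[!is.na(t)]) > 0))
    expect_true(all(t[!is.na(t)] <= 5))
  }
  # full withdrawals appear only in responding trials
  resp <- trial_responses(tr)
  full <- tr[!is.na(tr$event_category) &
               grepl("^full", tr$event_category), ]
  keyf <- paste(full$individual_id, full$stimulus_id, full$repeat_index)
  keyr <- paste(resp$individual_id, resp$stimulus_id, resp$repeat_index)
  expect_true(all(keyf %in% keyr[resp$response]))
  # non-responders carry no re-emergence time, responders always do
  expect_true(all(is.na(resp$reemergence_s[!resp$response])))
  expect_true(all(!is.na(resp$reemergence_s[resp$response])))
})

test_that("monotone generators yield strong rank correlations and rising re-emergence", {
  # the gradual contrast observer gives near-perfect rank ordering; the steep
  # resolution observer saturates at ceiling, where ties keep rho lower
  res <- simulate_experiment("contrast", seed = 12)
  expect_gt(res$analysis$spearman_response$rho, 0.9)
  reem <- res$analysis$reemergence
  reem <- reem[reem$level > 0 & reem$n_obs >= 3, ]
  fit <- cor(log(reem$level), reem$reemergence_s, method = "spearman")
  expect_gt(fit, 0.5)
})

test_that("threshold recovery identifies the smallest designed level above theta", {
  d <- simulation_design("resolution")
  pars <- resolution_observer()
  sim <- simulate_trials(d, pars, seed = 31)
  rec <- recover_threshold(sim, d, pars)
  expect_equal(rec$expected_level, 0.53)
  expect_true(rec$recovered)
  # theta above the series maximum -> no-threshold outcome expected
  hi <- resolution_observer(threshold = 5, guess_rate = 0.01)
  sim_hi <- simulate_trials(d, hi, seed = 31)
  rec_hi <- recover_threshold(sim_hi, d, hi)
  expect_true(is.na(rec_hi$expected_level))
})
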