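test_that("noiseless construction hits baseline and minimum exactly", {
  sim <- simulate_session(default_noiseless(), seed = 1)
  tr <- session_channel(sim$session, "smo2_pct")
  expect_equal(mean(tr$values[tr$times < 0]), 65, tolerance = 0)
  expect_equal(min(tr$values), 30, tolerance = 0)
  expect_equal(tr$times[which.min(tr$values)], 500)
  # the ramp-start sample is continuous with the rest period
  expect_equal(tr$values[tr$times == 0], 65)
})

test_that("identical seeds give bit-identical sessions", {
  a <- simulate_session(kinetics_params(), seed = 7)
  b <- simulate_session(kinetics_params(), seed = 7)
  expect_identical(a, b)
  c <- simulate_session(kinetics_params(), seed = 8)
  expect_false(identical(a$session, c$session))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_session(kinetics_params(), seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("exponential recovery obeys the tau*ln(2) half-time closed form", {
  sim <- simulate_session(default_noiseless(reoxy_tau_s = 30), seed = 1)
  tr <- session_channel(sim$session, "smo2_pct")
  tmin <- tr$times[which.min(tr$values)]
  # raw-trace crossing of the true half level, independent of the
  # feature-extraction code path
  half <- 30 + 0.5 * (max(tr$values[tr$times > tmin]) - 30)
  after <- which(tr$times > tmin)
  i <- after[tr$values[after] >= half][1]
  t_cross <- tr$times[i - 1] +
    (half - tr$values[i - 1]) / (tr$values[i] - tr$values[i - 1])
  expect_equal(t_cross - tmin, 30 * log(2), tolerance = 0.01)
})

test_that("invalid kinetics parameters are rejected naming the invariant", {
  expect_error(kinetics_params(min_smo2 = 70, baseline_smo2 = 65),
               "min_smo2")
  expect_error(kinetics_params(max_smo2 = 20), "max_smo2")
  expect_error(kinetics_params(reoxy_tau_s = 0), "reoxy_tau_s")
  expect_error(kinetics_params(noise_sd = -1), "noise_sd")
  expect_error(kinetics_params(exhaustion_time_s = -5), "exhaustion_time_s")
})

test_that("SmO2 stays in [0, 100] and the grid is uniform", {
  sim <- simulate_session(kinetics_params(noise_sd = 25), seed = 11)
  tr <- session_channel(sim$session, "smo2_pct")
  expect_true(all(tr$values >= 0 & tr$values <= 100))
  expect_true(all(diff(tr$times) > 0))
  expect_equal(trace_rate(tr), 1)
  sim4 <- simulate_session(kinetics_params(sample_rate_hz = 4), seed = 2)
  expect_equal(trace_rate(session_channel(sim4$session, "smo2_pct")), 4)
})

test_that("raising the reoxygenation asymptote raises the extracted overshoot", {
  ov <- vapply(c(67, 70, 73, 76), function(mx) {
    sim <- simulate_session(default_noiseless(max_smo2 = mx), seed = 1)
    ft <- compute_features(session_channel(sim$session, "smo2_pct"),
                           sim$session$protocol,
                           sim$session$exhaustion_time_s, cutoff_hz = NULL)
    ft$overshoot_pct
  }, numeric(1))
  expect_true(all(diff(ov) > 0))
})

test_that("ground truth is internally consistent with the parameters", {
  p <- kinetics_params(baseline_smo2 = 60, min_smo2 = 25, max_smo2 = 72)
  tr <- simulate_session(p, seed = 1)$truth
  expect_equal(tr$delta_deoxy_pct, 60 - 25)
  expect_equal(tr$half_level_pct, 25 + 0.5 * (tr$max_pct - 25))
  expect_equal(tr$overshoot_pct, tr$max_pct - 60)
  expect_equal(tr$vo2peak_rel_mLkgmin, 1000 * tr$vo2peak_Lmin / 80)
})

test_that("VO2 and HR freeze at exhaustion and follow stage power", {
  sim <- simulate_session(default_noiseless(), seed = 1)
  vo2 <- session_channel(sim$session, "vo2_Lmin")
  post <- vo2$values[vo2$times >= 500]
  expect_true(all(post == post[1]))
  # mid-ramp stage: t = 250 s lies in the stage at 25 + 5*floor(250/20) W
  expect_equal(vo2$values[vo2$times == 250], 0.4 + 0.010 * 85)
})
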