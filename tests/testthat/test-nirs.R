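test_that("baseline is the plain mean of the pre-rest window", {
  tr <- phys_trace(-180:180, c(rep(65, 180), rep(40, 181)), "smo2_pct", "%")
  expect_equal(compute_baseline(tr), 65)
  alt <- phys_trace(-180:-1, rep(c(60, 70), 90))
  expect_equal(compute_baseline(alt), 65)
  late <- phys_trace(0:100, rnorm(101))
  expect_error(compute_baseline(late), "pre-rest")
})

test_that("a unique V-shaped minimum is found at its vertex", {
  t <- -180:960
  v <- ifelse(t <= 0, 65,
       ifelse(t <= 480, 65 - 35 * t / 480, 30 + 40 * (t - 480) / 480))
  tr <- phys_trace(t, v, "smo2_pct", "%")
  m <- find_smo2_min(tr, 480)
  expect_equal(m$value, 30)
  expect_equal(m$time_s, 480)
  expect_false(m$degenerate)
})

test_that("the last local minimum before reoxygenation onset wins", {
  # dip to 32 at 300 s, brief (<30 s) bump, deeper dip to 30 at 500 s
  t <- -60:800
  v <- stats::approx(
    x = c(-60, 0, 300, 320, 500, 800),
    y = c(65, 65, 32, 36, 30, 70), xout = t)$y
  tr <- phys_trace(t, v, "smo2_pct", "%")
  m <- find_smo2_min(tr, 500)
  expect_equal(m$value, 30)
  expect_equal(m$time_s, 500)
})

test_that("minimum landmark matches an exhaustive brute-force scan", {
  set.seed(21)
  for (i in 1:60) {
    tr <- random_smo2_trace(n_pre = sample(30:90, 1),
                            n_down = sample(150:400, 1),
                            n_up = sample(60:300, 1),
                            noise = runif(1, 0, 2))
    trf <- lowpass_filter(tr)
    got <- find_smo2_min(trf, max(trf$times))
    want <- brute_smo2_min(trf$times, trf$values)
    expect_identical(got$value, want$value)
    expect_identical(got$time_s, want$time_s)
  }
})

test_that("degenerate and out-of-range inputs are flagged", {
  flat <- phys_trace(-10:100, rep(50, 111))
  expect_warning(m <- find_smo2_min(flat, 50), "flat")
  expect_true(m$degenerate)
  expect_equal(m$value, 50)
  tr <- random_smo2_trace()
  expect_error(find_smo2_min(tr, 1e6), "outside the trace span")
})

test_that("noiseless landmark arithmetic follows the definitions", {
  # tau = 20 s: the recovery asymptote is reached to <1e-9 within the
  # 8-min window, so the derived fields take their nominal values
  sim <- simulate_session(default_noiseless(reoxy_tau_s = 20), seed = 1)
  s <- sim$session
  ft <- compute_features(session_channel(s, "smo2_pct"), s$protocol,
                         s$exhaustion_time_s, cutoff_hz = NULL)
  expect_equal(ft$delta_deoxy_pct, 35)
  expect_equal(ft$half_level_pct, 50, tolerance = 1e-9)
  expect_equal(ft$delta_half_pct, 20, tolerance = 1e-9)
  expect_equal(ft$overshoot_pct, 5, tolerance = 1e-9)
  expect_equal(ft$slope_deoxy_pct_per_min, 35 / (500 / 60))
  expect_equal(ft$t_half_s, 20 * log(2), tolerance = 0.01)
  expect_equal(ft$slope_half_pct_per_min, 20 / (20 * log(2) / 60),
               tolerance = 0.01)
})

test_that("identity chain holds exactly on noisy extractions", {
  for (seed in 1:5) {
    sim <- simulate_session(kinetics_params(), seed = seed)
    s <- sim$session
    ft <- compute_features(session_channel(s, "smo2_pct"), s$protocol,
                           s$exhaustion_time_s)
    expect_identical(ft$delta_deoxy_pct, ft$baseline_pct - ft$min_pct)
    expect_equal(ft$half_level_pct - ft$min_pct,
                 0.5 * (ft$max_pct - ft$min_pct), tolerance = 1e-12)
    expect_identical(ft$overshoot_pct, ft$max_pct - ft$baseline_pct)
    expect_identical(ft$delta_half_pct, ft$half_level_pct - ft$min_pct)
  }
})

test_that("slower reoxygenation strictly lengthens the extracted half-time", {
  th <- vapply(c(20, 30, 45, 60, 90), function(tau) {
    sim <- simulate_session(default_noiseless(reoxy_tau_s = tau), seed = 1)
    s <- sim$session
    compute_features(session_channel(s, "smo2_pct"), s$protocol,
                     s$exhaustion_time_s, cutoff_hz = NULL)$t_half_s
  }, numeric(1))
  expect_true(all(diff(th) > 0))
})

test_that("a never-recovering signal flags t_half as missing", {
  # SmO2 keeps falling after exhaustion: no reoxygenation, no half level
  t <- -120:700
  v <- stats::approx(x = c(-120, 0, 300, 700), y = c(65, 65, 40, 20),
                     xout = t)$y
  tr <- phys_trace(t, v, "smo2_pct", "%")
  ft <- compute_features(tr, ramp_protocol(), 300, cutoff_hz = NULL)
  expect_true(is.na(ft$t_half_s))
  expect_true(is.na(ft$slope_half_pct_per_min))
  expect_true(attr(ft, "t_half_missing"))
  expect_false(is.na(ft$baseline_pct))
  expect_false(is.na(ft$min_pct))
})

test_that("irregular sampling is resampled before filtering", {
  set.seed(8)
  t <- sort(runif(900, -180, 700))
  v <- stats::approx(x = c(-180, 0, 500, 700), y = c(65, 65, 30, 68),
                     xout = t)$y
  tr <- phys_trace(t, v, "smo2_pct", "%")
  expect_message(
    ft <- compute_features(tr, ramp_protocol(), 500),
    "resampling")
  expect_equal(ft$baseline_pct, 65, tolerance = 0.1)
  expect_equal(ft$min_pct, 30, tolerance = 1)
})
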