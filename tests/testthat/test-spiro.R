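test_that("windowed peaks reduce to the constant on flat traces", {
  expect_equal(vo2_peak(phys_trace(0:60, rep(2, 61))), 2)
  expect_equal(hr_peak(phys_trace(0:10, rep(120, 11))), 120)
})

test_that("a linear VO2 rise peaks at the mean of the last window", {
  tr <- phys_trace(0:600, 1 + 2 * (0:600) / 600, "vo2_Lmin", "L/min")
  # final 30-sample window covers t = 571..600, mean value at t = 585.5
  expect_equal(vo2_peak(tr), 1 + 2 * 585.5 / 600, tolerance = 1e-9)
})

test_that("a 1-s HR spike is diluted across the 5-s window", {
  v <- rep(120, 61)
  v[31] <- 200
  expect_equal(hr_peak(phys_trace(0:60, v, "hr_bpm", "bpm")), 136)
})

test_that("windowed peaks equal brute-force enumeration", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(40:1200, 1)
    tr <- phys_trace(0:(n - 1), stats::rnorm(n, 100, 15))
    expect_equal(vo2_peak(tr), brute_window_peak(tr$values, 30))
    expect_equal(hr_peak(tr), brute_window_peak(tr$values, 5))
  }
})

test_that("too-short traces are refused", {
  expect_error(vo2_peak(phys_trace(0:10, rnorm(11))), "at least 30")
  expect_error(hr_peak(phys_trace(0:3, rnorm(4))), "at least 5")
})

test_that("peak power is the stage in progress at exhaustion", {
  pr <- ramp_protocol()
  expect_equal(p_peak(pr, 10), 25)
  expect_equal(p_peak(pr, 500), 150)
  expect_equal(p_peak(pr, 900), 250)
  expect_error(p_peak(pr, -1), "non-negative")
})

test_that("peak power steps by dp_W and never decreases", {
  pr <- ramp_protocol()
  grid <- seq(0, 900, by = 7)
  pp <- vapply(grid, function(t) p_peak(pr, t), numeric(1))
  expect_true(all(diff(pp) >= 0))
  expect_true(all(diff(pp) %in% c(0, 5)))
})

test_that("discrete peaks are plain maxima", {
  expect_equal(discrete_peak(c(1.1, 2.4, 6.0)), 6.0)
  expect_equal(discrete_peak(data.frame(time_s = 0, value = 3.2)), 3.2)
  expect_error(discrete_peak(numeric(0)), "no finite samples")
})

test_that("noiseless session peaks equal the generator truth", {
  sim <- simulate_session(default_noiseless(), seed = 1)
  pk <- extract_peaks(sim$session)
  for (f in names(unclass(pk)))
    expect_equal(pk[[f]], sim$truth[[f]], tolerance = 1e-6, label = f)
})

test_that("relative VO2peak follows the body-mass arithmetic", {
  sim <- simulate_session(default_noiseless(), seed = 1, body_mass_kg = 100)
  s <- sim$session
  s$traces$vo2_Lmin <- phys_trace(s$traces$vo2_Lmin$times,
                                  rep(2, length(s$traces$vo2_Lmin)),
                                  "vo2_Lmin", "L/min")
  pk <- extract_peaks(s)
  expect_equal(pk$vo2peak_Lmin, 2)
  expect_equal(pk$vo2peak_rel_mLkgmin, 20)
})

test_that("a session missing the HR channel errors naming it", {
  sim <- simulate_session(kinetics_params(), seed = 1)
  s <- sim$session
  s$traces$hr_bpm <- NULL
  expect_error(extract_peaks(s), "hr_bpm")
})

test_that("the windowed peak dominates the overall mean on random traces", {
  set.seed(17)
  for (i in 1:20) {
    tr <- phys_trace(0:299, stats::rnorm(300, 2, 0.4))
    expect_gte(vo2_peak(tr), mean(tr$values))
  }
})
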