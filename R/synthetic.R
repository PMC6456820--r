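#' Kinetics parameters for the synthetic ramp-test generator
#'
#' Parameterises the muscle-oxygen-saturation (SmO2) trajectory of an
#' exhaustive ramp test — a stable pre-exercise baseline, a sigmoidal
#' decline that accelerates through the second half of the ramp and reaches
#' its minimum at a controllable time, and an exponential reoxygenation
#' that overshoots the baseline — together with affine oxygen-uptake and
#' heart-rate responses to the ramp power and a rising blood-lactate
#' profile sampled on the 2-minute grid.
#'
#' Defaults describe a deconditioned cardiac patient: baseline 65% SmO2
#' desaturating to 30% at exhaustion after 500 s of ramping (peak stage
#' power 150 W under the default protocol), slowed reoxygenation with a
#' 60-s time constant (half-recovery ~42 s), and a 5% overshoot.
#'
#' @param baseline_smo2 Pre-exercise SmO2 in percent, (min_smo2, 100].
#' @param min_smo2 Exercise SmO2 minimum in percent.
#' @param max_smo2 Reoxygenation asymptote in percent; must exceed
#'   `min_smo2`. Values above `baseline_smo2` produce an overshoot.
#' @param t_min_offset_s Time of the SmO2 minimum, seconds from ramp start.
#' @param decline_width_s Logistic steepness of the desaturation phase in
#'   seconds; the steepest decline occurs `2 * decline_width_s` before the
#'   minimum.
#' @param reoxy_tau_s Exponential reoxygenation time constant in seconds.
#' @param vo2_rest_Lmin,vo2_gain_LminPerW Resting oxygen uptake (L/min) and
#'   its gain per watt of ramp power.
#' @param hr_rest_bpm,hr_gain_bpmPerW Resting heart rate (bpm) and its gain
#'   per watt.
#' @param bl_rest_mmolL,bl_peak_mmolL Resting and end-exercise blood
#'   lactate (mmol/L).
#' @param noise_sd Additive Gaussian noise standard deviation in SmO2
#'   percentage points; other channels receive noise scaled by the ratio of
#'   their trajectory excursion to the SmO2 excursion, so one value sets a
#'   common relative noise level.
#' @param exhaustion_time_s Time of volitional exhaustion, seconds from
#'   ramp start.
#' @param sample_rate_hz Sampling rate of the continuous channels in Hz.
#' @param lag_s First-order response lag of VO2/HR to power in seconds
#'   (0 = instantaneous).
#' @param sbp_rest_mmHg,sbp_peak_mmHg Resting and peak systolic blood
#'   pressure (mmHg), linear rise over the ramp.
#' @param dbp_rest_mmHg,dbp_peak_mmHg Resting and peak diastolic blood
#'   pressure (mmHg).
#'
#' @return An object of class `kinetics_params`.
#' @export
#' @examples
#' p <- kinetics_params(noise_sd = 0)
#' sim <- simulate_session(p, ramp_protocol(), seed = 1)
#' sim$truth$min_pct
kinetics_params <- function(baseline_smo2 = 65,
                            min_smo2 = 30,
                            max_smo2 = 70,
                            t_min_offset_s = 500,
                            decline_width_s = 60,
                            reoxy_tau_s = 60,
                            vo2_rest_Lmin = 0.4,
                            vo2_gain_LminPerW = 0.010,
                            hr_rest_bpm = 70,
                            hr_gain_bpmPerW = 0.5,
                            bl_rest_mmolL = 1.0,
                            bl_peak_mmolL = 8.0,
                            noise_sd = 1,
                            exhaustion_time_s = 500,
                            sample_rate_hz = 1,
                            lag_s = 0,
                            sbp_rest_mmHg = 120, sbp_peak_mmHg = 190,
                            dbp_rest_mmHg = 80, dbp_peak_mmHg = 90) {
  p <- as.list(environment())
  validate_kinetics_params(p)
  structure(p, class = "kinetics_params")
}

validate_kinetics_params <- function(p) {
  fail <- function(msg) stop("invalid kinetics_params: ", msg, call. = FALSE)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) fail(paste("non-finite field(s):",
                            paste(names(p)[!num], collapse = ", ")))
  if (!(p$min_smo2 >= 0)) fail("min_smo2 must satisfy 0 <= min_smo2")
  if (!(p$min_smo2 < p$baseline_smo2))
    fail("min_smo2 must satisfy min_smo2 < baseline_smo2")
  if (!(p$baseline_smo2 <= 100))
    fail("baseline_smo2 must satisfy baseline_smo2 <= 100")
  if (!(p$min_smo2 < p$max_smo2 && p$max_smo2 <= 100))
    fail("max_smo2 must satisfy min_smo2 < max_smo2 <= 100")
  if (!(p$reoxy_tau_s > 0)) fail("reoxy_tau_s must satisfy reoxy_tau_s > 0")
  if (!(p$exhaustion_time_s > 0))
    fail("exhaustion_time_s must satisfy exhaustion_time_s > 0")
  if (!(p$noise_sd >= 0)) fail("noise_sd must satisfy noise_sd >= 0")
  if (!(p$decline_width_s > 0))
    fail("decline_width_s must satisfy decline_width_s > 0")
  if (!(p$t_min_offset_s > 0))
    fail("t_min_offset_s must satisfy t_min_offset_s > 0")
  if (!(p$sample_rate_hz > 0))
    fail("sample_rate_hz must satisfy sample_rate_hz > 0")
  if (!(p$lag_s >= 0)) fail("lag_s must satisfy lag_s >= 0")
  invisible(p)
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<kinetics_params> SmO2 %g%% -> %g%% @ %gs -> %g%% (tau %gs)\n",
    "  exhaustion %gs, noise sd %g, %g Hz\n"),
    x$baseline_smo2, x$min_smo2, x$t_min_offset_s, x$max_smo2,
    x$reoxy_tau_s, x$exhaustion_time_s, x$noise_sd, x$sample_rate_hz))
  invisible(x)
}

# Noiseless SmO2 trajectory: baseline for t <= 0, normalised logistic
# decline on (0, t_min) hitting baseline at 0 and min at t_min exactly,
# exponential reoxygenation after t_min.
smo2_trajectory <- function(t, p) {
  tmin <- p$t_min_offset_s
  w <- p$decline_width_s
  tmid <- tmin - 2 * w
  L <- function(x) 1 / (1 + exp((x - tmid) / w))
  l0 <- L(0); l1 <- L(tmin)
  dec <- p$min_smo2 +
    (p$baseline_smo2 - p$min_smo2) * (L(t) - l1) / (l0 - l1)
  rec <- p$min_smo2 +
    (p$max_smo2 - p$min_smo2) * (1 - exp(-(t - tmin) / p$reoxy_tau_s))
  ifelse(t <= 0, p$baseline_smo2, ifelse(t < tmin, dec, rec))
}

# Affine response to stage power, frozen at the exhaustion value, with an
# optional first-order lag applied on the discrete grid.
affine_response <- function(t, p, protocol, rest, gain) {
  pw <- ramp_power(protocol, pmin(t, p$exhaustion_time_s))
  x <- rest + gain * pw
  if (p$lag_s > 0) {
    a <- 1 - exp(-1 / (p$sample_rate_hz * p$lag_s))
    y <- x
    for (i in 2:length(x)) y[i] <- y[i - 1] + a * (x[i] - y[i - 1])
    x <- y
  }
  x
}

bl_trajectory <- function(t, p) {
  frac <- pmin(pmax(t / p$exhaustion_time_s, 0), 1)
  p$bl_rest_mmolL + (p$bl_peak_mmolL - p$bl_rest_mmolL) * frac^2
}

# Discrete sampling grid: every 2 min during exercise plus the exhaustion
# time itself (the final in-test measurement).
discrete_grid <- function(p) {
  g <- seq(0, p$exhaustion_time_s, by = 120)
  if (g[length(g)] < p$exhaustion_time_s) g <- c(g, p$exhaustion_time_s)
  g
}

#' Simulate a ramp-test session with known ground truth
#'
#' Generates all continuous channels (SmO2, VO2, HR) on a uniform grid
#' spanning pre-rest through post-exercise recovery, the discrete 2-minute
#' samples (blood lactate, systolic/diastolic blood pressure), and the
#' analytically implied landmark values ("ground truth") that a perfect
#' analysis should recover. Identical seeds give bit-identical sessions.
#'
#' @param params A [kinetics_params()].
#' @param protocol A [ramp_protocol()].
#' @param seed Integer RNG seed.
#' @param body_mass_kg Subject body mass in kg (metadata carried into the
#'   session; used for relative VO2peak and power-test loads).
#'
#' @return A list with components `session` (a `ramp_session`) and `truth`
#'   (a named list of ground-truth landmark values).
#' @export
simulate_session <- function(params, protocol = ramp_protocol(), seed = 1,
                             body_mass_kg = 80) {
  stopifnot(inherits(params, "kinetics_params"),
            inherits(protocol, "ramp_protocol"))
  validate_kinetics_params(params)
  p <- params
  dt <- 1 / p$sample_rate_hz
  n <- floor((protocol$pre_rest_s + p$exhaustion_time_s +
                protocol$post_rest_s) * p$sample_rate_hz)
  t <- -protocol$pre_rest_s + dt * (0:n)

  smo2 <- smo2_trajectory(t, p)
  vo2 <- affine_response(t, p, protocol, p$vo2_rest_Lmin, p$vo2_gain_LminPerW)
  hr <- affine_response(t, p, protocol, p$hr_rest_bpm, p$hr_gain_bpmPerW)

  tg <- discrete_grid(p)
  bl <- bl_trajectory(tg, p)
  sbp <- p$sbp_rest_mmHg + (p$sbp_peak_mmHg - p$sbp_rest_mmHg) *
    tg / p$exhaustion_time_s
  dbp <- p$dbp_rest_mmHg + (p$dbp_peak_mmHg - p$dbp_rest_mmHg) *
    tg / p$exhaustion_time_s

  if (p$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
    span <- p$baseline_smo2 - p$min_smo2
    sdf <- function(x) p$noise_sd * diff(range(x)) / span
    smo2 <- smo2 + stats::rnorm(length(t), 0, p$noise_sd)
    vo2 <- pmax(vo2 + stats::rnorm(length(t), 0, sdf(vo2)), 0)
    hr <- pmax(hr + stats::rnorm(length(t), 0, sdf(hr)), 0)
    bl <- pmax(bl + stats::rnorm(length(bl), 0, sdf(bl)), 0)
    sbp <- pmax(sbp + stats::rnorm(length(sbp), 0, sdf(sbp)), 0)
    dbp <- pmax(dbp + stats::rnorm(length(dbp), 0, sdf(dbp)), 0)
  }
  smo2 <- pmin(pmax(smo2, 0), 100)

  session <- ramp_session(
    traces = list(
      smo2_pct = phys_trace(t, smo2, "smo2_pct", "%"),
      vo2_Lmin = phys_trace(t, vo2, "vo2_Lmin", "L/min"),
      hr_bpm = phys_trace(t, hr, "hr_bpm", "bpm")),
    discrete = data.frame(
      time_s = rep(tg, 3L),
      value = c(bl, sbp, dbp),
      channel = rep(c("bl_mmolL", "sbp_mmHg", "dbp_mmHg"), each = length(tg)),
      stringsAsFactors = FALSE),
    protocol = protocol,
    exhaustion_time_s = p$exhaustion_time_s,
    body_mass_kg = body_mass_kg)

  list(session = session,
       truth = ground_truth(p, protocol, body_mass_kg))
}

# Landmarks implied analytically by the kinetics parameters. The only
# numeric evaluation is the 30-s/5-s window peak under a nonzero VO2/HR
# lag, which the generator computes on its own noiseless trajectory.
ground_truth <- function(p, protocol, body_mass_kg) {
  tmin <- p$t_min_offset_s
  t_end <- p$exhaustion_time_s + protocol$post_rest_s
  # achieved reoxygenation maximum at the end of the recovery window
  eps <- exp(-(t_end - tmin) / p$reoxy_tau_s)
  max_pct <- p$min_smo2 + (p$max_smo2 - p$min_smo2) * (1 - eps)
  half_level <- p$min_smo2 + 0.5 * (max_pct - p$min_smo2)
  t_half <- p$reoxy_tau_s * log(2 / (1 + eps))
  delta_deoxy <- p$baseline_smo2 - p$min_smo2
  delta_half <- half_level - p$min_smo2

  ppeak <- ramp_power(protocol, p$exhaustion_time_s)
  if (p$lag_s > 0) {
    dt <- 1 / p$sample_rate_hz
    n <- floor((protocol$pre_rest_s + p$exhaustion_time_s +
                  protocol$post_rest_s) * p$sample_rate_hz)
    t <- -protocol$pre_rest_s + dt * (0:n)
    vo2 <- affine_response(t, p, protocol, p$vo2_rest_Lmin,
                           p$vo2_gain_LminPerW)
    hr <- affine_response(t, p, protocol, p$hr_rest_bpm, p$hr_gain_bpmPerW)
    vo2peak <- max_window_mean(vo2, round(30 * p$sample_rate_hz))
    hrpeak <- max_window_mean(hr, round(5 * p$sample_rate_hz))
  } else {
    vo2peak <- p$vo2_rest_Lmin + p$vo2_gain_LminPerW * ppeak
    hrpeak <- p$hr_rest_bpm + p$hr_gain_bpmPerW * ppeak
  }

  list(
    baseline_pct = p$baseline_smo2,
    min_pct = p$min_smo2,
    delta_deoxy_pct = delta_deoxy,
    t_deoxy_s = tmin,
    slope_deoxy_pct_per_min = delta_deoxy / (tmin / 60),
    max_pct = max_pct,
    half_level_pct = half_level,
    delta_half_pct = delta_half,
    t_half_s = t_half,
    slope_half_pct_per_min = delta_half / (t_half / 60),
    overshoot_pct = max_pct - p$baseline_smo2,
    vo2peak_Lmin = vo2peak,
    vo2peak_rel_mLkgmin = 1000 * vo2peak / body_mass_kg,
    ppeak_W = ppeak,
    hrpeak_bpm = hrpeak,
    sbp_peak_mmHg = p$sbp_peak_mmHg,
    dbp_peak_mmHg = p$dbp_peak_mmHg,
    blpeak_mmolL = p$bl_peak_mmolL)
}
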