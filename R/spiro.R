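# Cardiorespiratory peak extraction: windowed peaks for the continuous
# channels, simple maxima for the discrete ones, stage power at exhaustion.

# Maximum over all contiguous windows of `n` samples of the window mean.
max_window_mean <- function(x, n) {
  if (n <= 1L) return(max(x))
  ma <- stats::filter(x, rep(1 / n, n), sides = 1)
  max(ma, na.rm = TRUE)
}

window_peak <- function(trace, window_s, resample_hz = 1, what = "trace") {
  stopifnot(inherits(trace, "phys_trace"))
  if (!is_uniform(trace)) {
    message("non-uniform sampling: resampling ", what, " to ", resample_hz,
            " Hz by linear interpolation")
    trace <- resample_trace(trace, resample_hz)
  }
  span <- trace$times[length(trace$times)] - trace$times[1L]
  if (span < window_s)
    stop(what, " spans ", span, " s; at least ", window_s,
         " s are required", call. = FALSE)
  fs <- trace_rate(trace)
  n <- max(1L, round(window_s * fs))
  max_window_mean(trace$values, n)
}

#' Peak oxygen uptake: highest 30-s average
#'
#' Slides a 30-s window (sample by sample on the uniform grid) over the
#' VO2 trace and returns the largest window mean. Breath-by-breath input
#' with irregular time stamps is linearly resampled first.
#'
#' @param trace VO2 [phys_trace()] in L/min spanning at least `window_s`.
#' @param window_s Averaging window in seconds (default 30).
#' @param resample_hz Grid used for irregular input (default 1 Hz).
#' @return Peak VO2 in L/min.
#' @export
vo2_peak <- function(trace, window_s = 30, resample_hz = 1) {
  window_peak(trace, window_s, resample_hz, what = "VO2 trace")
}

#' Peak heart rate: highest 5-s average
#'
#' @param trace HR [phys_trace()] in bpm spanning at least `window_s`.
#' @param window_s Averaging window in seconds (default 5).
#' @param resample_hz Grid used for irregular input.
#' @return Peak HR in bpm.
#' @export
hr_peak <- function(trace, window_s = 5, resample_hz = 1) {
  window_peak(trace, window_s, resample_hz, what = "HR trace")
}

#' Peak aerobic power: ergometer stage in progress at exhaustion
#'
#' `p0 + dp * floor(t_exh / step)` — the power of the stage the subject
#' was riding when the test stopped (stage convention, not interpolated
#' ramp power).
#'
#' @param protocol A [ramp_protocol()].
#' @param exhaustion_time_s Exhaustion time in seconds, non-negative.
#' @return Peak power in watts.
#' @export
#' @examples
#' p_peak(ramp_protocol(), 500)   # 150 W
p_peak <- function(protocol, exhaustion_time_s) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  if (!is.numeric(exhaustion_time_s) || exhaustion_time_s < 0)
    stop("exhaustion_time_s must be non-negative", call. = FALSE)
  ramp_power(protocol, exhaustion_time_s)
}

#' Peak of a discrete sample series
#'
#' Blood lactate and blood pressure are measured every 2 minutes; their
#' peak is simply the largest measured value.
#'
#' @param samples Either a numeric vector of values or a data frame with a
#'   `value` column (e.g. from [session_discrete()]).
#' @return The maximum sample value.
#' @export
discrete_peak <- function(samples) {
  v <- if (is.data.frame(samples)) samples$value else as.numeric(samples)
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    stop("no finite samples to take a peak over", call. = FALSE)
  max(v)
}

#' Extract all cardiorespiratory peak parameters from a session
#'
#' @param session A [ramp_session()] with channels `vo2_Lmin` and `hr_bpm`
#'   and discrete series `bl_mmolL`, `sbp_mmHg`, `dbp_mmHg`.
#' @param body_mass_kg Body mass in kg; defaults to the session metadata.
#' @return An object of class `cardio_peaks`.
#' @export
extract_peaks <- function(session, body_mass_kg = session$body_mass_kg) {
  stopifnot(inherits(session, "ramp_session"))
  if (!is.numeric(body_mass_kg) || is.na(body_mass_kg) || body_mass_kg <= 0)
    stop("body_mass_kg must be a positive number", call. = FALSE)
  vo2 <- vo2_peak(session_channel(session, "vo2_Lmin"))
  hr <- hr_peak(session_channel(session, "hr_bpm"))
  pk <- list(
    vo2peak_Lmin = vo2,
    vo2peak_rel_mLkgmin = 1000 * vo2 / body_mass_kg,
    ppeak_W = p_peak(session$protocol, session$exhaustion_time_s),
    hrpeak_bpm = hr,
    sbp_peak_mmHg = discrete_peak(session_discrete(session, "sbp_mmHg")),
    dbp_peak_mmHg = discrete_peak(session_discrete(session, "dbp_mmHg")),
    blpeak_mmolL = discrete_peak(session_discrete(session, "bl_mmolL")))
  structure(pk, class = "cardio_peaks")
}

#' @export
print.cardio_peaks <- function(x, digits = 3, ...) {
  cat("<cardio_peaks>\n")
  print(round(unlist(unclass(x)), digits))
  invisible(x)
}

#' @export
as.data.frame.cardio_peaks <- function(x, ...) {
  as.data.frame(unclass(x), row.names = "")
}

#' Write cardiorespiratory peaks as JSON
#'
#' @param peaks A [extract_peaks()] result.
#' @param json_path Output path.
#' @return Invisibly, `peaks`.
#' @export
write_peaks <- function(peaks, json_path) {
  stopifnot(inherits(peaks, "cardio_peaks"))
  jsonlite::write_json(unclass(peaks), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(peaks)
}
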