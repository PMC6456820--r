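#' Mean SmO2 over the pre-exercise rest window
#'
#' The baseline is the arithmetic mean of all samples with time in
#' `[-pre_rest_s, 0)`, i.e. the seated-rest period before the ramp starts.
#'
#' @param trace A (typically filtered) [phys_trace()].
#' @param pre_rest_s Rest-window length in seconds (default 180).
#' @return Baseline SmO2 in percent.
#' @export
compute_baseline <- function(trace, pre_rest_s = 180) {
  stopifnot(inherits(trace, "phys_trace"))
  idx <- trace_window(trace, -pre_rest_s, 0)
  if (length(idx) == 0L)
    stop("no samples in the pre-rest window [-", pre_rest_s, ", 0) s",
         call. = FALSE)
  mean(trace$values[idx])
}

#' Locate the exercise SmO2 minimum
#'
#' Finds the last local minimum of the (filtered) SmO2 signal prior to
#' reoxygenation. Reoxygenation onset is operationalised as the start of
#' the first sustained rise of at least `onset_rise_s` seconds at or after
#' the ramp start; among all discrete local minima (a sample strictly below
#' its left neighbour and not above its right; plateaus take their earliest
#' sample) at or before that onset, the last one is returned. If no local
#' minimum exists the global minimum over `[0, onset]` is used.
#'
#' @param trace A filtered, uniformly sampled [phys_trace()].
#' @param exhaustion_time_s Exhaustion time in seconds; must lie within the
#'   trace span.
#' @param onset_rise_s Minimum sustained-rise duration that marks
#'   reoxygenation onset (default 30 s).
#' @param onset_min_rise_pct Minimum net amplitude of that rise in SmO2
#'   percentage points (default 2). Slow drifts of residual ripple can
#'   rise for longer than 30 s but only by a fraction of a percent;
#'   requiring a material net gain keeps the onset on the actual
#'   reoxygenation, which climbs by tens of percent. If no qualifying rise
#'   exists, the search window extends to the end of the record (harmless:
#'   the minimum of a non-recovering signal is its global minimum).
#' @return A list with `value` (percent), `time_s`, and `degenerate`
#'   (`TRUE` for a flat signal, where the first sample is returned).
#' @export
find_smo2_min <- function(trace, exhaustion_time_s, onset_rise_s = 30,
                          onset_min_rise_pct = 2) {
  stopifnot(inherits(trace, "phys_trace"))
  t <- trace$times
  v <- trace$values
  n <- length(v)
  if (exhaustion_time_s < t[1L] || exhaustion_time_s > t[n])
    stop("exhaustion_time_s (", exhaustion_time_s,
         ") lies outside the trace span [", t[1L], ", ", t[n], "]",
         call. = FALSE)
  if (diff(range(v)) == 0) {
    warning("flat SmO2 signal; returning the first sample", call. = FALSE)
    return(list(value = v[1L], time_s = t[1L], degenerate = TRUE))
  }

  onset_t <- reoxy_onset(t, v, onset_rise_s, onset_min_rise_pct)
  win <- which(t >= 0 & t <= onset_t)
  if (length(win) == 0L) win <- which(t >= 0)

  interior <- win[win > 1L & win < n]
  is_lmin <- interior[v[interior - 1L] > v[interior] &
                        v[interior] <= v[interior + 1L]]
  if (length(is_lmin) > 0L) {
    i <- is_lmin[length(is_lmin)]
  } else {
    i <- win[which.min(v[win])]
  }
  list(value = v[i], time_s = t[i], degenerate = FALSE)
}

# Start time of the first rise sustained for >= onset_rise_s and gaining
# at least min_rise at or after the ramp start; falls back to the end of
# the record if none exists.
reoxy_onset <- function(t, v, onset_rise_s, min_rise = 2) {
  n <- length(v)
  d <- diff(v) > 0
  i <- which(t >= 0)[1L]
  if (is.na(i)) i <- 1L
  r <- rle(d[i:(n - 1L)])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rising <- which(r$values)
  for (k in rising) {
    a <- i + starts[k] - 1L         # index of run start sample
    b <- i + ends[k]                # index of run end sample
    if (t[b] - t[a] >= onset_rise_s && v[b] - v[a] >= min_rise)
      return(t[a])
  }
  t[n]
}

#' Extract all SmO2 landmarks of a ramp test
#'
#' Runs the full SmO2 analysis: optional zero-phase low-pass filtering,
#' baseline over the pre-rest window, last local minimum before
#' reoxygenation, recovery maximum within the post-exercise rest window,
#' and the derived deoxygenation / half-reoxygenation deltas, times and
#' slopes. Slopes are expressed in percent per minute.
#'
#' @param trace The SmO2 [phys_trace()] covering pre-rest through
#'   post-exercise rest. Non-uniform input is resampled to `resample_hz`
#'   (with a message) before filtering.
#' @param protocol A [ramp_protocol()]; supplies the rest-window lengths.
#' @param exhaustion_time_s Exhaustion time in seconds from ramp start.
#' @param cutoff_hz Low-pass cut-off in Hz (default 0.03); `NULL` skips
#'   filtering entirely (appropriate for already-filtered or noise-free
#'   signals).
#' @param order Butterworth order for the single pass (default 2).
#' @param onset_rise_s,onset_min_rise_pct Sustained-rise duration and
#'   minimum rise amplitude defining reoxygenation onset, see
#'   [find_smo2_min()].
#' @param resample_hz Grid rate used when input is not uniformly sampled.
#' @return An object of class `smo2_features`; print it or coerce with
#'   `as.data.frame()`. When the signal never reaches the
#'   half-reoxygenation level within the recovery window, `t_half_s` and
#'   `slope_half_pct_per_min` are `NA` and the `t_half_missing` flag is
#'   set.
#' @export
#' @examples
#' sim <- simulate_session(kinetics_params(noise_sd = 0), seed = 1)
#' compute_features(session_channel(sim$session, "smo2_pct"),
#'                  sim$session$protocol, sim$session$exhaustion_time_s,
#'                  cutoff_hz = NULL)
compute_features <- function(trace, protocol = ramp_protocol(),
                             exhaustion_time_s,
                             cutoff_hz = 0.03, order = 2,
                             onset_rise_s = 30, onset_min_rise_pct = 2,
                             resample_hz = 1) {
  stopifnot(inherits(trace, "phys_trace"),
            inherits(protocol, "ramp_protocol"))
  if (!is_uniform(trace)) {
    message("non-uniform sampling: resampling to ", resample_hz,
            " Hz by linear interpolation")
    trace <- resample_trace(trace, resample_hz)
  }
  filtered <- if (is.null(cutoff_hz)) trace else
    lowpass_filter(trace, cutoff_hz = cutoff_hz, order = order)

  baseline <- compute_baseline(filtered, protocol$pre_rest_s)
  mn <- find_smo2_min(filtered, exhaustion_time_s, onset_rise_s,
                      onset_min_rise_pct)

  post <- trace_window(filtered, exhaustion_time_s,
                       exhaustion_time_s + protocol$post_rest_s,
                       left_open = TRUE, right_open = FALSE)
  if (length(post) == 0L)
    stop("no samples in the post-exercise rest window (",
         exhaustion_time_s, ", ", exhaustion_time_s + protocol$post_rest_s,
         "] s", call. = FALSE)
  max_pct <- max(filtered$values[post])

  half_level <- mn$value + 0.5 * (max_pct - mn$value)
  cross <- half_crossing(filtered, mn$time_s, half_level)
  t_half <- if (is.na(cross)) NA_real_ else cross - mn$time_s

  smo2_features(
    baseline_pct = baseline,
    min_pct = mn$value,
    t_deoxy_s = mn$time_s,
    max_pct = max_pct,
    t_half_s = t_half,
    degenerate_min = mn$degenerate)
}

# First time after t_min at which the signal reaches `level`, by linear
# interpolation between the bracketing samples; NA if never reached.
half_crossing <- function(trace, t_min, level) {
  t <- trace$times
  v <- trace$values
  after <- which(t > t_min)
  hit <- after[v[after] >= level]
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  if (i == 1L || v[i - 1L] >= level) return(t[i])
  t[i - 1L] + (level - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
}

#' SmO2 landmark set
#'
#' Assembles the full landmark set from the four measured quantities
#' (baseline, minimum and its time, recovery maximum, half-recovery time);
#' all derived fields honour the defining identities exactly:
#' `delta_deoxy = baseline - min`, `half_level = min + (max - min)/2`,
#' `delta_half = half_level - min`, `overshoot = max - baseline`.
#'
#' @param baseline_pct,min_pct,t_deoxy_s,max_pct,t_half_s Measured values;
#'   `t_half_s` may be `NA` when the half level is never reached.
#' @param degenerate_min Flag from [find_smo2_min()].
#' @return An object of class `smo2_features`.
#' @export
smo2_features <- function(baseline_pct, min_pct, t_deoxy_s, max_pct,
                          t_half_s, degenerate_min = FALSE) {
  if (t_deoxy_s <= 0)
    warning("t_deoxy_s is not positive; the minimum precedes the ramp start",
            call. = FALSE)
  delta_deoxy <- baseline_pct - min_pct
  half_level <- min_pct + 0.5 * (max_pct - min_pct)
  delta_half <- half_level - min_pct
  x <- list(
    baseline_pct = baseline_pct,
    min_pct = min_pct,
    delta_deoxy_pct = delta_deoxy,
    t_deoxy_s = t_deoxy_s,
    slope_deoxy_pct_per_min = delta_deoxy / (t_deoxy_s / 60),
    max_pct = max_pct,
    half_level_pct = half_level,
    delta_half_pct = delta_half,
    t_half_s = t_half_s,
    slope_half_pct_per_min =
      if (is.na(t_half_s)) NA_real_ else delta_half / (t_half_s / 60),
    overshoot_pct = max_pct - baseline_pct)
  structure(x, class = "smo2_features",
            degenerate_min = isTRUE(degenerate_min),
            t_half_missing = is.na(t_half_s))
}

#' @export
print.smo2_features <- function(x, digits = 3, ...) {
  cat("<smo2_features>\n")
  df <- as.data.frame(x)
  print(round(unlist(df), digits))
  if (attr(x, "t_half_missing"))
    cat("  [half-reoxygenation level never reached in recovery window]\n")
  if (attr(x, "degenerate_min"))
    cat("  [degenerate (flat) signal: minimum is the first sample]\n")
  invisible(x)
}

#' @export
as.data.frame.smo2_features <- function(x, ...) {
  as.data.frame(unclass(x), row.names = "")
}

#' Write SmO2 landmarks as JSON and a flat CSV row
#'
#' @param features An [smo2_features()] object.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, `features`.
#' @export
write_features <- function(features, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(features, "smo2_features"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(features), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(features), csv_path, row.names = FALSE)
  invisible(features)
}
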