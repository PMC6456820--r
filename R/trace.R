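#' Uniformly time-stamped physiological trace
#'
#' A trace couples a strictly increasing time axis (seconds from session
#' start; rest begins at a negative time, the ramp starts at 0) with the
#' sampled values of one physiological channel and its units.
#'
#' @param times Numeric vector of time stamps in seconds, strictly
#'   increasing, length at least 2.
#' @param values Numeric vector of channel values, finite, same length as
#'   `times`.
#' @param channel Channel label, e.g. `"smo2_pct"`, `"vo2_Lmin"`,
#'   `"hr_bpm"`.
#' @param units Unit string, e.g. `"%"`, `"L/min"`, `"bpm"`.
#'
#' @return An object of class `phys_trace`.
#' @export
#' @examples
#' tr <- phys_trace(0:59, rep(65, 60), "smo2_pct", "%")
#' trace_rate(tr)
phys_trace <- function(times, values, channel = "signal", units = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)))
    stop("`times` must be finite", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(
    list(times = times, values = values,
         channel = as.character(channel)[1L], units = as.character(units)[1L]),
    class = "phys_trace"
  )
}

#' @export
print.phys_trace <- function(x, ...) {
  cat(sprintf("<phys_trace> %s [%s], %d samples, t = [%g, %g] s\n",
              x$channel, x$units, length(x$times),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' @export
length.phys_trace <- function(x) length(x$times)

#' @export
as.data.frame.phys_trace <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' Sampling rate of a uniform trace
#'
#' @param trace A [phys_trace()].
#' @param tol Relative tolerance on spacing jitter.
#' @return Sampling rate in Hz, or `NA` if the trace is not uniformly
#'   sampled within `tol`.
#' @export
trace_rate <- function(trace, tol = 1e-6) {
  dts <- diff(trace$times)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > tol * dt) return(NA_real_)
  1 / dt
}

is_uniform <- function(trace, tol = 1e-6) !is.na(trace_rate(trace, tol))

#' Resample a trace to a uniform grid by linear interpolation
#'
#' Irregularly sampled channels (e.g. breath-by-breath gas exchange) are
#' mapped to a uniform grid before any windowed or filtered operation.
#'
#' @param trace A [phys_trace()].
#' @param rate_hz Target sampling rate in Hz (default 1).
#' @return A uniformly sampled `phys_trace` spanning the same time range.
#' @export
resample_trace <- function(trace, rate_hz = 1) {
  stopifnot(is.numeric(rate_hz), rate_hz > 0)
  dt <- 1 / rate_hz
  rng <- range(trace$times)
  n <- floor((rng[2L] - rng[1L]) / dt)
  grid <- rng[1L] + dt * (0:n)
  out <- stats::approx(trace$times, trace$values, xout = grid)$y
  phys_trace(grid, out, trace$channel, trace$units)
}

# Window of samples with times in [from, to) or (from, to] etc.
trace_window <- function(trace, from = -Inf, to = Inf,
                         left_open = FALSE, right_open = TRUE) {
  t <- trace$times
  lo <- if (left_open) t > from else t >= from
  hi <- if (right_open) t < to else t <= to
  which(lo & hi)
}
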