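#' Ramp-test session container
#'
#' Bundles the continuous channel traces, the discrete 2-minute samples,
#' the ramp protocol, the exhaustion time and subject metadata of one
#' ramp test.
#'
#' @param traces Named list of [phys_trace()] objects. Canonical channel
#'   names are `smo2_pct`, `vo2_Lmin` and `hr_bpm`.
#' @param discrete Data frame with columns `time_s`, `value`, `channel`
#'   holding the discrete samples (`bl_mmolL`, `sbp_mmHg`, `dbp_mmHg`).
#' @param protocol A [ramp_protocol()].
#' @param exhaustion_time_s Volitional exhaustion, seconds from ramp start.
#' @param body_mass_kg Subject body mass in kg.
#'
#' @return An object of class `ramp_session`.
#' @export
ramp_session <- function(traces, discrete, protocol, exhaustion_time_s,
                         body_mass_kg = NA_real_) {
  if (!is.list(traces) || length(traces) == 0L)
    stop("`traces` must be a non-empty named list of phys_trace objects",
         call. = FALSE)
  if (is.null(names(traces)) || any(!nzchar(names(traces))))
    stop("all traces must be named", call. = FALSE)
  ok <- vapply(traces, inherits, logical(1), what = "phys_trace")
  if (!all(ok))
    stop("non-trace element(s) in `traces`: ",
         paste(names(traces)[!ok], collapse = ", "), call. = FALSE)
  stopifnot(inherits(protocol, "ramp_protocol"))
  if (!is.numeric(exhaustion_time_s) || exhaustion_time_s <= 0)
    stop("`exhaustion_time_s` must be positive", call. = FALSE)
  discrete <- as.data.frame(discrete)
  if (!all(c("time_s", "value", "channel") %in% names(discrete)))
    stop("`discrete` needs columns time_s, value, channel", call. = FALSE)
  structure(
    list(traces = traces, discrete = discrete, protocol = protocol,
         exhaustion_time_s = as.numeric(exhaustion_time_s),
         body_mass_kg = as.numeric(body_mass_kg)),
    class = "ramp_session")
}

#' @export
print.ramp_session <- function(x, ...) {
  cat(sprintf("<ramp_session> exhaustion %g s, body mass %g kg\n",
              x$exhaustion_time_s, x$body_mass_kg))
  cat("  channels:", paste(names(x$traces), collapse = ", "), "\n")
  cat("  discrete:", paste(unique(x$discrete$channel), collapse = ", "),
      sprintf("(%d samples)\n", nrow(x$discrete)))
  invisible(x)
}

#' Fetch a channel trace from a session
#'
#' @param session A [ramp_session()].
#' @param channel Channel name, e.g. `"smo2_pct"`.
#' @return The [phys_trace()]; errors naming the channel if absent.
#' @export
session_channel <- function(session, channel) {
  tr <- session$traces[[channel]]
  if (is.null(tr))
    stop("session is missing channel \"", channel, "\"", call. = FALSE)
  tr
}

#' Fetch one discrete sample series from a session
#'
#' @param session A [ramp_session()].
#' @param channel Discrete channel name, e.g. `"bl_mmolL"`.
#' @return Data frame with columns `time_s`, `value`.
#' @export
session_discrete <- function(session, channel) {
  d <- session$discrete[session$discrete$channel == channel,
                        c("time_s", "value")]
  if (nrow(d) == 0L)
    stop("session has no discrete samples for channel \"", channel, "\"",
         call. = FALSE)
  d[order(d$time_s), , drop = FALSE]
}
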