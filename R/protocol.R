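#' Incremental ramp-test protocol
#'
#' The default protocol is the clinical one this package targets: 3 min of
#' seated rest, pedaling from 25 W with 5-W increments every 20 s
#' (15 W/min) to volitional exhaustion, then 8 min of seated recovery.
#'
#' @param pre_rest_s Pre-exercise rest duration in seconds.
#' @param p0_W Initial power in watts.
#' @param dp_W Power increment per stage in watts.
#' @param step_s Stage duration in seconds.
#' @param post_rest_s Post-exercise recovery duration in seconds.
#'
#' @return An object of class `ramp_protocol`.
#' @export
#' @examples
#' pr <- ramp_protocol()
#' ramp_rate(pr)              # 15 W/min
#' ramp_power(pr, 500)        # stage power in progress at 500 s
ramp_protocol <- function(pre_rest_s = 180, p0_W = 25, dp_W = 5,
                          step_s = 20, post_rest_s = 480) {
  vals <- c(pre_rest_s = pre_rest_s, p0_W = p0_W, dp_W = dp_W,
            step_s = step_s, post_rest_s = post_rest_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all ramp_protocol fields must be strictly positive; got ",
         paste(names(vals)[!(is.finite(vals) & vals > 0)], collapse = ", "),
         call. = FALSE)
  structure(as.list(vals), class = "ramp_protocol")
}

#' @export
print.ramp_protocol <- function(x, ...) {
  cat(sprintf(
    "<ramp_protocol> rest %gs | %g W + %g W / %g s (%g W/min) | recovery %gs\n",
    x$pre_rest_s, x$p0_W, x$dp_W, x$step_s, ramp_rate(x), x$post_rest_s))
  invisible(x)
}

#' Ramp rate in watts per minute
#'
#' @param protocol A [ramp_protocol()].
#' @return The work-rate increment expressed in W/min.
#' @export
ramp_rate <- function(protocol) {
  protocol$dp_W / protocol$step_s * 60
}

#' Ergometer stage power at a given time
#'
#' Returns the power of the stage in progress: `p0 + dp * floor(t / step)`
#' for `t >= 0`, and 0 during rest (`t < 0`).
#'
#' @param protocol A [ramp_protocol()].
#' @param t_s Time in seconds from ramp start (vectorised).
#' @return Power in watts.
#' @export
ramp_power <- function(protocol, t_s) {
  ifelse(t_s < 0, 0,
         protocol$p0_W + protocol$dp_W * floor(t_s / protocol$step_s))
}
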