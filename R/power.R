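# Soft-robot leg-press power tests: each test (Real Power = simulated
# squat jump, Reactive Power = simulated countermovement jump) consists of
# nominally four attempts per leg; the average and the peak attempt are
# the reported outcomes.

#' Aggregate power-test attempts into average and peak
#'
#' @param attempts_W Numeric vector of per-attempt power values in watts.
#' @param test_type `"real"` or `"reactive"`.
#' @param leg `"left"` or `"right"`.
#' @param valid Optional logical vector marking attempts in which both
#'   legs reached the 90-degree knee-flexion target; invalid attempts are
#'   excluded before aggregation.
#' @return An object of class `power_test_result` with `avg_W`, `peak_W`,
#'   the retained attempts and a `complete` flag (`TRUE` when exactly four
#'   valid attempts were aggregated).
#' @export
#' @examples
#' aggregate_attempts(c(400, 420, 410, 430), "real", "left")
aggregate_attempts <- function(attempts_W,
                               test_type = c("real", "reactive"),
                               leg = c("left", "right"),
                               valid = NULL) {
  test_type <- match.arg(test_type)
  leg <- match.arg(leg)
  attempts_W <- as.numeric(attempts_W)
  if (!is.null(valid)) {
    if (length(valid) != length(attempts_W))
      stop("`valid` must match `attempts_W` in length", call. = FALSE)
    attempts_W <- attempts_W[as.logical(valid)]
  }
  attempts_W <- attempts_W[is.finite(attempts_W)]
  if (length(attempts_W) == 0L)
    stop("no valid finite attempts to aggregate", call. = FALSE)
  structure(
    list(test_type = test_type, leg = leg, attempts_W = attempts_W,
         avg_W = mean(attempts_W), peak_W = max(attempts_W),
         complete = length(attempts_W) == 4L),
    class = "power_test_result")
}

#' @export
print.power_test_result <- function(x, ...) {
  cat(sprintf("<power_test_result> %s power, %s leg: avg %.1f W, peak %.1f W (%d attempt%s%s)\n",
              x$test_type, x$leg, x$avg_W, x$peak_W, length(x$attempts_W),
              if (length(x$attempts_W) == 1L) "" else "s",
              if (x$complete) "" else ", incomplete"))
  invisible(x)
}

#' Per-leg external load of the power tests
#'
#' Both power tests load each leg with half the body mass.
#'
#' @param body_mass_kg Body mass in kg, positive.
#' @return Load in kg per leg.
#' @export
#' @examples
#' external_load(92.8)   # 46.4
external_load <- function(body_mass_kg) {
  if (!is.numeric(body_mass_kg) || length(body_mass_kg) != 1L ||
      !is.finite(body_mass_kg) || body_mass_kg <= 0)
    stop("body_mass_kg must be a single positive number", call. = FALSE)
  0.5 * body_mass_kg
}

#' Read power-test attempts from CSV and aggregate them
#'
#' Expects columns `test_type`, `leg`, `power_W` and optionally `valid`
#' (plus any identifying columns such as `session_date`, which are carried
#' through as grouping keys).
#'
#' @param path CSV file of attempts.
#' @return A list of `power_test_result` objects, one per
#'   test-type/leg combination.
#' @export
read_power_attempts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("test_type", "leg", "power_W")
  if (!all(need %in% names(df)))
    stop("attempts CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  keys <- unique(df[, c("test_type", "leg")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$test_type == keys$test_type[i] & df$leg == keys$leg[i], ]
    out[[i]] <- aggregate_attempts(
      sub$power_W, keys$test_type[i], keys$leg[i],
      valid = if ("valid" %in% names(sub)) sub$valid else NULL)
  }
  names(out) <- paste(keys$test_type, keys$leg, sep = "_")
  out
}
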