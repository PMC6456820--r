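# Work-matched 8-week concentric/eccentric interval-training prescription.
# Loads are fractions of the ramp-test peak power; eccentric loads carry a
# multiplier (default 1.4) and the interval count is reduced so both modes
# perform the same external work per session.

con_fractions <- c(0.65, 0.65, 0.65, 0.65, 0.70, 0.70, 0.75, 0.75)
con_intervals <- c(10L, 10L, 15L, 15L, 15L, 15L, 15L, 15L)

round_half_up <- function(x) floor(x + 0.5)

new_prescription <- function(week, mode, load_fraction, load_W, n_intervals) {
  structure(
    data.frame(
      week = week,
      mode = mode,
      load_fraction = load_fraction,
      load_W = load_W,
      n_intervals = as.integer(n_intervals),
      work_interval_s = 60,
      rest_interval_s = 60,
      relative_work = load_fraction * n_intervals,
      stringsAsFactors = FALSE),
    class = c("prescription", "data.frame"))
}

#' Concentric 8-week interval-training schedule
#'
#' Weeks 1-2: 65% of peak power, 10 one-minute work intervals (one-minute
#' passive rest between); weeks 3-4: 65%, 15 intervals; weeks 5-6: 70%,
#' 15; weeks 7-8: 75%, 15. `relative_work` is the dimensionless session
#' work, load fraction x intervals x work minutes.
#'
#' @param ppeak_W Ramp-test peak power in watts, positive.
#' @return A `prescription` data frame with one row per week.
#' @export
#' @examples
#' con_schedule(150)
con_schedule <- function(ppeak_W) {
  if (!is.numeric(ppeak_W) || length(ppeak_W) != 1L || !is.finite(ppeak_W) ||
      ppeak_W <= 0)
    stop("ppeak_W must be a single positive number", call. = FALSE)
  new_prescription(1:8, "CON", con_fractions,
                   con_fractions * ppeak_W, con_intervals)
}

#' Eccentric 8-week schedule, work-matched to the concentric one
#'
#' Per-week loads are the concentric loads times `load_multiplier`
#' (default 1.4, the eccentric overload the protocol prescribes); the
#' interval count is `round_half_up(n_con / load_multiplier)` so the
#' external work per session stays matched. At the default multiplier this
#' gives 7 intervals where the concentric schedule has 10, and 11 where it
#' has 15.
#'
#' @param ppeak_W Ramp-test peak power in watts, positive.
#' @param load_multiplier Eccentric load multiplier, positive (default 1.4).
#' @return A `prescription` data frame with one row per week.
#' @export
#' @examples
#' ecc_schedule(250)$n_intervals   # 7 7 11 11 11 11 11 11
ecc_schedule <- function(ppeak_W, load_multiplier = 1.4) {
  if (!is.numeric(load_multiplier) || length(load_multiplier) != 1L ||
      !is.finite(load_multiplier) || load_multiplier <= 0)
    stop("load_multiplier must be a single positive number", call. = FALSE)
  con <- con_schedule(ppeak_W)
  new_prescription(1:8, "ECC",
                   con$load_fraction * load_multiplier,
                   con$load_W * load_multiplier,
                   round_half_up(con$n_intervals / load_multiplier))
}

#' External-work ratio between matched eccentric and concentric weeks
#'
#' `(ecc load x ecc intervals) / (con load x con intervals)`; 1 means the
#' two modes prescribe identical external work. Accepts whole schedules
#' (vectorised week by week) or single-week rows.
#'
#' @param ecc_week,con_week `prescription` rows (or whole schedules) for
#'   the same week(s).
#' @return Dimensionless work ratio(s).
#' @export
#' @examples
#' work_match_ratio(ecc_schedule(150), con_schedule(150))
work_match_ratio <- function(ecc_week, con_week) {
  if (!identical(ecc_week$week, con_week$week))
    stop("week indices of the two prescriptions differ", call. = FALSE)
  den <- con_week$load_W * con_week$n_intervals
  if (any(den == 0))
    stop("concentric external work is zero; ratio undefined", call. = FALSE)
  (ecc_week$load_W * ecc_week$n_intervals) / den
}

#' Fixed session settings of the pedaling-type interval exercise
#'
#' Range of motion 5-90 degrees of knee flexion, 30 rpm movement speed,
#' three sessions per week with at least 48 h between sessions, and two
#' familiarisation sessions (without a load prescription) in the week
#' before training starts.
#'
#' @return A named list of constants.
#' @export
session_settings <- function() {
  list(rom_deg = c(5, 90),
       cadence_rpm = 30,
       frequency_per_week = 3,
       min_rest_between_sessions_h = 48,
       familiarization_sessions = 2)
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("<prescription> %s, 8 weeks\n", x$mode[1L]))
  NextMethod()
  invisible(x)
}

#' Write a prescription as CSV and JSON
#'
#' @param schedule A `prescription` data frame.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, `schedule`.
#' @export
write_prescription <- function(schedule, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(schedule, "prescription"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(schedule), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(schedule), json_path,
                         digits = NA, pretty = TRUE)
  invisible(schedule)
}
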