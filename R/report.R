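# PRE/POST comparison: percentage change of every parameter measured both
# before and after the training period, grouped by instrument.

#' Percentage change POST versus PRE
#'
#' `100 * (post - pre) / pre`. Undefined when `pre` is 0 (returned as
#' `NA`, not an error); missing inputs propagate as missing, never as
#' zero. Vectorised.
#'
#' @param pre,post Numeric values measured before and after training.
#' @return Percent change(s).
#' @export
#' @examples
#' percent_change(150, 180)   # +20
percent_change <- function(pre, post) {
  pre <- as.numeric(pre)
  post <- as.numeric(post)
  out <- 100 * (post - pre) / pre
  out[!is.na(pre) & pre == 0] <- NA_real_
  out
}

# Instrument grouping of the canonical parameter names.
parameter_group <- function(name) {
  ramp <- c("vo2peak_Lmin", "vo2peak_rel_mLkgmin", "ppeak_W", "hrpeak_bpm",
            "sbp_peak_mmHg", "dbp_peak_mmHg", "blpeak_mmolL")
  nirs <- c("baseline_pct", "min_pct", "delta_deoxy_pct", "t_deoxy_s",
            "slope_deoxy_pct_per_min", "max_pct", "half_level_pct",
            "delta_half_pct", "t_half_s", "slope_half_pct_per_min",
            "overshoot_pct")
  ifelse(name %in% ramp, "ramp",
         ifelse(name %in% nirs, "nirs",
                ifelse(grepl("power|avg_W|peak_W", name), "power", "other")))
}

#' Flatten a session's extracted parameters into one named vector
#'
#' Convenience for building PRE/POST reports: runs [extract_peaks()] and
#' [compute_features()] on a session and returns all values as a single
#' named numeric vector.
#'
#' @param session A [ramp_session()].
#' @param ... Passed to [compute_features()] (e.g. `cutoff_hz`).
#' @return Named numeric vector of cardiorespiratory peaks and SmO2
#'   landmarks.
#' @export
session_parameters <- function(session, ...) {
  pk <- extract_peaks(session)
  ft <- compute_features(session_channel(session, "smo2_pct"),
                         session$protocol, session$exhaustion_time_s, ...)
  c(unlist(unclass(pk)), unlist(unclass(ft)))
}

#' Build a PRE/POST change report
#'
#' Computes the percentage change of every parameter present in both
#' input sets; parameters present in only one set are listed separately
#' and never silently dropped. Row order is deterministic (alphabetical
#' within instrument group). The same inputs always produce an identical
#' report.
#'
#' @param pre,post Named numeric vectors (or coercible lists) of
#'   parameters measured before / after the training period.
#' @param subject Optional subject label.
#' @param protocol_label Optional `"CON"` or `"ECC"` tag.
#' @return An object of class `change_report`: a data frame with columns
#'   `group`, `parameter`, `pre_value`, `post_value`, `pct_change`, with
#'   unmatched parameter names in attributes `unmatched_pre` /
#'   `unmatched_post`.
#' @export
#' @examples
#' build_report(c(ppeak_W = 150, vo2peak_Lmin = 1.94),
#'              c(ppeak_W = 180, vo2peak_Lmin = 2.44))
build_report <- function(pre, post, subject = NULL, protocol_label = NULL) {
  pre <- unlist(pre)
  post <- unlist(post)
  if (is.null(names(pre)) || is.null(names(post)))
    stop("`pre` and `post` must be named", call. = FALSE)
  shared <- intersect(names(pre), names(post))
  if (length(shared) == 0L)
    stop("the PRE and POST parameter sets are disjoint", call. = FALSE)
  grp <- parameter_group(shared)
  ord <- order(grp, shared)
  shared <- shared[ord]
  df <- data.frame(
    group = parameter_group(shared),
    parameter = shared,
    pre_value = as.numeric(pre[shared]),
    post_value = as.numeric(post[shared]),
    pct_change = percent_change(pre[shared], post[shared]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(df,
            class = c("change_report", "data.frame"),
            subject = subject, protocol_label = protocol_label,
            unmatched_pre = sort(setdiff(names(pre), shared)),
            unmatched_post = sort(setdiff(names(post), shared)))
}

#' @export
print.change_report <- function(x, digits = 1, ...) {
  lab <- c(attr(x, "subject"), attr(x, "protocol_label"))
  cat("<change_report>", if (length(lab)) paste(lab, collapse = " / "), "\n")
  shown <- as.data.frame(x)
  shown$pct_change <- round(shown$pct_change, digits)
  print(shown)
  up <- attr(x, "unmatched_pre"); uo <- attr(x, "unmatched_post")
  if (length(up)) cat("  PRE only:", paste(up, collapse = ", "), "\n")
  if (length(uo)) cat("  POST only:", paste(uo, collapse = ", "), "\n")
  invisible(x)
}

#' Write a change report as JSON and/or flat CSV
#'
#' Output is a pure function of the report: identical reports give
#' byte-identical files.
#'
#' @param report A [build_report()] result.
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, `report`.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "change_report"))
  payload <- list(
    subject = attr(report, "subject"),
    protocol = attr(report, "protocol_label"),
    changes = as.data.frame(report),
    unmatched_pre = attr(report, "unmatched_pre"),
    unmatched_post = attr(report, "unmatched_post"))
  if (!is.null(json_path))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  invisible(report)
}
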