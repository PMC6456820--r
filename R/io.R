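# Session serialisation: one CSV per continuous channel (time_s,value),
# one CSV for the discrete samples, and a JSON config carrying the
# protocol, exhaustion time and subject metadata. Numbers are written with
# 17 significant digits so a write/read cycle is lossless for doubles.

fmt_num <- function(x) sprintf("%.17g", x)

write_num_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a ramp session to a directory
#'
#' Produces `<channel>.csv` files with columns `time_s,value` for every
#' continuous channel, `discrete.csv` with columns `time_s,value,channel`,
#' and `session.json` with the protocol constants, exhaustion time and
#' body mass. [read_session()] restores the session field for field.
#'
#' @param session A [ramp_session()].
#' @param directory Target directory; created if missing.
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "ramp_session"))
  if (length(session$traces) == 0L)
    stop("session has no channel traces to write", call. = FALSE)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)

  files <- character(0)
  for (ch in names(session$traces)) {
    path <- file.path(directory, paste0(ch, ".csv"))
    write_num_csv(as.data.frame(session$traces[[ch]]), path)
    files <- c(files, path)
  }
  dpath <- file.path(directory, "discrete.csv")
  write_num_csv(session$discrete[, c("time_s", "value", "channel")], dpath)

  cfg <- list(
    protocol = unclass(session$protocol),
    exhaustion_time_s = session$exhaustion_time_s,
    body_mass_kg = session$body_mass_kg,
    channels = lapply(session$traces, function(tr)
      list(channel = tr$channel, units = tr$units)))
  cpath <- file.path(directory, "session.json")
  jsonlite::write_json(cfg, cpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, dpath, cpath))
}

#' Read a ramp session written by [write_session()]
#'
#' @param directory Directory containing the session files.
#' @return A [ramp_session()].
#' @export
read_session <- function(directory) {
  cpath <- file.path(directory, "session.json")
  if (!file.exists(cpath))
    stop("no session.json in ", directory, call. = FALSE)
  cfg <- jsonlite::read_json(cpath, simplifyVector = TRUE)

  traces <- list()
  for (ch in names(cfg$channels)) {
    path <- file.path(directory, paste0(ch, ".csv"))
    if (!file.exists(path))
      stop("missing channel file: ", path, call. = FALSE)
    df <- utils::read.csv(path)
    meta <- cfg$channels[[ch]]
    traces[[ch]] <- phys_trace(df$time_s, df$value,
                               meta$channel, meta$units)
  }
  discrete <- utils::read.csv(file.path(directory, "discrete.csv"),
                              stringsAsFactors = FALSE)
  proto <- do.call(ramp_protocol, as.list(cfg$protocol))
  ramp_session(traces, discrete, proto,
               exhaustion_time_s = cfg$exhaustion_time_s,
               body_mass_kg = cfg$body_mass_kg)
}
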