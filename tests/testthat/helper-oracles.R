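# Independent brute-force oracles used to cross-check the vectorised
# implementations. Deliberately written as plain loops over the
# definitions; they share no code with the package internals.

# Highest mean over all contiguous windows of n samples.
brute_window_peak <- function(values, n) {
  best <- -Inf
  for (i in seq_len(length(values) - n + 1L)) {
    m <- mean(values[i:(i + n - 1L)])
    if (m > best) best <- m
  }
  best
}

# Exhaustive re-implementation of the minimum-landmark definition:
# onset = start of the first rise sustained >= onset_rise_s and gaining
# >= min_rise at/after t=0, then the last discrete local minimum
# (strictly below left neighbour, not above right) at or before onset,
# else the global minimum on [0, onset].
brute_smo2_min <- function(times, values, onset_rise_s = 30, min_rise = 2) {
  n <- length(values)
  onset <- times[n]
  for (i in seq_len(n - 1L)) {
    if (times[i] < 0) next
    if (i > 1L && times[i - 1L] >= 0 && values[i] > values[i - 1L])
      next  # mid-run: the run already started at an earlier sample
    j <- i
    while (j < n && values[j + 1L] > values[j]) j <- j + 1L
    if (j > i && times[j] - times[i] >= onset_rise_s &&
        values[j] - values[i] >= min_rise) {
      onset <- times[i]
      break
    }
  }
  cand <- integer(0)
  for (i in 2:(n - 1L)) {
    if (times[i] < 0 || times[i] > onset) next
    if (values[i - 1L] > values[i] && values[i] <= values[i + 1L])
      cand <- c(cand, i)
  }
  if (length(cand) > 0L) {
    i <- cand[length(cand)]
  } else {
    win <- which(times >= 0 & times <= onset)
    i <- win[which.min(values[win])]
  }
  list(value = values[i], time_s = times[i])
}

# A random but plausible ramp-test-like SmO2 signal on a 1-Hz grid:
# noisy decline followed by noisy recovery.
random_smo2_trace <- function(n_pre = 60, n_down = 300, n_up = 200,
                              noise = 1) {
  v <- c(rep(65, n_pre),
         seq(65, 30, length.out = n_down),
         seq(30, 70, length.out = n_up)) +
    stats::rnorm(n_pre + n_down + n_up, 0, noise)
  t <- seq_along(v) - 1 - n_pre
  phys_trace(t, v, "smo2_pct", "%")
}

default_noiseless <- function(...) {
  kinetics_params(noise_sd = 0, ...)
}
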