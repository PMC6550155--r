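# Independent oracles used to freeze expected values. These deliberately
# re-derive quantities by the most direct route (naive O(n^2) DFT, brute
# scans, closed forms) and never call the implementation they check.

# naive packetized mean power spectrum: O(n^2) DFT per packet
naive_mean_power_spectrum <- function(signal, rate, packet) {
  n_pack <- length(signal) %/% packet
  keep <- packet %/% 2 + 1
  acc <- numeric(keep)
  for (b in seq_len(n_pack)) {
    seg <- signal[((b - 1) * packet + 1):(b * packet)]
    seg <- seg - mean(seg)
    for (k in 0:(keep - 1)) {
      re <- sum(seg * cos(-2 * pi * k * (0:(packet - 1)) / packet))
      im <- sum(seg * sin(-2 * pi * k * (0:(packet - 1)) / packet))
      acc[k + 1] <- acc[k + 1] + (re^2 + im^2)
    }
  }
  pw <- acc / n_pack
  list(freqs = (0:(keep - 1)) * rate / packet, power = pw / sum(pw))
}

# discrete quantile of a normalized spectrum by cumulative scan
oracle_power_quantile <- function(freqs, power, q) {
  cs <- 0
  for (i in seq_along(power)) {
    cs <- cs + power[i]
    if (cs >= q - 1e-12) return(freqs[i])
  }
  freqs[length(freqs)]
}

oracle_bandwidth <- function(freqs, power, coverage = 0.9) {
  tail <- (1 - coverage) / 2
  oracle_power_quantile(freqs, power, 1 - tail) -
    oracle_power_quantile(freqs, power, tail)
}

# brute-force stroke count: scan the on/off mask
oracle_stroke_count <- function(on) {
  n <- 0
  prev <- FALSE
  for (v in on) {
    if (v && !prev) n <- n + 1
    prev <- v
  }
  n
}

# brute-force in-air ratio from timestamp sums
oracle_in_air <- function(t, on) {
  off_sum <- 0
  for (i in seq_len(length(t) - 1))
    if (!on[i]) off_sum <- off_sum + (t[i + 1] - t[i])
  off_sum / (t[length(t)] - t[1])
}

# a minimal valid recording from x/y paths (defaults fill the rest)
make_recording <- function(x, y, t = NULL, on = NULL, rate = 200,
                           pressure = NULL, tilt_x = 0, tilt_y = 0,
                           meta = list()) {
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1) / rate
  if (is.null(on)) on <- rep(TRUE, n)
  if (is.null(pressure)) pressure <- rep(0.5, n)
  recording(t, x, y, pressure,
            rep_len(tilt_x, n), rep_len(tilt_y, n), on,
            sampling_rate = rate, meta = meta)
}

# random valid recording for round-trip properties
random_recording <- function(n = 50, seed = 1) {
  set.seed(seed)
  t <- cumsum(runif(n, 0.004, 0.006))
  recording(t, cumsum(rnorm(n)), cumsum(rnorm(n)),
            runif(n), runif(n, -60, 60), runif(n, -60, 60),
            runif(n) > 0.3, sampling_rate = 200,
            meta = list(id = paste0("w", seed), age = 8, gender = "f",
                        laterality = "R", label = "TD"))
}
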