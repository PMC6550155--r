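#' Spectral analysis configuration
#'
#' Parameters of the packetized power-spectrum pipeline shared by the
#' tremor, speed, pressure-change and tilt-change frequency features.
#'
#' @param packet_size samples per packet (default 600). The signal is cut
#'   into consecutive non-overlapping packets of this length and one power
#'   spectrum is computed per packet before averaging.
#' @param coverage fraction of total spectral power the bandwidth feature
#'   must cover (default 0.90, i.e. the central 90% interval).
#' @param window_size points per direction window of the tremor signal
#'   (default 10).
#' @param hann apply a Hann window to each packet before the transform.
#'   Off by default: packets are only mean-removed (rectangular window).
#' @return a list of class `spectral_config`.
#' @export
spectral_config <- function(packet_size = 600, coverage = 0.90,
                            window_size = 10, hann = FALSE) {
  stopifnot(packet_size >= 2 * window_size, coverage > 0, coverage < 1,
            window_size >= 2)
  structure(list(packet_size = as.integer(packet_size),
                 coverage = coverage,
                 window_size = as.integer(window_size),
                 hann = isTRUE(hann)),
            class = "spectral_config")
}

new_spectrum <- function(freqs, power) {
  structure(list(freqs = freqs, power = power), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "Normalized power spectrum: %d bins, 0-%.3g Hz (df = %.4g Hz)\n",
    length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  cat(sprintf("  median %.3g Hz, 90%% bandwidth %.3g Hz\n",
              spectral_median(x), spectral_bandwidth(x, 0.90)))
  invisible(x)
}

check_spectrum <- function(s) {
  if (!inherits(s, "spectrum"))
    stop("expected a 'spectrum' object")
  if (abs(sum(s$power) - 1) > 1e-9)
    stop("spectrum power is not normalized to unit sum")
  invisible(s)
}

#' Packet-averaged normalized power spectrum
#'
#' Cuts a signal into consecutive non-overlapping packets of
#' `cfg$packet_size` samples (any remainder is discarded), removes each
#' packet's mean, computes the squared magnitude of the discrete Fourier
#' transform at the non-negative frequencies, averages the per-packet power
#' across packets, and normalizes the averaged power vector to unit sum so
#' that spectra are comparable across writers of different amplitude.
#'
#' @param signal real-valued series.
#' @param rate sampling rate of the series in Hz; sets the frequency axis
#'   `freqs = (0:(packet_size %/% 2)) * rate / packet_size`.
#' @param cfg a [spectral_config()].
#' @return a `spectrum` object with fields `freqs` (Hz) and `power`
#'   (non-negative, summing to 1).
#' @export
mean_power_spectrum <- function(signal, rate, cfg = spectral_config()) {
  n <- length(signal)
  p <- cfg$packet_size
  if (n < p)
    stop("insufficient data: signal has ", n,
         " samples but one packet requires ", p)
  n_pack <- n %/% p
  m <- matrix(signal[seq_len(n_pack * p)], nrow = p)
  m <- sweep(m, 2L, colMeans(m))                    # mean removal per packet
  if (cfg$hann) {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(p) - 1) / (p - 1))
    m <- m * w
  }
  ft <- stats::mvfft(m)
  keep <- seq_len(p %/% 2 + 1L)                     # non-negative frequencies
  pw <- Mod(ft[keep, , drop = FALSE])^2
  avg <- rowMeans(pw)
  tot <- sum(avg)
  if (tot <= 0)
    stop("degenerate signal: spectrum has zero total power ",
         "(constant within every packet)")
  new_spectrum(freqs = (keep - 1L) * rate / p, power = avg / tot)
}

# smallest frequency at which cumulative power reaches q (discrete quantile)
power_quantile <- function(s, q) {
  cs <- cumsum(s$power)
  s$freqs[which(cs >= q - 1e-12)[1L]]
}

#' Bandwidth covering a fraction of spectral power
#'
#' Width of the central interval of the power-weighted frequency
#' distribution holding `coverage` of the total power, with symmetric tails
#' of `(1 - coverage)/2` on each side. Quantiles are discrete: the q-th
#' quantile is the smallest bin frequency at which cumulative power reaches
#' q. A single-bin spectrum has bandwidth 0.
#'
#' @param s a normalized `spectrum`.
#' @param coverage covered power fraction in (0, 1); default 0.90.
#' @return bandwidth in Hz.
#' @export
spectral_bandwidth <- function(s, coverage = 0.90) {
  check_spectrum(s)
  stopifnot(coverage > 0, coverage < 1)
  tail <- (1 - coverage) / 2
  power_quantile(s, 1 - tail) - power_quantile(s, tail)
}

#' Power-weighted median frequency
#'
#' Frequency of the bin at which cumulative power first reaches one half.
#' High values indicate spectra shifted toward high frequencies.
#'
#' @param s a normalized `spectrum`.
#' @return median frequency in Hz.
#' @export
spectral_median <- function(s) {
  check_spectrum(s)
  power_quantile(s, 0.5)
}

#' Euclidean distance between two spectra
#'
#' L2 distance between the normalized power vectors of two spectra sharing
#' the same frequency axis. Used for all "distance to cohort mean"
#' features; no resampling is attempted on mismatched axes.
#'
#' @param s,ref normalized `spectrum` objects on identical axes.
#' @return non-negative scalar.
#' @export
spectral_distance <- function(s, ref) {
  check_spectrum(s); check_spectrum(ref)
  if (length(s$freqs) != length(ref$freqs) ||
      max(abs(s$freqs - ref$freqs)) > 1e-9)
    stop("spectra are on different frequency axes; cannot compare")
  sqrt(sum((s$power - ref$power)^2))
}

#' Cohort mean spectrum
#'
#' Element-wise mean of the power vectors of a set of spectra on a shared
#' frequency axis, re-normalized to unit sum. This is the reference object
#' behind every distance-to-mean feature; computing it from the training
#' split only prevents information leaking into test-set features.
#'
#' @param spectra non-empty list of normalized `spectrum` objects.
#' @return a `spectrum`.
#' @export
cohort_mean_spectrum <- function(spectra) {
  spectra <- spectra[!vapply(spectra, is.null, TRUE)]
  if (!length(spectra)) stop("no spectra supplied")
  f0 <- spectra[[1L]]$freqs
  for (s in spectra) {
    check_spectrum(s)
    if (length(s$freqs) != length(f0) || max(abs(s$freqs - f0)) > 1e-9)
      stop("spectra are on different frequency axes; cannot average")
  }
  pw <- rowMeans(vapply(spectra, `[[`, numeric(length(f0)), "power"))
  new_spectrum(f0, pw / sum(pw))
}

# largest power of two <= n, floored at 128; NA if even 128 does not fit.
# Used to shrink the packet size for short (truncated) recordings so the
# spectral families stay computable down to 15-s traces.
adapt_packet <- function(n, packet_size) {
  if (n >= packet_size) return(as.integer(packet_size))
  if (n < 128L) return(NA_integer_)
  as.integer(2^floor(log2(n)))
}
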