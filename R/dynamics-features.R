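#' Dynamics feature configuration
#'
#' Parameters of the shared smoothed-derivative engine behind the speed,
#' pressure-change and tilt-change features.
#'
#' @param smooth_n moving-average window in samples (default 10) applied to
#'   the raw channel before differencing; suppresses digitizer noise.
#' @param subsample keep every k-th smoothed point (default 10); with a
#'   200 Hz tablet the derived series run at 20 Hz.
#' @param peak_sigma standard deviation, in seconds, of the Gaussian
#'   filter applied before extrema counting (default 0.25). Specified in
#'   seconds rather than samples so results survive resampling.
#' @param spectral a [spectral_config()] for the derived-series spectra.
#' @return a list of class `dynamics_config`.
#' @export
dynamics_config <- function(smooth_n = 10, subsample = 10,
                            peak_sigma = 0.25,
                            spectral = spectral_config()) {
  stopifnot(smooth_n >= 1, subsample >= 1, peak_sigma > 0)
  structure(list(smooth_n = as.integer(smooth_n),
                 subsample = as.integer(subsample),
                 peak_sigma = peak_sigma, spectral = spectral),
            class = "dynamics_config")
}

new_derived_series <- function(t, v, effective_rate, duration) {
  structure(list(t = t, v = v, effective_rate = effective_rate,
                 duration = duration),
            class = "derived_series")
}

#' @export
print.derived_series <- function(x, ...) {
  cat(sprintf(
    "Derived series: %d points at %.3g Hz effective, %.2f s on-surface\n",
    length(x$v), x$effective_rate, x$duration))
  invisible(x)
}

# rolling mean of window n (valid region only): out[i] = mean(v[i:(i+n-1)])
roll_mean <- function(v, n) {
  if (n == 1L) return(v)
  cs <- cumsum(c(0, v))
  (cs[(n + 1L):length(cs)] - cs[seq_len(length(cs) - n)]) / n
}

# shared engine: smooth the requested channels over each on-surface stroke,
# retain every `subsample`-th point, and return the retained positions with
# their (window-centre) timestamps. Spans never straddle a pen lift: a
# measurement is kept only if the pen stayed on the surface for all raw
# samples it covers.
retained_points <- function(rec, channels, cfg) {
  n <- cfg$smooth_n
  centre <- ((n - 1L) %/% 2L) + 1L
  segs <- list()
  for (s in segment_strokes(rec)) {
    if (nrow(s) < n + cfg$subsample) next
    m <- nrow(s) - n + 1L
    keep <- seq(1L, m, by = cfg$subsample)
    if (length(keep) < 2L) next
    seg <- list(t = s$t[keep + centre - 1L])
    for (ch in channels) seg[[ch]] <- roll_mean(s[[ch]], n)[keep]
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

on_surface_duration <- function(rec) {
  dt <- diff(rec$t)
  sum(dt[rec$on_surface[-nrow(rec)]])
}

#' Handwriting speed series
#'
#' Distance travelled by the pen divided by the time taken, computed
#' between consecutive retained points of the smoothed, subsampled pen
#' trajectory. Raw coordinates are moving-averaged over `cfg$smooth_n`
#' samples and every `cfg$subsample`-th point is kept; a speed measurement
#' is retained only when the pen stayed on the surface over all raw
#' samples it spans, so pen lifts contribute nothing.
#'
#' @param rec a [recording()].
#' @param cfg a [dynamics_config()].
#' @return a `derived_series` (units/s); `NULL` when no stroke is long
#'   enough.
#' @export
derived_speed <- function(rec, cfg = dynamics_config()) {
  segs <- retained_points(rec, c("x", "y"), cfg)
  if (!length(segs)) return(NULL)
  t <- v <- numeric(0)
  for (seg in segs) {
    dt <- diff(seg$t)
    sp <- sqrt(diff(seg$x)^2 + diff(seg$y)^2) / dt
    t <- c(t, (seg$t[-1L] + seg$t[-length(seg$t)]) / 2)
    v <- c(v, sp)
  }
  new_derived_series(t, v,
                     attr(rec, "sampling_rate") / cfg$subsample,
                     on_surface_duration(rec))
}

#' Change speed of a scalar pen channel
#'
#' Same smoothing/subsampling engine as [derived_speed()] applied to the
#' pressure or a tilt channel; the value between consecutive retained
#' points is `|change in smoothed channel| / time elapsed` (1/s for
#' pressure, deg/s for tilt). Tilt change is computed over on-surface
#' samples only (hover tilt is unreliable across devices).
#'
#' @param rec a [recording()].
#' @param channel one of `"pressure"`, `"tilt_x"`, `"tilt_y"`.
#' @param cfg a [dynamics_config()].
#' @return a `derived_series`, or `NULL` when no stroke is long enough.
#' @export
channel_change_speed <- function(rec,
                                 channel = c("pressure", "tilt_x", "tilt_y"),
                                 cfg = dynamics_config()) {
  channel <- match.arg(channel)
  segs <- retained_points(rec, channel, cfg)
  if (!length(segs)) return(NULL)
  t <- v <- numeric(0)
  for (seg in segs) {
    dt <- diff(seg$t)
    t <- c(t, (seg$t[-1L] + seg$t[-length(seg$t)]) / 2)
    v <- c(v, abs(diff(seg[[channel]])) / dt)
  }
  new_derived_series(t, v,
                     attr(rec, "sampling_rate") / cfg$subsample,
                     on_surface_duration(rec))
}

#' Mean, maximum and standard deviation of a derived series
#'
#' The std is the population standard deviation (n denominator).
#'
#' @param s a `derived_series` (or plain numeric vector).
#' @return named list `mean`, `max`, `std`; all `NA` for empty input.
#' @export
series_stats <- function(s) {
  v <- if (inherits(s, "derived_series")) s$v else s
  if (!length(v)) return(list(mean = NA_real_, max = NA_real_, std = NA_real_))
  list(mean = mean(v), max = max(v), std = pop_sd(v))
}

#' Temporal evolution (OLS slope) of a derived series
#'
#' Ordinary least-squares slope of the series values against time,
#' capturing drift such as fatigue-driven slow-down over the course of the
#' test.
#'
#' @param s a `derived_series`.
#' @return slope in (series units)/s; `NA` when time has no variance.
#' @export
slope_over_time <- function(s) {
  if (length(s$v) < 2L) return(NA_real_)
  tc <- s$t - mean(s$t)
  den <- sum(tc^2)
  if (den <= 0) return(NA_real_)
  sum(tc * (s$v - mean(s$v))) / den
}

gaussian_smooth <- function(v, sigma_samples) {
  if (sigma_samples <= 0) return(v)
  r <- max(1L, ceiling(4 * sigma_samples))
  k <- exp(-0.5 * ((-r:r) / sigma_samples)^2)
  n <- length(v)
  vp <- c(rep(v[1L], r), v, rep(v[n], r))      # edge replication
  out <- stats::filter(vp, k / sum(k), sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Local extrema per second of a derived series
#'
#' The series is Gaussian-smoothed (`cfg$peak_sigma` seconds, converted to
#' samples via the effective rate), strict local maxima and minima are
#' counted, and the count is divided by the on-surface handwriting time.
#' Heavier smoothing can only merge extrema, so the rate is non-increasing
#' in `peak_sigma`.
#'
#' @param s a `derived_series`.
#' @param cfg a [dynamics_config()].
#' @return extrema per second; `NA` for series shorter than 3 points.
#' @export
peaks_per_second <- function(s, cfg = dynamics_config()) {
  if (length(s$v) < 3L || !is.finite(s$duration) || s$duration <= 0)
    return(NA_real_)
  sm <- gaussian_smooth(s$v, cfg$peak_sigma * s$effective_rate)
  n <- length(sm)
  mid <- sm[2:(n - 1L)]
  lo <- sm[1:(n - 2L)]
  hi <- sm[3:n]
  n_ext <- sum(mid > lo & mid > hi) + sum(mid < lo & mid < hi)
  n_ext / s$duration
}

#' Acceleration statistics from a speed series
#'
#' Finite-difference magnitude `|dv|/dt` between consecutive speed points,
#' summarized by [series_stats()].
#'
#' @param s the speed `derived_series` from [derived_speed()].
#' @return named list `mean`, `max`, `std`.
#' @export
acceleration_stats <- function(s) {
  if (is.null(s) || length(s$v) < 2L)
    return(list(mean = NA_real_, max = NA_real_, std = NA_real_))
  a <- abs(diff(s$v)) / diff(s$t)
  series_stats(a[is.finite(a)])
}

#' In-air time ratio
#'
#' Fraction of the recording's duration during which the pen did not touch
#' the tablet surface. Each inter-sample interval is attributed to the
#' surface state of its opening sample; durations come from the actual
#' timestamps.
#'
#' @param rec a [recording()].
#' @return fraction in `[0, 1]`.
#' @export
in_air_time_ratio <- function(rec) {
  dt <- diff(rec$t)
  total <- sum(dt)
  if (total <= 0) return(NA_real_)
  sum(dt[!rec$on_surface[-nrow(rec)]]) / total
}

#' Spectral summaries of a derived series
#'
#' Packet-averaged normalized power spectrum of the series at its
#' effective rate, reduced to 90% bandwidth, power-weighted median and
#' (when a reference spectrum is given) Euclidean distance to the cohort
#' mean. The packet size shrinks to the largest power of two that fits the
#' series (floor 128) when the configured packet does not fit, so the
#' features stay computable on short truncated recordings.
#'
#' @param s a `derived_series`.
#' @param ref_spectrum optional cohort mean `spectrum` for this family.
#' @param cfg a [spectral_config()].
#' @param packet_size overrides the packet size (used to pin the axis to a
#'   cohort reference).
#' @return list `bandwidth`, `median`, `distance` (NA-filled when the
#'   series is too short).
#' @export
series_spectral_features <- function(s, ref_spectrum = NULL,
                                     cfg = spectral_config(),
                                     packet_size = NULL) {
  empty <- list(bandwidth = NA_real_, median = NA_real_, distance = NA_real_)
  if (is.null(s)) return(empty)
  sp <- series_spectrum(s, cfg, packet_size)
  if (is.null(sp)) return(empty)
  dist <- NA_real_
  if (!is.null(ref_spectrum) &&
      length(ref_spectrum$freqs) == length(sp$freqs) &&
      max(abs(ref_spectrum$freqs - sp$freqs)) <= 1e-9)
    dist <- spectral_distance(sp, ref_spectrum)
  list(bandwidth = spectral_bandwidth(sp, cfg$coverage),
       median = spectral_median(sp),
       distance = dist)
}

series_spectrum <- function(s, cfg, packet_size = NULL) {
  if (is.null(s)) return(NULL)
  p <- if (is.null(packet_size)) adapt_packet(length(s$v), cfg$packet_size)
       else as.integer(packet_size)
  if (is.na(p) || length(s$v) < p) return(NULL)
  cfg2 <- cfg
  cfg2$packet_size <- p
  tryCatch(mean_power_spectrum(s$v, s$effective_rate, cfg2),
           error = function(e) NULL)
}

# ---- feature-vector assembly ------------------------------------------------

#' Names of the handwriting feature bank
#'
#' The fixed name set and order of the feature vector: 8 static, 12
#' kinematic, 10 pressure and 22 tilt features (52 in total). `d` prefixes
#' denote change-speed series (e.g. `dpressure` = speed of pressure
#' change); `_freq_` features are spectral summaries of those series.
#'
#' @return character vector of feature names.
#' @export
feature_names <- function() {
  c(# static
    "space_between_words", "word_gap_std", "density", "moment", "size",
    "tremor_bandwidth", "tremor_median", "tremor_distance",
    # kinematic
    "speed_mean", "speed_max", "speed_std", "speed_slope",
    "speed_peaks_per_s",
    "speed_freq_bandwidth", "speed_freq_median", "speed_freq_distance",
    "accel_mean", "accel_max", "accel_std", "in_air_ratio",
    # pressure
    "pressure_mean", "pressure_max", "pressure_std",
    "dpressure_mean", "dpressure_max", "dpressure_std",
    "dpressure_peaks_per_s",
    "dpressure_freq_bandwidth", "dpressure_freq_median",
    "dpressure_freq_distance",
    # tilt
    "tilt_x_mean", "tilt_x_max", "tilt_x_std",
    "tilt_y_mean", "tilt_y_max", "tilt_y_std",
    "dtilt_x_mean", "dtilt_x_max", "dtilt_x_std", "dtilt_x_peaks_per_s",
    "dtilt_x_slope",
    "dtilt_y_mean", "dtilt_y_max", "dtilt_y_std", "dtilt_y_peaks_per_s",
    "dtilt_y_slope",
    "dtilt_x_freq_bandwidth", "dtilt_x_freq_median", "dtilt_x_freq_distance",
    "dtilt_y_freq_bandwidth", "dtilt_y_freq_median", "dtilt_y_freq_distance")
}

spectral_families <- c("tremor", "speed", "dpressure", "dtilt_x", "dtilt_y")

# the five family signals of a recording as derived_series objects
# (tremor is wrapped into a pseudo-series at the raw rate)
family_series <- function(rec, static_cfg, dyn_cfg) {
  tre <- tryCatch(tremor_signal(rec, static_cfg), error = function(e) NULL)
  tre_s <- if (is.null(tre)) NULL else
    new_derived_series(seq_along(tre) / attr(rec, "sampling_rate"), tre,
                       attr(rec, "sampling_rate"), on_surface_duration(rec))
  list(tremor = tre_s,
       speed = derived_speed(rec, dyn_cfg),
       dpressure = channel_change_speed(rec, "pressure", dyn_cfg),
       dtilt_x = channel_change_speed(rec, "tilt_x", dyn_cfg),
       dtilt_y = channel_change_speed(rec, "tilt_y", dyn_cfg))
}

# spectra of the five families at the given per-family packet sizes
family_spectra <- function(series, packets, static_cfg, dyn_cfg) {
  out <- list()
  for (fam in spectral_families) {
    cfg <- if (fam == "tremor")
      spectral_config(packet_size = static_cfg$tremor_packet,
                      window_size = static_cfg$tremor_window)
    else dyn_cfg$spectral
    out[[fam]] <- series_spectrum(series[[fam]], cfg,
                                  packet_size = packets[[fam]])
  }
  out
}

#' Cohort reference spectra
#'
#' Averages the five family spectra (tremor, speed, pressure change, tilt-x
#' change, tilt-y change) over a set of recordings, producing the reference
#' against which every "distance to mean" feature is computed. Build it
#' from training recordings only: using test-set recordings leaks
#' information into the evaluation.
#'
#' Per family, the packet size is the configured one, shrunk (power of
#' two, floor 128) to fit the shortest usable series in the cohort so that
#' all writers share one frequency axis.
#'
#' @param recordings list of [recording()] objects.
#' @param static_cfg a [static_config()].
#' @param dyn_cfg a [dynamics_config()].
#' @return object of class `cohort_reference`: list with `spectra` (one
#'   mean `spectrum` or NULL per family), `packets`, and `n` (recordings
#'   contributing per family).
#' @export
cohort_reference <- function(recordings, static_cfg = static_config(),
                             dyn_cfg = dynamics_config()) {
  if (!length(recordings)) stop("no recordings supplied")
  all_series <- lapply(recordings, family_series, static_cfg, dyn_cfg)
  packets <- reference_packets(all_series, static_cfg, dyn_cfg)
  sp <- lapply(all_series, family_spectra, packets, static_cfg, dyn_cfg)
  reference_from_spectra(sp, packets)
}

reference_packets <- function(all_series, static_cfg, dyn_cfg) {
  packets <- list()
  for (fam in spectral_families) {
    configured <- if (fam == "tremor") static_cfg$tremor_packet
                  else dyn_cfg$spectral$packet_size
    lens <- vapply(all_series, function(fs)
      if (is.null(fs[[fam]])) 0L else length(fs[[fam]]$v), 0L)
    lens <- lens[lens >= 128L]
    packets[[fam]] <- if (!length(lens)) NA_integer_
                      else adapt_packet(min(lens), configured)
  }
  packets
}

reference_from_spectra <- function(per_rec_spectra, packets) {
  spectra <- list(); n <- integer(0)
  for (fam in spectral_families) {
    fam_sp <- lapply(per_rec_spectra, `[[`, fam)
    fam_sp <- fam_sp[!vapply(fam_sp, is.null, TRUE)]
    spectra[[fam]] <- if (length(fam_sp)) cohort_mean_spectrum(fam_sp)
                      else NULL
    n[fam] <- length(fam_sp)
  }
  structure(list(spectra = spectra, packets = packets, n = n),
            class = "cohort_reference")
}

#' @export
print.cohort_reference <- function(x, ...) {
  cat("Cohort reference spectra:\n")
  for (fam in names(x$spectra))
    cat(sprintf("  %-10s packet %s, %d recordings\n", fam,
                ifelse(is.na(x$packets[[fam]]), "-",
                       as.character(x$packets[[fam]])), x$n[fam]))
  invisible(x)
}

#' Extract the full handwriting feature vector of one recording
#'
#' Assembles all 52 static, kinematic, pressure and tilt features (see
#' [feature_names()]). Deterministic given the recording and
#' configurations. Features whose preconditions fail (e.g. spectral
#' families on recordings too short for one packet) are `NA`, never
#' silently imputed; the three distance features additionally require a
#' cohort reference with a matching frequency axis.
#'
#' @param rec a [recording()].
#' @param ref optional [cohort_reference()]; when supplied, its per-family
#'   packet sizes pin the spectral axes so distances are well defined.
#' @param static_cfg a [static_config()].
#' @param dyn_cfg a [dynamics_config()].
#' @return named numeric vector of length 52.
#' @export
extract_features <- function(rec, ref = NULL,
                             static_cfg = static_config(),
                             dyn_cfg = dynamics_config()) {
  series <- family_series(rec, static_cfg, dyn_cfg)
  packets <- if (!is.null(ref)) ref$packets else
    lapply(stats::setNames(spectral_families, spectral_families),
           function(fam) {
             configured <- if (fam == "tremor") static_cfg$tremor_packet
                           else dyn_cfg$spectral$packet_size
             if (is.null(series[[fam]])) NA_integer_
             else adapt_packet(length(series[[fam]]$v), configured)
           })
  spectra <- family_spectra(series, packets, static_cfg, dyn_cfg)
  assemble_features(rec, series, spectra, ref, static_cfg, dyn_cfg)
}

assemble_features <- function(rec, series, spectra, ref,
                              static_cfg, dyn_cfg) {
  fv <- stats::setNames(rep(NA_real_, length(feature_names())),
                        feature_names())
  sbw <- space_between_words(rec, static_cfg)
  fv["space_between_words"] <- sbw$mean_log_gap
  fv["word_gap_std"] <- sbw$gap_std
  fv["density"] <- tryCatch(handwriting_density(rec, static_cfg),
                            error = function(e) NA_real_)
  fv["moment"] <- handwriting_moment(rec, static_cfg)
  fv["size"] <- handwriting_size(rec, static_cfg)

  scfg_t <- spectral_config(packet_size = max(static_cfg$tremor_packet,
                                              2 * static_cfg$tremor_window),
                            window_size = static_cfg$tremor_window)
  for (fam in spectral_families) {
    cfg <- if (fam == "tremor") scfg_t else dyn_cfg$spectral
    prefix <- if (fam == "tremor") "tremor" else paste0(fam, "_freq")
    sp <- spectra[[fam]]
    ref_sp <- if (!is.null(ref)) ref$spectra[[fam]] else NULL
    if (!is.null(sp)) {
      fv[paste0(prefix, "_bandwidth")] <- spectral_bandwidth(sp, cfg$coverage)
      fv[paste0(prefix, "_median")] <- spectral_median(sp)
      if (!is.null(ref_sp) &&
          length(ref_sp$freqs) == length(sp$freqs) &&
          max(abs(ref_sp$freqs - sp$freqs)) <= 1e-9)
        fv[paste0(prefix, "_distance")] <- spectral_distance(sp, ref_sp)
    }
  }
  names(fv) <- feature_names()   # guard against prefix typos dropping names

  sp_s <- series$speed
  if (!is.null(sp_s)) {
    st <- series_stats(sp_s)
    fv["speed_mean"] <- st$mean; fv["speed_max"] <- st$max
    fv["speed_std"] <- st$std
    fv["speed_slope"] <- slope_over_time(sp_s)
    fv["speed_peaks_per_s"] <- peaks_per_second(sp_s, dyn_cfg)
    ac <- acceleration_stats(sp_s)
    fv["accel_mean"] <- ac$mean; fv["accel_max"] <- ac$max
    fv["accel_std"] <- ac$std
  }
  fv["in_air_ratio"] <- in_air_time_ratio(rec)

  on <- rec[rec$on_surface, , drop = FALSE]
  if (nrow(on)) {
    fv["pressure_mean"] <- mean(on$pressure)
    fv["pressure_max"] <- max(on$pressure)
    fv["pressure_std"] <- pop_sd(on$pressure)
    fv["tilt_x_mean"] <- mean(on$tilt_x)
    fv["tilt_x_max"] <- max(on$tilt_x)
    fv["tilt_x_std"] <- pop_sd(on$tilt_x)
    fv["tilt_y_mean"] <- mean(on$tilt_y)
    fv["tilt_y_max"] <- max(on$tilt_y)
    fv["tilt_y_std"] <- pop_sd(on$tilt_y)
  }
  for (fam in c("dpressure", "dtilt_x", "dtilt_y")) {
    s <- series[[fam]]
    if (is.null(s)) next
    st <- series_stats(s)
    fv[paste0(fam, "_mean")] <- st$mean
    fv[paste0(fam, "_max")] <- st$max
    fv[paste0(fam, "_std")] <- st$std
    fv[paste0(fam, "_peaks_per_s")] <- peaks_per_second(s, dyn_cfg)
    if (fam != "dpressure")
      fv[paste0(fam, "_slope")] <- slope_over_time(s)
  }
  fv
}

#' Extract features for a whole cohort
#'
#' Runs [extract_features()] over a list of recordings with a shared
#' spectral axis per family, and keeps each recording's family spectra so
#' the distance-to-mean features can later be recomputed against a
#' training-split-only reference (see [evaluate_cohort()]).
#'
#' When no reference is given, one is built from all supplied recordings
#' (appropriate for exploratory use; the evaluation protocol rebuilds it
#' per training split from the stored spectra).
#'
#' @param recordings list of [recording()] objects.
#' @param ref optional [cohort_reference()] fixing the spectral axes.
#' @param static_cfg a [static_config()].
#' @param dyn_cfg a [dynamics_config()].
#' @param ids optional recording identifiers (defaults to metadata ids or
#'   the list index).
#' @return object of class `handwriting_features`: list with `features`
#'   (numeric matrix, one row per recording), `spectra` (per-recording
#'   family spectra), `packets`, `ids`, and `ref`.
#' @export
extract_cohort <- function(recordings, ref = NULL,
                           static_cfg = static_config(),
                           dyn_cfg = dynamics_config(), ids = NULL) {
  if (!length(recordings)) stop("no recordings supplied")
  if (is.null(ids))
    ids <- vapply(seq_along(recordings), function(i) {
      m <- attr(recordings[[i]], "meta")
      if (!is.null(m$id)) as.character(m$id) else sprintf("rec%03d", i)
    }, "")
  all_series <- lapply(recordings, family_series, static_cfg, dyn_cfg)
  packets <- if (!is.null(ref)) ref$packets
             else reference_packets(all_series, static_cfg, dyn_cfg)
  spectra <- lapply(all_series, family_spectra, packets, static_cfg, dyn_cfg)
  if (is.null(ref)) ref <- reference_from_spectra(spectra, packets)
  feats <- t(mapply(function(rec, series, sp)
    assemble_features(rec, series, sp, ref, static_cfg, dyn_cfg),
    recordings, all_series, spectra))
  rownames(feats) <- ids
  structure(list(features = feats, spectra = spectra, packets = packets,
                 ids = ids, ref = ref),
            class = "handwriting_features")
}

#' @export
print.handwriting_features <- function(x, ...) {
  cat(sprintf("Handwriting features: %d recordings x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x$features))))
  invisible(x)
}

# swap the five *_distance columns for distances against `ref`
# (recomputed from stored per-recording spectra; NA when axes mismatch)
recompute_distances <- function(fc, ref) {
  feats <- fc$features
  cols <- c(tremor = "tremor_distance", speed = "speed_freq_distance",
            dpressure = "dpressure_freq_distance",
            dtilt_x = "dtilt_x_freq_distance",
            dtilt_y = "dtilt_y_freq_distance")
  for (fam in names(cols)) {
    rs <- ref$spectra[[fam]]
    feats[, cols[fam]] <- vapply(fc$spectra, function(sp) {
      s <- sp[[fam]]
      if (is.null(s) || is.null(rs) ||
          length(s$freqs) != length(rs$freqs) ||
          max(abs(s$freqs - rs$freqs)) > 1e-9) return(NA_real_)
      spectral_distance(s, rs)
    }, 0)
  }
  feats
}

#' Write a feature table to TSV
#'
#' One row per recording: id, label (when given), then the fixed feature
#' columns; missing features are empty cells.
#'
#' @param fc a `handwriting_features` object (or plain matrix).
#' @param path output path.
#' @param labels optional label vector aligned with the rows.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fc, path, labels = NULL) {
  m <- if (inherits(fc, "handwriting_features")) fc$features else fc
  df <- data.frame(id = rownames(m), check.names = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
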