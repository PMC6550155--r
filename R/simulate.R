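#' Writer profile for the handwriting simulator
#'
#' Parameters of one simulated writer. The trajectory model — oscillatory
#' letter loops advanced left to right, grouped into words and lines with
#' pen-up gaps, a multiplicative saccade process on the writing speed,
#' additive band-limited tremor, and bounded stochastic pressure/tilt
#' channels — is a test harness for the feature pipeline, not a model of
#' children's motor control.
#'
#' @param base_speed mean pen speed while writing, device units/s.
#' @param speed_saccade_rate rate (1/s) of abrupt multiplicative speed
#'   jumps; `saccade_magnitude` is the log-scale magnitude of each jump.
#' @param saccade_magnitude see above.
#' @param tremor_amplitude amplitude (device units) of the additive tremor
#'   perturbation centred at `tremor_freq` (Hz) with a broadband noise
#'   component.
#' @param tremor_freq see above.
#' @param tremor_noise_frac fraction of the tremor amplitude carried by a
#'   broadband (smoothed white noise) component rather than the narrowband
#'   sinusoid; 0 gives a pure tone, 1 mostly noise. Broadband tremor
#'   widens the tremor-frequency bandwidth.
#' @param pressure_mean mean normalized pen pressure while on-surface.
#' @param pressure_change_rate dominant rate (1/s, used as Hz) of the
#'   pressure fluctuation.
#' @param tilt_x_base,tilt_y_base mean pen inclination, degrees.
#' @param tilt_change_freq_x,tilt_change_freq_y dominant frequency (Hz) of
#'   the tilt oscillation per axis; `tilt_amp_x`/`tilt_amp_y` its
#'   amplitude in degrees.
#' @param tilt_amp_x,tilt_amp_y see above.
#' @param tilt_jitter_x,tilt_jitter_y amplitude (degrees) of a broadband
#'   tilt jitter per axis; widens the tilt-change spectrum.
#' @param word_gap_mean,word_gap_std horizontal gap between consecutive
#'   words, device units (Gaussian, truncated at 5).
#' @param in_air_fraction target fraction of time with the pen lifted.
#' @param letters_per_word,words_per_line,n_lines page layout; writing
#'   continues past `n_lines` if time remains.
#' @param duration recording length in seconds.
#' @param rate sampling rate, Hz.
#' @return a list of class `writer_profile`.
#' @export
writer_profile <- function(base_speed = 80, speed_saccade_rate = 1.5,
                           saccade_magnitude = 0.15,
                           tremor_amplitude = 0.3, tremor_freq = 8,
                           tremor_noise_frac = 0.1,
                           pressure_mean = 0.55, pressure_change_rate = 1.2,
                           tilt_x_base = 20, tilt_y_base = 30,
                           tilt_change_freq_x = 0.8, tilt_amp_x = 5,
                           tilt_change_freq_y = 3.0, tilt_amp_y = 6,
                           tilt_jitter_x = 0.2, tilt_jitter_y = 0.3,
                           word_gap_mean = 90, word_gap_std = 12,
                           in_air_fraction = 0.18,
                           letters_per_word = 5, words_per_line = 6,
                           n_lines = 12, duration = 300, rate = 200) {
  p <- as.list(environment())
  num <- vapply(p, is.numeric, TRUE)
  if (!all(num) || any(vapply(p, length, 0L) != 1L))
    stop("all profile parameters must be single numbers")
  if (any(unlist(p[c("base_speed", "duration", "rate")]) <= 0))
    stop("base_speed, duration and rate must be positive")
  if (p$in_air_fraction < 0 || p$in_air_fraction >= 1)
    stop("in_air_fraction must be in [0, 1)")
  neg <- c("speed_saccade_rate", "saccade_magnitude", "tremor_amplitude",
           "tremor_freq", "tremor_noise_frac", "pressure_change_rate",
           "tilt_amp_x", "tilt_amp_y",
           "tilt_jitter_x", "tilt_jitter_y", "word_gap_std")
  if (any(unlist(p[neg]) < 0))
    stop("rates and amplitudes must be non-negative")
  structure(p, class = "writer_profile")
}

#' Default writer profiles for the two groups
#'
#' Typically-developing (TD) and dysgraphic (D) profiles differing along
#' the group contrasts reported for real writers: relative to TD, the D
#' profile has stronger tremor (wider tremor-frequency bandwidth), a more
#' saccadic speed process (speed-frequency median shifted upward), a lower
#' mean speed, smaller and more variable word gaps, more in-air time,
#' slower tilt-y change (lower tilt-y change-frequency median) and a
#' broader tilt-x change spectrum. All other parameters are equal.
#'
#' `effect` scales every manipulated difference about the group midpoint:
#' 1 is the clearly separable default (about 2 pooled SD per manipulated
#' axis given the cohort spreads of [cohort_spec()]); 0.25 gives a "hard"
#' preset of roughly 0.5 SD for power-style experiments.
#'
#' @param effect multiplier on the TD-D profile differences.
#' @param ... overrides passed to both profiles (e.g. `duration = 60`).
#' @return list with elements `td` and `d`, both [writer_profile()]s.
#' @export
default_profiles <- function(effect = 1, ...) {
  td_pars <- list(base_speed = 80, speed_saccade_rate = 1.5,
                  saccade_magnitude = 0.15, tremor_amplitude = 0.3,
                  tremor_noise_frac = 0.1,
                  word_gap_mean = 90, word_gap_std = 12,
                  in_air_fraction = 0.18,
                  tilt_change_freq_y = 3.0, tilt_amp_y = 6,
                  tilt_jitter_x = 0.2)
  d_pars <- list(base_speed = 55, speed_saccade_rate = 4,
                 saccade_magnitude = 0.5, tremor_amplitude = 1.5,
                 tremor_noise_frac = 0.8,
                 word_gap_mean = 55, word_gap_std = 20,
                 in_air_fraction = 0.30,
                 tilt_change_freq_y = 0.8, tilt_amp_y = 3,
                 tilt_jitter_x = 3)
  scale_pair <- function(a, b) {
    mid <- (a + b) / 2
    list(td = mid + (a - mid) * effect, d = mid + (b - mid) * effect)
  }
  td <- d <- list()
  for (k in names(td_pars)) {
    sp <- scale_pair(td_pars[[k]], d_pars[[k]])
    td[[k]] <- sp$td; d[[k]] <- sp$d
  }
  dots <- list(...)
  list(td = do.call(writer_profile, c(td, dots)),
       d = do.call(writer_profile, c(d, dots)))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

smooth3 <- function(v) {
  as.numeric(stats::filter(c(v[1L], v, v[length(v)]),
                           rep(1 / 3, 3), sides = 2))[2:(length(v) + 1L)]
}

#' Generate one synthetic pen-trace recording
#'
#' Deterministic for a given `(profile, seed)` pair. Letters are traced as
#' sinusoidal loops advanced left to right at a speed modulated by a
#' piecewise-constant saccade process; words are separated by in-air hover
#' segments realizing the profile's word gaps and in-air fraction, lines
#' by a carriage-return hover back to the left margin. Tremor is added as
#' a narrowband sinusoid plus smoothed broadband noise, scaled by
#' `tremor_amplitude`. Pressure and tilt evolve as clipped
#' sinusoid-plus-noise processes; pressure is zero while hovering.
#'
#' @param profile a [writer_profile()].
#' @param seed integer seed.
#' @param meta extra metadata stored on the recording (id, label, ...).
#' @return a validated [recording()] with `duration * rate` samples.
#' @export
generate_trace <- function(profile, seed = 1L, meta = list()) {
  if (!inherits(profile, "writer_profile"))
    profile <- do.call(writer_profile, as.list(profile))
  with_seed(seed, generate_trace_impl(profile, meta))
}

generate_trace_impl <- function(p, meta) {
  rate <- p$rate
  n_target <- round(p$duration * rate)
  letter_w <- 20; letter_h <- 30; loops_per_letter <- 1.5
  # path length of one letter's loop, used to convert speed to duration
  path_per_letter <- 2.4 * loops_per_letter * letter_h
  word_dur <- p$letters_per_word * path_per_letter / p$base_speed
  gap_dur <- word_dur * p$in_air_fraction / (1 - p$in_air_fraction)
  line_spacing <- 4 * letter_h
  margin <- 0

  t_all <- x_all <- y_all <- list()
  on_all <- list()
  n_done <- 0L
  x_cur <- margin; y_line <- 0; word_in_line <- 0L
  while (n_done < n_target) {
    # ---- one word, pen down
    n_s <- max(2L, round(word_dur * rate))
    # saccade process: piecewise-constant multiplicative speed factor
    n_ch <- stats::rpois(1L, p$speed_saccade_rate * word_dur)
    ch_at <- sort(stats::runif(n_ch, 0, 1))
    fac_lv <- exp(stats::rnorm(n_ch + 1L, 0, p$saccade_magnitude))
    pos <- seq(0, 1, length.out = n_s)
    fac <- fac_lv[findInterval(pos, ch_at) + 1L]
    u <- cumsum(fac)
    u <- u / u[n_s] * p$letters_per_word          # progress in letters
    theta <- 2 * pi * loops_per_letter * u
    xw <- x_cur + letter_w * (u + 0.15 * sin(theta))
    yw <- y_line - (letter_h / 2) * cos(theta)
    on <- rep(TRUE, n_s)
    x_all[[length(x_all) + 1L]] <- xw
    y_all[[length(y_all) + 1L]] <- yw
    on_all[[length(on_all) + 1L]] <- on
    n_done <- n_done + n_s
    x_cur <- x_cur + letter_w * p$letters_per_word
    word_in_line <- word_in_line + 1L

    # ---- hover to the next word or line, pen up
    line_break <- word_in_line >= p$words_per_line
    g_dur <- if (line_break) 2 * gap_dur else gap_dur
    n_g <- max(2L, round(g_dur * rate))
    if (line_break) {
      x_next <- margin
      y_next <- y_line + line_spacing
      word_in_line <- 0L
    } else {
      gap <- max(5, stats::rnorm(1L, p$word_gap_mean, p$word_gap_std))
      x_next <- x_cur + gap
      y_next <- y_line
    }
    frac <- seq(0, 1, length.out = n_g)
    xg <- x_all[[length(x_all)]][n_s] +
      (x_next - x_all[[length(x_all)]][n_s]) * frac
    yg <- yw[n_s] + (y_next - letter_h / 2 * cos(0) - yw[n_s]) * frac -
      10 * sin(pi * frac)                          # small hover arc
    x_all[[length(x_all) + 1L]] <- xg
    y_all[[length(y_all) + 1L]] <- yg
    on_all[[length(on_all) + 1L]] <- rep(FALSE, n_g)
    n_done <- n_done + n_g
    x_cur <- x_next; y_line <- y_next
  }

  x <- unlist(x_all)[seq_len(n_target)]
  y <- unlist(y_all)[seq_len(n_target)]
  on <- unlist(on_all)[seq_len(n_target)]
  t <- (seq_len(n_target) - 1L) / rate

  # tremor: narrowband sinusoid + smoothed broadband noise, on x and y
  ph <- stats::runif(2L, 0, 2 * pi)
  nz_x <- smooth3(stats::rnorm(n_target))
  nz_y <- smooth3(stats::rnorm(n_target))
  x <- x + p$tremor_amplitude *
    (sin(2 * pi * p$tremor_freq * t + ph[1L]) + p$tremor_noise_frac * nz_x)
  y <- y + p$tremor_amplitude *
    (cos(2 * pi * p$tremor_freq * t + ph[2L]) + p$tremor_noise_frac * nz_y)

  # pressure: sinusoid at the profile's change rate + slow noise, clipped
  php <- stats::runif(1L, 0, 2 * pi)
  pressure <- p$pressure_mean +
    0.15 * sin(2 * pi * p$pressure_change_rate * t + php) +
    0.03 * smooth3(stats::rnorm(n_target))
  pressure <- pmin(1, pmax(0.02, pressure))
  pressure[!on] <- 0

  # tilt: base + sinusoid + broadband jitter, clipped to the sensor range
  pht <- stats::runif(2L, 0, 2 * pi)
  tilt_x <- p$tilt_x_base +
    p$tilt_amp_x * sin(2 * pi * p$tilt_change_freq_x * t + pht[1L]) +
    p$tilt_jitter_x * smooth3(stats::rnorm(n_target))
  tilt_y <- p$tilt_y_base +
    p$tilt_amp_y * sin(2 * pi * p$tilt_change_freq_y * t + pht[2L]) +
    p$tilt_jitter_y * smooth3(stats::rnorm(n_target))
  tilt_x <- pmin(60, pmax(-60, tilt_x))
  tilt_y <- pmin(60, pmax(-60, tilt_y))

  recording(t, x, y, pressure, tilt_x, tilt_y, on,
            sampling_rate = rate, meta = meta)
}

#' Cohort specification for the simulator
#'
#' Describes a two-group synthetic cohort: group sizes, the two group-mean
#' profiles, the relative spread of the per-writer parameter draws, and a
#' seed. Default sizes follow the reference study population (242 TD,
#' 56 D).
#'
#' @param n_td,n_d group sizes.
#' @param td_profile,d_profile group-mean [writer_profile()]s.
#' @param spread relative SD of the per-writer lognormal jitter applied to
#'   the positive profile parameters (default 0.10).
#' @param seed integer cohort seed. Per-writer streams are derived from it
#'   by index, so adding writers never perturbs existing ones.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_td = 242, n_d = 56,
                        td_profile = default_profiles()$td,
                        d_profile = default_profiles()$d,
                        spread = 0.10, seed = 1L) {
  stopifnot(n_td >= 0, n_d >= 0, spread >= 0)
  structure(list(n_td = as.integer(n_td), n_d = as.integer(n_d),
                 td_profile = td_profile, d_profile = d_profile,
                 spread = spread, seed = as.integer(seed)),
            class = "cohort_spec")
}

writer_seed <- function(cohort_seed, index) {
  as.integer((as.double(cohort_seed) * 1000003 + index * 7919) %% 2147483629)
}

draw_profile <- function(mean_profile, spread, seed) {
  with_seed(seed, {
    p <- unclass(mean_profile)
    jitter_keys <- c("base_speed", "speed_saccade_rate", "saccade_magnitude",
                     "tremor_amplitude", "tremor_freq",
                     "tremor_noise_frac", "pressure_mean",
                     "pressure_change_rate", "tilt_change_freq_x",
                     "tilt_amp_x", "tilt_change_freq_y", "tilt_amp_y",
                     "tilt_jitter_x", "tilt_jitter_y", "word_gap_mean",
                     "word_gap_std")
    for (k in jitter_keys)
      p[[k]] <- p[[k]] * exp(stats::rnorm(1L, 0, spread))
    p$tilt_x_base <- p$tilt_x_base + stats::rnorm(1L, 0, 3)
    p$tilt_y_base <- p$tilt_y_base + stats::rnorm(1L, 0, 3)
    ia <- p$in_air_fraction * exp(stats::rnorm(1L, 0, spread))
    p$in_air_fraction <- min(0.9, ia)
    p$pressure_mean <- min(0.85, max(0.1, p$pressure_mean))
    do.call(writer_profile, p)
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws one [writer_profile()] per writer around the group means of the
#' spec (lognormal jitter of relative SD `spec$spread` on positive
#' parameters), generates every trace, and returns the recordings together
#' with labels and the ground-truth parameter table for recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `recordings` (list of
#'   [recording()]), `labels` (factor, levels `TD`, `D`), and
#'   `ground_truth` (data frame of per-writer parameters).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  n <- spec$n_td + spec$n_d
  labels <- factor(rep(c("TD", "D"), c(spec$n_td, spec$n_d)),
                   levels = c("TD", "D"))
  recordings <- vector("list", n)
  gt <- vector("list", n)
  idx_in_group <- c(seq_len(spec$n_td), seq_len(spec$n_d))
  for (i in seq_len(n)) {
    grp <- as.character(labels[i])
    mean_p <- if (grp == "TD") spec$td_profile else spec$d_profile
    # separate seed streams per group so growing one group never
    # perturbs the writers of the other
    off <- if (grp == "TD") 0L else 500000L
    ws <- writer_seed(spec$seed, off + idx_in_group[i])
    prof <- draw_profile(mean_p, spec$spread, ws)
    id <- sprintf("%s%03d", tolower(grp), idx_in_group[i])
    recordings[[i]] <- generate_trace(prof, seed = ws + 1L,
                                      meta = list(id = id, label = grp))
    gt[[i]] <- data.frame(id = id, label = grp, seed = ws,
                          as.data.frame(unclass(prof)))
  }
  structure(list(recordings = recordings, labels = labels,
                 ground_truth = do.call(rbind, gt)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic handwriting cohort: %d recordings (%s)\n",
              length(x$recordings),
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}
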