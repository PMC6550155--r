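test_that("speed of uniform and stationary motion is exact", {
  n <- 400
  t <- (0:(n - 1)) / 200
  uni <- make_recording(100 * t, rep(0, n), t = t)
  s <- derived_speed(uni)
  expect_equal(mean(s$v), 100, tolerance = 1e-9)
  expect_lt(graphokin:::pop_sd(s$v), 1e-6)

  still <- make_recording(rep(3, n), rep(4, n), t = t)
  expect_true(all(derived_speed(still)$v == 0))
})

test_that("speed on a circle matches r*omega within the smoothing bias", {
  r <- 200; f <- 0.5; omega <- 2 * pi * f
  t <- (0:2399) / 200
  circ <- make_recording(r * cos(omega * t), r * sin(omega * t), t = t)
  s <- derived_speed(circ)
  expect_lt(abs(mean(s$v) - r * omega) / (r * omega), 0.005)
})

test_that("speed measurements never span a pen lift", {
  n <- 400
  t <- (0:(n - 1)) / 200
  on <- rep(TRUE, n); on[190:210] <- FALSE
  # pen jumps far while lifted; spanning it would create a huge speed
  x <- 100 * t + ifelse(seq_len(n) > 210, 5000, 0)
  s <- derived_speed(make_recording(x, rep(0, n), t = t, on = on))
  expect_lt(max(s$v), 150)
})

test_that("channel change speed matches closed forms and a numeric oracle", {
  n <- 2400
  t <- (0:(n - 1)) / 200
  const <- make_recording(100 * t, rep(0, n), t = t,
                          pressure = rep(0.4, n))
  expect_true(all(channel_change_speed(const, "pressure")$v == 0))

  ramp <- make_recording(100 * t, rep(0, n), t = t,
                         pressure = pmin(1, 0.001 + 0.05 * t))
  expect_equal(mean(channel_change_speed(ramp, "pressure")$v), 0.05,
               tolerance = 1e-6)

  tilt <- make_recording(100 * t, rep(0, n), t = t,
                         tilt_y = 10 * sin(2 * pi * 0.5 * t))
  s <- channel_change_speed(tilt, "tilt_y")
  analytic <- 2 * 10 * 2 * pi * 0.5 / pi      # mean |A w cos|
  expect_lt(abs(mean(s$v) - analytic) / analytic, 0.01)
})

test_that("series stats and slope follow their definitions", {
  s3 <- graphokin:::new_derived_series(1:3, c(2, 2, 2), 1, 3)
  expect_equal(series_stats(s3), list(mean = 2, max = 2, std = 0))
  s2 <- graphokin:::new_derived_series(1:2, c(0, 4), 1, 2)
  expect_equal(series_stats(s2), list(mean = 2, max = 4, std = 2))
  set.seed(7)
  v <- rnorm(100)
  st <- series_stats(graphokin:::new_derived_series(1:100, v, 1, 100))
  expect_equal(st$mean, mean(v))
  expect_equal(st$std, sqrt(mean((v - mean(v))^2)))

  expect_equal(slope_over_time(s3), 0)
  tt <- seq(0, 10, by = 0.1)
  lin <- graphokin:::new_derived_series(tt, 3 * tt, 10, 10)
  expect_equal(slope_over_time(lin), 3, tolerance = 1e-12)
  noisy <- graphokin:::new_derived_series(tt, 3 * tt + rnorm(101, 0, 0.1),
                                          10, 10)
  expect_lt(abs(slope_over_time(noisy) - 3), 0.15)
})

test_that("extrema counting is exact for a sinusoid and monotone in sigma", {
  tt <- seq(0, 5, by = 0.05)
  s <- graphokin:::new_derived_series(tt, sin(2 * pi * 2 * tt + 0.3), 20, 5)
  cfg <- dynamics_config(peak_sigma = 0.05)
  expect_equal(peaks_per_second(s, cfg), 20 / 5)   # 10 maxima + 10 minima

  mono <- graphokin:::new_derived_series(tt, tt^2, 20, 5)
  expect_equal(peaks_per_second(mono, cfg), 0)

  set.seed(12)
  rough <- graphokin:::new_derived_series(tt, rnorm(101), 20, 5)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.25, 0.5),
                   function(sg) peaks_per_second(
                     rough, dynamics_config(peak_sigma = sg)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("acceleration statistics derive from speed differences", {
  tt <- seq(0, 10, by = 0.05)
  const <- graphokin:::new_derived_series(tt, rep(7, length(tt)), 20, 10)
  expect_equal(acceleration_stats(const), list(mean = 0, max = 0, std = 0))
  lin <- graphokin:::new_derived_series(tt, 2.5 * tt, 20, 10)
  expect_equal(acceleration_stats(lin)$mean, 2.5, tolerance = 1e-9)
  set.seed(3)
  v <- cumsum(rnorm(201))
  s <- graphokin:::new_derived_series(tt, v, 20, 10)
  expect_equal(acceleration_stats(s)$mean, mean(abs(diff(v)) / 0.05),
               tolerance = 1e-9)
})

test_that("in-air ratio equals the timestamp-sum oracle", {
  n <- 200
  t <- (0:(n - 1)) / 200
  all_on <- make_recording(1:n, rep(0, n), t = t)
  expect_equal(in_air_time_ratio(all_on), 0)

  # alternate 1 s on, 1 s off over 10 s
  t10 <- seq(0, 10, by = 0.005)
  on <- (floor(t10) %% 2) == 0
  alt <- make_recording(seq_along(t10), rep(0, length(t10)), t = t10,
                        on = on)
  expect_equal(in_air_time_ratio(alt), oracle_in_air(t10, on))
  expect_equal(in_air_time_ratio(alt), 0.5, tolerance = 0.01)

  set.seed(19)
  for (i in 1:5) {
    on <- runif(n) > 0.4
    ti <- cumsum(runif(n, 0.001, 0.02))
    r <- make_recording(1:n, rep(0, n), t = ti, on = on)
    expect_equal(in_air_time_ratio(r), oracle_in_air(ti, on))
  }
})

test_that("rescaling device units scales speeds and leaves ratios alone", {
  rec <- generate_trace(writer_profile(duration = 60), seed = 17)
  big <- rec
  big$x <- 3 * rec$x
  big$y <- 3 * rec$y
  f1 <- extract_features(rec)
  f2 <- extract_features(big)
  for (k in c("speed_mean", "speed_max", "speed_std", "accel_mean"))
    expect_equal(f2[[k]], 3 * f1[[k]], tolerance = 1e-9)
  for (k in c("in_air_ratio", "speed_peaks_per_s", "speed_freq_median",
              "tremor_median", "pressure_mean"))
    expect_equal(f2[[k]], f1[[k]], tolerance = 1e-9)
})

test_that("feature extraction is deterministic and complete on long traces", {
  rec <- generate_trace(default_profiles()$td, seed = 23)
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
  expect_named(f1, feature_names())
  # only the distance features may be missing without a reference
  expect_true(all(is.na(f1) | !grepl("distance", names(f1)) |
                    is.finite(f1)))
  no_dist <- f1[!grepl("distance", names(f1))]
  expect_false(anyNA(no_dist))
})

test_that("15-second truncations keep the feature bank usable", {
  rec <- truncate_recording(generate_trace(default_profiles()$td, seed = 29),
                            15)
  fv <- extract_features(rec)
  # spectral families shrink their packet instead of disappearing
  expect_false(is.na(fv[["speed_freq_median"]]))
  expect_false(is.na(fv[["tremor_bandwidth"]]))
  expect_false(is.na(fv[["in_air_ratio"]]))
})
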