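# pen-down strokes at given x starts, separated by in-air hover samples
# realizing the requested pen-up interval
multi_stroke_rec <- function(starts, gap_t = 0.5, width = 30, y = NULL) {
  n <- 60
  if (is.null(y)) y <- rep(0, length(starts))
  xs <- list(); ts <- list(); ys <- list(); ons <- list()
  t0 <- 0
  for (i in seq_along(starts)) {
    xs[[2 * i - 1]] <- seq(starts[i], starts[i] + width, length.out = n)
    ts[[2 * i - 1]] <- t0 + (seq_len(n) - 1) / 200
    ys[[2 * i - 1]] <- rep(y[i], n) + 0.5 * sin(seq_len(n))
    ons[[2 * i - 1]] <- rep(TRUE, n)
    t0 <- t0 + n / 200
    if (i < length(starts)) {
      xs[[2 * i]] <- rep(starts[i] + width, 3)
      ts[[2 * i]] <- t0 + gap_t * c(0.25, 0.5, 0.75)
      ys[[2 * i]] <- rep(y[i], 3)
      ons[[2 * i]] <- rep(FALSE, 3)
      t0 <- t0 + gap_t
    }
  }
  make_recording(unlist(xs), unlist(ys), t = unlist(ts), on = unlist(ons))
}

two_stroke_rec <- function(gap_x, gap_t = 0.5, width = 30)
  multi_stroke_rec(c(0, width + gap_x), gap_t = gap_t, width = width)

test_that("word segmentation needs both a time and a space gap", {
  st <- segment_strokes(two_stroke_rec(gap_x = 60, gap_t = 0.5))
  expect_equal(nrow(segment_words(st)), 2)
  st <- segment_strokes(two_stroke_rec(gap_x = 10, gap_t = 0.5))
  expect_equal(nrow(segment_words(st)), 1)          # letter spacing
  st <- segment_strokes(two_stroke_rec(gap_x = 60, gap_t = 0.05))
  expect_equal(nrow(segment_words(st)), 1)          # fast pen hop
})

test_that("line segmentation splits on carriage returns", {
  drift <- segment_strokes(two_stroke_rec(gap_x = 60))
  expect_length(segment_lines(drift), 1)

  rec <- multi_stroke_rec(c(0, 0), gap_t = 0.5, width = 200,
                          y = c(0, 400))
  expect_length(segment_lines(segment_strokes(rec)), 2)
})

test_that("simulated pages are segmented into the generated words and lines", {
  rec <- generate_trace(writer_profile(duration = 100), seed = 14)
  strokes <- segment_strokes(rec)
  lines <- segment_lines(strokes)
  words <- sum(vapply(lines, function(l)
    nrow(segment_words(strokes, l)), 0L))
  expect_equal(words, length(strokes))   # each generated word is one stroke
  expect_equal(length(lines), ceiling(length(strokes) / 6))
})

test_that("word spacing features match closed forms", {
  r <- two_stroke_rec(gap_x = 50)
  sbw <- space_between_words(r)
  expect_equal(sbw$mean_log_gap, log(50), tolerance = 1e-9)
  expect_equal(sbw$gap_std, 0)

  # three words with gaps 50 and 70
  r3 <- multi_stroke_rec(c(0, 80, 180))
  sbw3 <- space_between_words(r3)
  expect_equal(sbw3$mean_log_gap, log(60), tolerance = 1e-9)
  expect_equal(sbw3$gap_std, 10)

  expect_true(is.na(space_between_words(two_stroke_rec(10))$mean_log_gap))
  cfg_raw <- static_config(log_spacing = FALSE)
  expect_equal(space_between_words(r, cfg_raw)$mean_log_gap, 50)
})

test_that("density equals a brute-force grid histogram", {
  set.seed(21)
  r1 <- make_recording(runif(900, 0, 250), runif(900, 0, 250))
  expect_equal(handwriting_density(r1), 900)

  x <- c(runif(450, 0, 10), runif(450, 400, 410))
  r2 <- make_recording(x, runif(900, 0, 10))
  expect_equal(handwriting_density(r2), 450)

  for (i in 1:3) {
    x <- runif(500, 0, 2000); y <- runif(500, 0, 1500)
    r <- make_recording(x, y)
    cx <- floor((x - min(x)) / 300); cy <- floor((y - min(y)) / 300)
    counts <- table(paste(cx, cy, sep = "_"))
    expect_equal(handwriting_density(r), mean(as.numeric(counts)))
  }
})

test_that("line moment reflects vertical drift between point bins", {
  n <- 900
  flat <- make_recording(seq_len(n), rep(5, n))
  expect_equal(handwriting_moment(flat), 0)

  stepped <- make_recording(seq_len(n), rep(c(0, 7, 14), each = 300))
  expect_equal(handwriting_moment(stepped), 7)

  expect_true(is.na(handwriting_moment(make_recording(1:100, rep(0, 100)))))
})

test_that("handwriting size is the mean per-bin bounding-box area", {
  n <- 300
  point <- make_recording(rep(3, n), rep(4, n), t = (0:(n - 1)) / 200)
  expect_equal(handwriting_size(point), 0)

  rect <- make_recording(seq(0, 100, length.out = n),
                         rep(c(0, 50), length.out = n))
  expect_equal(handwriting_size(rect), 5000)
})

test_that("tremor signal is zero for collinear motion and linear in amplitude", {
  straight <- make_recording(1:100, 2 * (1:100))
  expect_true(all(tremor_signal(straight) == 0))

  zig <- function(a) make_recording(1:100, a * rep(c(-1, 1), 50))
  ts1 <- tremor_signal(zig(1))
  ts3 <- tremor_signal(zig(3))
  expect_equal(ts3, 3 * ts1, tolerance = 1e-12)
  expect_gt(mean(ts1), 0)
})

test_that("static features are invariant to translation and tremor to rotation", {
  rec <- generate_trace(writer_profile(duration = 60), seed = 8)
  shifted <- rec
  shifted$x <- rec$x + 1000
  shifted$y <- rec$y - 500
  expect_equal(space_between_words(shifted)$mean_log_gap,
               space_between_words(rec)$mean_log_gap)
  expect_equal(handwriting_density(shifted), handwriting_density(rec))
  expect_equal(handwriting_moment(shifted), handwriting_moment(rec))
  expect_equal(handwriting_size(shifted), handwriting_size(rec))
  expect_equal(tremor_signal(shifted), tremor_signal(rec))

  th <- 0.3
  rotated <- rec
  rotated$x <- cos(th) * rec$x - sin(th) * rec$y
  rotated$y <- sin(th) * rec$x + cos(th) * rec$y
  expect_equal(tremor_signal(rotated), tremor_signal(rec), tolerance = 1e-9)
})

test_that("injected tremor widens and shifts the tremor spectrum", {
  smooth <- generate_trace(writer_profile(duration = 60,
                                          tremor_amplitude = 0,
                                          tremor_noise_frac = 0),
                           seed = 5)
  shaky <- generate_trace(writer_profile(duration = 60,
                                         tremor_amplitude = 2,
                                         tremor_noise_frac = 0.8),
                          seed = 5)
  fs <- tremor_spectral_features(smooth)
  fh <- tremor_spectral_features(shaky)
  expect_gt(fh$bandwidth, fs$bandwidth)
  expect_gt(mean(tremor_signal(shaky)), mean(tremor_signal(smooth)))

  # the cross-product signal is a nonlinear fingerprint: a faster injected
  # tremor spreads its spectrum further out in frequency
  n <- 12000; t <- (0:(n - 1)) / 200
  bw_at <- function(f0) {
    r <- recording(t, 100 * t, 3 * sin(2 * pi * f0 * t), rep(0.5, n),
                   rep(0, n), rep(0, n), rep(TRUE, n))
    spectral_bandwidth(mean_power_spectrum(tremor_signal(r), 200,
                                           spectral_config(600)))
  }
  expect_gt(bw_at(8), bw_at(4))
})
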