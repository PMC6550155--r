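#' Static feature configuration
#'
#' Thresholds and bin sizes for the geometry-only features of the written
#' product. All lengths are in device units (0.25 mm per unit on the
#' reference hardware); all point counts refer to on-surface samples.
#'
#' @param word_gap_time minimum pen-up interval (s) between two strokes for
#'   a word break (default 0.15).
#' @param word_gap_x minimum horizontal bounding-box gap (device units)
#'   between two strokes for a word break (default 40). Both thresholds
#'   must be exceeded jointly.
#' @param density_cell_side side of the square density grid cells
#'   (default 300).
#' @param moment_bin points per barycenter bin of the line-moment feature
#'   (default 300).
#' @param size_bin points per bounding-box bin of the size feature
#'   (default 300).
#' @param tremor_packet points per spectral packet of the tremor signal
#'   (default 600).
#' @param tremor_window points per direction window of the tremor signal
#'   (default 10): each window yields 9 local difference vectors compared
#'   against their mean ("global") vector.
#' @param log_spacing log-transform the mean word gap (default TRUE).
#' @return a list of class `static_config`.
#' @export
static_config <- function(word_gap_time = 0.15, word_gap_x = 40,
                          density_cell_side = 300, moment_bin = 300,
                          size_bin = 300, tremor_packet = 600,
                          tremor_window = 10, log_spacing = TRUE) {
  stopifnot(word_gap_time > 0, word_gap_x > 0, density_cell_side > 0,
            moment_bin > 0, size_bin > 0, tremor_packet > 0,
            tremor_window >= 2)
  structure(list(word_gap_time = word_gap_time, word_gap_x = word_gap_x,
                 density_cell_side = density_cell_side,
                 moment_bin = as.integer(moment_bin),
                 size_bin = as.integer(size_bin),
                 tremor_packet = as.integer(tremor_packet),
                 tremor_window = as.integer(tremor_window),
                 log_spacing = isTRUE(log_spacing)),
            class = "static_config")
}

stroke_summary <- function(strokes) {
  data.frame(
    x_min = vapply(strokes, function(s) min(s$x), 0),
    x_max = vapply(strokes, function(s) max(s$x), 0),
    y_min = vapply(strokes, function(s) min(s$y), 0),
    y_max = vapply(strokes, function(s) max(s$y), 0),
    y_mid = vapply(strokes, function(s) mean(s$y), 0),
    t_start = vapply(strokes, function(s) s$t[1L], 0),
    t_end = vapply(strokes, function(s) s$t[nrow(s)], 0))
}

#' Group strokes into text lines
#'
#' Strokes are scanned in time order; a new line starts when a stroke's
#' left edge retreats leftward by more than half the running line's width
#' while its vertical centroid moves downward by more than the running
#' median stroke height (a carriage return). A single line is valid.
#'
#' @param strokes list of strokes from [segment_strokes()].
#' @param cfg a [static_config()] (reserved for future thresholds).
#' @return list of integer vectors, each the stroke indices of one line.
#' @export
segment_lines <- function(strokes, cfg = static_config()) {
  if (!length(strokes)) stop("no strokes to segment")
  info <- stroke_summary(strokes)
  heights <- pmax(info$y_max - info$y_min, 1e-9)
  lines <- list(1L)
  line_left <- info$x_min[1L]
  line_right <- info$x_max[1L]
  line_y <- info$y_mid[1L]
  for (i in seq_along(strokes)[-1L]) {
    width <- max(line_right - line_left, 1e-9)
    retreat <- (line_right - info$x_min[i]) > width / 2
    med_h <- stats::median(heights[seq_len(i - 1L)])
    descend <- (info$y_mid[i] - line_y) > med_h
    if (retreat && descend) {
      lines[[length(lines) + 1L]] <- i
      line_left <- info$x_min[i]
      line_right <- info$x_max[i]
      line_y <- info$y_mid[i]
    } else {
      lines[[length(lines)]] <- c(lines[[length(lines)]], i)
      line_left <- min(line_left, info$x_min[i])
      line_right <- max(line_right, info$x_max[i])
      line_y <- mean(info$y_mid[lines[[length(lines)]]])
    }
  }
  lines
}

#' Group the strokes of a line into words
#'
#' Consecutive strokes merge into the same word unless they are separated
#' by a pen-up interval longer than `cfg$word_gap_time` AND a horizontal
#' bounding-box gap wider than `cfg$word_gap_x` (both must hold, so dotted
#' i's and accents stay attached to their word).
#'
#' @param strokes list of all strokes of the recording.
#' @param line integer vector of stroke indices forming one line.
#' @param cfg a [static_config()].
#' @return data frame of word boxes: `left`, `right`, `top`, `bottom`,
#'   `n_strokes`, one row per word, ordered by left edge.
#' @export
segment_words <- function(strokes, line = seq_along(strokes),
                          cfg = static_config()) {
  if (!length(line)) stop("empty line")
  info <- stroke_summary(strokes[line])
  word_id <- integer(length(line))
  word_id[1L] <- 1L
  for (i in seq_along(line)[-1L]) {
    pen_up <- info$t_start[i] - info$t_end[i - 1L]
    gap_x <- info$x_min[i] - max(info$x_max[seq_len(i - 1L)][
      word_id[seq_len(i - 1L)] == word_id[i - 1L]])
    if (pen_up > cfg$word_gap_time && gap_x > cfg$word_gap_x)
      word_id[i] <- word_id[i - 1L] + 1L
    else
      word_id[i] <- word_id[i - 1L]
  }
  boxes <- do.call(rbind, lapply(split(seq_along(line), word_id), function(ix)
    data.frame(left = min(info$x_min[ix]), right = max(info$x_max[ix]),
               top = min(info$y_min[ix]), bottom = max(info$y_max[ix]),
               n_strokes = length(ix))))
  rownames(boxes) <- NULL
  boxes[order(boxes$left), , drop = FALSE]
}

#' Space between words
#'
#' Horizontal gaps between the bounding boxes of consecutive words on the
#' same line, pooled over all lines. The headline feature is the (natural)
#' log of the mean gap; the raw standard deviation of the gaps captures
#' spacing irregularity.
#'
#' @param rec a [recording()].
#' @param cfg a [static_config()].
#' @return list with `mean_log_gap` (or the raw mean when
#'   `cfg$log_spacing` is FALSE) and `gap_std`; both `NA` when no line has
#'   two words.
#' @export
space_between_words <- function(rec, cfg = static_config()) {
  strokes <- segment_strokes(rec)
  if (!length(strokes)) return(list(mean_log_gap = NA_real_, gap_std = NA_real_))
  gaps <- numeric(0)
  for (line in segment_lines(strokes, cfg)) {
    w <- segment_words(strokes, line, cfg)
    if (nrow(w) >= 2)
      gaps <- c(gaps, w$left[-1L] - w$right[-nrow(w)])
  }
  if (!length(gaps)) return(list(mean_log_gap = NA_real_, gap_std = NA_real_))
  m <- mean(gaps)
  list(mean_log_gap = if (cfg$log_spacing) log(m) else m,
       gap_std = pop_sd(gaps))
}

#' Handwriting density
#'
#' A square grid of side `cfg$density_cell_side` anchored at the
#' bottom-left of the trace bounding box; the feature is the mean number of
#' on-surface samples over the non-empty cells.
#'
#' @param rec a [recording()].
#' @param cfg a [static_config()].
#' @return scalar density (samples per occupied cell).
#' @export
handwriting_density <- function(rec, cfg = static_config()) {
  on <- rec[rec$on_surface, , drop = FALSE]
  if (!nrow(on)) stop("no on-surface samples")
  side <- cfg$density_cell_side
  cx <- floor((on$x - min(on$x)) / side)
  cy <- floor((on$y - min(on$y)) / side)
  counts <- table(paste(cx, cy))
  mean(as.numeric(counts))
}

line_point_runs <- function(rec, cfg) {
  strokes <- segment_strokes(rec)
  if (!length(strokes)) return(list())
  lapply(segment_lines(strokes, cfg), function(line)
    do.call(rbind, strokes[line]))
}

#' Moment of handwriting (baseline drift)
#'
#' Per text line, consecutive bins of `cfg$moment_bin` on-surface points
#' are reduced to their barycenter; the feature is the mean absolute
#' vertical distance between consecutive barycenters, averaged over lines
#' weighted by their number of barycenter pairs. A perfectly horizontal
#' line scores 0; sloped or wavy baselines score higher.
#'
#' @param rec a [recording()].
#' @param cfg a [static_config()].
#' @return scalar in device units; `NA` when no line has two full bins.
#' @export
handwriting_moment <- function(rec, cfg = static_config()) {
  tot <- 0; n_pairs <- 0L
  for (pts in line_point_runs(rec, cfg)) {
    nb <- nrow(pts) %/% cfg$moment_bin
    if (nb < 2) next
    grp <- rep(seq_len(nb), each = cfg$moment_bin)
    by <- tapply(pts$y[seq_len(nb * cfg$moment_bin)], grp, mean)
    tot <- tot + sum(abs(diff(by)))
    n_pairs <- n_pairs + (nb - 1L)
  }
  if (n_pairs == 0L) return(NA_real_)
  tot / n_pairs
}

#' Handwriting size
#'
#' Per text line, consecutive bins of `cfg$size_bin` on-surface points are
#' reduced to the area (width x height) of their axis-aligned bounding
#' box; the feature is the mean area over all bins.
#'
#' @param rec a [recording()].
#' @param cfg a [static_config()].
#' @return scalar in squared device units; `NA` when no full bin exists.
#' @export
handwriting_size <- function(rec, cfg = static_config()) {
  areas <- numeric(0)
  for (pts in line_point_runs(rec, cfg)) {
    nb <- nrow(pts) %/% cfg$size_bin
    if (nb < 1) next
    grp <- rep(seq_len(nb), each = cfg$size_bin)
    ix <- seq_len(nb * cfg$size_bin)
    w <- tapply(pts$x[ix], grp, function(v) diff(range(v)))
    h <- tapply(pts$y[ix], grp, function(v) diff(range(v)))
    areas <- c(areas, w * h)
  }
  if (!length(areas)) return(NA_real_)
  mean(areas)
}

#' Cross-product tremor signal
#'
#' Quantifies shaky deviation from the stroke path. Within each stroke,
#' consecutive windows of `cfg$tremor_window` on-surface points yield
#' `tremor_window - 1` local difference vectors and their mean, the
#' "global" direction vector of the window. For every local vector the
#' magnitude of the z-component of its cross product with the global
#' vector is recorded; collinear motion gives zeros, high-frequency
#' shaking gives large values. Windows never straddle stroke boundaries
#' (pen lifts would create spurious giant vectors); remainder points at
#' stroke ends are skipped.
#'
#' @param rec a [recording()].
#' @param cfg a [static_config()].
#' @return numeric series of cross-product magnitudes, concatenated in
#'   time order, at approximately the raw sampling rate.
#' @export
tremor_signal <- function(rec, cfg = static_config()) {
  w <- cfg$tremor_window
  out <- list()
  for (s in segment_strokes(rec)) {
    n_win <- nrow(s) %/% w
    if (n_win < 1) next
    m <- n_win * w
    X <- matrix(s$x[seq_len(m)], nrow = w)
    Y <- matrix(s$y[seq_len(m)], nrow = w)
    dX <- X[-1L, , drop = FALSE] - X[-w, , drop = FALSE]
    dY <- Y[-1L, , drop = FALSE] - Y[-w, , drop = FALSE]
    gX <- colMeans(dX)
    gY <- colMeans(dY)
    cr <- abs(sweep(dX, 2L, gY, `*`) - sweep(dY, 2L, gX, `*`))
    out[[length(out) + 1L]] <- as.vector(cr)
  }
  if (!length(out))
    stop("insufficient on-surface samples for the tremor signal (need >= ",
         w, " within one stroke)")
  unlist(out, use.names = FALSE)
}

#' Tremor spectral features
#'
#' The three frequency-domain summaries of the tremor signal: the packet-
#' averaged normalized power spectrum of [tremor_signal()] is reduced to
#' its 90% bandwidth, its power-weighted median, and (when a cohort
#' reference is supplied) its Euclidean distance to the cohort mean tremor
#' spectrum.
#'
#' @param rec a [recording()].
#' @param ref optional [cohort_reference()] providing the mean tremor
#'   spectrum; without it the distance is `NA`.
#' @param cfg a [static_config()].
#' @param spectral_cfg a [spectral_config()]; its packet size defaults to
#'   `cfg$tremor_packet`.
#' @return list with `bandwidth` (Hz), `median` (Hz) and `distance`.
#' @export
tremor_spectral_features <- function(rec, ref = NULL,
                                     cfg = static_config(),
                                     spectral_cfg = NULL) {
  if (is.null(spectral_cfg))
    spectral_cfg <- spectral_config(packet_size = cfg$tremor_packet,
                                    window_size = cfg$tremor_window)
  sig <- tremor_signal(rec, cfg)
  sp <- mean_power_spectrum(sig, attr(rec, "sampling_rate"), spectral_cfg)
  dist <- NA_real_
  if (!is.null(ref) && !is.null(ref$spectra$tremor))
    dist <- spectral_distance(sp, ref$spectra$tremor)
  list(bandwidth = spectral_bandwidth(sp, spectral_cfg$coverage),
       median = spectral_median(sp),
       distance = dist)
}

# population standard deviation (n in the denominator), used for every
# std feature in the bank
pop_sd <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  sqrt(mean((v - mean(v))^2))
}
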