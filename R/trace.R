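#' Construct a pen-trace recording
#'
#' A `recording` holds the multichannel time series captured by a digitizer
#' tablet while a subject writes: pen position in device units (0.25 mm per
#' unit on the reference hardware), normalized pen pressure, the two pen
#' inclination angles, and whether the pen tip touched the surface at each
#' sample. Hover (in-air) samples are retained with `on_surface = FALSE`;
#' the in-air time ratio and word segmentation depend on them.
#'
#' Irregular sampling is tolerated: all time computations downstream use the
#' actual timestamps, and `sampling_rate` is only used to build spectral
#' frequency axes.
#'
#' @param t numeric, seconds from recording start, strictly increasing.
#' @param x,y numeric pen coordinates in device units. `x` increases along
#'   the writing direction, `y` increases downward (screen convention).
#' @param pressure normalized pen force in `[0, 1]`. Cross-device pressure
#'   calibration is the acquisition step's responsibility; only the range is
#'   enforced here.
#' @param tilt_x,tilt_y pen inclination in degrees, in `[-60, 60]`:
#'   `tilt_x` along the written line, `tilt_y` below the written line.
#' @param on_surface logical, whether the pen tip touched the tablet.
#' @param sampling_rate nominal sampling rate in Hz (200 on the reference
#'   hardware).
#' @param meta named list of writer metadata; recognised keys are `id`,
#'   `age`, `gender`, `laterality` and `label` (`"TD"`, `"D"` or
#'   `"unknown"`).
#' @return An object of class `recording`: a data frame with columns
#'   `t, x, y, pressure, tilt_x, tilt_y, on_surface` and attributes
#'   `sampling_rate` and `meta`.
#' @seealso [read_trace()], [segment_strokes()], [truncate_recording()]
#' @export
recording <- function(t, x, y, pressure, tilt_x, tilt_y, on_surface,
                      sampling_rate = 200, meta = list()) {
  df <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                   pressure = as.numeric(pressure),
                   tilt_x = as.numeric(tilt_x), tilt_y = as.numeric(tilt_y),
                   on_surface = as.logical(on_surface))
  attr(df, "sampling_rate") <- as.numeric(sampling_rate)
  attr(df, "meta") <- meta
  class(df) <- c("recording", "data.frame")
  validate_recording(df)
  df
}

#' @export
print.recording <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("Pen-trace recording: %d samples, %.2f s, %g Hz nominal\n",
              nrow(x), diff(range(x$t)), attr(x, "sampling_rate")))
  cat(sprintf("  on-surface: %d samples (%.1f%% of time in air)\n",
              sum(x$on_surface), 100 * in_air_time_ratio(x)))
  if (!is.null(m$id))    cat(sprintf("  writer id: %s\n", m$id))
  if (!is.null(m$label)) cat(sprintf("  label: %s\n", m$label))
  invisible(x)
}

#' Validate a recording against the trace contract
#'
#' Checks the invariants every downstream computation relies on: strictly
#' increasing timestamps, non-negative time, pressure in `[0, 1]`, tilt
#' angles in `[-60, 60]` degrees, a positive sampling rate and at least two
#' samples. Called by [recording()] and [read_trace()].
#'
#' @param rec a `recording` (or a data frame with the same columns).
#' @return `rec`, invisibly, if valid; otherwise an error describing every
#'   violated field.
#' @export
validate_recording <- function(rec) {
  problems <- character(0)
  need <- c("t", "x", "y", "pressure", "tilt_x", "tilt_y", "on_surface")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols))
    stop("recording is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(rec) < 2)
    problems <- c(problems, "fewer than 2 samples")
  if (anyNA(rec[need]))
    problems <- c(problems, "NA values present")
  if (nrow(rec) >= 2 && any(diff(rec$t) <= 0))
    problems <- c(problems, "timestamps not strictly increasing")
  if (any(rec$t < 0, na.rm = TRUE))
    problems <- c(problems, "negative timestamps")
  if (any(rec$pressure < 0 | rec$pressure > 1, na.rm = TRUE))
    problems <- c(problems, "pressure outside [0, 1]")
  if (any(abs(rec$tilt_x) > 60, na.rm = TRUE))
    problems <- c(problems, "tilt_x outside [-60, 60] degrees")
  if (any(abs(rec$tilt_y) > 60, na.rm = TRUE))
    problems <- c(problems, "tilt_y outside [-60, 60] degrees")
  sr <- attr(rec, "sampling_rate")
  if (is.null(sr) || !is.finite(sr) || sr <= 0)
    problems <- c(problems, "sampling_rate must be a positive number")
  if (length(problems))
    stop("invalid recording: ", paste(problems, collapse = "; "))
  invisible(rec)
}

#' Read a pen trace from a tab-separated file
#'
#' The trace format is UTF-8 TSV with header
#' `t_s x y pressure tilt_x_deg tilt_y_deg on_surface`, one row per sample,
#' `on_surface` coded 0/1. A sidecar metadata file (same path with extension
#' replaced by `.meta`, or given explicitly) holds flat `key: value` lines
#' with keys `id`, `age`, `gender`, `laterality`, `label` and
#' `sampling_rate_hz`.
#'
#' @param path path to the trace TSV.
#' @param meta_path optional path to the metadata sidecar; defaults to
#'   `<path without extension>.meta` when that file exists.
#' @param flip_y if `TRUE`, negate the y axis at load (for devices using a
#'   bottom-up convention).
#' @return a validated [recording()].
#' @export
read_trace <- function(path, meta_path = NULL, flip_y = FALSE) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  header <- c("t_s", "x", "y", "pressure", "tilt_x_deg", "tilt_y_deg",
              "on_surface")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = "numeric", check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(names(df), header))
    stop("trace header must be: ", paste(header, collapse = " "))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  if (any(!df$on_surface %in% c(0, 1)))
    stop("on_surface column must contain only 0 or 1")

  meta <- list()
  if (is.null(meta_path)) {
    cand <- paste0(sub("\\.[^./]*$", "", path), ".meta")
    if (file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path) && file.exists(meta_path))
    meta <- read_meta(meta_path)
  rate <- if (!is.null(meta$sampling_rate_hz))
    as.numeric(meta$sampling_rate_hz) else 200
  y <- if (flip_y) -df$y else df$y
  recording(df$t_s, df$x, y, df$pressure, df$tilt_x_deg, df$tilt_y_deg,
            df$on_surface == 1, sampling_rate = rate, meta = meta)
}

read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = ":"), ""))
  meta <- as.list(vals)
  names(meta) <- keys
  for (k in c("age", "sampling_rate_hz"))
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  meta
}

#' Write a recording to the trace TSV format
#'
#' Inverse of [read_trace()]: numeric content round-trips to printed
#' precision (15 significant digits). When the recording carries metadata, a
#' `.meta` sidecar is written next to the trace.
#'
#' @param rec a [recording()].
#' @param path output path for the TSV.
#' @param write_meta write the metadata sidecar when metadata is present.
#' @return `path`, invisibly.
#' @export
write_trace <- function(rec, path, write_meta = TRUE) {
  df <- data.frame(t_s = rec$t, x = rec$x, y = rec$y,
                   pressure = rec$pressure,
                   tilt_x_deg = rec$tilt_x, tilt_y_deg = rec$tilt_y,
                   on_surface = as.integer(rec$on_surface))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, format, digits = 15, trim = TRUE,
                                  scientific = FALSE),
                           sep = "\t"))
  writeLines(body, con)
  meta <- attr(rec, "meta")
  if (write_meta && length(meta)) {
    mp <- paste0(sub("\\.[^./]*$", "", path), ".meta")
    m <- meta
    if (is.null(m$sampling_rate_hz))
      m$sampling_rate_hz <- attr(rec, "sampling_rate")
    writeLines(paste0(names(m), ": ",
                      vapply(m, function(v) format(v, digits = 15), "")),
               mp)
  }
  invisible(path)
}

#' Segment a recording into pen-down strokes
#'
#' A stroke is a maximal contiguous run of on-surface samples. The returned
#' strokes partition the on-surface samples exactly, in time order; a
#' recording with no on-surface sample yields an empty list.
#'
#' @param rec a [recording()].
#' @return list of data frames (rows of `rec`), each with attribute `index`
#'   giving its ordinal position.
#' @export
segment_strokes <- function(rec) {
  on <- rec$on_surface
  if (!any(on)) return(list())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    s <- as.data.frame(rec)[starts[k]:ends[k], , drop = FALSE]
    rownames(s) <- NULL
    attr(s, "index") <- i
    out[[i]] <- s
  }
  out
}

#' Truncate a recording to its first seconds
#'
#' Keeps the samples with `t < duration`, mirroring a protocol where only
#' the first seconds of a writing test are scored. Metadata and sampling
#' rate are preserved; the operation is idempotent.
#'
#' @param rec a [recording()].
#' @param duration seconds to keep (> 0).
#' @return a [recording()] with the retained samples.
#' @export
truncate_recording <- function(rec, duration) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a single positive number of seconds")
  keep <- rec$t < duration
  if (sum(keep) < 2)
    stop("truncation to ", duration,
         " s leaves fewer than 2 samples: degenerate recording")
  out <- as.data.frame(rec)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sampling_rate") <- attr(rec, "sampling_rate")
  attr(out, "meta") <- attr(rec, "meta")
  class(out) <- c("recording", "data.frame")
  out
}
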