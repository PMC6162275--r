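#' Calibrated height-map containers
#'
#' A `topograph` is a numeric matrix of surface heights in nanometres with a
#' pixel size attached; a `topo_movie` is an ordered list of equally sized
#' topographs sharing one pixel size, with per-frame timestamps and an
#' optional ground-truth record (site table, state matrix, injected drift)
#' attached by the scene simulator.
#'
#' Coordinate convention: the matrix is row-major with the origin at the
#' top-left pixel centre, x increasing rightwards (columns), y increasing
#' downwards (rows), heights (z) upwards. The centre of pixel `[r, c]` is at
#' `x = (c - 0.5) * pixel_size`, `y = (r - 0.5) * pixel_size`. Angles are in
#' degrees, positive clockwise as seen in the displayed image.
#'
#' @param heights numeric matrix, heights in nm (finite).
#' @param pixel_size pixel edge length in nm (> 0).
#' @return `topograph()` returns a `topograph`; `topo_movie()` a `topo_movie`.
#' @export
topograph <- function(heights, pixel_size) {
  stopifnot(is.matrix(heights), is.numeric(heights), all(is.finite(heights)),
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  structure(heights, pixel_size = pixel_size, class = c("topograph", "matrix", "array"))
}

#' @rdname topograph
#' @param frames list of height matrices (all the same dimension) or of
#'   `topograph` objects.
#' @param timestamps numeric vector of frame times in seconds, strictly
#'   increasing; defaults to `0:(n-1)`.
#' @param truth optional list of ground-truth annotations.
#' @export
topo_movie <- function(frames, pixel_size, timestamps = NULL, truth = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  frames <- lapply(frames, function(f) {
    f <- unclass(f)
    attr(f, "pixel_size") <- NULL
    stopifnot(is.matrix(f), all(is.finite(f)))
    f
  })
  d <- dim(frames[[1L]])
  stopifnot(all(vapply(frames, function(f) identical(dim(f), d), logical(1L))))
  if (is.null(timestamps)) timestamps <- seq_along(frames) - 1
  stopifnot(length(timestamps) == length(frames), !is.unsorted(timestamps, strictly = TRUE))
  structure(list(frames = frames, pixel_size = pixel_size,
                 timestamps = as.numeric(timestamps), truth = truth),
            class = "topo_movie")
}

#' @export
print.topograph <- function(x, ...) {
  cat(sprintf("<topograph> %d x %d px, %.3g nm/px, heights %.3g..%.3g nm\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

#' @export
print.topo_movie <- function(x, ...) {
  cat(sprintf("<topo_movie> %d frames, %d x %d px, %.3g nm/px, t = %.3g..%.3g s\n",
              length(x$frames), nrow(x$frames[[1L]]), ncol(x$frames[[1L]]),
              x$pixel_size, x$timestamps[1L], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a `topo_movie`.
#' @export
n_frames <- function(movie) length(movie$frames)

#' Extract one frame as a topograph
#' @param movie a `topo_movie`.
#' @param i frame index (1-based).
#' @export
movie_frame <- function(movie, i) topograph(movie$frames[[i]], movie$pixel_size)

pixel_size <- function(x) {
  if (inherits(x, "topo_movie")) x$pixel_size else attr(x, "pixel_size")
}

#' Write / read calibrated topograph movies
#'
#' Movies are stored as multi-page 32-bit float TIFF with heights normalized
#' to `[0, 1]` by a recorded scale, plus a mandatory JSON sidecar
#' (`<path>.json`) holding `pixel_size_nm`, `height_scale_nm`,
#' `height_offset_nm` and `timestamps_s`. `read_movie` refuses to guess a
#' calibration: a missing sidecar (and no explicit `pixel_size` argument) is
#' an error, never silent pixel units. An explicit `pixel_size` argument
#' overrides the sidecar value (documented precedence: argument > sidecar).
#'
#' @param movie a `topo_movie`.
#' @param path TIFF file path.
#' @return `read_movie` returns a `topo_movie` (without ground truth).
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "topo_movie"))
  lo <- min(vapply(movie$frames, min, numeric(1L)))
  hi <- max(vapply(movie$frames, max, numeric(1L)))
  scale <- max(hi - lo, .Machine$double.eps)
  norm <- lapply(movie$frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_nm = movie$pixel_size,
               height_scale_nm = scale,
               height_offset_nm = lo,
               timestamps_s = movie$timestamps,
               units = "nm")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param pixel_size optional pixel size in nm, overriding the sidecar.
#' @export
read_movie <- function(path, pixel_size = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (is.null(pixel_size)) {
    if (is.null(meta$pixel_size_nm))
      stop("no pixel-size calibration: sidecar '", sidecar,
           "' missing or incomplete and no pixel_size given", call. = FALSE)
    pixel_size <- meta$pixel_size_nm
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L))))
    stop("expected single-channel (grayscale float) TIFF pages", call. = FALSE)
  scale <- if (!is.null(meta$height_scale_nm)) meta$height_scale_nm else 1
  offset <- if (!is.null(meta$height_offset_nm)) meta$height_offset_nm else 0
  frames <- lapply(pages, function(p) p * scale + offset)
  ts <- if (!is.null(meta$timestamps_s)) meta$timestamps_s else seq_along(frames) - 1
  topo_movie(frames, pixel_size, timestamps = ts)
}
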