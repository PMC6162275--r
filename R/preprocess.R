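#' First-order plane flattening
#'
#' Subtracts the least-squares best-fit plane `a + b*x + c*y` from a
#' topograph, the standard first-order flattening applied to raw AFM frames.
#' With `robust = TRUE` (default) the plane is refit iteratively on the
#' lowest `lower_frac` of residual pixels, so that it tracks the exposed
#' membrane rather than being tilted by the protruding crystal patch.
#' Idempotent; a degenerate (constant) frame comes back as all zeros.
#'
#' @param t a `topograph` (or plain matrix).
#' @param robust refit the plane on membrane-level pixels (see above).
#' @param lower_frac fraction of pixels treated as membrane level.
#' @param n_iter robust refit passes.
#' @return flattened `topograph`.
#' @export
plane_flatten <- function(t, robust = TRUE, lower_frac = 0.35, n_iter = 2L) {
  px <- attr(t, "pixel_size")
  m <- unclass(t)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr * nc >= 3L)
  x <- rep(seq_len(nc), each = nr) - (nc + 1) / 2
  y <- rep(seq_len(nr), times = nc) - (nr + 1) / 2
  z <- as.vector(m)
  fit <- function(w) {   # LS plane on the pixel subset w
    X <- cbind(1, x[w], y[w])
    cf <- tryCatch(solve(crossprod(X), crossprod(X, z[w])),
                   error = function(e) c(mean(z[w]), 0, 0))
    cf[1L] + cf[2L] * x + cf[3L] * y
  }
  pl <- fit(seq_along(z))
  if (robust) {
    # protein protrudes upward: refit on the lowest residual pixels so the
    # plane tracks the exposed membrane, not the crystal patch
    for (i in seq_len(n_iter)) {
      r <- z - pl
      w <- which(r <= stats::quantile(r, lower_frac))
      pl <- fit(w)
    }
  }
  out <- matrix(z - pl, nr, nc)
  res <- if (is.null(px)) out else topograph(out, px)
  attr(res, "sites") <- attr(t, "sites")
  res
}

#' @rdname plane_flatten
#' @param movie a `topo_movie`; each frame is flattened independently.
#' @export
flatten_movie <- function(movie, robust = TRUE) {
  topo_movie(lapply(movie$frames, plane_flatten, robust = robust),
             movie$pixel_size, timestamps = movie$timestamps,
             truth = movie$truth)
}

# Cross-correlate two mean-subtracted frames via FFT and return the shift of
# `b` relative to `a` (i.e. b ~ a translated by +shift), subpixel-refined by
# a separable parabolic fit through the correlation peak, plus the normalized
# correlation coefficient at the peak.
xcorr_shift <- function(a, b, max_shift = NULL) {
  nr <- nrow(a); nc <- ncol(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(b0) * Conj(stats::fft(a0)), inverse = TRUE)) / (nr * nc)
  if (!is.null(max_shift)) {
    wr <- c(seq_len(min(max_shift + 1L, nr)), if (max_shift >= 1) nr - seq_len(min(max_shift, nr - 1L)) + 1L)
    wc <- c(seq_len(min(max_shift + 1L, nc)), if (max_shift >= 1) nc - seq_len(min(max_shift, nc - 1L)) + 1L)
    mask <- matrix(-Inf, nr, nc)
    mask[wr, wc] <- 0
    cc <- cc + mask
  }
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)   # index 1 == zero shift
  # parabolic refinement along each axis (periodic neighbours)
  nb <- function(i, n) c((i - 2L) %% n + 1L, i, i %% n + 1L)
  par3 <- function(v) if (!all(is.finite(v)) || (2 * v[2] - v[1] - v[3]) <= 0) 0 else
    0.5 * (v[1] - v[3]) / (v[1] - 2 * v[2] + v[3])
  dr <- par3(cc[nb(pk[1], nr), pk[2]])
  dc <- par3(cc[pk[1], nb(pk[2], nc)])
  peak_cc <- cc[pk[1], pk[2]] / sqrt(sum(a0^2) * sum(b0^2))
  c(dx = wrap(pk[2], nc) - 1 + dc, dy = wrap(pk[1], nr) - 1 + dr, peak = peak_cc)
}

#' Estimate frame-to-frame drift by cross-correlation
#'
#' Translation of each frame relative to the first, from the normalized
#' cross-correlation peak with subpixel parabolic refinement.
#' `mode = "pairwise"` accumulates consecutive frame-to-frame shifts;
#' `mode = "running-average"` registers each frame against the running
#' average of the already-registered preceding frames (more robust to noise).
#' Frames whose correlation peak falls below `peak_floor` are flagged
#' unreliable.
#'
#' @param movie a `topo_movie` with at least 2 frames.
#' @param mode registration reference strategy.
#' @param max_shift_px largest relative shift searched, in pixels.
#' @param peak_floor minimum acceptable correlation coefficient.
#' @return a `drift_track` data.frame: `frame`, `dx_px`, `dy_px`, `dx_nm`,
#'   `dy_nm`, `peak`, `reliable`; shift of the reference frame is (0, 0).
#' @export
estimate_drift <- function(movie, mode = c("running-average", "pairwise"),
                           max_shift_px = NULL, peak_floor = 0.2) {
  mode <- match.arg(mode)
  nfr <- n_frames(movie)
  stopifnot(nfr >= 2L)
  px <- movie$pixel_size
  if (is.null(max_shift_px))
    max_shift_px <- floor(min(dim(movie$frames[[1L]])) / 4)
  sh <- matrix(0, nfr, 2L); pk <- rep(1, nfr)
  if (mode == "pairwise") {
    for (k in 2:nfr) {
      r <- xcorr_shift(movie$frames[[k - 1L]], movie$frames[[k]], max_shift_px)
      sh[k, ] <- sh[k - 1L, ] + r[c("dx", "dy")]
      pk[k] <- r["peak"]
    }
  } else {
    ref <- movie$frames[[1L]]
    nref <- 1
    for (k in 2:nfr) {
      r <- xcorr_shift(ref / nref, movie$frames[[k]], max_shift_px)
      sh[k, ] <- r[c("dx", "dy")]
      pk[k] <- r["peak"]
      reg <- fourier_shift(movie$frames[[k]], -sh[k, 1L], -sh[k, 2L])
      ref <- ref + reg
      nref <- nref + 1
    }
  }
  out <- data.frame(frame = seq_len(nfr), dx_px = sh[, 1L], dy_px = sh[, 2L],
                    dx_nm = sh[, 1L] * px, dy_nm = sh[, 2L] * px,
                    peak = pk, reliable = pk >= peak_floor)
  class(out) <- c("drift_track", "data.frame")
  out
}

#' Apply a drift track to a movie
#'
#' Translates each frame by minus its estimated shift (subpixel Fourier
#' interpolation), so that ground-truth features become stationary. The
#' band swept in from the frame edge by the translation contains no real
#' data: it is overwritten with the frame median and excluded from the
#' per-frame valid region recorded in the result (`$valid`, one row per
#' frame, pixel bounds), which downstream site measurements respect.
#' Frames flagged unreliable can be dropped.
#'
#' @param movie a `topo_movie`.
#' @param track a `drift_track` from [estimate_drift()] (one row per frame).
#' @param drop_unreliable drop frames whose track row is flagged unreliable.
#' @export
register_movie <- function(movie, track, drop_unreliable = FALSE) {
  stopifnot(nrow(track) == n_frames(movie))
  keep <- if (drop_unreliable) which(track$reliable) else seq_len(n_frames(movie))
  nr <- nrow(movie$frames[[1L]]); nc <- ncol(movie$frames[[1L]])
  valid <- data.frame(frame = seq_along(keep), r0 = 1L, r1 = nr, c0 = 1L, c1 = nc)
  frames <- lapply(seq_along(keep), function(i) {
    k <- keep[i]
    f <- fourier_shift(movie$frames[[k]], -track$dx_px[k], -track$dy_px[k])
    med <- stats::median(f)
    bx <- ceiling(abs(track$dx_px[k])); by <- ceiling(abs(track$dy_px[k]))
    if (by > 0) {
      if (track$dy_px[k] > 0) { f[max(1L, nr - by + 1L):nr, ] <- med; valid$r1[i] <<- nr - by }
      else { f[seq_len(min(by, nr)), ] <- med; valid$r0[i] <<- by + 1L }
    }
    if (bx > 0) {
      if (track$dx_px[k] > 0) { f[, max(1L, nc - bx + 1L):nc] <- med; valid$c1[i] <<- nc - bx }
      else { f[, seq_len(min(bx, nc))] <- med; valid$c0[i] <<- bx + 1L }
    }
    f
  })
  truth <- movie$truth
  if (!is.null(truth$states) && drop_unreliable)
    truth$states <- truth$states[keep, , drop = FALSE]
  out <- topo_movie(frames, movie$pixel_size, timestamps = movie$timestamps[keep],
                    truth = truth)
  out$valid <- valid
  out
}
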