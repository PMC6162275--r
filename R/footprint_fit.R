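#' Centres of mass of protrusion peaks
#'
#' For each of the `n_peaks` highest local maxima, the centre of mass of
#' the integrated height within the connected region above
#' `threshold_frac` of the peak height (the "integrated volume under the
#' protrusion"). Regions that touch two maxima are flagged merged.
#'
#' @param map matrix or `average_map`.
#' @param n_peaks number of protrusions.
#' @param threshold_frac region threshold as a fraction of each peak height.
#' @param min_sep_nm minimum separation between accepted maxima.
#' @param pixel_size nm/px (taken from the map when available).
#' @return data.frame `x`, `y` (nm, image frame), `peak_height`, `merged`.
#' @export
peak_centers_of_mass <- function(map, n_peaks = 4L, threshold_frac = 0.5,
                                 min_sep_nm = NULL, pixel_size = NULL) {
  if (inherits(map, "average_map")) { m <- map$mean; px <- map$pixel_size }
  else { m <- unclass(map); px <- if (!is.null(pixel_size)) pixel_size else attr(map, "pixel_size") }
  stopifnot(!is.null(px))
  if (is.null(min_sep_nm)) min_sep_nm <- 0.2 * ncol(m) * px
  pks <- local_maxima(m)
  sel <- list()
  for (q in seq_len(nrow(pks))) {
    p <- c(pks$col[q], pks$row[q])
    if (all(vapply(sel, function(s) sqrt(sum((s[1:2] - p)^2)) * px >= min_sep_nm,
                   logical(1L)))) {
      sel[[length(sel) + 1L]] <- c(p, pks$value[q])
      if (length(sel) == n_peaks) break
    }
  }
  maxima_rc <- do.call(rbind, lapply(sel, function(s) c(s[2L], s[1L])))
  out <- do.call(rbind, lapply(seq_along(sel), function(q) {
    p <- sel[[q]]
    reg <- flood_region(m, p[2L], p[1L], threshold_frac * p[3L])
    w <- m[reg]
    rows <- reg[, 1L]; cols <- reg[, 2L]
    merged <- sum(apply(maxima_rc, 1L, function(rc)
      any(rows == rc[1L] & cols == rc[2L]))) > 1L
    data.frame(x = sum(w * cols) / sum(w) * px, y = sum(w * rows) / sum(w) * px,
               peak_height = p[3L], merged = merged)
  }))
  out
}

# Connected region (4-connectivity) of pixels above `thr` containing (r, c).
flood_region <- function(m, r, c, thr) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  stack <- matrix(c(r, c), 1L)
  seen[r, c] <- TRUE
  out <- list()
  while (nrow(stack)) {
    p <- stack[nrow(stack), ]; stack <- stack[-nrow(stack), , drop = FALSE]
    out[[length(out) + 1L]] <- p
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      q <- p + d
      if (q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L && q[2L] <= nc &&
          !seen[q[1L], q[2L]] && m[q[1L], q[2L]] >= thr) {
        seen[q[1L], q[2L]] <- TRUE
        stack <- rbind(stack, q)
      }
    }
  }
  do.call(rbind, out)
}

#' Fit the in-plane rotation between an observed map and a model footprint
#'
#' Exhaustive rotation scan of the model against the observation: at each
#' angle the model is rotated (bilinear), both maps are zero-meaned and
#' circularly masked, and the score is the normalized cross-correlation
#' maximized over translation (FFT). The best angle is refined by a
#' parabolic fit of the score curve. For a molecule of symmetry order `s`
#' the angle is reported modulo `360/s`, as the smallest-magnitude
#' equivalent in `(-180/s, 180/s]`.
#'
#' @param observed `average_map` or matrix.
#' @param model matrix rendered at the same pixel size (e.g. from
#'   [render_footprint()]), or an `average_map`.
#' @param symmetry_order molecular symmetry order (4 for a tetramer).
#' @param step scan step in degrees.
#' @param max_shift_px translation search bound.
#' @return `fit_result` list: `rotation` (degrees CW), `score` (NCC in
#'   [-1, 1]), `ambiguity_order`, `scores` (the scan curve).
#' @export
fit_rotation <- function(observed, model, symmetry_order = 4L, step = 0.5,
                         max_shift_px = NULL) {
  get_m <- function(x) if (inherits(x, "average_map")) x$mean else unclass(x)
  obs <- get_m(observed); mod <- get_m(model)
  stopifnot(nrow(obs) == ncol(obs), nrow(mod) == ncol(mod))
  if (stats::sd(obs) == 0 || stats::sd(mod) == 0)
    stop("flat map: rotation score undefined", call. = FALSE)
  n <- min(nrow(obs), nrow(mod))
  crop <- function(m) {
    o <- (nrow(m) - n) %/% 2L
    m[(o + 1L):(o + n), (o + 1L):(o + n)]
  }
  obs <- crop(obs); mod <- crop(mod)
  if (is.null(max_shift_px)) max_shift_px <- max(2L, floor(n / 6))
  ctr <- (n + 1) / 2
  rad2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  mask <- rad2 <= (n / 2 - 1)^2
  prep <- function(m) { m0 <- m - mean(m[mask]); m0[!mask] <- 0; m0 }
  obs0 <- prep(obs)
  period <- 360 / symmetry_order
  angles <- seq(-period / 2 + step, period / 2, by = step)
  scores <- vapply(angles, function(th) {
    r0 <- prep(rotate_image(mod, th, fill = stats::median(mod)))
    xcorr_shift(r0, obs0, max_shift_px)[["peak"]]
  }, numeric(1L))
  i <- which.max(scores)
  # parabolic refinement on the periodic score curve
  ng <- length(angles)
  v <- scores[c((i - 2L) %% ng + 1L, i, i %% ng + 1L)]
  den <- v[1L] - 2 * v[2L] + v[3L]
  dd <- if (is.finite(den) && den < 0) max(-0.5, min(0.5, 0.5 * (v[1L] - v[3L]) / den)) else 0
  ang <- angles[i] + dd * step
  ang <- ((ang + period / 2) %% period) - period / 2
  if (ang <= -period / 2) ang <- ang + period
  structure(list(rotation = ang, score = max(scores),
                 ambiguity_order = symmetry_order,
                 scores = data.frame(angle = angles, score = scores)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> rotation %.2f deg CW (mod %g), score %.3f\n",
              x$rotation, 360 / x$ambiguity_order, x$score))
  invisible(x)
}

#' Displacements between two conformational-state averages
#'
#' Summarizes the activation motion between two averaged tetramer maps,
#' both referenced to the membrane: `dz` = difference of mean peak heights
#' (negative = activation moves the domains toward the membrane), `dr` =
#' difference of mean peak radial distances (positive = outward splay),
#' `dphi` = fitted rotation (positive = clockwise, intracellular view).
#' All differences are `activated - resting`.
#'
#' @param avg_activated,avg_resting `average_map`s at the same pixel size.
#' @param n_peaks protrusions per molecule.
#' @return list `dz_nm`, `dr_nm`, `dphi_deg`, plus the per-state
#'   measurements.
#' @export
state_displacements <- function(avg_activated, avg_resting, n_peaks = 4L) {
  pk_height <- function(a) {
    m <- if (inherits(a, "average_map")) a$mean else unclass(a)
    px <- if (inherits(a, "average_map")) a$pixel_size else attr(a, "pixel_size")
    com <- peak_centers_of_mass(a, n_peaks = n_peaks)
    mean(com$peak_height)
  }
  r_act <- radial_distances(avg_activated, n_peaks = n_peaks)
  r_res <- radial_distances(avg_resting, n_peaks = n_peaks)
  rot <- fit_rotation(avg_activated, avg_resting)
  list(dz_nm = pk_height(avg_activated) - pk_height(avg_resting),
       dr_nm = r_act$mean - r_res$mean,
       dphi_deg = rot$rotation,
       radial_activated = r_act, radial_resting = r_res, rotation_fit = rot)
}
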