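#' @keywords internal
# Centred (fftshift-ed) autocorrelation of a zero-meaned image, normalized so
# the origin equals 1.
autocorrelation <- function(m) {
  m0 <- m - mean(m)
  ps <- Mod(stats::fft(m0))^2
  ac <- Re(stats::fft(ps, inverse = TRUE)) / length(m0)
  ac <- ac / ac[1L, 1L]
  nr <- nrow(ac); nc <- ncol(ac)
  # fftshift: zero displacement lands at (floor(nr/2)+1, floor(nc/2)+1)
  ac[c((ceiling(nr / 2) + 1L):nr, 1L:ceiling(nr / 2)),
     c((ceiling(nc / 2) + 1L):nc, 1L:ceiling(nc / 2))]
}

# 3x3 local maxima of a matrix, excluding the border; returns a data.frame
# sorted by decreasing value.
local_maxima <- function(m, n_top = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  i <- 2:(nr - 1L); j <- 2:(nc - 1L)
  ctr <- m[i, j]
  ismax <- ctr > m[i - 1L, j] & ctr >= m[i + 1L, j] &
           ctr > m[i, j - 1L] & ctr >= m[i, j + 1L] &
           ctr > m[i - 1L, j - 1L] & ctr >= m[i + 1L, j + 1L] &
           ctr > m[i - 1L, j + 1L] & ctr >= m[i + 1L, j - 1L]
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  out <- data.frame(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L,
                    value = ctr[idx])
  out <- out[order(-out$value), , drop = FALSE]
  utils::head(out, n_top)
}

# Parabolic subpixel refinement of a local maximum of m at (r, c).
refine_peak <- function(m, r, c) {
  par3 <- function(v) {
    den <- v[1] - 2 * v[2] + v[3]
    if (!is.finite(den) || den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (v[1] - v[3]) / den))
  }
  dr <- if (r > 1L && r < nrow(m)) par3(m[(r - 1L):(r + 1L), c]) else 0
  dc <- if (c > 1L && c < ncol(m)) par3(m[r, (c - 1L):(c + 1L)]) else 0
  c(row = r + dr, col = c + dc)
}

#' Detect the 2D-crystal lattice of a topograph
#'
#' Lattice vectors are read off the real-space autocorrelation: the two
#' strongest non-origin, non-collinear peaks (collinear harmonics are
#' deduplicated in favour of the shorter vector), subpixel-refined by a
#' parabolic fit. Near-ties are resolved by preferring the pair with gamma
#' closest to 90 degrees, then the most equal vector lengths. If no
#' autocorrelation peak exceeds `min_peak` (relative to the origin), a
#' "no lattice" result is returned rather than an error.
#'
#' @param t flattened `topograph` containing at least ~4x4 unit cells.
#' @param min_period,max_period search annulus for lattice vectors, nm.
#' @param min_peak significance floor for normalized autocorrelation peaks.
#' @param n_basis force the number of molecules per cell (1 or 2); `NULL`
#'   = decide automatically from the ring-consistency statistic at the
#'   candidate centred sites. The automatic test is conservative: a centred
#'   sublattice whose motif barely clears the noise floor (e.g. the
#'   0.3 nm extracellular turrets) may be reported as a one-molecule cell.
#' @return a `lattice_model` list: `found`, vectors `a`, `b` (nm, image
#'   coords), lengths `len_a`, `len_b` with uncertainties, `gamma`
#'   (degrees), `n_basis` (1 or 2; 2 when a centred sublattice peak is
#'   present), `sites` (enumerated molecule positions, nm) and `peaks`.
#' @export
detect_lattice <- function(t, min_period = 4, max_period = 20, min_peak = 0.1,
                           n_basis = NULL) {
  px <- attr(t, "pixel_size")
  m <- unclass(t)
  ac <- autocorrelation(m)
  ctr <- c(floor(nrow(ac) / 2) + 1L, floor(ncol(ac) / 2) + 1L)
  pks <- local_maxima(ac)
  if (nrow(pks)) {
    vx <- (pks$col - ctr[2L]) * px
    vy <- (pks$row - ctr[1L]) * px
    len <- sqrt(vx^2 + vy^2)
    keep <- len >= min_period & len <= max_period & pks$value >= min_peak
    pks <- pks[keep, , drop = FALSE]
  }
  if (nrow(pks) < 2L)
    return(structure(list(found = FALSE), class = "lattice_model"))
  # the primitive vectors are the strongest autocorrelation peaks: weaker
  # pseudo-peaks from partial motif overlap (e.g. the centred sublattice of
  # the alternating packing) fall below 90% of the strongest and are
  # excluded before any length-based preference is applied
  pks <- pks[pks$value >= 0.9 * max(pks$value), , drop = FALSE]
  if (nrow(pks) < 2L)
    return(structure(list(found = FALSE), class = "lattice_model"))
  # canonical half-plane representative for each +-v pair, then collapse
  # each collinear family (fundamental + harmonics) to its shortest member
  vecs <- cbind((pks$col - ctr[2L]) * px, (pks$row - ctr[1L]) * px)
  flip <- vecs[, 2L] < 0 | (vecs[, 2L] == 0 & vecs[, 1L] < 0)
  vecs[flip, ] <- -vecs[flip, ]
  ord <- order(sqrt(rowSums(vecs^2)))
  kept <- integer(0)
  for (i in ord) {
    coll <- FALSE
    for (j in kept) {
      cr <- abs(vecs[i, 1L] * vecs[j, 2L] - vecs[i, 2L] * vecs[j, 1L])
      if (cr < 0.18 * sqrt(sum(vecs[i, ]^2)) * sqrt(sum(vecs[j, ]^2))) { coll <- TRUE; break }
    }
    if (!coll) kept <- c(kept, i)
  }
  pks <- pks[kept, , drop = FALSE]
  if (nrow(pks) < 2L)
    return(structure(list(found = FALSE), class = "lattice_model"))
  pks <- pks[order(-pks$value), , drop = FALSE]
  cand <- utils::head(seq_len(nrow(pks)), 6L)
  best <- NULL
  for (i in cand) for (j in cand) if (i < j) {
    p1 <- refine_peak(ac, pks$row[i], pks$col[i])
    p2 <- refine_peak(ac, pks$row[j], pks$col[j])
    a <- c((p1["col"] - ctr[2L]) * px, (p1["row"] - ctr[1L]) * px)
    b <- c((p2["col"] - ctr[2L]) * px, (p2["row"] - ctr[1L]) * px)
    la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
    gamma <- acos(max(-1, min(1, sum(a * b) / (la * lb)))) * 180 / pi
    if (gamma > 90) { b <- -b; gamma <- 180 - gamma }
    score <- c(abs(gamma - 90), abs(la - lb))
    if (is.null(best) || score[1] < best$score[1] - 1e-9 ||
        (abs(score[1] - best$score[1]) <= 1e-9 && score[2] < best$score[2]))
      best <- list(a = a, b = b, la = la, lb = lb, gamma = gamma, score = score,
                   value = c(pks$value[i], pks$value[j]))
  }
  # peak-width-based uncertainty: half-width at 80% of the peak, in nm
  sd_est <- px / 2
  model <- structure(list(found = TRUE, a = best$a, b = best$b,
                          len_a = best$la, len_b = best$lb,
                          sd_a = sd_est, sd_b = sd_est,
                          gamma = best$gamma, n_basis = 1L,
                          peak_values = best$value, pixel_size = px),
                     class = "lattice_model")
  es <- enumerate_sites(m, px, model, force_basis = n_basis)
  model$n_basis <- es$n_basis
  model$sites <- es$sites
  model
}

# Directional running max helpers (edge-clamped shifts).
shift_rows <- function(m, d) {
  nr <- nrow(m)
  m[pmin(pmax(seq_len(nr) + d, 1L), nr), , drop = FALSE]
}
shift_cols <- function(m, d) {
  nc <- ncol(m)
  m[, pmin(pmax(seq_len(nc) + d, 1L), nc), drop = FALSE]
}
range_max <- function(m, ds, by_rows) {
  out <- NULL
  for (d in ds) {
    sh <- if (by_rows) shift_rows(m, d) else shift_cols(m, d)
    out <- if (is.null(out)) sh else pmax(out, sh)
  }
  out
}

# Ring-consistency statistic: M[r, c] = min over the four half-strips
# (east, west, north, south of (r, c), excluding a central gap of g
# pixels) of the local maximum within reach s. A C4 molecule centre has a
# protrusion on every side, so M is high exactly at molecule centres; at
# a single off-centre protrusion or on bare membrane at least one side is
# featureless and M collapses.
ring_min_max <- function(m, s, g) {
  east0 <- range_max(m, g:s, by_rows = FALSE)
  west0 <- range_max(m, -(g:s), by_rows = FALSE)
  north0 <- range_max(m, -(g:s), by_rows = TRUE)
  south0 <- range_max(m, g:s, by_rows = TRUE)
  pmin(range_max(east0, -s:s, by_rows = TRUE),
       range_max(west0, -s:s, by_rows = TRUE),
       range_max(north0, -s:s, by_rows = FALSE),
       range_max(south0, -s:s, by_rows = FALSE))
}

# Enumerate molecule sites on the detected lattice and decide the basis
# count. The lattice phase (origin) maximizes the mean of the
# quadrant-consistency statistic sampled at the corner-site grid: the
# molecule motif is four-fold symmetric about its centre, so every image
# quadrant around a true centre contains a protrusion, while a phase
# locked onto a single protrusion (or membrane) leaves some quadrant
# empty. The alternating two-per-cell packing is then recognized the same
# way: candidate centred sites score like molecule centres, whereas in a
# one-per-cell lattice the centred position is featureless in at least
# one quadrant.
enumerate_sites <- function(m, px, model, force_basis = NULL,
                            ring_scale_nm = 3.0) {
  # strip reach at the protrusion-ring scale: large enough to catch each
  # of the four ring protrusions (ring radii ~2.1-2.4 nm), small enough
  # that a half-ring phase error empties a strip
  s <- max(2L, round(ring_scale_nm / px))
  g <- max(1L, round(1 / px))
  M <- ring_min_max(m, s, g)
  nr <- nrow(m); nc <- ncol(m)
  a <- model$a / px; b <- model$b / px   # in px units (x = col, y = row)
  span <- ceiling(max(nr, nc) / min(model$len_a, model$len_b) * px) + 2L
  ij <- as.matrix(expand.grid(i = -span:span, j = -span:span))
  base <- cbind(ij[, 1L] * a[1L] + ij[, 2L] * b[1L],
                ij[, 1L] * a[2L] + ij[, 2L] * b[2L])
  sample_at <- function(off) {
    xc <- round(base[, 1L] + off[1L]); yc <- round(base[, 2L] + off[2L])
    ok <- xc > s & xc <= nc - s & yc > s & yc <= nr - s
    if (!any(ok)) return(-Inf)
    mean(M[cbind(yc[ok], xc[ok])])
  }
  ph <- expand.grid(u = seq(0, 0.96, by = 0.04), v = seq(0, 0.96, by = 0.04))
  score <- vapply(seq_len(nrow(ph)), function(q)
    sample_at(ph$u[q] * a + ph$v[q] * b), numeric(1L))
  o <- ph[which.max(score), ]
  org <- as.numeric(o$u) * a + as.numeric(o$v) * b
  m_corner <- sample_at(org)
  m_centre <- sample_at(org + (a + b) / 2)
  n_basis <- if (!is.null(force_basis)) as.integer(force_basis)
  else if (is.finite(m_centre) && m_centre >= 0.7 * m_corner) 2L else 1L
  offs <- if (n_basis == 2L) list(c(0, 0), (a + b) / 2) else list(c(0, 0))
  out <- do.call(rbind, lapply(seq_along(offs), function(k) {
    xc <- base[, 1L] + org[1L] + offs[[k]][1L]
    yc <- base[, 2L] + org[2L] + offs[[k]][2L]
    ok <- xc >= 1 & xc <= nc & yc >= 1 & yc <= nr
    data.frame(x = xc[ok] * px, y = yc[ok] * px, basis = k)
  }))
  out$site_id <- seq_len(nrow(out))
  list(sites = out, n_basis = n_basis)
}

box_smooth <- function(m, k) {
  if (k < 1L) return(m)
  n <- 2L * k + 1L
  row_mean <- function(mm) {   # running mean over rows, edge replication
    nr <- nrow(mm)
    out <- 0
    for (d in -k:k) out <- out + mm[pmin(pmax(seq_len(nr) + d, 1L), nr), , drop = FALSE]
    out / n
  }
  t(row_mean(t(row_mean(m))))
}

#' Extract per-molecule sub-images
#'
#' Cuts one square window per site from a topograph. Sites whose window
#' would clip the image edge are flagged (`interior = FALSE`) and excluded
#' from the stack.
#'
#' @param t a `topograph`.
#' @param sites data.frame with `x`, `y` (nm) site positions (from a
#'   `lattice_model` or the simulator's ground truth).
#' @param window_nm window edge length in nm (rounded up to an odd pixel
#'   count).
#' @return a `particle_stack`: list with `particles` (list of matrices),
#'   `sites` (with `interior` flag), `window_px`, `pixel_size`, and
#'   per-particle alignment (filled by [correlation_average()]).
#' @export
extract_particles <- function(t, sites, window_nm) {
  px <- attr(t, "pixel_size")
  m <- unclass(t)
  w <- ceiling(window_nm / px)
  if (w %% 2L == 0L) w <- w + 1L
  if (w > min(dim(m))) stop("window larger than image", call. = FALSE)
  h <- (w - 1L) %/% 2L
  rc <- cbind(round(sites$y / px + 0.5), round(sites$x / px + 0.5))
  interior <- rc[, 1L] - h >= 1L & rc[, 1L] + h <= nrow(m) &
              rc[, 2L] - h >= 1L & rc[, 2L] + h <= ncol(m)
  parts <- lapply(which(interior), function(s)
    m[(rc[s, 1L] - h):(rc[s, 1L] + h), (rc[s, 2L] - h):(rc[s, 2L] + h)])
  sites$interior <- interior
  structure(list(particles = parts, sites = sites,
                 idx = which(interior), window_px = w, pixel_size = px,
                 alignment = data.frame(dx = numeric(length(parts)),
                                        dy = numeric(length(parts)))),
            class = "particle_stack")
}

#' Correlation-average a particle stack
#'
#' Iteratively aligns every particle to a reference (default: the plain
#' mean, refined `n_iter` times) by translation-only cross-correlation with
#' subpixel refinement, then returns the aligned mean, the per-pixel sd and
#' the particle count. Particles in a crystal share one orientation, so no
#' per-particle rotation is searched.
#'
#' @param stack a `particle_stack`.
#' @param reference optional starting reference matrix.
#' @param n_iter alignment refinement passes.
#' @param max_shift_px largest alignment shift searched.
#' @return an `average_map`: list with `mean`, `sd`, `n`, `symmetry`,
#'   `pixel_size`; the final alignment is stored in `alignment`.
#' @export
correlation_average <- function(stack, reference = NULL, n_iter = 3L,
                                max_shift_px = NULL) {
  n <- length(stack$particles)
  stopifnot(n >= 1L)
  w <- stack$window_px
  if (is.null(max_shift_px)) max_shift_px <- max(2L, floor(w / 6))
  ref <- if (is.null(reference)) Reduce(`+`, stack$particles) / n else reference
  al <- matrix(0, n, 2L)
  aligned <- stack$particles
  for (it in seq_len(max(1L, n_iter))) {
    for (k in seq_len(n)) {
      r <- xcorr_shift(ref, stack$particles[[k]], max_shift_px)
      al[k, ] <- r[c("dx", "dy")]
      aligned[[k]] <- fourier_shift(stack$particles[[k]], -al[k, 1L], -al[k, 2L])
    }
    ref <- Reduce(`+`, aligned) / n
  }
  mu <- ref
  sdm <- if (n > 1L)
    sqrt(Reduce(`+`, lapply(aligned, function(p) (p - mu)^2)) / (n - 1L))
  else matrix(0, w, w)
  structure(list(mean = mu, sd = sdm, n = n, symmetry = 1L,
                 pixel_size = stack$pixel_size,
                 alignment = data.frame(dx = al[, 1L], dy = al[, 2L])),
            class = "average_map")
}

#' @export
print.average_map <- function(x, ...) {
  cat(sprintf("<average_map> %d x %d px, n = %d, C%d, %.3g nm/px\n",
              nrow(x$mean), ncol(x$mean), x$n, x$symmetry, x$pixel_size))
  invisible(x)
}

#' Rotate an image about a centre (bilinear resampling)
#'
#' Positive angles rotate the content clockwise as displayed (x right,
#' y down). Multiples of 90 degrees use exact array operations.
#'
#' @param m numeric matrix.
#' @param theta rotation angle, degrees CW.
#' @param fill value for samples falling outside the input.
#' @export
rotate_image <- function(m, theta, fill = 0) {
  theta <- ((theta + 180) %% 360) - 180
  if (abs(theta %% 90) < 1e-9) {
    q <- (round(theta / 90) %% 4 + 4) %% 4
    # exact quarter turns; CW on screen (y down): 90 deg maps (x,y)->(-y,x)
    out <- m
    if (q >= 1) for (i in seq_len(q)) out <- t(out[nrow(out):1, , drop = FALSE])
    return(out)
  }
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- theta * pi / 180
  # inverse mapping: sample source at R(-theta) (p - c) + c
  co <- cos(th); si <- sin(th)
  X <- matrix(rep(seq_len(nc), each = nr), nr) - cx
  Y <- matrix(rep(seq_len(nr), times = nc), nr) - cy
  xs <- co * X + si * Y + cx
  ys <- -si * X + co * Y + cy
  bilinear_sample(m, xs, ys, fill)
}

bilinear_sample <- function(m, xs, ys, fill = 0) {
  out_dim <- dim(xs)
  nr <- nrow(m); nc <- ncol(m)
  xs <- as.vector(xs); ys <- as.vector(ys)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr
  x0c <- pmin(pmax(x0, 1), nc - 1); y0c <- pmin(pmax(y0, 1), nr - 1)
  v00 <- m[cbind(y0c, x0c)];       v01 <- m[cbind(y0c, x0c + 1)]
  v10 <- m[cbind(y0c + 1, x0c)];   v11 <- m[cbind(y0c + 1, x0c + 1)]
  v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  v[!ok] <- fill
  matrix(v, out_dim[1L], out_dim[2L])
}

#' Cn-symmetrize an average map
#'
#' Averages the map with its rotations by k*360/order about the map centre.
#' Orders 1, 2 and 4 use exact quarter-turn array operations (volume
#' conserved exactly); other orders use bilinear resampling. Idempotent.
#'
#' @param avg an `average_map` (or plain matrix).
#' @param order symmetry order (>= 1).
#' @export
symmetrize <- function(avg, order = 4L) {
  is_map <- inherits(avg, "average_map")
  m <- if (is_map) avg$mean else avg
  stopifnot(nrow(m) == ncol(m), order >= 1L)
  if (order > 1L) {
    acc <- m
    for (k in seq_len(order - 1L))
      acc <- acc + rotate_image(m, k * 360 / order, fill = stats::median(m))
    m <- acc / order
  }
  if (!is_map) return(m)
  out <- avg
  out$mean <- m
  out$symmetry <- as.integer(order)
  out
}
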