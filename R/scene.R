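#' Parametric channel footprints
#'
#' A footprint is the parametric surface model of one tetrameric channel as
#' seen by the AFM from one membrane face: a set of protrusions (spherical
#' caps or Gaussian bumps) placed around the molecular four-fold axis. The
#' analysis pipeline only consumes protrusion positions and heights, so
#' parametric geometry replaces any atomic model.
#'
#' @param protrusions data.frame with columns `dx`, `dy` (offsets from the
#'   molecular centre, nm), `height` (apex height above the membrane, nm,
#'   >= 0), `radius` (base radius for `"cap"`, Gaussian sigma for
#'   `"gaussian"`, nm, > 0) and `shape` (`"cap"` or `"gaussian"`).
#' @param face `"extracellular"` or `"intracellular"`.
#' @param symmetry_order rotational symmetry order of the molecule (4 for a
#'   tetramer).
#' @return an object of class `channel_footprint`.
#' @export
channel_footprint <- function(protrusions, face = c("intracellular", "extracellular"),
                              symmetry_order = 4L) {
  face <- match.arg(face)
  stopifnot(is.data.frame(protrusions), nrow(protrusions) >= 1L,
            all(c("dx", "dy", "height", "radius", "shape") %in% names(protrusions)),
            all(protrusions$radius > 0), all(protrusions$height >= 0),
            all(protrusions$shape %in% c("cap", "gaussian")))
  structure(list(protrusions = protrusions, face = face,
                 symmetry_order = as.integer(symmetry_order)),
            class = "channel_footprint")
}

#' Four protrusions on a ring (C4 placement helper)
#' @param ring_radius radial distance of each protrusion centre from the
#'   molecular axis, nm.
#' @param azimuth0 azimuth of the first protrusion in degrees (from +x,
#'   clockwise on screen).
#' @param height,radius,shape protrusion parameters, see [channel_footprint()].
#' @keywords internal
ring_protrusions <- function(ring_radius, azimuth0, height, radius, shape) {
  az <- (azimuth0 + c(0, 90, 180, 270)) * pi / 180
  data.frame(dx = ring_radius * cos(az), dy = ring_radius * sin(az),
             height = height, radius = radius, shape = shape)
}

#' Channel footprint presets
#'
#' Encodes the measured morphometry of the two conformations of the SthK-like
#' tetramer. Intracellular face: four CNBD lobes plus a lower central
#' C-linker (gating ring) disk. In the activated (cAMP-bound) state the CNBD
#' lobes sit splayed 0.4 nm further out (ring radius 3.4 vs 3.0 nm), rotated
#' 25 degrees clockwise, and 4.3 nm above the membrane; in the resting
#' (cGMP/apo) state they sit at 3.0 nm radius and 5.05 nm height (so the
#' mean activation height change is -0.6 nm). Extracellular face: four small
#' pore-domain turrets (0.3 nm) that serve as the rotational fiducial of the
#' pore domain.
#'
#' @param face which membrane face is being imaged.
#' @param state conformational state of the molecule.
#' @return a `channel_footprint`.
#' @export
sthk_footprint <- function(face = c("intracellular", "extracellular"),
                           state = c("activated", "resting")) {
  face <- match.arg(face)
  state <- match.arg(state)
  if (face == "intracellular") {
    rot <- if (state == "activated") 25 else 0
    rad <- if (state == "activated") 3.4 else 3.0
    hgt <- if (state == "activated") 4.3 else 5.05
    pr <- rbind(
      ring_protrusions(rad, 45 + rot, height = hgt, radius = 0.9, shape = "gaussian"),
      data.frame(dx = 0, dy = 0, height = 3.2, radius = 1.5, shape = "gaussian"))
  } else {
    # turrets are state-invariant; packing (z-offsets) makes the two classes
    pr <- ring_protrusions(2.4, 0, height = 0.3, radius = 1.2, shape = "cap")
  }
  channel_footprint(pr, face = face, symmetry_order = 4L)
}

#' 2D-crystal lattice specification
#'
#' @param a,b lattice constants in nm (> 0).
#' @param gamma angle between the lattice vectors in degrees (0, 180].
#' @param basis data.frame with columns `fx`, `fy` (fractional cell
#'   coordinates), `rot` (in-plane rotation, degrees CW), `dz` (vertical
#'   offset, nm), `footprint` (id resolved against the footprint list at
#'   render time).
#' @param extent number of unit cells per side.
#' @param patch_radius optional radius (nm) of a circular crystal-patch mask
#'   about the lattice centre; sites outside are omitted, which exposes
#'   membrane around the patch and creates a patch border.
#' @export
lattice_spec <- function(a, b = a, gamma = 90, basis, extent = 6L, patch_radius = NULL) {
  stopifnot(a > 0, b > 0, gamma > 0, gamma <= 180,
            is.data.frame(basis), nrow(basis) >= 1L,
            all(c("fx", "fy", "rot", "dz", "footprint") %in% names(basis)))
  structure(list(a = a, b = b, gamma = gamma, basis = basis,
                 extent = as.integer(extent), patch_radius = patch_radius),
            class = "lattice_spec")
}

#' Crystal packing presets
#'
#' Activated (cAMP) polymorph: square cell a = b = 11.6 nm, gamma = 90, two
#' tetramers per cell (corner and centre), the centre molecule rotated 25
#' degrees and raised 0.3 nm — the alternating packing that produces the
#' 0.3/0.6 nm extracellular and 4.3/4.6 nm intracellular height classes.
#' Resting (cGMP/apo) polymorph: square cell a = b = 8.1 nm, one tetramer
#' per cell.
#'
#' @param state packing polymorph.
#' @inheritParams lattice_spec
#' @export
sthk_lattice <- function(state = c("activated", "resting"), extent = 6L,
                         patch_radius = NULL) {
  state <- match.arg(state)
  if (state == "activated") {
    basis <- data.frame(fx = c(0, 0.5), fy = c(0, 0.5), rot = c(0, 25),
                        dz = c(0, 0.3), footprint = "activated")
    lattice_spec(11.6, gamma = 90, basis = basis, extent = extent,
                 patch_radius = patch_radius)
  } else {
    basis <- data.frame(fx = 0, fy = 0, rot = 0, dz = 0, footprint = "resting")
    lattice_spec(8.1, gamma = 90, basis = basis, extent = extent,
                 patch_radius = patch_radius)
  }
}

#' Spherical tip model
#' @param radius apex radius of curvature in nm; 0 means an ideal
#'   (dimensionless) tip, i.e. no dilation.
#' @export
tip_model <- function(radius = 2) {
  stopifnot(radius >= 0)
  structure(list(radius = radius), class = "tip_model")
}

#' Scan parameters
#'
#' @param pixel_size nm per pixel.
#' @param pixel_noise_sd per-pixel Gaussian height noise sd, nm.
#' @param line_offset_sd per-scan-line Gaussian offset sd, nm (fast-scan
#'   lines are matrix rows).
#' @param drift_velocity 2-vector, sample drift in nm per frame (x, y).
#' @param frame_interval seconds between frames.
#' @param seed RNG seed for the artifact stage (`NULL` leaves the RNG state
#'   alone).
#' @export
scan_params <- function(pixel_size = 0.35, pixel_noise_sd = 0.05,
                        line_offset_sd = 0.02, drift_velocity = c(0, 0),
                        frame_interval = 1, seed = NULL) {
  stopifnot(pixel_size > 0, pixel_noise_sd >= 0, line_offset_sd >= 0,
            length(drift_velocity) == 2L, frame_interval > 0)
  structure(list(pixel_size = pixel_size, pixel_noise_sd = pixel_noise_sd,
                 line_offset_sd = line_offset_sd,
                 drift_velocity = as.numeric(drift_velocity),
                 frame_interval = frame_interval, seed = seed),
            class = "scan_params")
}

# Enumerate lattice sites in image coordinates (nm), with a margin so the
# outermost footprints fit inside the frame.
lattice_sites <- function(lattice, margin = 8) {
  g <- lattice$gamma * pi / 180
  av <- c(lattice$a, 0)
  bv <- c(lattice$b * cos(g), lattice$b * sin(g))
  n <- lattice$extent
  ij <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L))
  out <- do.call(rbind, lapply(seq_len(nrow(lattice$basis)), function(k) {
    bs <- lattice$basis[k, ]
    data.frame(i = ij$i, j = ij$j, basis = k,
               x = (ij$i + bs$fx) * av[1] + (ij$j + bs$fy) * bv[1],
               y = (ij$i + bs$fx) * av[2] + (ij$j + bs$fy) * bv[2],
               rot = bs$rot, dz = bs$dz, footprint = bs$footprint,
               stringsAsFactors = FALSE)
  }))
  ctr <- c(mean(range(out$x)), mean(range(out$y)))
  if (!is.null(lattice$patch_radius)) {
    keep <- sqrt((out$x - ctr[1])^2 + (out$y - ctr[2])^2) <= lattice$patch_radius
    out <- out[keep, , drop = FALSE]
  }
  out$x <- out$x - min(out$x) + margin
  out$y <- out$y - min(out$y) + margin
  out$site_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Evaluate one protrusion's surface over a local window and fold it into the
# height grid by max composition (the AFM contours the outer envelope).
add_protrusion <- function(grid, px, cx, cy, height, radius, shape, dz, zeps = 0.05) {
  w_nm <- if (shape == "cap") radius else radius * sqrt(2 * log(height / min(zeps, height)))
  nr <- nrow(grid); nc <- ncol(grid)
  c0 <- max(1L, floor((cx - w_nm) / px + 0.5))
  c1 <- min(nc, ceiling((cx + w_nm) / px + 0.5))
  r0 <- max(1L, floor((cy - w_nm) / px + 0.5))
  r1 <- min(nr, ceiling((cy + w_nm) / px + 0.5))
  if (c0 > c1 || r0 > r1) return(grid)
  xs <- ((c0:c1) - 0.5) * px - cx
  ys <- ((r0:r1) - 0.5) * px - cy
  d2 <- outer(ys^2, xs^2, "+")
  if (shape == "cap") {
    rs <- (radius^2 + height^2) / (2 * height)   # sphere radius through rim and apex
    z <- (height - rs) + sqrt(pmax(rs^2 - d2, 0))
    z[d2 > radius^2] <- 0
    z <- pmax(z, 0)
  } else {
    z <- height * exp(-d2 / (2 * radius^2))
  }
  contrib <- ifelse(z > zeps, z + dz, 0)
  grid[r0:r1, c0:c1] <- pmax(grid[r0:r1, c0:c1], pmax(contrib, 0))
  grid
}

render_site <- function(grid, px, site, footprint) {
  th <- site$rot * pi / 180   # CW on screen (y down)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  for (p in seq_len(nrow(footprint$protrusions))) {
    pr <- footprint$protrusions[p, ]
    off <- R %*% c(pr$dx, pr$dy)
    grid <- add_protrusion(grid, px, site$x + off[1], site$y + off[2],
                           pr$height, pr$radius, pr$shape, site$dz)
  }
  grid
}

#' Render an ideal (noise- and tip-free) crystal surface
#'
#' Composes all protrusion surfaces by pointwise maximum over the membrane
#' level (0 nm): the AFM tip contours the outer envelope of the hard bodies,
#' it does not sum overlapping densities. The ground-truth site table is
#' attached as attribute `"sites"`.
#'
#' @param lattice a [lattice_spec()].
#' @param footprints a single `channel_footprint`, or a named list of them
#'   resolved against the basis/state `footprint` ids.
#' @param pixel_size nm per pixel; must resolve the smallest protrusion
#'   radius with at least 3 px (a warning is issued otherwise).
#' @param states optional character vector of per-site footprint ids
#'   (e.g. conformational states), overriding the basis ids.
#' @param margin margin in nm between the outermost sites and the frame edge.
#' @return a `topograph` with attribute `"sites"` (ground-truth table).
#' @export
render_surface <- function(lattice, footprints, pixel_size, states = NULL,
                           margin = 8) {
  if (inherits(footprints, "channel_footprint"))
    footprints <- stats::setNames(list(footprints), unique(lattice$basis$footprint))
  sites <- lattice_sites(lattice, margin = margin)
  if (!is.null(states)) {
    stopifnot(length(states) == nrow(sites))
    sites$footprint <- as.character(states)
  }
  miss <- setdiff(unique(sites$footprint), names(footprints))
  if (length(miss))
    stop("unresolvable footprint id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  # visible lobe radius: base radius for caps, ~2 sigma for Gaussian bumps
  rmin <- min(vapply(footprints, function(f)
    min(ifelse(f$protrusions$shape == "cap", f$protrusions$radius,
               2 * f$protrusions$radius)), numeric(1L)))
  if (pixel_size > rmin / 3)
    warning(sprintf("pixel_size %.3g nm resolves the smallest protrusion radius (%.3g nm) with < 3 px",
                    pixel_size, rmin))
  nc <- ceiling((max(sites$x) + margin) / pixel_size)
  nr <- ceiling((max(sites$y) + margin) / pixel_size)
  grid <- matrix(0, nr, nc)
  for (s in seq_len(nrow(sites)))
    grid <- render_site(grid, pixel_size, sites[s, ], footprints[[sites$footprint[s]]])
  out <- topograph(grid, pixel_size)
  attr(out, "sites") <- sites
  out
}

#' Render a single footprint alone, centred in a square frame
#'
#' @inheritParams render_surface
#' @param footprint a `channel_footprint`.
#' @param size_nm frame edge length in nm.
#' @param rotation extra in-plane rotation (degrees CW) applied to the
#'   footprint.
#' @param dz vertical offset in nm.
#' @export
render_footprint <- function(footprint, pixel_size, size_nm = 14,
                             rotation = 0, dz = 0) {
  n <- ceiling(size_nm / pixel_size)
  if (n %% 2L == 0L) n <- n + 1L   # odd frame: exact centre pixel
  grid <- matrix(0, n, n)
  ctr <- n / 2 * pixel_size
  site <- data.frame(x = ctr, y = ctr, rot = rotation, dz = dz)
  topograph(render_site(grid, pixel_size, site, footprint), pixel_size)
}

#' Tip-sample dilation
#'
#' Models the finite spherical tip apex: the imaged surface is the grayscale
#' morphological dilation of the true surface by the reflected tip,
#' `out(x) = max_s [ in(x + s) - t(|s|) ]` with tip profile
#' `t(d) = R - sqrt(R^2 - d^2)`. Output >= input everywhere; local maxima
#' of isolated features keep their apex height.
#'
#' @param surface a `topograph`.
#' @param tip a [tip_model()]; a radius smaller than half a pixel returns
#'   the input unchanged (with a message).
#' @export
tip_dilate <- function(surface, tip) {
  px <- attr(surface, "pixel_size")
  R <- tip$radius
  if (R < px / 2) {
    if (R > 0) message("tip radius below pixel resolution; no dilation applied")
    return(surface)
  }
  kmax <- floor(R / px)
  off <- expand.grid(di = -kmax:kmax, dj = -kmax:kmax)
  d <- px * sqrt(off$di^2 + off$dj^2)
  keep <- d <= R
  off <- off[keep, ]; d <- d[keep]
  tprof <- R - sqrt(R^2 - d^2)
  m <- unclass(surface)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  for (k in seq_along(d)) {
    ri <- pmin(pmax(seq_len(nr) + off$di[k], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + off$dj[k], 1L), nc)
    out <- pmax(out, m[ri, ci] - tprof[k])
  }
  res <- topograph(out, px)
  attr(res, "sites") <- attr(surface, "sites")
  res
}

# Centre-crop / zero-pad a matrix to target dims (membrane level 0).
fit_to_dims <- function(m, d) {
  out <- matrix(0, d[1L], d[2L])
  nr <- min(nrow(m), d[1L]); nc <- min(ncol(m), d[2L])
  sr <- (nrow(m) - nr) %/% 2L; sc <- (ncol(m) - nc) %/% 2L
  tr <- (d[1L] - nr) %/% 2L; tc <- (d[2L] - nc) %/% 2L
  out[tr + seq_len(nr), tc + seq_len(nc)] <- m[sr + seq_len(nr), sc + seq_len(nc)]
  out
}

#' Subpixel translation by Fourier shift
#'
#' Shifts image content by (`dx`, `dy`) pixels (positive = rightwards /
#' downwards) using the FFT phase ramp; periodic at the frame edges.
#'
#' @param m numeric matrix.
#' @param dx,dy shift in pixels (may be fractional).
#' @export
fourier_shift <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- fft_freqs(nr); kc <- fft_freqs(nc)
  phase <- exp(-2i * pi * (outer(kr * dy, kc * dx, "+")))
  Re(stats::fft(stats::fft(m) * phase, inverse = TRUE)) / (nr * nc)
}

fft_freqs <- function(n) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  if (n == 1L) k <- 0
  k[seq_len(n)] / n
}

#' Apply scan artifacts to an ideal movie
#'
#' Adds, in order: cumulative frame-to-frame drift (subpixel Fourier shift by
#' `drift_velocity * (frame - 1)`), per-scan-line Gaussian offsets, and
#' per-pixel Gaussian noise. The injected drift is recorded in the movie's
#' ground truth (`truth$drift_nm`).
#'
#' @param movie a `topo_movie` (ideal frames).
#' @param scan a [scan_params()]; its `seed` (if non-NULL) makes the stage
#'   reproducible.
#' @export
apply_scan_artifacts <- function(movie, scan) {
  stopifnot(inherits(movie, "topo_movie"), inherits(scan, "scan_params"))
  if (!is.null(scan$seed)) set.seed(scan$seed)
  px <- movie$pixel_size
  nfr <- n_frames(movie)
  drift <- t(vapply(seq_len(nfr), function(k) scan$drift_velocity * (k - 1),
                    numeric(2L)))
  frames <- lapply(seq_len(nfr), function(k) {
    f <- movie$frames[[k]]
    if (any(drift[k, ] != 0))
      f <- fourier_shift(f, drift[k, 1] / px, drift[k, 2] / px)
    if (scan$line_offset_sd > 0)
      f <- f + stats::rnorm(nrow(f), 0, scan$line_offset_sd)  # recycled along rows
    if (scan$pixel_noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, scan$pixel_noise_sd), nrow(f))
    f
  })
  truth <- movie$truth
  truth$drift_nm <- data.frame(frame = seq_len(nfr), dx = drift[, 1], dy = drift[, 2])
  topo_movie(frames, px, timestamps = movie$timestamps, truth = truth)
}

#' Simulate an HS-AFM movie of a crystal patch with known ground truth
#'
#' Renders each frame from the per-site conformational states (drawn from a
#' border-nucleated domino model when `transition` is given), applies tip
#' dilation and scan artifacts. Transitioned molecules are rendered with the
#' target-state footprint at their original lattice positions; mid-transition
#' lattice repacking is not modelled. If `final_scene` is supplied, frames in
#' which every site has transitioned are rendered from that (repacked) scene
#' instead.
#'
#' @param scene list with elements `lattice` ([lattice_spec()]),
#'   `footprints` (named list of [channel_footprint()]s), `tip`
#'   ([tip_model()]).
#' @param scan a [scan_params()].
#' @param n_frames number of frames (>= 1).
#' @param transition optional list: `model` (a [domino_model()]), `from`,
#'   `to` (footprint ids), `seed`.
#' @param final_scene optional scene list used once all sites transitioned.
#' @return a `topo_movie` whose `truth` holds the site table, the
#'   frame-by-site state matrix, per-site transition times and injected drift.
#' @export
simulate_movie <- function(scene, scan, n_frames, transition = NULL,
                           final_scene = NULL) {
  stopifnot(n_frames >= 1L)
  px <- scan$pixel_size
  base <- render_surface(scene$lattice, scene$footprints, px)
  sites <- attr(base, "sites")
  ts <- (seq_len(n_frames) - 1) * scan$frame_interval
  if (is.null(transition)) {
    states <- matrix(sites$footprint, n_frames, nrow(sites), byrow = TRUE)
    times <- rep(Inf, nrow(sites))
  } else {
    graph <- site_graph(sites)
    times <- simulate_domino(transition$model, graph,
                             t_max = max(ts) + scan$frame_interval,
                             seed = transition$seed)$times
    states <- t(vapply(ts, function(t0)
      ifelse(times <= t0, transition$to, sites$footprint), character(nrow(sites))))
  }
  final_frame <- NULL
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    if (!is.null(final_scene) && all(states[k, ] != sites$footprint)) {
      if (is.null(final_frame)) {
        ff <- unclass(tip_dilate(
          render_surface(final_scene$lattice, final_scene$footprints, px),
          scene$tip))
        final_frame <- fit_to_dims(ff, dim(base))
      }
      frames[[k]] <- final_frame
    } else if (k > 1L && identical(states[k, ], states[k - 1L, ])) {
      frames[[k]] <- frames[[k - 1L]]
    } else {
      fr <- render_surface(scene$lattice, scene$footprints, px,
                           states = states[k, ])
      frames[[k]] <- unclass(tip_dilate(fr, scene$tip))
    }
  }
  ideal <- topo_movie(frames, px, timestamps = ts,
                      truth = list(sites = sites, states = states,
                                   transition_times = times))
  apply_scan_artifacts(ideal, scan)
}
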