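# Shared fixture builders and independent brute-force oracles.

default_tip <- function() tip_model(2)

# a quiet scan (no artifacts) for deterministic geometry tests
quiet_scan <- function(...) scan_params(pixel_noise_sd = 0, line_offset_sd = 0, ...)

# small simulated crystal frame via the internal pipeline helper
crystal_frame <- function(state, face, extent = 6L, seed = 42L,
                          scan = scan_params(), tip = default_tip(), ...) {
  hsafm:::simulated_crystal_frame(state, face, extent, scan, tip, seed = seed, ...)
}

# a small transition movie scene (intracellular activated patch)
transition_scene <- function(extent = 4L, patch_radius = 26) {
  list(lattice = sthk_lattice("activated", extent = extent, patch_radius = patch_radius),
       footprints = list(activated = sthk_footprint("intracellular", "activated"),
                         resting = sthk_footprint("intracellular", "resting")),
       tip = default_tip())
}

# Brute-force grayscale dilation: out(x) = max_s [in(x+s) - t(|s|)], direct
# triple loop over a spherical tip profile. Independent of tip_dilate().
brute_dilate <- function(m, R, px) {
  nr <- nrow(m); nc <- ncol(m)
  kmax <- floor(R / px)
  out <- matrix(-Inf, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    best <- -Inf
    for (di in -kmax:kmax) for (dj in -kmax:kmax) {
      d <- px * sqrt(di^2 + dj^2)
      if (d > R) next
      rr <- min(max(r + di, 1L), nr); cc <- min(max(c + dj, 1L), nc)
      v <- m[rr, cc] - (R - sqrt(R^2 - d^2))
      if (v > best) best <- v
    }
    out[r, c] <- best
  }
  out
}

# Brute-force integer-shift search maximizing cross-correlation.
brute_shift <- function(a, b, max_shift = 6L) {
  best <- c(0, 0); bestv <- -Inf
  a0 <- a - mean(a); b0 <- b - mean(b)
  nr <- nrow(a); nc <- ncol(a)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    rs <- intersect(seq_len(nr), seq_len(nr) + dy)
    cs <- intersect(seq_len(nc), seq_len(nc) + dx)
    v <- sum(b0[rs, cs] * a0[rs - dy, cs - dx])
    if (v > bestv) { bestv <- v; best <- c(dx, dy) }
  }
  best
}

# Direct (independent) autocorrelation at a given real-space displacement
# (integer pixels), on overlapping regions, normalized by the zero-shift
# value of the same estimator.
brute_autocorr_at <- function(m, dx_px, dy_px) {
  m0 <- m - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  val <- function(dx, dy) {
    rs <- intersect(seq_len(nr), seq_len(nr) + dy)
    cs <- intersect(seq_len(nc), seq_len(nc) + dx)
    sum(m0[rs, cs] * m0[rs - dy, cs - dx])
  }
  val(dx_px, dy_px) / val(0L, 0L)
}

# Direct centre-of-mass of heights above a threshold, by exhaustive pixel
# sum (independent of peak_centers_of_mass's region growing).
brute_com <- function(m, thr, px) {
  idx <- which(m >= thr, arr.ind = TRUE)
  w <- m[idx]
  c(x = sum(w * idx[, 2L]) / sum(w) * px, y = sum(w * idx[, 1L]) / sum(w) * px)
}
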