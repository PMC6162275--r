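test_that("membrane reference finds the lowest height mode", {
  set.seed(5)
  m <- matrix(rnorm(10000, 0, 0.05), 100)          # membrane at 0
  m[30:40, 30:40] <- m[30:40, 30:40] + 4.5         # a protein patch
  t <- topograph(m, 0.5)
  expect_lt(abs(membrane_reference(t)), 0.03)
  expect_lt(abs(membrane_reference(topograph(m + 2, 0.5)) - 2), 0.03)
  # synthetic crystal with exposed membrane: reference within 0.05 nm of 0
  fr <- crystal_frame("activated", "intracellular", 4L, patch_radius = 24)
  expect_lt(abs(membrane_reference(fr)), 0.05)
  # all-protein frame falls back to a low percentile with a warning
  flat <- topograph(matrix(rnorm(400, 5, 0.02), 20), 0.5)
  expect_warning(membrane_reference(flat, min_prominence = 2))  # no mode qualifies
  expect_lt(abs(suppressWarnings(membrane_reference(flat, min_prominence = 2)) - 5), 0.2)
})

test_that("height profiles sample the surface along a segment", {
  m <- matrix(3, 40, 40)
  t <- topograph(m, 0.5)
  pr <- height_profile(t, c(2, 10), c(18, 10))
  expect_true(all(abs(pr$height_nm - 3) < 1e-9))
  expect_equal(max(pr$dist_nm), 16, tolerance = 0.3)
  expect_error(height_profile(t, c(2, 2), c(2, 2)), "zero-length")
  # a line through a rendered 4.6 nm protrusion peaks at its height
  fp <- channel_footprint(data.frame(dx = 0, dy = 0, height = 4.6, radius = 1.5,
                                     shape = "cap"), "intracellular")
  lat <- lattice_spec(10, basis = data.frame(fx = 0, fy = 0, rot = 0, dz = 0,
                                             footprint = "f"), extent = 1L)
  tt <- render_surface(lat, stats::setNames(list(fp), "f"), 0.4, margin = 8.2)
  s <- attr(tt, "sites")
  pr2 <- height_profile(tt, c(s$x - 4, s$y), c(s$x + 4, s$y))
  expect_equal(max(pr2$height_nm), 4.6, tolerance = 0.02)
})

test_that("profiles along the activated lattice vector alternate by the packing offset", {
  fr <- crystal_frame("activated", "extracellular", 6L, scan = quiet_scan())
  sites <- attr(fr, "sites")
  heights <- molecule_heights(fr, sites, window_nm = 6, membrane = 0)
  hb <- tapply(heights$height_nm, sites$basis, mean, na.rm = TRUE)
  expect_equal(unname(hb[2] - hb[1]), 0.3, tolerance = 0.05)
  expect_equal(unname(hb[1]), 0.3, tolerance = 0.05)
})

test_that("molecule heights are exact for a clean isolated cap", {
  fp <- channel_footprint(data.frame(dx = 0, dy = 0, height = 4.6, radius = 1.5,
                                     shape = "cap"), "intracellular")
  lat <- lattice_spec(10, basis = data.frame(fx = 0, fy = 0, rot = 0, dz = 0,
                                             footprint = "f"), extent = 1L)
  t <- render_surface(lat, stats::setNames(list(fp), "f"), 0.4, margin = 8.2)
  h <- molecule_heights(t, attr(t, "sites"), window_nm = 5, k = 1L, membrane = 0)
  expect_equal(h$height_nm, 4.6, tolerance = 1e-9)
  # a site whose window clips the frame edge is flagged
  h2 <- molecule_heights(t, data.frame(x = c(0.5, attr(t, "sites")$x),
                                       y = c(0.5, attr(t, "sites")$y)),
                         window_nm = 5, membrane = 0)
  expect_false(h2$interior[1])
  expect_true(is.na(h2$height_nm[1]))
})

test_that("two-class height splitting recovers the 0.3/0.6 nm classes", {
  cl <- classify_height_classes(c(rep(0.3, 50), rep(0.6, 50)), k = 2L)
  expect_equal(cl$k, 2L)
  expect_equal(cl$means, c(0.3, 0.6))
  expect_equal(cl$delta, 0.3)
  # all identical values: one class
  cl1 <- classify_height_classes(rep(0.45, 20), k = 2L)
  expect_equal(cl1$k, 1L)
  # overlapping classes collapse to one
  set.seed(9)
  cl2 <- classify_height_classes(rnorm(200, 0.45, 0.2), k = 2L)
  expect_equal(cl2$k, 1L)
  expect_error(classify_height_classes(c(0.3, 0.6, 0.4), k = 2L), "2k")
})

test_that("mixture means are recovered within 0.03 nm on simulated classes", {
  set.seed(101)
  h <- c(rnorm(100, 0.3, 0.05), rnorm(100, 0.6, 0.05))
  cl <- classify_height_classes(h, k = 2L)
  expect_equal(cl$k, 2L)
  expect_lt(abs(cl$means[1] - 0.3), 0.03)
  expect_lt(abs(cl$means[2] - 0.6), 0.03)
})

test_that("radial distances: exact construction, C4 equality, rotation invariance", {
  px <- 0.35
  n <- 41
  xs <- (seq_len(n) - (n + 1) / 2) * px
  mk <- function(r0, az0) {
    m <- matrix(0, n, n)
    for (az in az0 + c(0, 90, 180, 270)) {
      cx <- r0 * cos(az * pi / 180); cy <- r0 * sin(az * pi / 180)
      m <- pmax(m, outer(xs, xs, function(y, x)
        4.5 * exp(-((x - cx)^2 + (y - cy)^2) / (2 * 0.8^2))))
    }
    m
  }
  m <- mk(3.0, 45)
  rd <- radial_distances(m, pixel_size = px)
  expect_true(rd$complete)
  expect_equal(rd$mean, 3.0, tolerance = 0.05)
  expect_lt(max(abs(rd$distances - rd$mean)), 0.05)    # C4: all equal
  # rotation invariance of the mean radius (within 2%)
  rd2 <- radial_distances(rotate_image(m, 30), pixel_size = px)
  expect_lt(abs(rd2$mean - rd$mean) / rd$mean, 0.02)
})

test_that("activated and resting CNBD presets differ by ~0.4 nm in radial distance", {
  set.seed(71)
  aa <- hsafm:::averaged_footprint_map(sthk_footprint("intracellular", "activated"), 0.35)
  ar <- hsafm:::averaged_footprint_map(sthk_footprint("intracellular", "resting"), 0.35)
  ra <- radial_distances(symmetrize(aa, 4L))
  rr <- radial_distances(symmetrize(ar, 4L))
  expect_equal(ra$mean - rr$mean, 0.4, tolerance = 0.1)
})

test_that("height measurements are invariant to an added plane (pipeline property)", {
  fr <- crystal_frame("activated", "intracellular", 4L, scan = quiet_scan())
  m <- unclass(fr)
  x <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m))
  y <- matrix(rep(seq_len(nrow(m)), times = ncol(m)), nrow(m))
  tilted <- topograph(m + 1.5 + 0.01 * x - 0.02 * y, attr(fr, "pixel_size"))
  sites <- attr(fr, "sites")
  h0 <- molecule_heights(plane_flatten(fr), sites)
  h1 <- molecule_heights(plane_flatten(tilted), sites)
  expect_equal(h0$height_nm, h1$height_nm, tolerance = 0.02)
})
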