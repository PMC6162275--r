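test_that("rendering composes protrusions by max over the membrane level", {
  # empty lattice (patch mask excludes everything except one molecule) and
  # single-feature maximum
  fp <- channel_footprint(data.frame(dx = 0, dy = 0, height = 4.6, radius = 1.5,
                                     shape = "cap"), "intracellular")
  lat <- lattice_spec(10, basis = data.frame(fx = 0, fy = 0, rot = 0, dz = 0,
                                             footprint = "f"), extent = 1L)
  # margin chosen so the apex lands exactly on a pixel centre
  t <- render_surface(lat, stats::setNames(list(fp), "f"), pixel_size = 0.4,
                      margin = 8.2)
  expect_equal(max(t), 4.6, tolerance = 1e-9)
  site <- attr(t, "sites")
  pk <- arrayInd(which.max(unclass(t)), dim(t))
  expect_lt(abs((pk[2] - 0.5) * 0.4 - site$x), 1e-9)
  expect_lt(abs((pk[1] - 0.5) * 0.4 - site$y), 1e-9)
  expect_true(all(unclass(t) >= 0))
})

test_that("an unresolvable footprint id is a configuration error", {
  lat <- lattice_spec(10, basis = data.frame(fx = 0, fy = 0, rot = 0, dz = 0,
                                             footprint = "missing"), extent = 1L)
  fp <- sthk_footprint("intracellular", "activated")
  expect_error(render_surface(lat, stats::setNames(list(fp), "other"), 0.35),
               "unresolvable")
})

test_that("a C4 footprint rendered alone is invariant under 90-degree rotation", {
  fp <- sthk_footprint("intracellular", "resting")
  t <- render_footprint(fp, 0.3, size_nm = 12)
  m <- unclass(t)
  expect_lt(max(abs(m - rotate_image(m, 90))), 1e-9)
})

test_that("the resting crystal's autocorrelation peaks at the 8.1 nm lattice vectors", {
  t <- crystal_frame("resting", "intracellular", extent = 6L,
                     scan = quiet_scan())
  m <- unclass(t)
  px <- attr(t, "pixel_size")
  k <- round(8.1 / px)
  # brute-force autocorrelation oracle: lattice displacements correlate far
  # above a generic incommensurate displacement
  on_peak <- brute_autocorr_at(m, k, 0L)
  off_peak <- brute_autocorr_at(m, round(0.62 * k), round(0.21 * k))
  expect_gt(on_peak, 0.35)
  expect_gt(on_peak, off_peak + 0.2)
  expect_gt(brute_autocorr_at(m, 0L, k), 0.35)
})

test_that("tip dilation matches the brute-force oracle and is extensive", {
  px <- 0.5
  set.seed(11)
  m <- matrix(0, 21, 21)
  m[11, 11] <- 3          # delta spike
  m[4, 16] <- 1.2
  m <- m + matrix(runif(441, 0, 0.1), 21)
  t <- topograph(m, px)
  d <- tip_dilate(t, tip_model(2))
  expect_equal(unclass(d), brute_dilate(m, 2, px), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(unclass(d) >= m))                      # extensivity
  expect_equal(max(d), max(m))                           # apex preserved
  # identity cases
  expect_equal(unclass(tip_dilate(t, tip_model(0))), m, ignore_attr = TRUE)
  expect_message(tip_dilate(t, tip_model(0.1)), "resolution")
})

test_that("tip dilation is monotone and commutes with adding a constant", {
  set.seed(2)
  a <- matrix(runif(400, 0, 2), 20)
  b <- a + matrix(runif(400, 0, 1), 20)
  ta <- topograph(a, 0.5); tb <- topograph(b, 0.5)
  tip <- tip_model(1.5)
  expect_true(all(unclass(tip_dilate(tb, tip)) >= unclass(tip_dilate(ta, tip))))
  shifted <- tip_dilate(topograph(a + 5, 0.5), tip)
  expect_equal(unclass(shifted), unclass(tip_dilate(ta, tip)) + 5,
               tolerance = 1e-12)
})

test_that("scan artifacts: identity at zero noise, calibrated noise sd, seeded determinism", {
  base <- matrix(rnorm(300 * 300, 1, 0.3), 300)
  mv <- topo_movie(list(base), 0.35)
  out0 <- apply_scan_artifacts(mv, quiet_scan())
  expect_equal(out0$frames[[1]], base)
  sc <- scan_params(pixel_noise_sd = 0.05, line_offset_sd = 0, seed = 7L)
  out <- apply_scan_artifacts(mv, sc)
  noise_sd <- sd(out$frames[[1]] - base)
  expect_lt(abs(noise_sd - 0.05) / 0.05, 0.05)   # law of large numbers, 300x300
  out2 <- apply_scan_artifacts(mv, sc)
  expect_identical(out$frames, out2$frames)      # seeded determinism
})

test_that("injected drift displaces frames by the prescribed amount", {
  t <- crystal_frame("resting", "intracellular", extent = 5L, scan = quiet_scan())
  base <- unclass(t)
  mv <- topo_movie(rep(list(base), 10), attr(t, "pixel_size"))
  sc <- scan_params(pixel_size = attr(t, "pixel_size"), pixel_noise_sd = 0.02,
                    line_offset_sd = 0, drift_velocity = c(0.5, 0), seed = 3L)
  out <- apply_scan_artifacts(mv, sc)
  px <- out$pixel_size
  sh <- brute_shift(out$frames[[1]], out$frames[[10]],
                    max_shift = ceiling(6 / px))
  expect_equal(sh[1] * px, 4.5, tolerance = px)  # 9 frames at 0.5 nm/frame
  expect_equal(sh[2], 0)
  expect_equal(out$truth$drift_nm$dx[10], 4.5)
})

test_that("simulate_movie: rate zero freezes states; border nucleation starts at the patch border", {
  scene <- transition_scene(extent = 3L, patch_radius = 20)
  scan <- scan_params(seed = 5L)
  frozen <- simulate_movie(scene, scan, n_frames = 3,
                           transition = list(model = domino_model(0), from = "activated",
                                             to = "resting", seed = 1L))
  expect_true(all(frozen$truth$states == "activated"))
  mv <- simulate_movie(scene, scan, n_frames = 12,
                       transition = list(model = domino_model(0.08, 3), from = "activated",
                                         to = "resting", seed = 2L))
  g <- site_graph(mv$truth$sites)
  tt <- mv$truth$transition_times
  first <- order(tt)[seq_len(3)]
  expect_true(all(g$border[first]))
})

test_that("a completed transition to the resting preset shows the 8.1 nm lattice", {
  scene <- transition_scene(extent = 3L, patch_radius = 20)
  final <- list(lattice = sthk_lattice("resting", extent = 5L),
                footprints = list(resting = sthk_footprint("intracellular", "resting")))
  scan <- scan_params(seed = 9L)
  mv <- simulate_movie(scene, scan, n_frames = 4,
                       transition = list(model = domino_model(5, 10), from = "activated",
                                         to = "resting", seed = 3L),
                       final_scene = final)
  expect_true(all(is.finite(mv$truth$transition_times)))
  lat <- detect_lattice(plane_flatten(movie_frame(mv, 4)))
  expect_true(lat$found)
  expect_equal(lat$len_a, 8.1, tolerance = 0.03)
})

test_that("scene files round-trip through read_scene", {
  path <- file.path(tempdir(), "scene.yml")
  writeLines(c("lattice:", "  preset: activated", "  extent: 4",
               "footprint:", "  face: intracellular",
               "tip:", "  radius: 1.5",
               "scan:", "  pixel_size: 0.4", "  seed: 12"), path)
  sc <- read_scene(path)
  expect_equal(sc$lattice$a, 11.6)
  expect_equal(sc$lattice$extent, 4L)
  expect_equal(sc$tip$radius, 1.5)
  expect_equal(sc$scan$pixel_size, 0.4)
  expect_error(read_scene(file.path(tempdir(), "absent.yml")), "not found")
  unlink(path)
})
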