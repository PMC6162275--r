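test_that("lattice detection recovers both packing polymorphs", {
  act <- detect_lattice(crystal_frame("activated", "intracellular", 6L))
  expect_true(act$found)
  expect_lt(abs(act$len_a - 11.6), 0.2)
  expect_lt(abs(act$len_b - 11.6), 0.2)
  expect_lt(abs(act$gamma - 90), 2)
  expect_equal(act$n_basis, 2L)
  # the enumerated site grid tracks the ground-truth molecule centres to
  # within the protrusion-ring scale
  truth <- attr(crystal_frame("activated", "intracellular", 6L), "sites")
  dmin <- vapply(seq_len(nrow(act$sites)), function(i)
    min(sqrt((truth$x - act$sites$x[i])^2 + (truth$y - act$sites$y[i])^2)),
    numeric(1))
  expect_lt(median(dmin), 2.5)
  res <- detect_lattice(crystal_frame("resting", "intracellular", 8L, seed = 13L))
  expect_true(res$found)
  expect_lt(abs(res$len_a - 8.1), 0.2)
  expect_lt(abs(res$len_b - 8.1), 0.2)
  expect_lt(abs(res$gamma - 90), 2)
  ext <- detect_lattice(crystal_frame("activated", "extracellular", 6L, seed = 14L),
                        n_basis = 2L)
  expect_lt(abs(pmin(ext$len_a, ext$len_b) - 11.6), 0.4)
  expect_equal(ext$n_basis, 2L)
  expect_equal(sort(unique(ext$sites$basis)), 1:2)
})

test_that("pure noise yields a 'no lattice' result, not an error", {
  set.seed(21)
  t <- topograph(matrix(rnorm(200 * 200, 0, 0.05), 200), 0.35)
  lat <- detect_lattice(t)
  expect_false(lat$found)
})

test_that("lattice detection is equivariant under exact quarter-turn rotation", {
  t <- crystal_frame("activated", "intracellular", 6L)
  lat <- detect_lattice(t)
  rt <- topograph(rotate_image(unclass(t), 90), attr(t, "pixel_size"))
  lat90 <- detect_lattice(rt)
  expect_true(lat90$found)
  # lengths unchanged; the vector angle set rotates with the image
  expect_equal(sort(c(lat90$len_a, lat90$len_b)), sort(c(lat$len_a, lat$len_b)),
               tolerance = 0.05)
  ang90 <- function(v) (atan2(v[2], v[1]) * 180 / pi) %% 90
  expect_equal(sort(c(ang90(lat90$a), ang90(lat90$b))),
               sort(c(ang90(lat$a), ang90(lat$b))), tolerance = 1)
})

test_that("particle extraction counts interior sites and flags the border", {
  m <- matrix(0, 100, 100)
  t <- topograph(m, 1)
  sites <- expand.grid(x = seq(10, 90, by = 20), y = seq(10, 90, by = 20))
  # 5x5 grid, 20-unit spacing; a 22-px window clips the outer ring
  st <- extract_particles(t, sites, window_nm = 22)
  expect_length(st$particles, 9L)
  expect_equal(sum(st$sites$interior), 9L)
  # empty site table -> empty stack
  st0 <- extract_particles(t, sites[0, ], window_nm = 22)
  expect_length(st0$particles, 0L)
  expect_error(extract_particles(t, sites, window_nm = 200), "larger")
})

test_that("correlation averaging: identity on identical particles, noise reduction, jitter removal", {
  fp <- sthk_footprint("intracellular", "activated")
  motif <- unclass(render_footprint(fp, 0.35, size_nm = 12))
  n <- 100L
  stack <- structure(list(particles = rep(list(motif), 5), window_px = nrow(motif),
                          sites = data.frame(site_id = 1:5), idx = 1:5,
                          pixel_size = 0.35,
                          alignment = data.frame(dx = numeric(5), dy = numeric(5))),
                     class = "particle_stack")
  avg <- correlation_average(stack, n_iter = 1L)
  expect_equal(avg$mean, motif, tolerance = 1e-9)
  expect_equal(avg$n, 5L)
  set.seed(33)
  noisy <- lapply(seq_len(n), function(i)
    motif + matrix(rnorm(length(motif), 0, 0.1), nrow(motif)))
  stack$particles <- noisy
  stack$sites <- data.frame(site_id = seq_len(n)); stack$idx <- seq_len(n)
  stack$alignment <- data.frame(dx = numeric(n), dy = numeric(n))
  avgn <- correlation_average(stack, n_iter = 2L)
  expect_lte(sd(avgn$mean - motif), 0.015)       # ~ sd/sqrt(n) with alignment slack
  # known +-2 px integer jitter is removed (asymmetric motif: a single
  # off-centre bump, so the aligned peak position is unambiguous)
  n_px <- nrow(motif)
  xs <- seq_len(n_px) - n_px / 2
  bump <- outer(xs, xs, function(y, x) 3 * exp(-((x - 5)^2 + (y + 3)^2) / (2 * 2^2)))
  set.seed(34)
  jit <- lapply(seq_len(40), function(i) {
    dx <- sample(-2:2, 1); dy <- sample(-2:2, 1)
    fourier_shift(bump, dx, dy) + matrix(rnorm(length(bump), 0, 0.03), n_px)
  })
  stack$particles <- jit
  stack$sites <- data.frame(site_id = 1:40); stack$idx <- 1:40
  stack$alignment <- data.frame(dx = numeric(40), dy = numeric(40))
  avgj <- correlation_average(stack, n_iter = 3L)
  pk_true <- arrayInd(which.max(bump), dim(bump))
  pk_avg <- arrayInd(which.max(avgj$mean), dim(avgj$mean))
  expect_lt(sqrt(sum((pk_true - pk_avg)^2)), 1.01)
  expect_lt(sd(avgj$mean - bump), 0.03)
})

test_that("per-pixel sd of the average does not grow with more i.i.d. copies", {
  fp <- sthk_footprint("intracellular", "resting")
  motif <- unclass(render_footprint(fp, 0.4, size_nm = 10))
  set.seed(55)
  mk <- function(n) {
    parts <- lapply(seq_len(n), function(i)
      motif + matrix(rnorm(length(motif), 0, 0.08), nrow(motif)))
    structure(list(particles = parts, window_px = nrow(motif),
                   sites = data.frame(site_id = seq_len(n)), idx = seq_len(n),
                   pixel_size = 0.4,
                   alignment = data.frame(dx = numeric(n), dy = numeric(n))),
              class = "particle_stack")
  }
  a10 <- correlation_average(mk(10), n_iter = 1L)
  a80 <- correlation_average(mk(80), n_iter = 1L)
  err10 <- sd(a10$mean - motif)
  err80 <- sd(a80$mean - motif)
  expect_lt(err80, err10)
})

test_that("symmetrization: identity, exact C4, volume conservation, idempotence", {
  fp <- sthk_footprint("intracellular", "activated")
  m <- unclass(render_footprint(fp, 0.35, size_nm = 12))
  expect_equal(symmetrize(m, 1L), m)
  expect_lt(max(abs(symmetrize(m, 4L) - m)), 1e-9)   # C4 input unchanged
  # one off-centre bump: order 4 spreads it into four; volume conserved
  b <- matrix(0, 41, 41)
  xs <- ((1:41) - 21) * 0.5
  b <- outer(xs, xs, function(y, x) 2 * exp(-((x - 4)^2 + y^2) / (2 * 0.8^2)))
  s4 <- symmetrize(b, 4L)
  expect_lt(abs(sum(s4) - sum(b)) / sum(b), 1e-3)
  expect_equal(max(s4), max(b) / 4, tolerance = 0.01)
  expect_equal(symmetrize(s4, 4L), s4, tolerance = 1e-9)   # idempotent
  # non-quarter order on a centred motif conserves volume within 0.1%
  ctr <- outer(xs, xs, function(y, x) exp(-(x^2 + y^2) / (2 * 2^2)))
  s3 <- symmetrize(ctr, 3L)
  expect_lt(abs(sum(s3) - sum(ctr)) / sum(ctr), 1e-3)
})
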