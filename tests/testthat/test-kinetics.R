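test_that("site graphs encode adjacency and the patch border", {
  g <- grid_graph(5L, spacing = 8.2)
  expect_equal(g$n, 25L)
  expect_true(all(lengths(g$adj)[c(1, 5, 21, 25)] == 2L))   # corners
  inner <- which(!g$border)
  expect_length(inner, 9L)                                  # 3x3 interior
  expect_true(all(lengths(g$adj)[inner] == 4L))
  # adjacency is symmetric
  for (i in seq_len(g$n)) for (j in g$adj[[i]])
    expect_true(i %in% g$adj[[j]])
})

test_that("domino simulation: zero rate freezes; strong coupling propagates from the border inward", {
  g <- grid_graph(8L)
  expect_true(all(is.infinite(simulate_domino(domino_model(0), g, seed = 1)$times)))
  # c -> infinity: no interior site transitions before one of its
  # neighbours has already transitioned
  traj <- simulate_domino(domino_model(0.01, c = 1e6), g, seed = 2)
  times <- traj$times
  for (i in which(!g$border)) {
    nb_first <- min(times[g$adj[[i]]])
    expect_lt(nb_first, times[i])
  }
})

test_that("uncoupled waiting times are exponential with rate k0", {
  g <- grid_graph(32L)                  # 1024 independent sites
  k0 <- 0.02
  traj <- simulate_domino(domino_model(k0, c = 1, border_nucleated = FALSE),
                          g, seed = 3)
  expect_true(all(is.finite(traj$times)))
  ks <- stats::ks.test(traj$times, "pexp", rate = k0)
  expect_gt(ks$p.value, 0.01)
})

test_that("fraction curves and transition-time fits behave as closed forms predict", {
  # trivial extremes
  tr0 <- list(times = rep(Inf, 10), order = integer(0))
  class(tr0) <- "state_trajectory"
  f0 <- fraction_transitioned(tr0, times_s = 0:5)
  expect_true(all(f0$fraction == 0))
  tr1 <- list(times = rep(0, 10), order = 1:10)
  class(tr1) <- "state_trajectory"
  expect_true(all(fraction_transitioned(tr1, times_s = 0:5)$fraction == 1))
  # step at t = 150 -> t50 = 150
  step <- data.frame(time_s = c(0, 149, 150, 300),
                     fraction = c(0, 0, 1, 1))
  expect_equal(fit_transition_time(step)$t50, 149.5, tolerance = 0.51)
  # linear ramp over [0, 100]: t50 = 50, rise = 80
  ramp <- data.frame(time_s = 0:100, fraction = seq(0, 1, length.out = 101))
  ft <- fit_transition_time(ramp)
  expect_equal(ft$t50, 50)
  expect_equal(ft$rise, 80)
  # sigmoid with known midpoint, frame-sampled: t50 within one interval
  tt <- seq(0, 300, by = 1)
  sig <- data.frame(time_s = tt, fraction = 1 / (1 + exp(-(tt - 150) / 12)))
  expect_lt(abs(fit_transition_time(sig)$t50 - 150), 1)
  # incomplete transition flagged
  part <- data.frame(time_s = 0:10, fraction = seq(0, 0.4, length.out = 11))
  expect_false(fit_transition_time(part)$complete)
})

test_that("a simulated domino run yields a monotone curve reaching 1, invariant to relabeling", {
  g <- grid_graph(10L)
  traj <- simulate_domino(domino_model(0.05, 3), g, seed = 7)
  ts <- seq(0, max(traj$times) + 1, by = 1)
  cv <- fraction_transitioned(traj, times_s = ts)
  expect_true(all(diff(cv$fraction) >= 0))
  expect_equal(cv$fraction[length(ts)], 1)
  # site relabeling leaves the curve unchanged
  perm <- sample(g$n)
  trp <- traj; trp$times <- traj$times[perm]
  expect_equal(fraction_transitioned(trp, times_s = ts)$fraction, cv$fraction)
  # t50 shifts with the time axis
  f1 <- fit_transition_time(cv)
  cv2 <- cv; cv2$time_s <- cv$time_s + 37
  expect_equal(fit_transition_time(cv2)$t50, f1$t50 + 37)
})

test_that("neighbour-count hazard analysis recovers homogeneous and coupled rates", {
  # homogeneous truth: all buckets agree within sampling error
  g <- grid_graph(24L)
  traj <- simulate_domino(domino_model(0.02, c = 1, border_nucleated = FALSE),
                          g, seed = 11)
  nr <- neighbor_rate_analysis(traj)
  big <- nr[nr$exposure_s > 0.2 * sum(nr$exposure_s), ]
  expect_true(all(abs(big$hazard - 0.02) / 0.02 < 0.3))
  # coupled truth c = 3: hazard ratio 1-neighbour vs 0-neighbour ~ 3
  g2 <- grid_graph(21L)                 # 441 >= 400 sites
  traj2 <- simulate_domino(domino_model(0.004, c = 3, border_nucleated = FALSE),
                           g2, seed = 12)
  nr2 <- neighbor_rate_analysis(traj2)
  h0 <- nr2$hazard[nr2$neighbours == 0]
  h1 <- nr2$hazard[nr2$neighbours == 1]
  expect_lt(abs(h1 / h0 - 3) / 3, 0.3)
  # no events -> empty table
  nr0 <- neighbor_rate_analysis(structure(list(times = rep(Inf, 4), order = integer(0),
                                               graph = grid_graph(2L)),
                                          class = "state_trajectory"))
  expect_equal(nrow(nr0), 0L)
})

test_that("state classification recovers the generator's trajectory through the full pipeline", {
  scene <- transition_scene(extent = 4L, patch_radius = 26)
  scan <- scan_params(seed = 31L)
  mv <- simulate_movie(scene, scan, n_frames = 16,
                       transition = list(model = domino_model(0.06, 3),
                                         from = "activated", to = "resting",
                                         seed = 32L))
  fl <- flatten_movie(mv)
  reg <- register_movie(fl, estimate_drift(fl))
  st <- classify_states(reg, mv$truth$sites)
  truth <- ifelse(mv$truth$states == "resting", "resting", "activated")
  resolved <- st != "unresolved"
  expect_gt(mean(resolved), 0.95)
  expect_gte(mean((st == truth)[resolved]), 0.98)
  # an all-activated scene classifies 100% activated
  mv0 <- simulate_movie(scene, scan, n_frames = 3)
  st0 <- classify_states(flatten_movie(mv0), mv0$truth$sites)
  expect_true(all(st0 == "activated"))
})

test_that("the default domino preset is tuned to the crystal transition timescale", {
  traj <- simulate_domino(sthk_domino_model(), grid_graph(20L), seed = 5)
  ts <- seq(0, max(traj$times) + 1, by = 1)
  tf <- fit_transition_time(fraction_transitioned(traj, times_s = ts))
  expect_gt(tf$t50, 110)
  expect_lt(tf$t50, 190)
  # border-first ordering under the preset
  g <- grid_graph(20L)
  first <- order(traj$times)[1:10]
  expect_true(all(g$border[first]))
})
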