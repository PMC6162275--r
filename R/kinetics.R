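#' Site adjacency graph of a crystal patch
#'
#' Neighbours are sites closer than `cutoff` (default 1.3x the smallest
#' inter-site distance). Border sites are those with fewer than 4
#' neighbours — the molecules at the crystal patch edge that are held by
#' only 2–3 lattice contacts.
#'
#' @param sites data.frame with `x`, `y` (nm).
#' @param cutoff neighbour distance cutoff, nm.
#' @return `site_graph` list: `adj` (list of neighbour indices), `border`
#'   (logical), `n`.
#' @export
site_graph <- function(sites, cutoff = NULL) {
  n <- nrow(sites)
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  diag(d) <- Inf
  if (is.null(cutoff)) cutoff <- 1.3 * min(d)
  adj <- lapply(seq_len(n), function(i) which(d[i, ] <= cutoff))
  deg <- lengths(adj)
  structure(list(adj = adj, border = deg < 4L, n = n), class = "site_graph")
}

#' Regular square-grid site graph
#'
#' Convenience constructor for kinetics-only simulations (no imaging):
#' an `nx` by `ny` grid of sites with 4-neighbour adjacency.
#'
#' @param nx,ny grid dimensions.
#' @param spacing site spacing in nm.
#' @export
grid_graph <- function(nx, ny = nx, spacing = 8.2) {
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  sites <- data.frame(site_id = seq_len(nrow(g)),
                      x = g$i * spacing, y = g$j * spacing)
  site_graph(sites, cutoff = 1.3 * spacing)
}

#' Border-nucleated domino transition model
#'
#' Continuous-time Markov model of the conformational wave through the
#' crystal: each untransitioned site has hazard `k0 * c^m`, with `m` its
#' number of already-transitioned neighbours. With `border_nucleated =
#' TRUE` (the default) interior sites cannot transition spontaneously —
#' their hazard is zero until at least one neighbour has transitioned —
#' so the wave necessarily starts at the patch border, where the lattice
#' constraint is weakest.
#'
#' @param k0 base transition rate per site, 1/s.
#' @param c neighbour coupling factor (rate multiplier per transitioned
#'   neighbour, >= 0).
#' @param border_nucleated see above.
#' @export
domino_model <- function(k0, c = 3, border_nucleated = TRUE) {
  stopifnot(k0 >= 0, c >= 0)
  structure(list(k0 = k0, c = c, border_nucleated = border_nucleated),
            class = "domino_model")
}

#' Simulate the domino transition (exact event-driven scheme)
#'
#' Gillespie simulation of the irreversible transition over a site graph:
#' hazards are recomputed after every event, waiting times are exponential
#' in the total hazard, and the transitioning site is drawn proportionally
#' to its hazard. Reproducible given `seed`.
#'
#' @param model a [domino_model()].
#' @param graph a [site_graph()].
#' @param t_max simulate events up to this time (s); later sites keep
#'   `Inf`.
#' @param seed RNG seed (`NULL` = leave RNG state alone).
#' @return `state_trajectory` list: `times` (per-site transition time, s,
#'   `Inf` if none), `order` (site indices in event order), `graph`.
#' @export
simulate_domino <- function(model, graph, t_max = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n
  done <- logical(n)
  m_nb <- integer(n)            # transitioned-neighbour counts
  times <- rep(Inf, n)
  ord <- integer(0)
  t <- 0
  repeat {
    rate <- ifelse(done, 0, model$k0 * model$c^m_nb)
    if (model$border_nucleated)
      rate[!graph$border & m_nb == 0L & !done] <- 0
    R <- sum(rate)
    if (R <= 0) break
    t <- t + stats::rexp(1L, R)
    if (t > t_max) break
    i <- sample.int(n, 1L, prob = rate)
    done[i] <- TRUE
    times[i] <- t
    ord <- c(ord, i)
    for (j in graph$adj[[i]]) m_nb[j] <- m_nb[j] + 1L
  }
  structure(list(times = times, order = ord, graph = graph),
            class = "state_trajectory")
}

#' Classify per-site conformational states over a movie
#'
#' Per frame and site, the peak height (top-k mean above the membrane
#' reference of that frame, in a circular site window) is compared with the
#' midpoint between the heights of the two states; the resting state
#' protrudes higher. By default the two state levels are calibrated from
#' the data: the pooled per-site heights (packing z-offsets from an
#' optional `dz` site column subtracted) are split into two classes and
#' their means used as templates, which absorbs the systematic measurement
#' biases (pixel sampling, tip dilation, membrane referencing) common to
#' both states; explicit `h_active`/`h_resting` override this. A
#' hysteresis band around the midpoint suppresses frame-to-frame flicker:
#' a site only switches label when its height crosses the midpoint by more
#' than `hysteresis`. Sites whose window clips the frame or falls in the
#' invalid registration margin are `"unresolved"`.
#'
#' @param movie registered `topo_movie` (a `$valid` region recorded by
#'   [register_movie()] is respected).
#' @param sites site table (`x`, `y` in nm; optional `dz`).
#' @param h_active,h_resting optional template peak heights of the two
#'   states, nm; `NULL` = calibrate from the pooled height histogram.
#' @param hysteresis nm.
#' @param window_nm site window (disk diameter) for the height measurement.
#' @return character matrix frames x sites with values `"activated"`,
#'   `"resting"`, `"unresolved"`.
#' @export
classify_states <- function(movie, sites, h_active = NULL, h_resting = NULL,
                            hysteresis = 0.1, window_nm = 7) {
  nfr <- n_frames(movie)
  n <- nrow(sites)
  dz <- if ("dz" %in% names(sites)) sites$dz else rep(0, n)
  px <- movie$pixel_size
  hw <- window_nm / 2
  H <- matrix(NA_real_, nfr, n)
  for (k in seq_len(nfr)) {
    tb <- molecule_heights(movie_frame(movie, k), sites, window_nm = window_nm,
                           circular = TRUE)
    h <- tb$height_nm
    h[!tb$interior] <- NA
    if (!is.null(movie$valid)) {
      v <- movie$valid[k, ]
      bad <- !(sites$x - hw >= (v$c0 - 1) * px & sites$x + hw <= v$c1 * px &
                 sites$y - hw >= (v$r0 - 1) * px & sites$y + hw <= v$r1 * px)
      h[bad] <- NA
    }
    H[k, ] <- h
  }
  Hc <- sweep(H, 2L, dz)   # remove packing offsets before pooling
  if (is.null(h_active) || is.null(h_resting)) {
    cl <- classify_height_classes(as.vector(Hc), k = 2L)
    if (cl$k == 2L) {
      h_active <- cl$means[1L]; h_resting <- cl$means[2L]
    } else {
      # single state present: calibration impossible, fall back to the
      # preset template heights (activated 4.3/4.6, resting 5.05)
      h_active <- 4.45; h_resting <- 5.05
    }
  }
  mid <- (h_active + h_resting) / 2
  out <- matrix("unresolved", nfr, n)
  for (s in seq_len(n)) {
    prev <- NA_character_
    for (k in seq_len(nfr)) {
      h <- Hc[k, s]
      if (is.na(h)) { prev <- NA_character_; next }
      lab <- if (is.na(prev)) {
        if (h > mid) "resting" else "activated"
      } else if (prev == "activated" && h > mid + hysteresis) "resting"
      else if (prev == "resting" && h < mid - hysteresis) "activated"
      else prev
      out[k, s] <- lab
      prev <- lab
    }
  }
  out
}

#' Fraction of sites in the target state per frame
#'
#' @param states character matrix (frames x sites) from [classify_states()],
#'   or a `state_trajectory` (evaluated at `times_s`).
#' @param target state counted as transitioned.
#' @param times_s frame timestamps (required for a `state_trajectory`).
#' @return data.frame `time_s`, `fraction` (of resolved sites).
#' @export
fraction_transitioned <- function(states, target = "resting", times_s = NULL) {
  if (inherits(states, "state_trajectory")) {
    stopifnot(!is.null(times_s))
    fr <- vapply(times_s, function(t0) mean(states$times <= t0), numeric(1L))
    return(data.frame(time_s = times_s, fraction = fr))
  }
  stopifnot(is.matrix(states))
  if (is.null(times_s)) times_s <- seq_len(nrow(states)) - 1
  fr <- apply(states, 1L, function(row) {
    res <- row != "unresolved"
    if (!any(res)) NA_real_ else mean(row[res] == target)
  })
  data.frame(time_s = times_s, fraction = fr)
}

#' Transition half-time and 10–90% rise time
#'
#' Model-free summaries of a transition curve: `t50` is the first linear
#' interpolated crossing of 0.5, the rise time the span between the first
#' crossings of 0.1 and 0.9.
#'
#' @param series data.frame with `time_s`, `fraction` (from
#'   [fraction_transitioned()]).
#' @return list with `t50`, `t10`, `t90`, `rise`, `complete` (whether the
#'   curve spans the transition; otherwise values are NA and the result is
#'   flagged partial).
#' @export
fit_transition_time <- function(series) {
  t <- series$time_s; f <- series$fraction
  ok <- !is.na(f)
  t <- t[ok]; f <- f[ok]
  crossing <- function(level) {
    i <- which(f >= level)[1L]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(t[1L])
    t[i - 1L] + (level - f[i - 1L]) / (f[i] - f[i - 1L]) * (t[i] - t[i - 1L])
  }
  complete <- length(f) > 1L && f[1L] < 0.5 && f[length(f)] > 0.5
  if (!complete)
    return(list(t50 = NA_real_, t10 = NA_real_, t90 = NA_real_,
                rise = NA_real_, complete = FALSE))
  t50 <- crossing(0.5); t10 <- crossing(0.1); t90 <- crossing(0.9)
  list(t50 = t50, t10 = t10, t90 = t90, rise = t90 - t10, complete = TRUE)
}

#' Hazard versus transitioned-neighbour count
#'
#' Exposure-time estimator of the per-site transition hazard, stratified by
#' the number of already-transitioned neighbours at the time: for each
#' untransitioned interval of each site the current neighbour count defines
#' the bucket; hazard = events / total exposure time per bucket.
#'
#' @param traj a `state_trajectory` from [simulate_domino()].
#' @param t_end censoring time for sites that never transitioned; default
#'   is the last event time.
#' @return data.frame `neighbours`, `events`, `exposure_s`, `hazard`
#'   (absent buckets are simply not listed).
#' @export
neighbor_rate_analysis <- function(traj, t_end = NULL) {
  times <- traj$times
  g <- traj$graph
  fin <- is.finite(times)
  if (!any(fin))
    return(data.frame(neighbours = integer(), events = integer(),
                      exposure_s = numeric(), hazard = numeric()))
  if (is.null(t_end)) t_end <- max(times[fin])
  ev <- integer(0); expo <- numeric(0)
  bucket <- function(m) as.character(m)
  acc_e <- new.env(parent = emptyenv())
  add <- function(m, dt, event) {
    key <- bucket(m)
    cur <- if (!is.null(acc_e[[key]])) acc_e[[key]] else c(0, 0)
    acc_e[[key]] <- cur + c(event, dt)
  }
  for (i in seq_len(g$n)) {
    ti <- min(times[i], t_end)
    if (ti <= 0) next
    nbt <- sort(times[g$adj[[i]]])
    nbt <- nbt[is.finite(nbt) & nbt < ti]
    bounds <- c(0, nbt, ti)
    for (s in seq_len(length(bounds) - 1L)) {
      dt <- bounds[s + 1L] - bounds[s]
      if (dt > 0) add(s - 1L, dt, event = (s == length(bounds) - 1L) &&
                        is.finite(times[i]) && times[i] <= t_end)
    }
  }
  keys <- ls(acc_e)
  out <- data.frame(neighbours = as.integer(keys),
                    events = vapply(keys, function(k) acc_e[[k]][1L], numeric(1L)),
                    exposure_s = vapply(keys, function(k) acc_e[[k]][2L], numeric(1L)))
  out <- out[order(out$neighbours), ]
  out$hazard <- out$events / out$exposure_s
  rownames(out) <- NULL
  out
}
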