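#' Two-state gating model
#'
#' Minimal C <-> O Markov scheme for a ligand-gated channel: opening rate
#' `k_open`, closing rate `k_close`, so the stationary open probability is
#' `k_open / (k_open + k_close)`. The defaults encode a channel with
#' Po = 0.25 at ~4 pA unitary current and enough gating cycles per 100 s
#' for a tight Po estimate.
#'
#' @param k_open,k_close transition rates, 1/s (>= 0, not both 0).
#' @param amplitude unitary current, pA (> 0).
#' @param n_channels independent channels in the bilayer.
#' @param noise_sd Gaussian current noise sd, pA.
#' @param sample_rate Hz.
#' @param filter_cutoff low-pass cutoff, Hz (`NULL` = no filter).
#' @export
gating_model <- function(k_open = 15, k_close = 45, amplitude = 4,
                         n_channels = 1L, noise_sd = 0.4,
                         sample_rate = 20000, filter_cutoff = 1000) {
  stopifnot(k_open >= 0, k_close >= 0, k_open + k_close > 0, amplitude > 0,
            n_channels >= 1L, noise_sd >= 0, sample_rate > 0)
  structure(list(k_open = k_open, k_close = k_close, amplitude = amplitude,
                 n_channels = as.integer(n_channels), noise_sd = noise_sd,
                 sample_rate = sample_rate, filter_cutoff = filter_cutoff),
            class = "gating_model")
}

#' Stationary open probability of a gating model
#' @param m a [gating_model()].
#' @export
stationary_po <- function(m) m$k_open / (m$k_open + m$k_close)

# One channel's open/closed level per sample: exact exponential dwell
# sampling, initial state drawn from the stationary distribution.
simulate_channel_levels <- function(m, n_samples, dt) {
  duration <- n_samples * dt
  po <- stationary_po(m)
  state <- stats::rbinom(1L, 1L, po)          # 1 = open
  t <- 0
  times <- numeric(0); states <- integer(0)
  while (t < duration) {
    times <- c(times, t); states <- c(states, state)
    rate <- if (state == 1L) m$k_close else m$k_open
    if (rate <= 0) break
    t <- t + stats::rexp(1L, rate)
    state <- 1L - state
  }
  idx <- findInterval((seq_len(n_samples) - 0.5) * dt, times)
  states[idx]
}

#' Simulate a multi-channel current recording
#'
#' Sums `n_channels` independent two-state chains (exact dwell sampling),
#' scales by the unitary amplitude, adds Gaussian noise and applies the
#' optional causal low-pass (2nd-order Butterworth). The ground-truth
#' summed level path is retained.
#'
#' @param m a [gating_model()].
#' @param duration trace length, s.
#' @param seed RNG seed (`NULL` = leave RNG state alone).
#' @return `current_trace` list: `current_pA`, `sample_rate`, `truth_levels`
#'   (summed open-channel count per sample), `model`.
#' @export
simulate_trace <- function(m, duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / m$sample_rate
  ns <- round(duration * m$sample_rate)
  levels <- integer(ns)
  for (ch in seq_len(m$n_channels))
    levels <- levels + simulate_channel_levels(m, ns, dt)
  cur <- levels * m$amplitude
  if (m$noise_sd > 0) cur <- cur + stats::rnorm(ns, 0, m$noise_sd)
  if (!is.null(m$filter_cutoff) && m$filter_cutoff < m$sample_rate / 2)
    cur <- lowpass(cur, m$filter_cutoff, m$sample_rate)
  structure(list(current_pA = cur, sample_rate = m$sample_rate,
                 truth_levels = levels, model = m),
            class = "current_trace")
}

lowpass <- function(x, cutoff, fs) {
  bf <- signal::butter(2L, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filter(bf, x))
}

#' Half-amplitude idealization
#'
#' Assigns each sample the conductance level `round(current / amplitude)`
#' clipped to `[0, n_channels]` — i.e. thresholds midway between unitary
#' levels — then merges events shorter than the dead time (default two
#' filter time constants, `2 / filter_cutoff`) into their longer
#' neighbour. Flagged unreliable when the amplitude does not exceed the
#' noise sd.
#'
#' @param trace a `current_trace` (or numeric vector with `sample_rate`).
#' @param amplitude unitary current, pA.
#' @param n_channels maximum level.
#' @param dead_time s; events shorter than this are absorbed.
#' @param sample_rate Hz, required if `trace` is a bare vector.
#' @return `idealized_trace` list: `events` (data.frame `level`,
#'   `start_s`, `duration_s`), `levels` (per sample), `sample_rate`,
#'   `reliable`.
#' @export
idealize <- function(trace, amplitude, n_channels = 1L, dead_time = NULL,
                     sample_rate = NULL) {
  if (inherits(trace, "current_trace")) {
    x <- trace$current_pA
    sample_rate <- trace$sample_rate
    if (is.null(dead_time) && !is.null(trace$model$filter_cutoff))
      dead_time <- 2 / trace$model$filter_cutoff
    noise_sd <- trace$model$noise_sd
  } else {
    x <- as.numeric(trace)
    stopifnot(!is.null(sample_rate))
    noise_sd <- 0
  }
  if (is.null(dead_time)) dead_time <- 0
  reliable <- amplitude > noise_sd
  lev <- pmin(pmax(round(x / amplitude), 0L), n_channels)
  dead_n <- floor(dead_time * sample_rate)
  if (dead_n >= 1L) {
    r <- rle(lev)
    vals <- r$values; lens <- r$lengths
    collapse <- function(vals, lens) {     # merge adjacent equal-valued runs
      j <- which(diff(vals) == 0)
      while (length(j)) {
        j1 <- j[1L]
        lens[j1] <- lens[j1] + lens[j1 + 1L]
        vals <- vals[-(j1 + 1L)]; lens <- lens[-(j1 + 1L)]
        j <- which(diff(vals) == 0)
      }
      list(vals = vals, lens = lens)
    }
    repeat {
      if (length(lens) <= 1L) break
      i <- which.min(lens)
      if (lens[i] >= dead_n) break
      # absorb the shortest run into its longer neighbour
      nb <- if (i == 1L) 2L
            else if (i == length(lens)) i - 1L
            else if (lens[i - 1L] >= lens[i + 1L]) i - 1L else i + 1L
      lens[nb] <- lens[nb] + lens[i]
      vals <- vals[-i]; lens <- lens[-i]
      cc <- collapse(vals, lens)
      vals <- cc$vals; lens <- cc$lens
    }
    lev <- rep.int(vals, lens)
  }
  r <- rle(lev)
  start <- (c(0L, cumsum(r$lengths)[-length(r$lengths)])) / sample_rate
  events <- data.frame(level = r$values, start_s = start,
                       duration_s = r$lengths / sample_rate)
  structure(list(events = events, levels = lev, sample_rate = sample_rate,
                 n_channels = as.integer(n_channels), reliable = reliable),
            class = "idealized_trace")
}

#' Time-weighted open probability from an idealized trace
#'
#' `Po = sum(level * duration) / (n_channels * total duration)`.
#'
#' @param ideal an `idealized_trace`.
#' @param n_channels channel count (defaults to the one recorded at
#'   idealization).
#' @export
estimate_po <- function(ideal, n_channels = NULL) {
  if (is.null(n_channels)) n_channels <- ideal$n_channels
  ev <- ideal$events
  sum(ev$level * ev$duration_s) / (n_channels * sum(ev$duration_s))
}

#' Count active channels in a recording
#'
#' The channel count is the largest observed (filtered) current divided by
#' the unitary amplitude, rounded — valid when the recording is long
#' enough that all channels open simultaneously at least once. The
#' probability of having observed the all-open level (given the estimated
#' per-channel Po and the number of idealized gating events) is returned
#' as a reliability score.
#'
#' @param trace a `current_trace`.
#' @param amplitude unitary current, pA.
#' @return list `n_channels`, `p_all_open_observed`.
#' @export
count_channels <- function(trace, amplitude) {
  x <- trace$current_pA
  n <- max(0L, round(max(x) / amplitude))
  p_obs <- NA_real_
  if (n >= 1L) {
    id <- idealize(trace, amplitude, n_channels = n)
    po <- estimate_po(id, n)
    n_events <- nrow(id$events)
    p_obs <- 1 - (1 - po^n)^n_events
  }
  list(n_channels = n, p_all_open_observed = p_obs)
}
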