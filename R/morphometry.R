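#' Membrane reference level
#'
#' Heights are reported "from the membrane": the reference level is the
#' lowest local mode of the height histogram (kernel density), on the
#' assumption that exposed lipid is the lowest flat level in the frame. If
#' the histogram has no distinct low mode (field of view entirely protein),
#' the 1st percentile is used with a warning.
#'
#' @param t a `topograph`.
#' @param min_prominence a mode must reach this fraction of the highest
#'   density peak to count.
#' @return membrane level in nm.
#' @export
membrane_reference <- function(t, min_prominence = 0.2) {
  z <- as.vector(unclass(t))
  d <- stats::density(z, n = 512)
  y <- d$y
  ismode <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1L], -Inf))
  ismode <- ismode[y[ismode] >= min_prominence * max(y)]
  if (length(ismode) == 0L) {
    warning("no distinct membrane mode; falling back to 1st percentile")
    return(stats::quantile(z, 0.01, names = FALSE))
  }
  d$x[ismode[1L]]
}

#' Height profile along a segment
#'
#' Samples heights along the segment `p0 -> p1` (bilinear interpolation),
#' averaged over `width_px` parallel lines perpendicular to the segment.
#'
#' @param t a `topograph`.
#' @param p0,p1 segment endpoints, c(x, y) in nm.
#' @param width_px number of perpendicular averaging lines (odd).
#' @param step_px sampling step along the segment, pixels.
#' @return data.frame with `dist_nm` and `height_nm`.
#' @export
height_profile <- function(t, p0, p1, width_px = 1L, step_px = 0.5) {
  px <- attr(t, "pixel_size")
  m <- unclass(t)
  v <- (p1 - p0) / px
  len <- sqrt(sum(v^2))
  if (len == 0) stop("zero-length segment", call. = FALSE)
  u <- v / len
  perp <- c(-u[2L], u[1L])
  s <- seq(0, len, by = step_px)
  offs <- seq_len(width_px) - (width_px + 1) / 2
  acc <- 0
  for (o in offs) {
    xs <- p0[1L] / px + 0.5 + s * u[1L] + o * perp[1L]
    ys <- p0[2L] / px + 0.5 + s * u[2L] + o * perp[2L]
    acc <- acc + bilinear_sample_vec(m, xs, ys)
  }
  data.frame(dist_nm = s * px, height_nm = acc / width_px)
}

bilinear_sample_vec <- function(m, xs, ys) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- pmin(pmax(floor(xs), 1), nc - 1)
  y0 <- pmin(pmax(floor(ys), 1), nr - 1)
  fx <- pmin(pmax(xs - x0, 0), 1); fy <- pmin(pmax(ys - y0, 0), 1)
  (1 - fy) * ((1 - fx) * m[cbind(y0, x0)] + fx * m[cbind(y0, x0 + 1)]) +
    fy * ((1 - fx) * m[cbind(y0 + 1, x0)] + fx * m[cbind(y0 + 1, x0 + 1)])
}

#' Per-molecule peak heights
#'
#' For each lattice site, the peak height is the mean of the `k` highest
#' pixels in the site window minus the membrane reference (top-k mean, not
#' the single maximum, for robustness against the ~0.05 nm pixel noise
#' floor). Sites whose window clips the frame edge are flagged and carry NA.
#'
#' @param t a `topograph`.
#' @param sites data.frame with `x`, `y` in nm (detected lattice sites or
#'   ground truth).
#' @param window_nm site window edge (or diameter, if circular), nm.
#' @param k number of top pixels averaged.
#' @param membrane membrane level in nm; computed by
#'   [membrane_reference()] when `NULL`.
#' @param circular restrict the window to the inscribed disk; avoids
#'   sampling a neighbouring molecule through the window corners.
#' @return `molecule_table` data.frame: `site_id`, `x`, `y`, `height_nm`,
#'   `interior`.
#' @export
molecule_heights <- function(t, sites, window_nm = 8, k = 5L, membrane = NULL,
                             circular = FALSE) {
  px <- attr(t, "pixel_size")
  m <- unclass(t)
  if (is.null(membrane)) membrane <- membrane_reference(t)
  w <- max(3L, ceiling(window_nm / px))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  keep <- if (circular) {
    d2 <- outer((-h:h)^2, (-h:h)^2, "+")
    as.vector(d2 <= h^2)
  } else rep(TRUE, w * w)
  rc <- cbind(round(sites$y / px + 0.5), round(sites$x / px + 0.5))
  n <- nrow(sites)
  out <- data.frame(site_id = if ("site_id" %in% names(sites)) sites$site_id else seq_len(n),
                    x = sites$x, y = sites$y, height_nm = NA_real_,
                    interior = FALSE)
  for (s in seq_len(n)) {
    r0 <- rc[s, 1L] - h; r1 <- rc[s, 1L] + h
    c0 <- rc[s, 2L] - h; c1 <- rc[s, 2L] + h
    if (r0 < 1L || c0 < 1L || r1 > nrow(m) || c1 > ncol(m)) next
    win <- as.vector(m[r0:r1, c0:c1])[keep]
    topk <- sort(win, decreasing = TRUE)[seq_len(min(k, length(win)))]
    out$height_nm[s] <- mean(topk) - membrane
    out$interior[s] <- TRUE
  }
  out
}

#' Split heights into k classes (1D Gaussian classing)
#'
#' k-means on the height values, initialized at the k evenly spaced
#' quantiles, followed by per-class Gaussian mean/sd. Two collapse rules
#' guard against spurious splits: adjacent class means closer than one
#' pooled sd are deemed inseparable, and (for k = 2) a Gaussian-mixture
#' BIC comparison must actually prefer two components over one — a
#' k-means split of a unimodal sample always looks "separated", so the
#' model comparison is what distinguishes the genuinely bimodal height
#' histograms of the alternating packing from plain measurement scatter.
#'
#' @param heights numeric vector (NA dropped).
#' @param k number of classes.
#' @return list with `k`, `means` (ascending), `sds`, `labels` (1 =
#'   lowest class; NA where input was NA) and `delta` (difference of
#'   adjacent class means; NULL when k = 1).
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_height_classes <- function(heights, k = 2L) {
  ok <- which(!is.na(heights))
  h <- heights[ok]
  if (length(h) < 2L * k) stop("need at least 2k observations", call. = FALSE)
  labels_full <- rep(NA_integer_, length(heights))
  if (length(unique(h)) < k) {
    labels_full[ok] <- 1L
    return(list(k = 1L, means = mean(h), sds = stats::sd(h),
                labels = labels_full, delta = NULL))
  }
  init <- stats::quantile(h, (seq_len(k) - 0.5) / k, names = FALSE)
  km <- suppressWarnings(stats::kmeans(h, centers = matrix(init, ncol = 1L)))
  ord <- order(km$centers)
  lab <- match(km$cluster, ord)
  means <- vapply(seq_len(k), function(i) mean(h[lab == i]), numeric(1L))
  sds <- vapply(seq_len(k), function(i) {
    v <- h[lab == i]; if (length(v) > 1L) stats::sd(v) else 0
  }, numeric(1L))
  # separability: adjacent means at least one pooled sd apart, and for
  # k = 2 the mixture model must beat a single Gaussian on BIC
  pooled <- sqrt(mean(sds^2))
  separable <- !(pooled > 0 && any(diff(means) < pooled))
  if (separable && k == 2L && pooled > 0) {
    mc <- tryCatch(Mclust(h, G = 1:2, verbose = FALSE),
                   error = function(e) NULL)
    if (!is.null(mc) && mc$G == 1L) separable <- FALSE
  }
  if (k > 1L && !separable) {
    labels_full[ok] <- 1L
    return(list(k = 1L, means = mean(h), sds = stats::sd(h),
                labels = labels_full, delta = NULL))
  }
  labels_full[ok] <- lab
  list(k = k, means = means, sds = sds, labels = labels_full,
       delta = diff(means))
}

#' Radial distances of protrusion peaks from the molecular axis
#'
#' The centre is the centre-of-mass of the thresholded map; the peaks are
#' the `n_peaks` highest local maxima respecting a minimum separation
#' (default a quarter of the map width, against double-counting one lobe),
#' subpixel-refined. Distances are peak-to-centre, in nm.
#'
#' @param map an `average_map` or matrix (one molecule, roughly centred).
#' @param n_peaks number of protrusions expected (4 for a tetramer).
#' @param min_sep_nm minimum peak separation; default 0.25 * map width.
#' @param pixel_size required if `map` is a plain matrix.
#' @param threshold_frac centre-of-mass threshold, fraction of max height.
#' @return list with `distances` (nm), `mean`, `sd`, `centre` (nm),
#'   `peaks` (nm coordinates), `complete` (found all n_peaks).
#' @export
radial_distances <- function(map, n_peaks = 4L, min_sep_nm = NULL,
                             pixel_size = NULL, threshold_frac = 0.5) {
  if (inherits(map, "average_map")) {
    m <- map$mean; px <- map$pixel_size
  } else {
    m <- unclass(map); px <- if (!is.null(pixel_size)) pixel_size else attr(map, "pixel_size")
  }
  stopifnot(!is.null(px))
  if (is.null(min_sep_nm)) min_sep_nm <- 0.25 * ncol(m) * px
  thr <- threshold_frac * max(m)
  w <- pmax(m - thr, 0)
  tot <- sum(w)
  cx <- sum(w * matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m))) / tot
  cy <- sum(w * matrix(rep(seq_len(nrow(m)), times = ncol(m)), nrow(m))) / tot
  pks <- local_maxima(m)
  sel <- list()
  for (q in seq_len(nrow(pks))) {
    p <- c(pks$col[q], pks$row[q])
    if (all(vapply(sel, function(s) sqrt(sum((s - p)^2)) * px >= min_sep_nm,
                   logical(1L)))) {
      sel[[length(sel) + 1L]] <- p
      if (length(sel) == n_peaks) break
    }
  }
  peaks <- do.call(rbind, lapply(sel, function(p) {
    r <- refine_peak(m, p[2L], p[1L])
    c(x = (r[["col"]] - cx) * px, y = (r[["row"]] - cy) * px)
  }))
  dist <- if (is.null(peaks)) numeric(0) else sqrt(rowSums(peaks^2))
  list(distances = dist, mean = mean(dist), sd = stats::sd(dist),
       centre = c(x = cx * px, y = cy * px), peaks = peaks,
       complete = length(dist) == n_peaks)
}
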