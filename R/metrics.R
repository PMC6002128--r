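#' Colony front position
#'
#' The outermost coordinate at which the density profile crosses
#' `threshold`, located by linear interpolation between grid nodes. For a
#' Cartesian profile spanning negative and positive x the outward (positive)
#' side is used by default.
#'
#' @param x grid coordinates (mm), increasing.
#' @param rho density profile (nonnegative).
#' @param threshold crossing level (normalized density units).
#' @return the front position (mm), or `NA` if the profile never exceeds
#'   the threshold.
#' @export
front_position <- function(x, rho, threshold = 0.1) {
  above <- rho >= threshold
  if (!any(above)) return(NA_real_)
  i <- max(which(above))
  if (i == length(x)) return(x[i])
  # interpolate between the last point above and the first below
  x[i] + (threshold - rho[i]) * (x[i + 1] - x[i]) / (rho[i + 1] - rho[i])
}

#' Colony front speed
#'
#' Least-squares slope of the front position against time over a window
#' (default 10-20 h, the interval over which expansion is steady).
#'
#' @param run a `pde_run` or a list with `x` and `snapshots`.
#' @param t_window time window in seconds, `c(lo, hi)`.
#' @param threshold front-detection threshold.
#' @return front speed in mm/h.
#' @export
front_speed <- function(run, t_window = c(10, 20) * 3600, threshold = 0.1) {
  tt <- vapply(run$snapshots, `[[`, numeric(1), "t")
  keep <- tt >= t_window[1] & tt <= t_window[2]
  pos <- vapply(run$snapshots[keep], function(s)
    front_position(run$x, s$rho, threshold), numeric(1))
  ok <- is.finite(pos)
  if (sum(ok) < 2) stop("front_speed: fewer than 2 valid front positions")
  stats::coef(stats::lm(pos[ok] ~ tt[keep][ok]))[[2]] * 3600
}

#' Detect stripe peaks in a density profile
#'
#' Interior local maxima with topographic prominence at least
#' `prominence_frac` of the global maximum. Prominence of a peak is its
#' height minus the highest of the two lowest points separating it from
#' higher terrain (or the profile edge) on each side. The outermost peak is
#' the moving colony front and can be excluded, leaving the established
#' stripes.
#'
#' @param x coordinates (mm), increasing.
#' @param rho density profile.
#' @param prominence_frac prominence threshold as a fraction of `max(rho)`.
#' @param exclude_front drop the outermost peak.
#' @return a data.frame with columns `x`, `height`, `prominence`, `index`,
#'   ordered by position. Zero rows if nothing qualifies.
#' @export
find_stripe_peaks <- function(x, rho, prominence_frac = 0.1,
                              exclude_front = TRUE) {
  n <- length(rho)
  empty <- data.frame(x = numeric(0), height = numeric(0),
                      prominence = numeric(0), index = integer(0))
  if (n < 3) return(empty)
  # local maxima, plateau-tolerant: strictly above the previous distinct
  # value and at least the next distinct value
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (rho[i] > rho[i - 1] && rho[i] >= rho[i + 1]) {
      # walk over a plateau to confirm a descent follows
      j <- i + 1
      while (j < n && rho[j] == rho[i]) j <- j + 1
      if (rho[j] < rho[i]) cand <- c(cand, i)
    }
  }
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) {
    hp <- rho[i]
    lmin <- hp
    j <- i - 1
    while (j >= 1 && rho[j] <= hp) { lmin <- min(lmin, rho[j]); j <- j - 1 }
    rmin <- hp
    j <- i + 1
    while (j <= n && rho[j] <= hp) { rmin <- min(rmin, rho[j]); j <- j + 1 }
    hp - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= prominence_frac * max(rho)
  peaks <- data.frame(x = x[cand[keep]], height = rho[cand[keep]],
                      prominence = prom[keep], index = cand[keep])
  if (exclude_front && nrow(peaks) > 0) {
    outer <- which.max(abs(peaks$x))
    peaks <- peaks[-outer, , drop = FALSE]
  }
  peaks[order(peaks$x), , drop = FALSE]
}

#' Stripe wavelength
#'
#' Mean distance between the maxima of successive high-density stripes
#' (interior peaks after excluding the moving front).
#'
#' @inheritParams find_stripe_peaks
#' @return wavelength in mm, or `NA` if fewer than two stripes exist.
#' @export
wavelength <- function(x, rho, prominence_frac = 0.1, exclude_front = TRUE) {
  pk <- find_stripe_peaks(x, rho, prominence_frac, exclude_front)
  if (nrow(pk) < 2) return(NA_real_)
  mean(diff(pk$x))
}

#' Height ratio and density ratio of the stripes
#'
#' For each complete stripe (an interior peak bracketed by density minima),
#' the height ratio is the following minimum `h2` divided by the peak
#' density `h1`; the density ratio is the geometry-weighted mean density
#' over the bracketing window relative to `h1`:
#' `int_B^C xi rho dxi / (h1 int_B^C xi dxi)` in the radial geometry
#' (unit weight in 1D), with `[B, C]` the successive minima around the
#' peak (one full wavelength). Values are averaged over complete stripes.
#'
#' @inheritParams find_stripe_peaks
#' @param radial use the radial weight `xi` in the integral.
#' @return a list with `height_ratio`, `density_ratio`, `n_stripes` and the
#'   per-stripe data.frame `stripes`.
#' @export
stripe_structure <- function(x, rho, prominence_frac = 0.1, radial = TRUE) {
  pk_all <- find_stripe_peaks(x, rho, prominence_frac, exclude_front = FALSE)
  pk <- find_stripe_peaks(x, rho, prominence_frac)
  if (nrow(pk) < 1)
    return(list(height_ratio = NA_real_, density_ratio = NA_real_,
                n_stripes = 0L, stripes = NULL))
  w <- if (radial) x else rep(1, length(x))
  rows <- lapply(seq_len(nrow(pk)), function(k) {
    i <- pk$index[k]
    # bracket the stripe by the deepest troughs separating it from the
    # neighbouring prominent peaks (robust to small shoulder ripples)
    left_pk <- pk_all$index[pk_all$index < i]
    right_pk <- pk_all$index[pk_all$index > i]
    lo <- if (length(left_pk)) max(left_pk) else 1L
    hi <- if (length(right_pk)) min(right_pk) else return(NULL)
    j <- lo + which.min(rho[lo:i]) - 1L
    l <- i + which.min(rho[i:hi]) - 1L
    if (j == i || l == i) return(NULL)
    h1 <- rho[i]; h2 <- rho[l]
    seg <- j:l
    num <- sum((w[seg] * rho[seg])[-1] + (w[seg] * rho[seg])[-length(seg)]) / 2
    den <- sum(w[seg][-1] + w[seg][-length(seg)]) / 2
    data.frame(x_peak = x[i], h1 = h1, h2 = h2,
               height_ratio = h2 / h1,
               density_ratio = num / (h1 * den),
               x_inner = x[j], x_outer = x[l])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(list(height_ratio = NA_real_, density_ratio = NA_real_,
                n_stripes = 0L, stripes = NULL))
  list(height_ratio = mean(rows$height_ratio),
       density_ratio = mean(rows$density_ratio),
       n_stripes = nrow(rows), stripes = rows)
}

#' Stripe ratios over an explicit window
#'
#' Height and density ratios over a user-given window `[B, C]` of a profile,
#' without peak detection: `h1` is the maximum and `h2` the minimum density
#' over the window, and the density ratio is the geometry-weighted mean
#' density relative to `h1`. Degenerate flat windows give both ratios 1.
#'
#' @param x coordinates (mm).
#' @param rho density profile.
#' @param window `c(B, C)` limits (mm).
#' @param radial use the radial weight `xi`.
#' @return a list with `h1`, `h2`, `height_ratio`, `density_ratio`.
#' @export
stripe_window_ratios <- function(x, rho, window, radial = TRUE) {
  seg <- which(x >= window[1] & x <= window[2])
  if (length(seg) < 2) stop("window contains fewer than 2 grid points")
  w <- if (radial) x[seg] else rep(1, length(seg))
  r <- rho[seg]
  h1 <- max(r); h2 <- min(r)
  num <- sum((w * r)[-1] + (w * r)[-length(seg)]) / 2
  den <- sum(w[-1] + w[-length(seg)]) / 2
  list(h1 = h1, h2 = h2, height_ratio = h2 / h1,
       density_ratio = num / (h1 * den))
}

#' Times at which successive stripes first appear
#'
#' Scans a snapshot series and records, for each interior stripe index k,
#' the first time the profile shows at least k interior peaks (prominence
#' threshold as in [find_stripe_peaks()]). The mean difference between
#' successive appearance times is the stripe formation interval.
#'
#' @param run a `pde_run` (or compatible list with `x` and `snapshots`).
#' @param prominence_frac prominence threshold.
#' @return a list with `appearance_times` (s) and `mean_interval` (s).
#' @export
stripe_formation_times <- function(run, prominence_frac = 0.1) {
  tt <- vapply(run$snapshots, `[[`, numeric(1), "t")
  counts <- vapply(run$snapshots, function(s)
    nrow(find_stripe_peaks(run$x, s$rho, prominence_frac)), integer(1))
  # running maximum: a stripe, once formed, stays
  kmax <- max(counts)
  if (kmax < 1)
    return(list(appearance_times = numeric(0), mean_interval = NA_real_))
  appear <- vapply(seq_len(kmax), function(k) tt[min(which(counts >= k))],
                   numeric(1))
  list(appearance_times = appear,
       mean_interval = if (kmax >= 2) mean(diff(appear)) else NA_real_)
}

#' Summary pattern metrics of a run
#'
#' Convenience wrapper: front speed over the standard window, and
#' wavelength, height ratio, density ratio, stripe count and formation
#' interval at the final snapshot.
#'
#' @param run a `pde_run`.
#' @param t_window front-speed window (s).
#' @param threshold front threshold.
#' @param prominence_frac stripe prominence threshold.
#' @return a list of class `pattern_metrics`.
#' @export
pattern_metrics <- function(run, t_window = c(10, 20) * 3600,
                            threshold = 0.1, prominence_frac = 0.1) {
  last <- run$snapshots[[length(run$snapshots)]]
  radial <- !is.null(run$config) && run$config$geometry == "radial"
  ss <- stripe_structure(run$x, last$rho, prominence_frac, radial = radial)
  tt <- vapply(run$snapshots, `[[`, numeric(1), "t")
  fs <- tryCatch(front_speed(run, t_window, threshold),
                 error = function(e) NA_real_)
  sf <- stripe_formation_times(run, prominence_frac)
  structure(list(
    front_speed = fs,
    wavelength = wavelength(run$x, last$rho, prominence_frac),
    height_ratio = ss$height_ratio,
    density_ratio = ss$density_ratio,
    n_stripes = ss$n_stripes,
    formation_interval = sf$mean_interval,
    t_final = tt[length(tt)]
  ), class = "pattern_metrics")
}

#' @export
print.pattern_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<pattern_metrics> t=%.1f h: front speed=%.3g mm/h, wavelength=%.3g mm,\n",
    "  height ratio=%.3g, density ratio=%.3g, stripes=%d, interval=%.3g min\n"),
    x$t_final / 3600, x$front_speed, x$wavelength, x$height_ratio,
    x$density_ratio, x$n_stripes, x$formation_interval / 60))
  invisible(x)
}
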