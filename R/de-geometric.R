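#' Envelope (rotated-scatter percentile) caller settings
#'
#' The caller works on the 45-degree-clockwise-rotated log10 scatter of
#' infected versus uninfected expression: `u = (x + y)/sqrt(2)` is overall
#' expression, `v = (y - x)/sqrt(2)` is regulation.  The u-range is cut into
#' equal bins, per-bin upper and lower v-percentiles form anchor points, and
#' a hyperbola `v = a + b/(u - d)` is fitted to each anchor series.  The
#' hyperbola widens the acceptance envelope at low expression, where the
#' spread of ratios inflates.
#'
#' @param n_bins number of equal-width u bins (>= 3; default 20).
#' @param cutoff_percent per-bin tail percentage defining the envelope
#'   anchors, typically between 0.5 and 10 (default 1).
#' @param min_bin_points bins with fewer points than this are skipped when
#'   anchoring (default `ceiling(100 / cutoff_percent)`, the smallest count
#'   at which the tail percentile is supported by at least one point).
#' @return list of class `envelope_config`.
#' @export
envelope_config <- function(n_bins = 20, cutoff_percent = 1,
                            min_bin_points = NULL) {
  stopifnot(n_bins >= 3, cutoff_percent > 0, cutoff_percent < 50)
  if (is.null(min_bin_points)) {
    min_bin_points <- ceiling(100 / cutoff_percent)
  }
  structure(list(n_bins = n_bins, cutoff_percent = cutoff_percent,
                 min_bin_points = min_bin_points),
            class = "envelope_config")
}

#' Band (percentile-anchored threshold line) caller settings
#'
#' @param anchor_low,anchor_high percentile intervals of the x (uninfected)
#'   values over which the anchor y means are taken (defaults `[20, 30)` and
#'   `[70, 80)`).
#' @param tail_percentile percentile of the signed perpendicular distances,
#'   within each orthogonal bin, through which the threshold line is drawn
#'   (default 99; the down boundary uses the same percentile in the
#'   axis-swapped frame, i.e. the 1st-percentile construction).
#' @param ortho_bin_halfwidth half-width of the orthogonal bin around each
#'   anchor, as a fraction of the along-line coordinate range (default 0.05).
#' @return list of class `band_config`.
#' @export
band_config <- function(anchor_low = c(20, 30), anchor_high = c(70, 80),
                        tail_percentile = 99, ortho_bin_halfwidth = 0.05) {
  stopifnot(length(anchor_low) == 2, length(anchor_high) == 2,
            anchor_low[1] < anchor_low[2], anchor_high[1] < anchor_high[2],
            anchor_low[2] <= anchor_high[1],
            anchor_low[1] > 0, anchor_high[2] < 100,
            tail_percentile > 50, tail_percentile < 100,
            ortho_bin_halfwidth > 0)
  structure(list(anchor_low = anchor_low, anchor_high = anchor_high,
                 tail_percentile = tail_percentile,
                 ortho_bin_halfwidth = ortho_bin_halfwidth),
            class = "band_config")
}

# log10-transform strictly positive pairs; zero-involved pairs are excluded
# here (they are handled by infection_specific()).
log10_pairs <- function(pairs) {
  ok <- !is.na(pairs$control) & !is.na(pairs$infected) &
    pairs$control > 0 & pairs$infected > 0
  list(id = pairs$transcript_id[ok],
       x = log10(pairs$control[ok]),
       y = log10(pairs$infected[ok]),
       excluded = pairs$transcript_id[!ok])
}

# Least-squares hyperbola v = a + b/(u - d), d constrained strictly below
# min(u).  Separable: for fixed d the fit is linear, so optimize over d.
fit_hyperbola <- function(u, v) {
  if (length(u) < 3) stop("fewer than 3 usable anchors; cannot fit envelope")
  span <- max(diff(range(u)), 1e-8)
  d_hi <- min(u) - 1e-6 * span
  d_lo <- min(u) - 10 * span
  rss_for <- function(d) {
    X <- 1 / (u - d)
    fit <- stats::lm(v ~ X)
    sum(stats::resid(fit)^2)
  }
  opt <- stats::optimize(rss_for, c(d_lo, d_hi))
  d <- opt$minimum
  X <- 1 / (u - d)
  if (stats::sd(X) < 1e-12) {
    # ill-conditioned 3-parameter fit; fall back to v = a + b/u
    if (any(u == 0)) stop("ill-conditioned envelope fit")
    X0 <- 1 / u
    fit <- stats::lm(v ~ X0)
    ab <- stats::coef(fit)
    return(function(uu) unname(ab[1] + ab[2] / uu))
  }
  ab <- stats::coef(stats::lm(v ~ X))
  function(uu) unname(ab[1] + ab[2] / (uu - d))
}

#' Envelope caller: binned rotated-scatter percentiles plus hyperbola fit
#'
#' Alternative differential-regulation caller 1.  Both expression values are
#' log10 transformed and the scatter rotated 45 degrees clockwise; the
#' rotated abscissa is partitioned into `n_bins` equal bins; in each
#' sufficiently populated bin the `100 - cutoff_percent` and
#' `cutoff_percent` percentiles of the rotated ordinate, placed at the bin
#' centre, become the upper and lower envelope anchors; a hyperbola is
#' fitted separately to each anchor series.  Transcripts strictly above the
#' upper curve are called up, strictly below the lower curve down; the score
#' is the vertical (rotated-ordinate) distance from the curve.  Pairs with a
#' zero value are excluded and reported via the `flag` column (use
#' [infection_specific()] for their classification).
#'
#' @param pairs data frame `transcript_id`, `control`, `infected`.
#' @param config an [envelope_config()].
#' @return calls data frame `transcript_id`, `verdict`, `method`, `score`,
#'   `flag`.
#' @export
envelope_call <- function(pairs, config = envelope_config()) {
  pts <- log10_pairs(pairs)
  if (length(pts$x) < config$n_bins) stop("too few positive pairs to bin")
  s2 <- sqrt(2)
  u <- (pts$x + pts$y) / s2
  v <- (pts$y - pts$x) / s2

  breaks <- seq(min(u), max(u), length.out = config$n_bins + 1)
  bin <- findInterval(u, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2

  upper_u <- upper_v <- lower_v <- numeric(0)
  p <- config$cutoff_percent / 100
  for (b in seq_len(config$n_bins)) {
    idx <- bin == b
    if (sum(idx) < config$min_bin_points) next
    upper_u <- c(upper_u, centers[b])
    upper_v <- c(upper_v, stats::quantile(v[idx], 1 - p, type = 7, names = FALSE))
    lower_v <- c(lower_v, stats::quantile(v[idx], p, type = 7, names = FALSE))
  }
  up_curve <- fit_hyperbola(upper_u, upper_v)
  dn_curve <- fit_hyperbola(upper_u, lower_v)

  up_lim <- up_curve(u)
  dn_lim <- dn_curve(u)
  verdict <- rep("none", length(u))
  score <- numeric(length(u))
  is_up <- v > up_lim
  is_dn <- v < dn_lim
  verdict[is_up] <- "up"
  verdict[is_dn] <- "down"
  score[is_up] <- (v - up_lim)[is_up]
  score[is_dn] <- (v - dn_lim)[is_dn]

  rbind(
    new_calls(pts$id, verdict, "envelope", score),
    if (length(pts$excluded)) {
      new_calls(pts$excluded, "none", "envelope", NA_real_, "zero_expression")
    }
  )
}

#' Signed perpendicular distance from a point to a line
#'
#' Distance from `point` to the line through `line_p1` and `line_p2`, signed
#' positive on the upper (greater-y) side of the line.
#'
#' @param point numeric length-2 vector `(x, y)` (or a 2-column matrix of
#'   points).
#' @param line_p1,line_p2 two distinct points defining a non-vertical line.
#' @return signed distance(s).
#' @export
outlier_distance <- function(point, line_p1, line_p2) {
  d <- c(line_p2[1] - line_p1[1], line_p2[2] - line_p1[2])
  nrm2 <- sqrt(sum(d^2))
  if (nrm2 == 0) stop("degenerate line: identical points")
  if (d[1] == 0) stop("vertical line has no upper side")
  normal <- c(-d[2], d[1]) / nrm2
  if (normal[2] < 0) normal <- -normal
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  as.numeric((pts[, 1] - line_p1[1]) * normal[1] +
               (pts[, 2] - line_p1[2]) * normal[2])
}

band_threshold_line <- function(x, y, config, tail_q) {
  qs <- stats::quantile(x, c(config$anchor_low, 25, config$anchor_high, 75) / 100,
                        type = 7, names = FALSE)
  lo_band <- x >= qs[1] & x < qs[2]
  hi_band <- x >= qs[4] & x < qs[5]
  if (!any(lo_band) || !any(hi_band)) stop("empty anchor band")
  P_low <- c(qs[3], mean(y[lo_band]))
  P_high <- c(qs[6], mean(y[hi_band]))
  if (P_low[1] == P_high[1]) stop("degenerate anchor line (identical x anchors)")

  dirv <- (P_high - P_low) / sqrt(sum((P_high - P_low)^2))
  tvals <- (x - P_low[1]) * dirv[1] + (y - P_low[2]) * dirv[2]
  svals <- outlier_distance(cbind(x, y), P_low, P_high)
  hw <- config$ortho_bin_halfwidth * diff(range(tvals))

  t_low <- 0
  t_high <- (P_high[1] - P_low[1]) * dirv[1] + (P_high[2] - P_low[2]) * dirv[2]
  sel_low <- abs(tvals - t_low) <= hw
  sel_high <- abs(tvals - t_high) <= hw
  if (!any(sel_low) || !any(sel_high)) stop("empty orthogonal bin")
  normal <- c(-dirv[2], dirv[1])
  if (normal[2] < 0) normal <- -normal
  tail_low <- stats::quantile(svals[sel_low], tail_q, type = 7, names = FALSE)
  tail_high <- stats::quantile(svals[sel_high], tail_q, type = 7, names = FALSE)
  list(p1 = P_low + tail_low * normal, p2 = P_high + tail_high * normal)
}

#' Band caller: threshold line through local distance percentiles
#'
#' Alternative differential-regulation caller 2.  On log10 axes, a reference
#' line is drawn through the 25th-percentile x value paired with the mean y
#' of points in the 20th-30th percentile x band, and the 75th-percentile x
#' value paired with the mean y of the 70th-80th band.  Around each anchor,
#' points within an orthogonal bin are projected onto the reference line and
#' the `tail_percentile` of their signed perpendicular distances defines a
#' local threshold point; the line through the two threshold points is the
#' up-regulation boundary.  Points strictly above it are called up, with the
#' perpendicular distance to the boundary as score; down-regulation is the
#' exact mirror, i.e. the identical construction applied with the axes
#' swapped (equivalent to the low-tail construction in the reflected frame),
#' so that swapping the two conditions swaps the up and down call sets.
#' Pairs with a zero value are excluded and flagged.
#'
#' @param pairs data frame `transcript_id`, `control`, `infected`.
#' @param config a [band_config()].
#' @return calls data frame `transcript_id`, `verdict`, `method`, `score`,
#'   `flag`.
#' @export
band_call <- function(pairs, config = band_config()) {
  pts <- log10_pairs(pairs)
  if (length(pts$x) < 10) stop("too few positive pairs")
  x <- pts$x
  y <- pts$y

  T_up <- band_threshold_line(x, y, config, config$tail_percentile / 100)
  d_up <- outlier_distance(cbind(x, y), T_up$p1, T_up$p2)
  # down-regulation is the exact mirror: the up procedure on swapped axes
  T_dn <- band_threshold_line(y, x, config, config$tail_percentile / 100)
  d_dn <- outlier_distance(cbind(y, x), T_dn$p1, T_dn$p2)

  verdict <- rep("none", length(x))
  score <- numeric(length(x))
  is_up <- d_up > 0
  is_dn <- d_dn > 0
  verdict[is_up] <- "up"
  verdict[is_dn & !is_up] <- "down"
  score[is_up] <- d_up[is_up]
  score[is_dn & !is_up] <- -d_dn[is_dn & !is_up]

  rbind(
    new_calls(pts$id, verdict, "band", score),
    if (length(pts$excluded)) {
      new_calls(pts$excluded, "none", "band", NA_real_, "zero_expression")
    }
  )
}
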