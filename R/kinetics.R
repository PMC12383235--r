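#' Normalize a kinetic curve to fractional amplitude
#'
#' `(f - baseline) / (plateau - baseline)`, with the baseline estimated
#' as the mean of the first 5% of points and the plateau as the mean of
#' the top 5% of values — 5%-tail estimators are robust to the small
#' pre-transition drift common in plate-reader ThT data.
#'
#' @param curve A [kinetic_curve()].
#' @return A [kinetic_curve()] on the (approximately) 0..1 scale.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "kinetic_curve"))
  f <- curve$f
  if (max(f) <= min(f)) stop("no transition: curve is flat")
  n <- length(f)
  k <- max(ceiling(n * 0.05), 1L)
  baseline <- mean(f[seq_len(k)])
  plateau <- mean(sort(f, decreasing = TRUE)[seq_len(k)])
  if (plateau <= baseline) stop("no transition: plateau not above baseline")
  kinetic_curve(curve$t, (f - baseline) / (plateau - baseline), curve$t_units)
}

#' End of the lag phase from a sigmoidal curve
#'
#' Scales the curve to its plateau (mean of the top 5% of values) and
#' returns the linearly interpolated first upward crossing of
#' `threshold_fraction` of maximum (10% by default, the conventional
#' end-of-lag-phase point), plus the midpoint (50%) crossing.  The
#' threshold is a fraction of the maximal signal, not of the
#' baseline-subtracted amplitude — instrument offsets should be removed
#' beforehand.  A light running-mean smooth is used for crossing
#' detection; a smoothed curve with multiple upward threshold crossings
#' is rejected as non-sigmoidal.
#'
#' @param curve A [kinetic_curve()].
#' @param threshold_fraction Fraction of maximum defining the lag end.
#' @param smooth_window Running-mean window, samples (odd; 1 disables).
#' @return List with `lag_end` and `midpoint`, in the curve's time
#'   units.
#' @export
lag_end_time <- function(curve, threshold_fraction = 0.10,
                         smooth_window = 9L) {
  stopifnot(inherits(curve, "kinetic_curve"),
            threshold_fraction > 0, threshold_fraction < 1)
  if (max(curve$f) <= min(curve$f)) stop("no transition: curve is flat")
  k5 <- max(ceiling(length(curve$f) * 0.05), 1L)
  plateau <- mean(sort(curve$f, decreasing = TRUE)[seq_len(k5)])
  if (plateau <= 0) stop("no transition: plateau not positive")
  nc <- kinetic_curve(curve$t, curve$f / plateau, curve$t_units)
  f <- nc$f
  if (smooth_window >= 3) {
    k <- rep(1 / smooth_window, smooth_window)
    fs <- stats::filter(f, k, sides = 2)
    f <- ifelse(is.na(fs), f, as.numeric(fs))
  }
  if (f[1] >= threshold_fraction)
    stop("curve starts above the threshold: lag phase not observed")
  # debounced upward crossings: the curve must stay above the
  # threshold for 3 samples before a crossing counts, so single noisy
  # samples neither trigger nor split a crossing
  n <- length(f)
  sustained <- f >= threshold_fraction &
    c(f[-1], f[n]) >= threshold_fraction &
    c(f[-(1:2)], f[n], f[n]) >= threshold_fraction
  below_before <- c(TRUE, f[-n] < threshold_fraction)
  up <- which(sustained & below_before)
  if (!length(up)) stop("curve never crosses the threshold")
  if (length(up) > 1) stop("non-sigmoidal: multiple upward threshold crossings")
  cross_at <- function(level) {
    i <- which(f[-1] >= level & f[-n] < level)[1]
    if (is.na(i)) return(NA_real_)
    fr <- (level - f[i]) / (f[i + 1] - f[i])
    nc$t[i] + fr * (nc$t[i + 1] - nc$t[i])
  }
  list(lag_end = cross_at(threshold_fraction), midpoint = cross_at(0.5))
}

#' Fluo-4 influx normalization
#'
#' Elementwise `F / F0 - 1`, the standard background-referenced
#' presentation of Ca2+ indicator fluorescence.
#'
#' @param f Observed fluorescence series.
#' @param f0 Background fluorescence just before addition (> 0).
#' @return Normalized series.
#' @export
normalize_influx <- function(f, f0) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0)
    stop("f0 must be a positive scalar")
  f / f0 - 1
}

#' Track a single elongating assembly across an AFM series
#'
#' Traces the filament in every frame, anchors the track at the
#' centroid of the frame-0 object, propagates end identity across
#' frames by nearest-endpoint matching, and measures the excursion of
#' each end as the arc length along the current path from the
#' anchor-nearest point to that end, minus its frame-0 value (arc
#' length, not Euclidean displacement, since the filaments are
#' curvilinear).  If a frame loses the object (merge, border exit or
#' failed trace), the track is truncated at the last clean frame and
#' flagged.
#'
#' @param series A [height_map_series()].
#' @return Object of class `growth_track`: `timestamps`,
#'   `total_length`, `end_a_excursion`, `end_b_excursion`, `anchor`,
#'   `truncated`.
#' @export
track_growth <- function(series) {
  stopifnot(inherits(series, "height_map_series"))
  px <- series$pixel_size
  n <- length(series$frames)
  total <- exc_a <- exc_b <- rep(NA_real_, n)
  anchor <- NULL; prev_a <- prev_b <- NULL
  base_a <- base_b <- 0
  truncated <- FALSE
  for (k in seq_len(n)) {
    paths <- tryCatch(trace_filament(series$frames[[k]], voxel_size = px),
                      error = function(e) list())
    paths <- Filter(function(p) !p$border_flag, paths)
    if (!length(paths)) { truncated <- k > 1; break }
    lens <- vapply(paths, path_length, numeric(1))
    p <- paths[[which.max(lens)]]
    pts <- resample_path(p$points, px / 4)   # fine arc sampling for the split
    if (k == 1) {
      anchor <- colMeans(pts)
      prev_a <- p$end_a; prev_b <- p$end_b
    } else {
      # nearest-endpoint matching to the previous frame's ends
      d_aa <- sum((p$end_a - prev_a)^2) + sum((p$end_b - prev_b)^2)
      d_ab <- sum((p$end_a - prev_b)^2) + sum((p$end_b - prev_a)^2)
      if (d_ab < d_aa) pts <- pts[nrow(pts):1, , drop = FALSE]
      prev_a <- pts[1, ]; prev_b <- pts[nrow(pts), ]
    }
    cl <- path_cumlength(pts)
    d_anchor <- sqrt(rowSums((pts - matrix(anchor, nrow(pts), ncol(pts),
                                           byrow = TRUE))^2))
    s_anchor <- cl[which.min(d_anchor)]
    a_len <- s_anchor
    b_len <- cl[length(cl)] - s_anchor
    if (k == 1) { base_a <- a_len; base_b <- b_len }
    total[k] <- cl[length(cl)]
    exc_a[k] <- a_len - base_a
    exc_b[k] <- b_len - base_b
  }
  keep <- !is.na(total)
  structure(list(timestamps = series$timestamps[keep],
                 total_length = total[keep],
                 end_a_excursion = exc_a[keep],
                 end_b_excursion = exc_b[keep],
                 anchor = anchor,
                 initial_length = if (any(keep)) total[which(keep)[1]] else NA_real_,
                 truncated = truncated || sum(keep) < n),
            class = "growth_track")
}

#' Fit bidirectional growth rates to a track
#'
#' Ordinary least-squares slope of each end's excursion versus time
#' (plain linear best fit, no weighting), plus the equivalent monomer
#' addition rate `rate / strand_rise` (0.48 nm per monomer: one
#' cross-beta strand per added molecule).
#'
#' @param track A [growth_track()].
#' @param strand_rise Axial rise per monomer, nm.
#' @return Object of class `growth_rates`: `rate_a`, `rate_b` (nm/min),
#'   `r_squared_a`, `r_squared_b`, `monomers_per_min_a`,
#'   `monomers_per_min_b`.
#' @export
fit_growth_rates <- function(track, strand_rise = 0.48) {
  stopifnot(inherits(track, "growth_track"), strand_rise > 0)
  if (length(track$timestamps) < 3)
    stop("need at least 3 frames to fit growth rates")
  fit_one <- function(y) {
    fit <- stats::lm(y ~ t, data = data.frame(t = track$timestamps, y = y))
    r2 <- if (stats::var(y) > 0) summary(fit)$r.squared else 1
    c(rate = unname(stats::coef(fit)[2]), r2 = r2)
  }
  a <- fit_one(track$end_a_excursion)
  b <- fit_one(track$end_b_excursion)
  structure(list(rate_a = unname(a["rate"]), rate_b = unname(b["rate"]),
                 r_squared_a = unname(a["r2"]), r_squared_b = unname(b["r2"]),
                 monomers_per_min_a = unname(a["rate"]) / strand_rise,
                 monomers_per_min_b = unname(b["rate"]) / strand_rise),
            class = "growth_rates")
}
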