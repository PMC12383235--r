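#' Kinetic (fluorescence vs time) curve
#'
#' @param t Time, strictly increasing; hours by default.
#' @param f Fluorescence, arbitrary units, finite.
#' @param t_units `"h"` or `"min"`.
#' @return Object of class `kinetic_curve`.
#' @export
kinetic_curve <- function(t, f, t_units = "h") {
  stopifnot(length(t) == length(f), all(is.finite(t)), all(is.finite(f)))
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  structure(list(t = as.numeric(t), f = as.numeric(f),
                 t_units = match.arg(t_units, c("h", "min"))),
            class = "kinetic_curve")
}

#' Synthetic sigmoidal ThT aggregation curve
#'
#' Logistic curve `plateau / (1 + exp(-k (t - midpoint)))` whose
#' steepness is chosen so that the 10%-of-plateau crossing falls exactly
#' at `lag_h` (the end of the lag phase): `k = log(9) / (midpoint - lag)`.
#' Additive Gaussian noise emulates plate-reader scatter.
#'
#' @param lag_h End of lag phase (10% crossing), hours; `0 < lag < midpoint`.
#' @param midpoint_h Half-maximum time, hours.
#' @param plateau Plateau fluorescence (a.u.); `0` gives a flat curve
#'   (degenerate input for downstream detectors).
#' @param noise_sd Noise SD, same units as `plateau`.
#' @param t_grid Sampling times, hours.
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @return A [kinetic_curve()].
#' @export
gen_tht_curve <- function(lag_h = 28, midpoint_h = 50, plateau = 100,
                          noise_sd = 0, t_grid = seq(0, 100, by = 0.5),
                          seed = NULL) {
  stopifnot(lag_h > 0, lag_h < midpoint_h, plateau >= 0, noise_sd >= 0)
  k <- log(9) / (midpoint_h - lag_h)
  f <- plateau / (1 + exp(-k * (t_grid - midpoint_h)))
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is mandatory when noise_sd > 0")
    f <- f + with_seed(seed, stats::rnorm(length(t_grid), 0, noise_sd))
  }
  kinetic_curve(t_grid, f, "h")
}

#' Population of measured assembly lengths at one time point
#'
#' @param lengths Lengths, nm, all positive.
#' @param t_label Optional time label, hours.
#' @return Object of class `length_population`.
#' @export
length_population <- function(lengths, t_label = NA_real_) {
  lengths <- as.numeric(lengths)
  if (!length(lengths) || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be positive and finite")
  structure(list(lengths = lengths, t_label = t_label),
            class = "length_population")
}

#' Synthetic lognormal length populations over a growth time course
#'
#' Samples lengths from lognormal distributions whose analytic mode
#' (`exp(mu - sigma^2)`) equals the requested modal length at each time
#' point, emulating the drift of the modal assembly length from a few
#' nm at the end of the lag phase to hundreds of nm a few hours later.
#'
#' @param t_points Time labels, hours.
#' @param modal_lengths Requested modal lengths, nm (same length as
#'   `t_points`, all positive).
#' @param dispersion Lognormal `sigma` (log-scale SD); `0` gives a point
#'   mass at the mode.
#' @param n_per_t Samples per time point; below 30 the histogram mode
#'   estimate is unstable and a warning is raised.
#' @param seed Integer seed (mandatory).
#' @return List of [length_population()], one per time point.
#' @export
gen_length_population <- function(t_points, modal_lengths, dispersion = 0.35,
                                  n_per_t = 100, seed) {
  stopifnot(length(t_points) == length(modal_lengths),
            all(modal_lengths > 0), dispersion >= 0, n_per_t >= 1)
  if (missing(seed)) stop("seed is mandatory")
  if (n_per_t < 30) warning("n_per_t < 30: mode estimation is unstable")
  with_seed(seed, lapply(seq_along(t_points), function(i) {
    mu <- log(modal_lengths[i]) + dispersion^2   # mode = exp(mu - sigma^2)
    x <- if (dispersion == 0) rep(modal_lengths[i], n_per_t)
         else stats::rlnorm(n_per_t, mu, dispersion)
    length_population(x, t_label = t_points[i])
  }))
}
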