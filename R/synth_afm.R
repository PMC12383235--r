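#' Time-stamped AFM height-map series
#'
#' @param frames List of numeric matrices (height, nm), all same shape.
#' @param pixel_size Pixel edge, nm (> 0).
#' @param frame_interval Minutes between frames.
#' @param timestamps Frame times, min (defaults to
#'   `0, frame_interval, ...`).
#' @return Object of class `height_map_series`.
#' @export
height_map_series <- function(frames, pixel_size, frame_interval,
                              timestamps = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1, pixel_size > 0,
            frame_interval > 0)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("all frames must share one shape")
    if (any(!is.finite(f))) stop("heights must be finite")
  }
  if (is.null(timestamps))
    timestamps <- (seq_along(frames) - 1) * frame_interval
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 timestamps = timestamps),
            class = "height_map_series")
}

#' AFM growth simulation parameters
#'
#' Conditions emulating real-time contact-mode AFM of an oligomer
#' elongating bidirectionally on mica: a frame every 8 min, pixels of
#' 9 to 19 nm, a probe of 20 nm nominal tip radius, and a 2.8-nm tube.
#'
#' @param rate_end_a,rate_end_b Elongation rate of each end, nm/min
#'   (>= 0).
#' @param frame_interval Minutes between frames (> 0).
#' @param n_frames Number of frames (>= 1).
#' @param pixel_size Pixel edge, nm, in `[1, 50]`.
#' @param tip_radius Probe tip radius, nm (0 disables tip broadening).
#' @param roughness_sd Gaussian surface roughness SD, nm.
#' @param tube_diameter Assembly tube diameter (= height), nm.
#' @param field_nm Square field edge, nm.
#' @param persistence_nm Centerline persistence length, nm.
#' @return List of class `growth_sim_params`.
#' @export
growth_sim_params <- function(rate_end_a = 8, rate_end_b = 8,
                              frame_interval = 8, n_frames = 6,
                              pixel_size = 12, tip_radius = 20,
                              roughness_sd = 0.05, tube_diameter = 2.8,
                              field_nm = 1500, persistence_nm = 250) {
  stopifnot(rate_end_a >= 0, rate_end_b >= 0, frame_interval > 0,
            n_frames >= 1, pixel_size >= 1, pixel_size <= 50,
            tip_radius >= 0, roughness_sd >= 0, tube_diameter > 0,
            field_nm > 10 * tube_diameter, persistence_nm > 0)
  for (r in c(rate_end_a, rate_end_b))
    if (r > 0 && r * frame_interval < 0.1 * pixel_size)
      stop("per-frame extension below 0.1 pixel: growth unobservable")
  structure(as.list(environment()), class = "growth_sim_params")
}

# measured apex height of a cylinder of radius `tube_r` lying on the
# support, imaged by a spherical tip of radius `tip_r`, as a function of
# lateral distance d from the axis (grayscale dilation in the continuum)
tip_broadened_profile <- function(d, tube_r, tip_r) {
  if (tip_r <= 0) {
    h <- ifelse(abs(d) < tube_r, tube_r + sqrt(pmax(tube_r^2 - d^2, 0)), 0)
    return(h)
  }
  s <- seq(-tube_r, tube_r, length.out = 201)
  tube_h <- tube_r + sqrt(pmax(tube_r^2 - s^2, 0))
  vapply(d, function(di) {
    u <- di - s
    ok <- abs(u) < tip_r
    if (!any(ok)) return(0)
    max(pmax(tube_h[ok] + sqrt(tip_r^2 - u[ok]^2) - tip_r, 0))
  }, numeric(1))
}

#' Simulate an AFM series of one bidirectionally elongating oligomer
#'
#' Frame 0 holds an oligomer of `initial_length` centred in the field;
#' each later frame extends the exposed window of a fixed master
#' centerline (a persistent random walk) by `rate x frame_interval` at
#' each end, so per-frame ground-truth lengths and end excursions are
#' exact bookkeeping, independent of pixelation.  Height maps are the
#' tube height field imaged through a spherical-tip contact model plus
#' Gaussian roughness.  Master centerlines that would pass within
#' `clearance_nm` of themselves are rejected and regenerated
#' deterministically from the seed.
#'
#' @param params [growth_sim_params()].
#' @param initial_length Frame-0 oligomer length, nm.
#' @param seed Integer seed (mandatory).
#' @param clearance_nm Minimum self-clearance of the centerline, nm.
#' @return List with `series` (a [height_map_series()]) and `truth`
#'   (per frame: centerline, `length_nm`, `excursion_a`, `excursion_b`,
#'   `anchor`, exact by construction).
#' @export
gen_afm_series <- function(params, initial_length = 20, seed,
                           clearance_nm = NULL) {
  stopifnot(inherits(params, "growth_sim_params"), initial_length > 0)
  if (missing(seed)) stop("seed is mandatory")
  # the apparent (tip-broadened) tube half-width is ~2 sqrt(R r); two
  # passes closer than twice that, plus a few pixels of segmentation
  # smoothing and gap closing, would merge in the traced mask
  if (is.null(clearance_nm))
    clearance_nm <- 4 * sqrt(params$tip_radius * params$tube_diameter / 2) +
      4 * params$pixel_size
  t_total <- (params$n_frames - 1) * params$frame_interval
  half_a <- initial_length / 2 + params$rate_end_a * t_total + 10
  half_b <- initial_length / 2 + params$rate_end_b * t_total + 10
  fld <- params$field_nm
  bounds <- c(0, fld, 0, fld)
  margin <- 80
  master <- NULL
  for (attempt in 0:119) {
    # a 6-nm step keeps the stated persistence length while avoiding
    # discretization-scale curls tighter than the imaged footprint
    cand <- with_seed((seed %% 100000L) * 20000L + attempt * 101L + 17L, {
      th0 <- stats::runif(1, 0, 2 * pi)
      fwd <- persistent_path(half_b, step_nm = 6,
                             persistence_nm = params$persistence_nm,
                             start = c(fld / 2, fld / 2), heading = th0,
                             bounds = bounds, margin_nm = margin)
      bwd <- persistent_path(half_a, step_nm = 6,
                             persistence_nm = params$persistence_nm,
                             start = c(fld / 2, fld / 2), heading = th0 + pi,
                             bounds = bounds, margin_nm = margin)
      rbind(bwd[nrow(bwd):2, , drop = FALSE], fwd)
    })
    ok_clear <- min_self_distance(cand, skip_nm = 2 * clearance_nm) >= clearance_nm
    ok_in <- all(cand[, 1] > 40, cand[, 1] < fld - 40,
                 cand[, 2] > 40, cand[, 2] < fld - 40)
    if (ok_clear && ok_in) { master <- cand; break }
  }
  if (is.null(master))
    stop("could not generate a self-avoiding centerline; relax the settings")
  cl_master <- path_cumlength(master)
  s_anchor <- half_a                      # arc position of the anchor
  anchor <- path_point_at(master, s_anchor)
  n_px <- round(fld / params$pixel_size)
  r <- params$tube_diameter / 2
  d_grid <- seq(0, 2 * sqrt(params$tip_radius * r) + r + 2, by = 0.05)
  prof <- tip_broadened_profile(d_grid, r, params$tip_radius)
  prof_fun <- stats::approxfun(d_grid, prof, yleft = prof[1], yright = 0)
  frames <- vector("list", params$n_frames)
  truth <- vector("list", params$n_frames)
  for (k in seq_len(params$n_frames)) {
    t_min <- (k - 1) * params$frame_interval
    exc_a <- params$rate_end_a * t_min
    exc_b <- params$rate_end_b * t_min
    s0 <- s_anchor - initial_length / 2 - exc_a
    s1 <- s_anchor + initial_length / 2 + exc_b
    ss <- unique(c(seq(s0, s1, by = 1), s1))
    sub <- t(vapply(ss, function(s) path_point_at(master, s), numeric(2)))
    dmap <- polyline_distance_field(sub, n_px, n_px, params$pixel_size,
                                    max_dist = max(d_grid))
    h <- matrix(prof_fun(dmap), n_px, n_px)
    if (params$roughness_sd > 0)
      h <- h + with_seed((seed %% 100000L) * 20000L + 5000L + k,
                         matrix(stats::rnorm(n_px^2, 0, params$roughness_sd),
                                n_px, n_px))
    frames[[k]] <- h
    truth[[k]] <- list(centerline = sub,
                       length_nm = initial_length + exc_a + exc_b,
                       excursion_a = exc_a, excursion_b = exc_b,
                       end_a = sub[1, ], end_b = sub[nrow(sub), ],
                       anchor = anchor)
  }
  list(series = height_map_series(frames, params$pixel_size,
                                  params$frame_interval),
       truth = truth, params = params, initial_length = initial_length)
}
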