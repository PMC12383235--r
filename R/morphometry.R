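# field input helper: accept a density_field, a height frame matrix, or
# a matrix + voxel size
as_field <- function(field, voxel_size = NULL) {
  if (inherits(field, "density_field")) return(field)
  if (is.matrix(field) || length(dim(field)) == 3) {
    if (is.null(voxel_size)) stop("a bare array needs an explicit voxel_size")
    return(density_field(field, voxel_size))
  }
  stop("field must be a density_field or a calibrated array")
}

#' Trace elongated assemblies in a calibrated field
#'
#' Segments the field (Otsu threshold), skeletonizes each connected
#' elongated object, extracts the longest geodesic path through the
#' skeleton, smooths it to subpixel coordinates and extends both path
#' ends by the local object half-width (from the distance transform) so
#' the traced length spans the full object.  3D volumes are traced on
#' the maximum-intensity projection; the axial coordinate is recovered
#' per point as the intensity-weighted centroid along the axis.
#'
#' Objects touching the field border are flagged (`border_flag`) and
#' should be excluded from length statistics; branched skeletons return
#' their longest branch with `branch_flag` set.
#'
#' @param field A [density_field()] or a single height frame (matrix;
#'   then supply `voxel_size`).
#' @param voxel_size Voxel/pixel size in nm for bare arrays.
#' @param min_area_px Minimum object area, pixels.
#' @param threshold Optional absolute foreground threshold (default:
#'   Otsu's method on the intensity histogram).
#' @return List of [filament_path()], ordered by object label.
#' @export
trace_filament <- function(field, voxel_size = NULL, min_area_px = 2,
                           threshold = NULL) {
  fld <- as_field(field, voxel_size)
  g <- fld$grid
  voxel <- fld$voxel_size
  is3d <- length(dim(g)) == 3
  img <- if (is3d) apply(g, c(1, 2), max) else g
  rng <- range(img)
  if (diff(rng) <= 0) return(list())
  # segmentation runs on a lightly pre-smoothed copy: at coarse pixel
  # sizes a thin filament's footprint is barely one pixel wide and the
  # raw mask fragments; measurements still use the raw image
  img_seg <- gaussian_blur_field(img, 0.6)
  if (is.null(threshold)) threshold <- auto_threshold(img_seg)
  mask <- img_seg > threshold
  if (!any(mask)) return(list())
  mask <- EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1),
                                              EBImage::makeBrush(3, "box"))) > 0
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- round(EBImage::imageData(lab))
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  labv <- as.integer(lab)
  pix <- split(which(labv > 0L), labv[labv > 0L])
  pix <- pix[vapply(pix, length, integer(1)) >= min_area_px]
  out <- list()
  for (id in names(pix)) {
    comp <- matrix(FALSE, nrow(img), ncol(img))
    comp[pix[[id]]] <- TRUE
    rc_all <- which(comp, arr.ind = TRUE)
    border <- any(rc_all[, 1] %in% c(1L, nrow(img))) ||
      any(rc_all[, 2] %in% c(1L, ncol(img)))
    # work within the component bounding box only
    r0 <- max(min(rc_all[, 1]) - 2L, 1L); r1 <- min(max(rc_all[, 1]) + 2L, nrow(img))
    c0 <- max(min(rc_all[, 2]) - 2L, 1L); c1 <- min(max(rc_all[, 2]) + 2L, ncol(img))
    sub <- comp[r0:r1, c0:c1, drop = FALSE]
    coarse <- mean(dt[comp]) < 2
    # coarse regime: the mask is 1-2 px wide, and thinning erodes its
    # ragged ends; the geodesic through the mask itself is the better
    # spine there
    lp <- skeleton_longest_path(if (coarse) sub else skeletonize(sub))
    if (is.null(lp)) next
    if (coarse) lp$branched <- FALSE
    if (nrow(lp$rc) < 2) {
      # compact (blob-like) object: use its principal axis instead
      ctr <- colMeans(rc_all)
      cc <- sweep(rc_all, 2, ctr)
      v1 <- svd(cc)$v[, 1]
      proj <- cc %*% v1
      lp <- list(rc = rbind(ctr + v1 * min(proj), ctr + v1 * max(proj)),
                 branched = FALSE)
    } else {
      lp$rc <- lp$rc + matrix(c(r0 - 1L, c0 - 1L), nrow(lp$rc), 2, byrow = TRUE)
    }
    rc_cl <- pmin(pmax(round(lp$rc), 1L),
                  matrix(dim(img), nrow(lp$rc), 2, byrow = TRUE))
    half_width_px <- mean(dt[rc_cl])
    pts <- (lp$rc - 0.5) * voxel
    if (!coarse) {
      # fine-pixel regime: subpixel smoothing + ridge refinement
      win <- max(3L, 2L * floor(half_width_px) + 1L)
      pts <- smooth_path_coords(pts, win)
      pts <- refine_ridge(pts, img, voxel, threshold)
      pts <- smooth_path_coords(pts, 3L)
    }
    # coarse-pixel regime (object barely wider than a pixel): keep the
    # raw skeleton; smoothing or centroid refinement at this scale cuts
    # corners and systematically shortens arc lengths
    # extend each end along its tangent by the local half-width
    ext_end <- function(pts, head_end) {
      rc <- if (head_end) lp$rc[1, , drop = FALSE] else lp$rc[nrow(lp$rc), , drop = FALSE]
      rc <- matrix(pmin(pmax(round(rc), 1L), dim(img)), 1)
      reach <- max(dt[rc] - 0.5, 0) * voxel
      if (reach <= 0) return(pts)
      n <- nrow(pts)
      tang <- if (head_end) pts[1, ] - pts[min(4, n), ]
              else pts[n, ] - pts[max(n - 3, 1), ]
      nt <- sqrt(sum(tang^2))
      if (nt < .Machine$double.eps) return(pts)
      newp <- (if (head_end) pts[1, ] else pts[n, ]) + tang / nt * reach
      if (head_end) rbind(newp, pts) else rbind(pts, newp)
    }
    pts <- ext_end(ext_end(pts, TRUE), FALSE)
    if (is3d) {
      zs <- (seq_len(dim(g)[3]) - 0.5) * voxel
      z <- apply(pts, 1, function(p) {
        i <- pmin(pmax(round(p[1] / voxel + 0.5), 1), dim(g)[1])
        j <- pmin(pmax(round(p[2] / voxel + 0.5), 1), dim(g)[2])
        w <- pmax(g[i, j, ], 0)
        if (sum(w) <= 0) mean(zs) else sum(w * zs) / sum(w)
      })
      pts <- cbind(pts, z)
    }
    out[[length(out) + 1L]] <-
      filament_path(pts, branch_flag = lp$branched, border_flag = border)
  }
  out
}

#' Cross-sectional profile orthogonal to a filament path
#'
#' Interpolates the field along the line through the path point at arc
#' length `station`, perpendicular (in-slice) to the local tangent.
#' `n_average` profiles at adjacent stations can be averaged,
#' emulating the slab averaging used when presenting tomogram slices.
#' The baseline is the median of the outer 25% of offsets on each side.
#'
#' @param field A [density_field()] or matrix plus `voxel_size`.
#' @param path A [filament_path()].
#' @param station Arc-length position, nm, in `[0, path_length]`.
#' @param half_width Half-width of the profile window, nm.
#' @param n_average Number of adjacent stations averaged (odd).
#' @param voxel_size For bare arrays.
#' @param threshold_fraction Width convention carried into
#'   [diameter_at_threshold()].
#' @return Object of class `cross_profile` with fields `offsets`,
#'   `values`, `baseline`, `noise_sd`, `threshold_fraction`, `spacing`.
#' @export
cross_profile <- function(field, path, station, half_width = 6,
                          n_average = 1, voxel_size = NULL,
                          threshold_fraction = 0.15) {
  fld <- as_field(field, voxel_size)
  g <- fld$grid
  if (length(dim(g)) == 3) g <- apply(g, c(1, 2), max)
  voxel <- fld$voxel_size
  pts <- path$points[, 1:2, drop = FALSE]
  total <- path_length(pts)
  if (station < 0 || station > total) stop("station outside [0, path length]")
  offs <- seq(-half_width, half_width, by = voxel / 4)
  stations <- station + (seq_len(n_average) - (n_average + 1) / 2) * voxel
  stations <- stations[stations >= 0 & stations <= total]
  acc <- matrix(0, length(offs), length(stations))
  for (si in seq_along(stations)) {
    p0 <- path_point_at(pts, stations[si])
    tg <- path_tangent_at(pts, stations[si], window = 4 * voxel)
    nv <- c(-tg[2], tg[1])
    xs <- p0[1] + offs * nv[1]
    ys <- p0[2] + offs * nv[2]
    fi <- xs / voxel + 0.5; fj <- ys / voxel + 0.5
    if (any(fi < 1 | fi > nrow(g) | fj < 1 | fj > ncol(g)))
      stop("profile window exits the field")
    i0 <- pmin(floor(fi), nrow(g) - 1); j0 <- pmin(floor(fj), ncol(g) - 1)
    fx <- fi - i0; fy <- fj - j0
    acc[, si] <- g[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      g[cbind(i0 + 1, j0)] * fx * (1 - fy) +
      g[cbind(i0, j0 + 1)] * (1 - fx) * fy +
      g[cbind(i0 + 1, j0 + 1)] * fx * fy
  }
  vals <- rowMeans(acc)
  n <- length(offs)
  outer_idx <- c(seq_len(ceiling(n * 0.25)), (n - ceiling(n * 0.25) + 1):n)
  baseline <- stats::median(vals[outer_idx])
  noise_sd <- stats::mad(vals[outer_idx])
  structure(list(offsets = offs, values = vals, baseline = baseline,
                 noise_sd = noise_sd, threshold_fraction = threshold_fraction,
                 spacing = voxel / 4),
            class = "cross_profile")
}

# interpolated outermost crossings of `level`; runs above level shorter
# than min_run samples are treated as noise
outermost_crossings <- function(x, v, level, min_run = 2L) {
  above <- v >= level
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep)) return(NULL)
  i1 <- starts[keep[1]]; i2 <- ends[keep[length(keep)]]
  cross_left <- if (i1 == 1) x[1] else {
    f <- (level - v[i1 - 1]) / (v[i1] - v[i1 - 1])
    x[i1 - 1] + f * (x[i1] - x[i1 - 1])
  }
  cross_right <- if (i2 == length(v)) x[length(x)] else {
    f <- (level - v[i2 + 1]) / (v[i2] - v[i2 + 1])
    x[i2 + 1] + f * (x[i2] - x[i2 + 1])
  }
  c(cross_left, cross_right)
}

#' Width of a cross profile at a fraction above baseline
#'
#' Width between the outermost crossings of the level
#' `baseline + threshold_fraction * (peak - baseline)` (default 15%
#' above baseline), with linear interpolation between samples.  Taking
#' the outermost crossings makes the measure robust to central dips
#' (annuli); single-sample noise spikes are ignored via a minimum run
#' length, and the profile is lightly smoothed first when noisy.
#'
#' @param profile A [cross_profile()].
#' @param threshold_fraction Overrides the profile's convention.
#' @param smooth_window Running-mean window (samples) applied before
#'   crossing detection; 1 disables smoothing.  Default: smoothing is
#'   applied only when the profile is visibly noisy (noise above 2% of
#'   the amplitude), since smoothing a clean profile widens the
#'   threshold width by up to half a window.
#' @return Width in nm.
#' @export
diameter_at_threshold <- function(profile,
                                  threshold_fraction = profile$threshold_fraction,
                                  smooth_window = NULL) {
  stopifnot(inherits(profile, "cross_profile"),
            threshold_fraction > 0, threshold_fraction < 1)
  v <- profile$values
  if (is.null(smooth_window)) {
    amp <- max(v) - profile$baseline
    noisy <- is.finite(profile$noise_sd) && profile$noise_sd > 0.05 * amp
    smooth_window <- if (noisy) 5L else 1L
  }
  if (smooth_window >= 3) {
    k <- rep(1 / smooth_window, smooth_window)
    vs <- stats::filter(v, k, sides = 2)
    v <- ifelse(is.na(vs), v, as.numeric(vs))
  }
  peak <- max(v)
  if (peak - profile$baseline <= 0)
    stop("no object: profile has no amplitude above baseline")
  if (is.finite(profile$noise_sd) && profile$noise_sd > 0 &&
      peak - profile$baseline <= 3 * profile$noise_sd)
    stop("peak does not rise 3 noise SDs above baseline")
  level <- profile$baseline + threshold_fraction * (peak - profile$baseline)
  # a real object must stay above the level for >1 voxel; narrower
  # excursions are noise (interpolated samples are sub-voxel spaced)
  cr <- outermost_crossings(profile$offsets, v, level, min_run = 6L)
  if (is.null(cr)) stop("no object: profile never exceeds the threshold level")
  diff(cr)
}

#' Flatten an AFM frame (first-order plane removal)
#'
#' Fits a plane to the non-object pixels (object mask by Otsu's
#' threshold) and subtracts it, mirroring the first-order flattening
#' and plane fitting applied to raw AFM scans.
#'
#' @param frame Height matrix, nm.
#' @param pixel_size Pixel edge, nm.
#' @return Flattened matrix (support plane at 0).
#' @export
flatten_frame <- function(frame, pixel_size = 1) {
  rng <- range(frame)
  mask <- if (diff(rng) > 0) frame > auto_threshold(frame)
          else matrix(FALSE, nrow(frame), ncol(frame))
  if (mean(mask) > 0.6)
    stop("object covers more than 60% of the frame: plane fit unreliable")
  ij <- which(!mask, arr.ind = TRUE)
  df <- data.frame(z = frame[!mask], x = ij[, 1], y = ij[, 2])
  fit <- stats::lm(z ~ x + y, data = df)
  co <- stats::coef(fit)
  all_i <- matrix(seq_len(nrow(frame)), nrow(frame), ncol(frame))
  all_j <- matrix(seq_len(ncol(frame)), nrow(frame), ncol(frame), byrow = TRUE)
  frame - (co[1] + co[2] * all_i + co[3] * all_j)
}

#' AFM object height above the support plane
#'
#' Peak of the cross-sectional height profile at `station`, after
#' first-order flattening of the frame.
#'
#' @param frame Height matrix (nm) or [density_field()].
#' @param path A [filament_path()] traced on the frame.
#' @param station Arc-length position, nm.
#' @param pixel_size Pixel edge, nm (bare matrices).
#' @param half_width Profile half-width, nm.
#' @return Height in nm.
#' @export
afm_height <- function(frame, path, station, pixel_size = NULL,
                       half_width = NULL) {
  fld <- as_field(frame, pixel_size)
  flat <- flatten_frame(fld$grid, fld$voxel_size)
  if (is.null(half_width)) half_width <- 6 * fld$voxel_size
  prof <- cross_profile(density_field(flat, fld$voxel_size), path, station,
                        half_width = half_width)
  max(prof$values) - min(prof$baseline, 0)
}

#' Ring (annulus) geometry from two orthogonal profiles
#'
#' Takes line profiles along x and y through `center` (central axial
#' slice for 3D fields).  The outer diameter is the separation of the
#' outermost crossings, either at the threshold-above-baseline
#' convention (`convention = "threshold"`) or at the baseline itself
#' (`"baseline"`, i.e. the outermost points detectably above
#' background).  The inner (channel) diameter is the width of the
#' central dip, with the same fractional convention applied to the
#' inverted dip.  Values are averaged over the two profiles.  For 3D
#' fields the channel length is the axial extent of the ring wall at
#' the mid-ring radius, with the same threshold convention.
#'
#' @param field [density_field()] (2D or 3D) or matrix + `voxel_size`.
#' @param center Ring centre, nm (length 2; z defaults to the volume
#'   middle).
#' @param voxel_size For bare arrays.
#' @param threshold_fraction Fraction for the width conventions.
#' @param convention `"threshold"` or `"baseline"` for the outer
#'   diameter.
#' @param half_width Profile half-width, nm.
#' @return Object of class `ring_geometry`: `outer_diameter`,
#'   `inner_diameter`, `channel_length` (NA for 2D).
#' @export
ring_geometry <- function(field, center, voxel_size = NULL,
                          threshold_fraction = 0.15,
                          convention = c("threshold", "baseline"),
                          half_width = NULL) {
  convention <- match.arg(convention)
  fld <- as_field(field, voxel_size)
  g <- fld$grid
  voxel <- fld$voxel_size
  is3d <- length(dim(g)) == 3
  if (is3d) {
    kz <- if (length(center) >= 3) pmin(pmax(round(center[3] / voxel + 0.5), 1),
                                        dim(g)[3]) else ceiling(dim(g)[3] / 2)
    sl <- g[, , kz]
  } else sl <- g
  if (is.null(half_width))
    half_width <- min(center[1], center[2],
                      nrow(sl) * voxel - center[1],
                      ncol(sl) * voxel - center[2]) - voxel
  # axis-aligned line profile, interpolated in 1D along the nearest
  # row/column so the rendered edge ramp is not smeared twice
  sample_line <- function(dir) {
    offs <- seq(-half_width, half_width, by = voxel / 4)
    if (dir[1] == 1) {
      j0 <- pmin(pmax(round(center[2] / voxel + 0.5), 1), ncol(sl))
      row <- sl[, j0]
      fi <- (center[1] + offs) / voxel + 0.5
      i0 <- pmin(pmax(floor(fi), 1), nrow(sl) - 1)
      fx <- fi - i0
      v <- row[i0] * (1 - fx) + row[i0 + 1] * fx
    } else {
      i0 <- pmin(pmax(round(center[1] / voxel + 0.5), 1), nrow(sl))
      col <- sl[i0, ]
      fj <- (center[2] + offs) / voxel + 0.5
      j0 <- pmin(pmax(floor(fj), 1), ncol(sl) - 1)
      fy <- fj - j0
      v <- col[j0] * (1 - fy) + col[j0 + 1] * fy
    }
    list(x = offs, v = v)
  }
  # When an edge rises from 10% to 90% of its amplitude within ~2
  # voxels it is unresolved: the threshold level then measures the
  # digitization ramp, not structure, and the half-amplitude point is
  # the unbiased edge estimate.  Resolved (blurred) edges keep the
  # threshold convention untouched.
  refine_cross <- function(x, v, cx, base, peak) {
    amp <- peak - base
    if (!is.finite(cx) || amp <= 0) return(cx)
    w <- which(abs(x - cx) <= 3 * voxel)
    if (length(w) < 3) return(cx)
    vx <- v[w]; xx <- x[w]
    lo <- base + 0.1 * amp; hi <- base + 0.9 * amp
    if (min(vx) > lo || max(vx) < hi) return(cx)
    if (abs(xx[which.min(abs(vx - hi))] - xx[which.min(abs(vx - lo))]) >
        2.5 * voxel) return(cx)
    mid <- base + 0.5 * amp
    s <- sign(vx - mid)
    ch <- which(s[-1] != s[-length(s)])
    if (!length(ch)) return(cx)
    i <- ch[which.min(abs(xx[ch] - cx))]
    f <- (mid - vx[i]) / (vx[i + 1] - vx[i])
    xx[i] + f * (xx[i + 1] - xx[i])
  }
  measure_one <- function(pr) {
    x <- pr$x; v <- pr$v
    n <- length(x)
    outer_idx <- c(seq_len(ceiling(n * 0.25)), (n - ceiling(n * 0.25) + 1):n)
    base <- stats::median(v[outer_idx])
    noise <- stats::mad(v[outer_idx])
    peak <- max(v)
    lev_out <- if (convention == "threshold")
      base + threshold_fraction * (peak - base)
    else base + max(3 * noise, 0.02 * (peak - base))
    cr <- outermost_crossings(x, v, lev_out)
    if (is.null(cr)) stop("no ring detected in profile")
    cr <- c(refine_cross(x, v, cr[1], base, peak),
            refine_cross(x, v, cr[2], base, peak))
    outer_d <- diff(cr)
    # central dip between the highest peak on each side of the centre
    left <- which(x < 0); right <- which(x > 0)
    pl <- left[which.max(v[left])]; prt <- right[which.max(v[right])]
    mid <- which(x >= x[pl] & x <= x[prt])
    dip_i <- mid[which.min(v[mid])]
    dip <- v[dip_i]
    pk <- mean(c(v[pl], v[prt]))
    if (!(pk - dip > max(3 * noise, 0.2 * (peak - base))))
      stop("no channel: central dip not detectable")
    # the threshold convention applied to the inverted dip: 15% above
    # the inverted baseline (the wall tops), i.e. just below the rim
    lev_in <- pk - threshold_fraction * (pk - dip)
    li <- dip_i; while (li > pl && v[li - 1] <= lev_in) li <- li - 1
    ri <- dip_i; while (ri < prt && v[ri + 1] <= lev_in) ri <- ri + 1
    xi_l <- if (li > 1) {
      f <- (lev_in - v[li]) / (v[li - 1] - v[li]); x[li] + f * (x[li - 1] - x[li])
    } else x[li]
    xi_r <- if (ri < n) {
      f <- (lev_in - v[ri]) / (v[ri + 1] - v[ri]); x[ri] + f * (x[ri + 1] - x[ri])
    } else x[ri]
    xi_l <- refine_cross(x, v, xi_l, dip, pk)
    xi_r <- refine_cross(x, v, xi_r, dip, pk)
    c(outer = outer_d, inner = xi_r - xi_l)
  }
  m <- (measure_one(sample_line(c(1, 0))) + measure_one(sample_line(c(0, 1)))) / 2
  chan <- NA_real_
  if (is3d) {
    rmid <- (m["outer"] + m["inner"]) / 4
    th <- seq(0, 2 * pi, length.out = 73)[-73]
    zs <- (seq_len(dim(g)[3]) - 0.5) * voxel
    xs <- center[1] + rmid * cos(th); ys <- center[2] + rmid * sin(th)
    fi <- pmin(pmax(xs / voxel + 0.5, 1), dim(g)[1] - 1e-9)
    fj <- pmin(pmax(ys / voxel + 0.5, 1), dim(g)[2] - 1e-9)
    i0 <- pmin(floor(fi), dim(g)[1] - 1); j0 <- pmin(floor(fj), dim(g)[2] - 1)
    fx <- fi - i0; fy <- fj - j0
    wall <- vapply(seq_len(dim(g)[3]), function(k) {
      slk <- g[, , k]
      mean(slk[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
             slk[cbind(i0 + 1, j0)] * fx * (1 - fy) +
             slk[cbind(i0, j0 + 1)] * (1 - fx) * fy +
             slk[cbind(i0 + 1, j0 + 1)] * fx * fy)
    }, numeric(1))
    base_w <- stats::median(c(wall[1:2], wall[(length(wall) - 1):length(wall)]))
    lev <- base_w + threshold_fraction * (max(wall) - base_w)
    cr <- outermost_crossings(zs, wall, lev, min_run = 1L)
    if (!is.null(cr)) {
      vz <- voxel
      cr <- c(refine_cross(zs, wall, cr[1], base_w, max(wall)),
              refine_cross(zs, wall, cr[2], base_w, max(wall)))
      chan <- diff(cr)
    }
  }
  if (!(m["inner"] < m["outer"])) stop("inner diameter not below outer diameter")
  structure(list(outer_diameter = unname(m["outer"]),
                 inner_diameter = unname(m["inner"]),
                 channel_length = chan),
            class = "ring_geometry")
}

#' Summary statistics of a length population
#'
#' Median (exact), modal length estimated as the centre of the highest
#' bin of a Freedman-Diaconis histogram (ties broken toward the smaller
#' length, conservative for growth claims), and the histogram itself.
#'
#' @param pop A [length_population()] or numeric vector of lengths, nm.
#' @return List with `mode`, `median`, `n`, `histogram` (a
#'   [graphics::hist()] object) and `bin_width`.
#' @export
length_stats <- function(pop) {
  x <- if (inherits(pop, "length_population")) pop$lengths else as.numeric(pop)
  stopifnot(length(x) >= 1, all(x > 0))
  if (length(x) == 1 || diff(range(x)) == 0) {
    return(list(mode = x[1], median = x[1], n = length(x),
                histogram = NULL, bin_width = NA_real_))
  }
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(range(x)) / ceiling(sqrt(length(x)))
  breaks <- seq(min(x), max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  top <- which(h$counts == max(h$counts))[1]   # smallest bin on ties
  list(mode = h$mids[top], median = stats::median(x), n = length(x),
       histogram = h, bin_width = bw)
}
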