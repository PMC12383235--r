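#' Filament path (ordered polyline in physical coordinates)
#'
#' An ordered set of points, in nm, tracing the long axis of an
#' elongated assembly.  End ordering is stable: the lexicographically
#' smaller endpoint comes first.
#'
#' @param points Numeric matrix, one row per point, 2 or 3 columns (nm).
#' @param branch_flag Whether the traced skeleton was branched (the
#'   longest branch is kept).
#' @param border_flag Whether the object touched the field border (its
#'   length is censored).
#' @return Object of class `filament_path` with fields `points`,
#'   `end_a`, `end_b`, `branch_flag`, `border_flag`.
#' @export
filament_path <- function(points, branch_flag = FALSE, border_flag = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2) stop("a path needs at least 2 points")
  if (!ncol(points) %in% c(2L, 3L)) stop("points must be 2D or 3D")
  dup <- rowSums(abs(diff(points))) == 0
  if (any(dup)) points <- points[c(TRUE, !dup), , drop = FALSE]
  if (nrow(points) < 2) stop("degenerate path: all points coincide")
  # stable end ordering: lexicographic smallest endpoint first
  a <- points[1, ]; b <- points[nrow(points), ]
  cmp <- sign(a - b); first_nz <- cmp[cmp != 0]
  if (length(first_nz) && first_nz[1] > 0)
    points <- points[nrow(points):1, , drop = FALSE]
  structure(list(points = points,
                 end_a = points[1, ],
                 end_b = points[nrow(points), ],
                 branch_flag = isTRUE(branch_flag),
                 border_flag = isTRUE(border_flag)),
            class = "filament_path")
}

#' Arc length of a filament path
#'
#' Sum of consecutive point-to-point distances, nm.
#'
#' @param path A [filament_path()] or a point matrix.
#' @return Length in nm.
#' @export
path_length <- function(path) {
  pts <- if (inherits(path, "filament_path")) path$points else as.matrix(path)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# cumulative arc length, one value per vertex (starts at 0)
path_cumlength <- function(pts) {
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# point on the polyline at arc length s (linear interpolation)
path_point_at <- function(pts, s) {
  cl <- path_cumlength(pts)
  s <- min(max(s, 0), cl[length(cl)])
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(i, nrow(pts) - 1L)
  f <- (s - cl[i]) / max(cl[i + 1] - cl[i], .Machine$double.eps)
  pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
}

# unit tangent at arc length s, by central difference over a window
path_tangent_at <- function(pts, s, window = NULL) {
  cl <- path_cumlength(pts)
  total <- cl[length(cl)]
  if (is.null(window)) window <- max(total / 50, 1e-6)
  p1 <- path_point_at(pts, max(s - window / 2, 0))
  p2 <- path_point_at(pts, min(s + window / 2, total))
  v <- p2 - p1
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) c(1, rep(0, length(v) - 1)) else v / n
}

# resample a polyline at (approximately) uniform spacing, keeping ends
resample_path <- function(pts, spacing) {
  cl <- path_cumlength(pts)
  total <- cl[length(cl)]
  s <- unique(c(seq(0, total, by = spacing), total))
  t(vapply(s, function(si) path_point_at(pts, si), numeric(ncol(pts))))
}

#' Persistent random-walk centerline
#'
#' Generates a smoothly curving planar polyline of the requested arc
#' length: a worm-like-chain-style walk whose per-step turning angle is
#' Gaussian with variance `step / persistence_nm`.  Used as the
#' centerline model for curvilinear protofibrils, which show irregular
#' curvature with occasional tighter turns.  When `bounds` is given the
#' heading is steered back toward the box centre as the walk approaches
#' the margin, so generated assemblies stay inside the field.
#'
#' @param total_nm Total arc length, nm.
#' @param step_nm Step (vertex spacing), nm.
#' @param persistence_nm Persistence length, nm.
#' @param start Starting point (x, y), nm.
#' @param heading Initial heading, radians.
#' @param bounds Optional `c(xmin, xmax, ymin, ymax)` steering box, nm.
#' @param margin_nm Distance from the box edge at which steering starts.
#' @return Matrix of points (nm); cumulative arc length is exactly
#'   `step_nm` per segment.
#' @export
persistent_path <- function(total_nm, step_nm = 2, persistence_nm = 250,
                            start = c(0, 0), heading = 0,
                            bounds = NULL, margin_nm = 50) {
  stopifnot(total_nm > 0, step_nm > 0, persistence_nm > 0)
  n <- max(ceiling(total_nm / step_nm), 1L)
  sd_turn <- sqrt(step_nm / persistence_nm)
  pts <- matrix(0, n + 1L, 2)
  pts[1, ] <- start
  th <- heading
  for (i in seq_len(n)) {
    th <- th + stats::rnorm(1, 0, sd_turn)
    if (!is.null(bounds)) {
      p <- pts[i, ]
      d_edge <- min(p[1] - bounds[1], bounds[2] - p[1],
                    p[2] - bounds[3], bounds[4] - p[2])
      if (d_edge < margin_nm) {
        ctr <- c(mean(bounds[1:2]), mean(bounds[3:4]))
        th_ctr <- atan2(ctr[2] - p[2], ctr[1] - p[1])
        w <- (1 - max(d_edge, 0) / margin_nm) * 0.3
        dth <- atan2(sin(th_ctr - th), cos(th_ctr - th))
        th <- th + w * dth
      }
    }
    pts[i + 1L, ] <- pts[i, ] + step_nm * c(cos(th), sin(th))
  }
  pts
}

# minimum distance between path points whose arc-length separation
# exceeds `skip_nm`; used to reject self-intersecting centerlines
min_self_distance <- function(pts, skip_nm) {
  cl <- path_cumlength(pts)
  n <- nrow(pts)
  best <- Inf
  for (i in seq_len(n - 1L)) {
    j <- which(cl > cl[i] + skip_nm)
    if (!length(j)) break
    d2 <- (pts[j, 1] - pts[i, 1])^2 + (pts[j, 2] - pts[i, 2])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# distance from every pixel centre of a nx x ny grid (pixel centres at
# (i - 0.5) * voxel, 1-based) to a polyline; vectorised over pixels,
# looped over segments with a bounding-box cull
polyline_distance_field <- function(pts, nx, ny, voxel, max_dist = Inf) {
  xs <- (seq_len(nx) - 0.5) * voxel
  ys <- (seq_len(ny) - 0.5) * voxel
  px <- matrix(xs, nx, ny)
  py <- matrix(ys, nx, ny, byrow = TRUE)
  d2 <- matrix(Inf, nx, ny)
  pad <- if (is.finite(max_dist)) max_dist + voxel else Inf
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    if (is.finite(pad)) {
      xi <- which(xs >= min(a[1], b[1]) - pad & xs <= max(a[1], b[1]) + pad)
      yi <- which(ys >= min(a[2], b[2]) - pad & ys <= max(a[2], b[2]) + pad)
      if (!length(xi) || !length(yi)) next
    } else { xi <- seq_len(nx); yi <- seq_len(ny) }
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    L2 <- vx^2 + vy^2
    dx <- px[xi, yi, drop = FALSE] - a[1]
    dy <- py[xi, yi, drop = FALSE] - a[2]
    t <- if (L2 > 0) pmin(pmax((dx * vx + dy * vy) / L2, 0), 1) else 0
    seg_d2 <- (dx - t * vx)^2 + (dy - t * vy)^2
    d2[xi, yi] <- pmin(d2[xi, yi, drop = FALSE], seg_d2)
  }
  sqrt(d2)
}
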