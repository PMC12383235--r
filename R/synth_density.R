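# run code with a locally-set RNG seed, restoring global state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Density field (2D image or 3D volume with physical calibration)
#'
#' @param grid Numeric matrix (2D) or 3D array, arbitrary density units.
#' @param voxel_size Voxel edge, nm (> 0); voxel centres sit at
#'   `(i - 0.5) * voxel_size` in each axis.
#' @param origin Physical offset of the grid corner, nm.
#' @return Object of class `density_field`.
#' @export
density_field <- function(grid, voxel_size, origin = NULL) {
  stopifnot(is.numeric(grid), voxel_size > 0)
  nd <- length(dim(grid))
  if (is.null(dim(grid)) || nd < 2 || nd > 3)
    stop("grid must be a 2D matrix or 3D array")
  if (is.null(origin)) origin <- rep(0, nd)
  structure(list(grid = grid, voxel_size = voxel_size, origin = origin),
            class = "density_field")
}

#' Ground-truth description of one synthetic assembly
#'
#' @param kind One of `"oligomer"`, `"curvilinear"`, `"annulus"`,
#'   `"fibril"`.
#' @param centerline Point matrix (nm) for elongated kinds.
#' @param tube_diameter Tube diameter, nm.
#' @param center Ring centre (nm) for annuli.
#' @param ring_outer_diameter,ring_inner_diameter Ring diameters, nm.
#' @param channel_length Axial channel extent, nm (annuli in 3D).
#' @return Object of class `assembly_truth`.
#' @export
assembly_truth <- function(kind, centerline = NULL, tube_diameter = 2.8,
                           center = NULL, ring_outer_diameter = NULL,
                           ring_inner_diameter = NULL, channel_length = NULL) {
  kind <- match.arg(kind, c("oligomer", "curvilinear", "annulus", "fibril"))
  stopifnot(tube_diameter > 0)
  if (kind == "annulus") {
    stopifnot(!is.null(center), !is.null(ring_outer_diameter),
              !is.null(ring_inner_diameter))
    if (ring_inner_diameter <= 0 || ring_inner_diameter >= ring_outer_diameter)
      stop("annulus requires 0 < inner < outer diameter")
    if (is.null(channel_length))
      channel_length <- (ring_outer_diameter - ring_inner_diameter) / 2
  } else {
    centerline <- as.matrix(centerline)
    if (nrow(centerline) < 2) stop("elongated assemblies need a centerline")
    md <- min_self_distance(centerline, skip_nm = 2 * tube_diameter)
    if (is.finite(md) && md < tube_diameter)
      stop("centerline self-intersects within one tube diameter")
  }
  structure(list(kind = kind, centerline = centerline,
                 tube_diameter = tube_diameter, center = center,
                 ring_outer_diameter = ring_outer_diameter,
                 ring_inner_diameter = ring_inner_diameter,
                 channel_length = channel_length),
            class = "assembly_truth")
}

# separable Gaussian blur of a 2D/3D array, sd in voxels
gaussian_blur_field <- function(arr, sd_px) {
  if (sd_px <= 0) return(arr)
  half <- max(ceiling(4 * sd_px), 1L)
  k <- stats::dnorm(-half:half, 0, sd_px)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))  # replicate-pad edges
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  nd <- length(dim(arr))
  if (nd == 2) {
    arr <- apply(arr, 2, conv1)
    arr <- t(apply(arr, 1, conv1))
  } else {
    d <- dim(arr)
    for (ax in 1:3) arr <- aperm(apply(arr, setdiff(1:3, ax), conv1),
                                 order(c(ax, setdiff(1:3, ax))))
    dim(arr) <- d
  }
  arr
}

render_tube_2d <- function(truth, nx, ny, voxel, mode) {
  r <- truth$tube_diameter / 2
  pts <- resample_path(truth$centerline, voxel / 2)
  d <- polyline_distance_field(pts, nx, ny, voxel, max_dist = r + 2 * voxel)
  if (mode == "projection") {
    g <- matrix(0, nx, ny)
    inside <- d < r
    g[inside] <- 2 * sqrt(r^2 - d[inside]^2)
    g / (2 * r)                       # unit peak
  } else {
    (d < r) * 1.0
  }
}

# annuli are rendered with 3x3(x3) subvoxel coverage (anti-aliased):
# point sampling puts hard edges up to a voxel off, which matters for
# sub-voxel ring-geometry recovery
render_annulus_2d <- function(truth, nx, ny, voxel) {
  R <- (truth$ring_outer_diameter + truth$ring_inner_diameter) / 4
  a <- (truth$ring_outer_diameter - truth$ring_inner_diameter) / 4
  sub <- c(-1, 0, 1) * voxel / 3
  g <- matrix(0, nx, ny)
  for (dx in sub) for (dy in sub) {
    xs <- (seq_len(nx) - 0.5) * voxel + dx - truth$center[1]
    ys <- (seq_len(ny) - 0.5) * voxel + dy - truth$center[2]
    s <- sqrt(outer(xs^2, ys^2, "+"))
    g <- g + (abs(s - R) < a)
  }
  g / 9
}

render_assembly_3d <- function(truth, dims, voxel) {
  g <- array(0, dims)
  xs <- (seq_len(dims[1]) - 0.5) * voxel
  ys <- (seq_len(dims[2]) - 0.5) * voxel
  zs <- (seq_len(dims[3]) - 0.5) * voxel
  if (truth$kind == "annulus") {
    R <- (truth$ring_outer_diameter + truth$ring_inner_diameter) / 4
    a <- (truth$ring_outer_diameter - truth$ring_inner_diameter) / 4
    b <- truth$channel_length / 2
    ctr <- truth$center
    if (length(ctr) == 2) ctr <- c(ctr, mean(zs))
    sub <- c(-1, 0, 1) * voxel / 3
    for (k in seq_along(zs)) {
      acc <- matrix(0, dims[1], dims[2])
      for (dx in sub) for (dy in sub) for (dz in sub) {
        s <- sqrt(outer((xs + dx - ctr[1])^2, (ys + dy - ctr[2])^2, "+"))
        z <- zs[k] + dz - ctr[3]
        acc <- acc + (((s - R) / a)^2 + (z / b)^2 < 1)
      }
      g[, , k] <- acc / 27
    }
  } else {
    r <- truth$tube_diameter / 2
    cl <- truth$centerline
    if (ncol(cl) == 2) cl <- cbind(cl, mean(zs))
    pts <- resample_path(cl, voxel / 2)
    d2d <- polyline_distance_field(pts[, 1:2, drop = FALSE],
                                   dims[1], dims[2], voxel,
                                   max_dist = r + 2 * voxel)
    zc <- mean(pts[, 3])
    for (k in seq_along(zs)) {
      dz <- zs[k] - zc
      g[, , k] <- (d2d^2 + dz^2 < r^2) * 1.0
    }
  }
  g
}

# minimum distance between the support outlines of two assemblies
assembly_clearance <- function(t1, t2) {
  outline <- function(tr) {
    if (tr$kind == "annulus") {
      th <- seq(0, 2 * pi, length.out = 72)
      R <- tr$ring_outer_diameter / 2
      cbind(tr$center[1] + R * cos(th), tr$center[2] + R * sin(th))
    } else resample_path(tr$centerline[, 1:2, drop = FALSE], 1)
  }
  p1 <- outline(t1); p2 <- outline(t2)
  reach <- function(tr) if (tr$kind == "annulus") 0 else tr$tube_diameter / 2
  best <- Inf
  for (i in seq_len(nrow(p1)))
    best <- min(best, min(sqrt((p2[, 1] - p1[i, 1])^2 + (p2[, 2] - p1[i, 2])^2)))
  best - reach(t1) - reach(t2)
}

#' Render synthetic assemblies into a density field
#'
#' Tubes (oligomers, curvilinear protofibrils, fibrils) are rendered as
#' constant-density solid cylinders along their centerlines; annuli as
#' tori (elliptical cross-section when `channel_length` differs from the
#' wall thickness).  In 2D, `mode = "slice"` gives the tomographic-slice
#' convention (constant density inside the tube: a plateau profile) and
#' `mode = "projection"` the class-average convention (line integral
#' through the cylinder: a dome profile).  The field is then Gaussian
#' blurred and Gaussian noise is added.  Ground truth is returned
#' unmodified alongside the field.
#'
#' @param assemblies List of [assembly_truth()] objects.
#' @param dims Grid dimensions (length 2 or 3).
#' @param voxel_size Voxel edge, nm.
#' @param blur_sd Gaussian blur SD, nm.
#' @param noise_sd Additive Gaussian noise SD (density units; solid
#'   density is 1).
#' @param seed Integer seed (mandatory).
#' @param mode 2D rendering convention, `"slice"` or `"projection"`.
#' @return List with `field` (a [density_field()]) and `truth`
#'   (the input list).
#' @export
gen_density_field <- function(assemblies, dims, voxel_size,
                              blur_sd = 0.1, noise_sd = 0,
                              seed, mode = c("slice", "projection")) {
  mode <- match.arg(mode)
  stopifnot(voxel_size > 0, blur_sd >= 0, noise_sd >= 0)
  if (missing(seed)) stop("seed is mandatory")
  if (inherits(assemblies, "assembly_truth")) assemblies <- list(assemblies)
  nd <- length(dims)
  stopifnot(nd %in% c(2L, 3L))
  ext <- dims * voxel_size
  for (tr in assemblies) {
    dia <- if (tr$kind == "annulus") tr$ring_outer_diameter else tr$tube_diameter
    pts <- if (tr$kind == "annulus") matrix(tr$center[1:2], 1) else tr$centerline[, 1:2, drop = FALSE]
    lo <- apply(pts, 2, min) - dia
    hi <- apply(pts, 2, max) + dia
    if (any(lo < 0) || any(hi > ext[1:2]))
      stop("assembly does not fit inside the field with a one-diameter margin")
  }
  if (length(assemblies) > 1) {
    for (i in seq_len(length(assemblies) - 1)) for (j in (i + 1):length(assemblies)) {
      cl <- assembly_clearance(assemblies[[i]], assemblies[[j]])
      dia <- max(assemblies[[i]]$tube_diameter, assemblies[[j]]$tube_diameter)
      if (cl < dia)
        stop("two assemblies lie closer than one tube diameter: tracing ground truth is ambiguous")
    }
  }
  g <- if (nd == 2) matrix(0, dims[1], dims[2]) else array(0, dims)
  for (tr in assemblies) {
    g <- g + if (nd == 2) {
      if (tr$kind == "annulus") render_annulus_2d(tr, dims[1], dims[2], voxel_size)
      else render_tube_2d(tr, dims[1], dims[2], voxel_size, mode)
    } else render_assembly_3d(tr, dims, voxel_size)
  }
  g <- gaussian_blur_field(g, blur_sd / voxel_size)
  if (noise_sd > 0)
    g <- g + with_seed(seed, array(stats::rnorm(length(g), 0, noise_sd), dim(g)))
  g <- array(as.numeric(g), dims)
  list(field = density_field(g, voxel_size), truth = assemblies)
}
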