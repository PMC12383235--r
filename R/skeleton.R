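# Morphological skeletonization (Zhang-Suen thinning) and longest
# geodesic path extraction for filament tracing.

shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0L, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Automatic foreground threshold for tracing: robust background
# statistics (the background dominates every modality here).  The
# threshold clears the noise floor by 3 MADs and sits at least 10% of
# the amplitude above the background median, so faint tip-broadened
# wings survive at coarse AFM pixel sizes while strong pixel noise in
# low-SNR density fields stays below it.
auto_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(rng[1])
  bg_med <- stats::median(img)
  bg_mad <- stats::mad(img)
  bg_med + max(3 * bg_mad, 0.1 * (rng[2] - bg_med))
}

# Zhang-Suen thinning of a binary matrix; returns a 1-px-wide skeleton
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift_mat(img, -1, 0); p3 <- shift_mat(img, -1, 1)
      p4 <- shift_mat(img, 0, 1);  p5 <- shift_mat(img, 1, 1)
      p6 <- shift_mat(img, 1, 0);  p7 <- shift_mat(img, 1, -1)
      p8 <- shift_mat(img, 0, -1); p9 <- shift_mat(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

# longest geodesic path through a skeleton (double-sweep shortest
# paths on the 8-connected pixel graph, diagonal steps weighted sqrt(2));
# returns list(rc = matrix of row/col indices, branched = logical)
skeleton_longest_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(NULL)
  if (n == 1) return(list(rc = idx, branched = FALSE))
  key <- idx[, 1] + nrow(skel) * (idx[, 2] - 1L)
  lut <- integer(nrow(skel) * ncol(skel)); lut[key] <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb_r <- idx[, 1] + d[1]; nb_c <- idx[, 2] + d[2]
    ok <- nb_r >= 1 & nb_r <= nrow(skel) & nb_c >= 1 & nb_c <= ncol(skel)
    nb_key <- nb_r + nrow(skel) * (nb_c - 1L)
    hit <- logical(n)
    hit[ok] <- skel[cbind(nb_r[ok], nb_c[ok])]
    if (any(hit)) {
      from <- c(from, which(hit))
      to <- c(to, lut[nb_key[hit]])
      w <- c(w, rep(sqrt(sum(d^2)), sum(hit)))
    }
  }
  deg <- tabulate(c(from, to), nbins = n)
  branched <- any(deg > 2)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vm <- which(comp$membership == main)
  d1 <- igraph::distances(g, v = vm[1])[1, ]
  u <- which.max(ifelse(is.finite(d1), d1, -1))
  d2 <- igraph::distances(g, v = u)[1, ]
  v <- which.max(ifelse(is.finite(d2), d2, -1))
  sp <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1]]
  list(rc = idx[as.integer(sp), , drop = FALSE], branched = branched)
}

# subpixel ridge refinement: move each path vertex to the
# intensity-weighted centroid of the perpendicular profile, so arc
# lengths are not inflated by pixel-grid staircasing
refine_ridge <- function(pts, img, voxel, threshold, half_px = 2.5) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  offs <- seq(-half_px, half_px, by = 0.5) * voxel
  interp <- function(x, y) {
    fi <- pmin(pmax(x / voxel + 0.5, 1), nrow(img) - 1e-9)
    fj <- pmin(pmax(y / voxel + 0.5, 1), ncol(img) - 1e-9)
    i0 <- pmin(floor(fi), nrow(img) - 1); j0 <- pmin(floor(fj), ncol(img) - 1)
    fx <- fi - i0; fy <- fj - j0
    img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
      img[cbind(i0 + 1, j0)] * fx * (1 - fy) +
      img[cbind(i0, j0 + 1)] * (1 - fx) * fy +
      img[cbind(i0 + 1, j0 + 1)] * fx * fy
  }
  out <- pts
  for (i in 2:(n - 1)) {
    tg <- pts[min(i + 1, n), ] - pts[max(i - 1, 1), ]
    nt <- sqrt(sum(tg^2))
    if (nt < .Machine$double.eps) next
    nv <- c(-tg[2], tg[1]) / nt
    v <- interp(pts[i, 1] + offs * nv[1], pts[i, 2] + offs * nv[2])
    w <- pmax(v - threshold, 0)
    if (sum(w) > 0) out[i, ] <- pts[i, ] + nv * sum(w * offs) / sum(w)
  }
  out
}

# centred running mean of path coordinates, endpoints kept
smooth_path_coords <- function(pts, window) {
  if (window < 3 || nrow(pts) <= window) return(pts)
  if (window %% 2 == 0) window <- window + 1
  k <- rep(1 / window, window)
  sm <- apply(pts, 2, function(v) {
    s <- stats::filter(v, k, sides = 2)
    s[is.na(s)] <- v[is.na(s)]
    as.numeric(s)
  })
  sm[1, ] <- pts[1, ]; sm[nrow(pts), ] <- pts[nrow(pts), ]
  sm
}
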