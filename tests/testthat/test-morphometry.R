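test_that("a straight noiseless tube traces to one path of the right length", {
  r <- render_straight_tube(48, voxel = 0.5)
  p <- trace_filament(r$field)
  expect_length(p, 1)
  expect_lt(abs(path_length(p[[1]]) - 48), 1)          # within ~1 px
  expect_false(p[[1]]$branch_flag)
  expect_false(p[[1]]$border_flag)
})

test_that("a semicircular tube traces to the analytic arc length", {
  th <- seq(0, pi, length.out = 200); r_arc <- 20
  cl <- cbind(40 + r_arc * cos(th), 30 + r_arc * sin(th))
  tr <- assembly_truth("curvilinear", centerline = cl)
  r <- gen_density_field(list(tr), dims = c(160, 160), voxel_size = 0.5,
                         blur_sd = 0, noise_sd = 0, seed = 1)
  p <- trace_filament(r$field)
  expect_length(p, 1)
  expect_lt(abs(path_length(p[[1]]) / (pi * r_arc) - 1), 0.02)
})

test_that("a featureless field yields no paths", {
  expect_length(trace_filament(matrix(0, 60, 60), voxel_size = 0.5), 0)
})

test_that("border-touching objects are flagged", {
  cl <- cbind(seq(0.5, 30, by = 0.5), rep(10, 60))
  g <- abmorph:::polyline_distance_field(cl, 80, 40, 0.5) < 1.4
  p <- trace_filament(density_field(g * 1, 0.5))
  expect_true(any(vapply(p, `[[`, logical(1), "border_flag")))
})

test_that("branched skeletons return the longest branch with the branch flag", {
  g <- matrix(0, 90, 90)
  g[10:80, 41:49] <- 1                   # main stem, well resolved
  g[41:49, 49:78] <- 1                   # side branch
  p <- trace_filament(density_field(g, 0.5))
  expect_length(p, 1)
  expect_true(p[[1]]$branch_flag)
  expect_gt(path_length(p[[1]]), 30)     # the long stem, not the branch
})

test_that("path_length sums consecutive distances and matches generator bookkeeping", {
  expect_equal(path_length(rbind(c(0, 0), c(10, 0))), 10)
  expect_equal(path_length(cbind(0:100, rep(0, 101))), 100)
  set.seed(5)
  pts <- persistent_path(200, step_nm = 2, persistence_nm = 100)
  # generator arc length is exactly step * n by construction
  expect_equal(path_length(pts), 2 * (nrow(pts) - 1), tolerance = 1e-9)
})

test_that("cross profiles are symmetric with correct baselines", {
  r <- render_straight_tube(48, voxel = 0.25, blur_sd = 0.2)
  p <- trace_filament(r$field)[[1]]
  pr <- cross_profile(r$field, p, station = 24, half_width = 6)
  v <- pr$values
  expect_equal(v, rev(v), tolerance = 0.02 * max(v))
  expect_lt(abs(pr$baseline), 1e-6)
  # constant field: baseline equals the constant, amplitude zero
  cf <- density_field(matrix(5, 100, 100), 0.5)
  pth <- filament_path(rbind(c(10, 25), c(40, 25)))
  prc <- cross_profile(cf, pth, 15, half_width = 5)
  expect_equal(prc$baseline, 5)
  expect_equal(max(prc$values) - prc$baseline, 0)
})

test_that("blurred tube peak height matches a numeric convolution oracle", {
  sigma <- 0.4
  r <- render_straight_tube(48, voxel = 0.1, blur_sd = sigma,
                            mode = "projection")
  p <- trace_filament(r$field)[[1]]
  pr <- cross_profile(r$field, p, station = 24, half_width = 6)
  # oracle: 1D convolution of the normalized dome profile with the
  # Gaussian (valid mid-tube, where the geometry is locally 1D)
  x <- seq(-8, 8, by = 0.001)
  dome <- ifelse(abs(x) < 1.4, sqrt(pmax(1.4^2 - x^2, 0)) / 1.4, 0)
  k <- dnorm(seq(-6 * sigma, 6 * sigma, by = 0.001), 0, sigma)
  oracle <- max(stats::filter(dome, k / sum(k), sides = 2), na.rm = TRUE)
  expect_lt(abs(max(pr$values) / oracle - 1), 0.02)
})

test_that("threshold width of analytic profiles follows the closed forms", {
  # rectangular profile of width w -> w (to sampling resolution)
  prw <- make_profile(function(x) as.numeric(abs(x) <= 3.1))
  expect_lt(abs(diameter_at_threshold(prw) - 6.2), 0.01)
  # Gaussian of SD sigma -> 2 sigma sqrt(2 ln(1/0.15)) ~ 3.8958 sigma
  for (sigma in c(0.7, 1.3, 2.5)) {
    prg <- make_profile(function(x) exp(-x^2 / (2 * sigma^2)))
    expect_equal(diameter_at_threshold(prg),
                 2 * sigma * sqrt(2 * log(1 / 0.15)), tolerance = 1e-6)
  }
  # profile that never exceeds the level
  prf <- make_profile(function(x) rep(0, length(x)))
  expect_error(diameter_at_threshold(prf), "no object")
})

test_that("threshold width is exactly invariant to affine intensity rescaling", {
  prg <- make_profile(function(x) exp(-x^2 / 2))
  d0 <- diameter_at_threshold(prg)
  pr2 <- prg
  pr2$values <- 7.3 * prg$values + 2.1
  pr2$baseline <- 7.3 * prg$baseline + 2.1
  expect_equal(diameter_at_threshold(pr2), d0, tolerance = 1e-12)
})

test_that("traced length is invariant under field rotation", {
  r <- render_straight_tube(40, voxel = 0.5)
  g <- r$field$grid
  l0 <- path_length(trace_filament(density_field(g, 0.5))[[1]])
  g90 <- t(g)[ncol(g):1, ]                      # rigid 90-degree rotation
  l90 <- path_length(trace_filament(density_field(g90, 0.5))[[1]])
  expect_lt(abs(l0 - l90), 0.5)
})

test_that("AFM heights recover the tube diameter after plane flattening", {
  pars <- growth_sim_params(rate_end_a = 2, rate_end_b = 2, n_frames = 1,
                            pixel_size = 2, roughness_sd = 0,
                            field_nm = 400)
  sim <- gen_afm_series(pars, initial_length = 30, seed = 4)
  f <- sim$series$frames[[1]]
  p <- trace_filament(f, voxel_size = 2)[[1]]
  h <- afm_height(f, p, station = path_length(p) / 2, pixel_size = 2)
  expect_equal(h, 2.8, tolerance = 0.05)
  # a 6-nm fibril
  pars6 <- growth_sim_params(rate_end_a = 2, rate_end_b = 2, n_frames = 1,
                             pixel_size = 2, roughness_sd = 0.05,
                             tube_diameter = 6, field_nm = 400)
  sim6 <- gen_afm_series(pars6, initial_length = 100, seed = 5)
  p6 <- trace_filament(sim6$series$frames[[1]], voxel_size = 2)[[1]]
  h6 <- afm_height(sim6$series$frames[[1]], p6,
                   station = path_length(p6) / 2, pixel_size = 2)
  expect_equal(h6, 6, tolerance = 0.2)
  # a tilted support plane does not change the height
  tilt <- outer(seq_len(nrow(f)), seq_len(ncol(f)),
                function(i, j) i * 2 / 783)     # 1 nm per 783 nm
  h_t <- afm_height(f + tilt, p, station = path_length(p) / 2,
                    pixel_size = 2)
  expect_equal(h_t, h, tolerance = 0.02)
})

test_that("ring geometry recovers noiseless torus parameters within a voxel", {
  an <- assembly_truth("annulus", center = c(10, 10, 6.4),
                       ring_outer_diameter = 7.5, ring_inner_diameter = 2.0)
  r <- gen_density_field(list(an), dims = c(80, 80, 52), voxel_size = 0.25,
                         blur_sd = 0, noise_sd = 0, seed = 2)
  rg <- ring_geometry(r$field, c(10, 10, 6.4))
  expect_lt(abs(rg$outer_diameter - 7.5), 0.25)
  expect_lt(abs(rg$inner_diameter - 2.0), 0.25)
  expect_lt(rg$inner_diameter, rg$outer_diameter)
})

test_that("a solid disc raises the no-channel error", {
  x <- (1:160 - 0.5) * 0.25 - 20
  d <- sqrt(outer(x^2, x^2, "+"))
  disc <- density_field((d < 3) * 1, 0.25)
  expect_error(ring_geometry(disc, c(20, 20)), "no channel")
})

test_that("length statistics: median exact, FD mode within 15%, conservative ties", {
  expect_equal(length_stats(42)$mode, 42)
  expect_equal(length_stats(42)$median, 42)
  set.seed(31)
  x <- stats::rlnorm(500, log(110) + 0.35^2, 0.35)   # analytic mode 110
  st <- length_stats(x)
  expect_equal(st$median, stats::median(x))
  expect_lt(abs(st$mode / 110 - 1), 0.15)
  # tie-break: equal-count histogram modes report the lower bin
  y <- c(seq(0.9, 1.1, length.out = 5), seq(9.9, 10.1, length.out = 5))
  st2 <- length_stats(y)
  expect_equal(max(st2$histogram$counts),
               st2$histogram$counts[findInterval(st2$mode, st2$histogram$breaks)])
  expect_lt(st2$mode, stats::median(y))
})

test_that("estimated modes increase monotonically across a growth time course", {
  pops <- gen_length_population(c(28, 30, 32, 34, 36),
                                c(5, 55, 110, 170, 225),
                                dispersion = 0.35, n_per_t = 150, seed = 11)
  modes <- vapply(pops, function(p) length_stats(p)$mode, numeric(1))
  expect_true(all(diff(modes) > 0))
})
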