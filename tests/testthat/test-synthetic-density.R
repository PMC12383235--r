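test_that("an unblurred straight tube renders as a 2.8 nm plateau in slice mode", {
  r <- render_straight_tube(48, 2.8, voxel = 0.2, blur_sd = 0)
  g <- r$field$grid
  j_mid <- round(ncol(g) / 2)
  col <- g[round(nrow(g) / 2), ]
  on <- which(col == 1)
  expect_true(length(on) > 0)
  width <- (max(on) - min(on) + 1) * 0.2
  expect_lt(abs(width - 2.8), 2 * 0.2)
  expect_true(all(col %in% c(0, 1)))
})

test_that("a torus central-slice profile shows peaks separated by the midline diameter", {
  an <- assembly_truth("annulus", center = c(15, 15),
                       ring_outer_diameter = 7.5, ring_inner_diameter = 2.0)
  r <- gen_density_field(list(an), dims = c(120, 120), voxel_size = 0.25,
                         blur_sd = 0.2, noise_sd = 0, seed = 1)
  g <- r$field$grid
  j <- round(15 / 0.25 + 0.5)
  prof <- g[, j]
  xs <- (seq_along(prof) - 0.5) * 0.25 - 15
  left <- which(xs < 0); right <- which(xs > 0)
  sep <- xs[right[which.max(prof[right])]] - xs[left[which.max(prof[left])]]
  expect_lt(abs(sep - (7.5 + 2.0) / 2), 2 * 0.25)   # analytic midline: 4.75 nm
})

test_that("rendered tube lengths are recovered by tracing across a lognormal population", {
  set.seed(99)
  lens <- stats::rlnorm(12, log(40), 0.3)
  lens <- pmin(pmax(lens, 15), 90)
  rec <- vapply(seq_along(lens), function(i) {
    r <- render_straight_tube(lens[i], voxel = 0.5, blur_sd = 0.1, seed = i)
    p <- trace_filament(r$field)
    expect_length(p, 1)
    path_length(p[[1]])
  }, numeric(1))
  # end localization is good to ~2 voxels per tip
  expect_true(all(abs(rec - lens) <= 2))
})

test_that("assemblies that overlap or exit the field are rejected", {
  cl1 <- cbind(seq(10, 30, by = 0.5), rep(15, 41))
  cl2 <- cbind(seq(10, 30, by = 0.5), rep(16.5, 41))   # 1.5 nm away
  t1 <- assembly_truth("curvilinear", centerline = cl1)
  t2 <- assembly_truth("curvilinear", centerline = cl2)
  expect_error(gen_density_field(list(t1, t2), dims = c(80, 80),
                                 voxel_size = 0.5, seed = 1),
               "closer than one tube diameter")
  t3 <- assembly_truth("curvilinear",
                       centerline = cbind(seq(0.5, 20, by = 0.5),
                                          rep(5, 40)))
  expect_error(gen_density_field(list(t3), dims = c(50, 50),
                                 voxel_size = 0.5, seed = 1),
               "margin")
})

test_that("a self-intersecting centerline is rejected as ambiguous ground truth", {
  th <- seq(0, 2.2 * pi, length.out = 200)     # closes on itself
  cl <- cbind(20 + 8 * cos(th), 20 + 8 * sin(th))
  expect_error(assembly_truth("curvilinear", centerline = cl),
               "self-intersects")
})

test_that("density generation is deterministic in the seed", {
  mk <- function(s) render_straight_tube(30, noise_sd = 0.1, seed = s)$field$grid
  expect_identical(mk(7), mk(7))
  expect_false(identical(mk(7), mk(8)))
})
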