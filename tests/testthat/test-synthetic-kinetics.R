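test_that("the logistic steepness places the 10% crossing exactly at the lag end", {
  cv <- gen_tht_curve(lag_h = 28, midpoint_h = 50, plateau = 100,
                      t_grid = seq(0, 150, by = 0.5))
  # analytic: f(28)/plateau = 0.1 by construction
  k <- log(9) / (50 - 28)
  expect_equal(100 / (1 + exp(-k * (28 - 50))), 10, tolerance = 1e-12)
  lt <- lag_end_time(cv, smooth_window = 1L)
  expect_lt(abs(lt$lag_end - 28), 0.01)
  expect_lt(abs(lt$midpoint - 50), 0.01)
})

test_that("a zero-plateau curve is flat and downstream detectors refuse it", {
  cv <- gen_tht_curve(plateau = 0)
  expect_true(all(cv$f == 0))
  expect_error(lag_end_time(cv), "flat|transition")
  expect_error(normalize_curve(cv), "flat|transition")
})

test_that("lag detection stays within an hour under 1% plateau noise", {
  errs <- vapply(1:100, function(s) {
    cv <- gen_tht_curve(lag_h = 28, midpoint_h = 50, plateau = 100,
                        noise_sd = 1, t_grid = seq(0, 150, by = 0.5),
                        seed = s)
    tryCatch(lag_end_time(cv)$lag_end - 28, error = function(e) NA_real_)
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_true(all(abs(errs) <= 1))
})

test_that("lognormal populations have the requested analytic modes", {
  # zero dispersion collapses to a point mass at the mode
  p0 <- gen_length_population(28, 5, dispersion = 0, n_per_t = 50, seed = 1)
  expect_true(all(p0[[1]]$lengths == 5))
  # large-sample density peak sits at the requested mode
  pops <- gen_length_population(c(30, 34), c(55, 170), dispersion = 0.35,
                                n_per_t = 20000, seed = 2)
  for (i in 1:2) {
    d <- stats::density(pops[[i]]$lengths, n = 2048)
    expect_lt(abs(d$x[which.max(d$y)] / c(55, 170)[i] - 1), 0.05)
  }
})

test_that("small populations trigger the unstable-mode warning", {
  expect_warning(gen_length_population(28, 5, n_per_t = 10, seed = 3),
                 "unstable")
})

test_that("mode recovery from n = 100 samples lands within 15% in most replicates", {
  # the FD-histogram mode carries a median-ward bias on skewed samples
  # of this size; simulation puts the 15% hit rate near 80%
  hits <- vapply(1:60, function(s) {
    pop <- gen_length_population(30, 110, dispersion = 0.35,
                                 n_per_t = 100, seed = s)[[1]]
    abs(length_stats(pop)$mode / 110 - 1) <= 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})
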