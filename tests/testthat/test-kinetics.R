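test_that("amplitude normalization maps flat tails to exactly 0 and 1", {
  t <- seq(0, 100, by = 0.5)
  f <- numeric(length(t))
  f[t > 30 & t < 60] <- 50 / (1 + exp(-(t[t > 30 & t < 60] - 45)))
  f[t >= 60] <- 50
  cv <- kinetic_curve(t, f)
  nc <- normalize_curve(cv)
  expect_equal(min(nc$f), 0)
  expect_equal(max(nc$f), 1)
})

test_that("normalization is invariant to affine transforms of the signal", {
  cv <- gen_tht_curve(lag_h = 28, midpoint_h = 50, plateau = 100,
                      noise_sd = 1, seed = 9)
  cv2 <- kinetic_curve(cv$t, 3.7 * cv$f + 120)
  expect_equal(normalize_curve(cv)$f, normalize_curve(cv2)$f,
               tolerance = 1e-12)
})

test_that("normalized noisy plateaus land near one", {
  for (s in 1:5) {
    cv <- gen_tht_curve(lag_h = 28, midpoint_h = 50, plateau = 100,
                        noise_sd = 1, seed = s)
    nc <- normalize_curve(cv)
    tail_mean <- mean(nc$f[nc$t > 90])
    expect_true(tail_mean > 0.97 && tail_mean < 1.03)
  }
})

test_that("the 50% threshold on a symmetric logistic returns the midpoint", {
  cv <- gen_tht_curve(lag_h = 28, midpoint_h = 50, plateau = 100,
                      t_grid = seq(0, 150, by = 0.5))
  lt <- lag_end_time(cv, threshold_fraction = 0.5, smooth_window = 1L)
  expect_lt(abs(lt$lag_end - 50), 0.01)
})

test_that("curves that start above threshold are rejected", {
  cv <- kinetic_curve(seq(0, 10, by = 0.5), seq(50, 100, length.out = 21))
  expect_error(lag_end_time(cv), "above the threshold")
})

test_that("Fluo-4 influx normalization is (F/F0) - 1", {
  expect_equal(normalize_influx(c(5, 5, 5), 5), c(0, 0, 0))
  expect_equal(normalize_influx(10, 5), 1)
  step <- c(rep(2, 5), rep(10, 5))             # ionomycin-like 5x step
  expect_equal(normalize_influx(step, 2), c(rep(0, 5), rep(4, 5)))
  expect_error(normalize_influx(1:3, 0), "positive")
})

test_that("growth tracks conserve length: initial + end excursions = total", {
  for (s in c(2, 6)) {
    pars <- growth_sim_params(rate_end_a = 7.9, rate_end_b = 8.0,
                              n_frames = 5, pixel_size = 12,
                              roughness_sd = 0.05)
    sim <- gen_afm_series(pars, initial_length = 20, seed = s)
    tk <- track_growth(sim$series)
    resid <- tk$total_length -
      (tk$total_length[1] + tk$end_a_excursion + tk$end_b_excursion)
    expect_true(all(abs(resid) <= 2 * pars$pixel_size))
  }
})

test_that("zero growth yields excursions within noise of zero", {
  pars <- growth_sim_params(rate_end_a = 0, rate_end_b = 0, n_frames = 4,
                            pixel_size = 12, roughness_sd = 0.05,
                            field_nm = 600)
  sim <- gen_afm_series(pars, initial_length = 60, seed = 8)
  tk <- track_growth(sim$series)
  expect_true(all(abs(tk$end_a_excursion) <= 2 * pars$pixel_size))
  expect_true(all(abs(tk$end_b_excursion) <= 2 * pars$pixel_size))
})

test_that("asymmetric growth is recovered with the right end ratio", {
  pars <- growth_sim_params(rate_end_a = 18.5, rate_end_b = 9.6,
                            n_frames = 5, pixel_size = 12,
                            roughness_sd = 0.05, field_nm = 1500)
  sim <- gen_afm_series(pars, initial_length = 20, seed = 13)
  tk <- track_growth(sim$series)
  n <- length(tk$timestamps)
  expect_gte(n, 4)
  ratio <- max(tk$end_a_excursion[n], tk$end_b_excursion[n]) /
    min(tk$end_a_excursion[n], tk$end_b_excursion[n])
  expect_lt(abs(ratio - 18.5 / 9.6), 0.35)
})

test_that("exact linear excursions fit to the exact slope with r2 = 1", {
  tk <- structure(list(timestamps = seq(0, 40, by = 8),
                       total_length = 20 + 16 * seq(0, 40, by = 8),
                       end_a_excursion = 8 * seq(0, 40, by = 8),
                       end_b_excursion = 8 * seq(0, 40, by = 8),
                       anchor = c(0, 0), initial_length = 20,
                       truncated = FALSE),
                  class = "growth_track")
  gr <- fit_growth_rates(tk)
  expect_equal(gr$rate_a, 8, tolerance = 1e-12)
  expect_equal(gr$r_squared_a, 1, tolerance = 1e-9)
  expect_equal(gr$monomers_per_min_a, 8 / 0.48, tolerance = 1e-12)
})

test_that("growth-rate fitting is exactly equivariant to time rescaling", {
  set.seed(3)
  t0 <- seq(0, 40, by = 8)
  exc <- 8 * t0 + rnorm(6, 0, 3)
  mk <- function(tt) structure(
    list(timestamps = tt, total_length = 20 + 2 * exc,
         end_a_excursion = exc, end_b_excursion = exc,
         anchor = c(0, 0), initial_length = 20, truncated = FALSE),
    class = "growth_track")
  r1 <- fit_growth_rates(mk(t0))
  r2 <- fit_growth_rates(mk(3 * t0))
  expect_equal(r2$rate_a, r1$rate_a / 3, tolerance = 1e-12)
})

test_that("too few frames cannot be fitted", {
  tk <- structure(list(timestamps = c(0, 8), total_length = c(20, 40),
                       end_a_excursion = c(0, 10),
                       end_b_excursion = c(0, 10),
                       anchor = c(0, 0), initial_length = 20,
                       truncated = TRUE),
                  class = "growth_track")
  expect_error(fit_growth_rates(tk), "3 frames")
})
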