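test_that("open-level current is g x V away from transitions", {
  pars <- channel_sim_params(conductance_levels = 320, baseline_sd = 0,
                             drift_amplitude = 0,
                             voltage_protocol = list(c(3000, 80)))
  sim <- gen_current_trace(pars, duration_ms = 20000, seed = 1)
  st <- sim$states
  # samples deep inside open dwells (10 samples from any transition)
  # margin > filter length: the zero-phase FIR rings near transitions
  r <- rle(st)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  deep <- unlist(lapply(which(r$values > 0 & r$lengths > 110), function(k)
    (starts[k] + 50):(ends[k] - 50)))
  expect_gt(length(deep), 100)
  expect_equal(unname(sim$trace$i_pA[deep]),
               rep(25.6, length(deep)), tolerance = 1e-3)
})

test_that("polarity symmetry: the same channel gives positive conductance at both signs", {
  pars <- channel_sim_params(baseline_sd = 0, drift_amplitude = 0)
  sim <- gen_current_trace(pars, duration_ms = 22000, seed = 2)
  g <- conductance_series(sim$trace)
  open_neg <- sim$states > 0 & sim$trace$v_mV == -80
  open_pos <- sim$states > 0 & sim$trace$v_mV == 80
  expect_gt(median(g[open_neg], na.rm = TRUE), 300)
  expect_gt(median(g[open_pos], na.rm = TRUE), 300)
})

test_that("an always-closed channel produces baseline only", {
  pars <- channel_sim_params(open_rate = 0, baseline_sd = 0.5,
                             drift_amplitude = 0)
  sim <- gen_current_trace(pars, duration_ms = 11000, seed = 3)
  expect_true(all(sim$states == 0L))
  expect_lt(max(abs(sim$trace$i_pA)), 3)       # noise only
})

test_that("fast symmetric gating reaches the stationary open probability 1/2", {
  pars <- channel_sim_params(open_rate = 50, close_rate = 50,
                             baseline_sd = 0, drift_amplitude = 0)
  sim <- gen_current_trace(pars, duration_ms = 60000, seed = 4)
  p_open <- mean(sim$states > 0)
  n_dwell <- 60 * 50                           # ~ independent dwell pairs
  expect_lt(abs(p_open - 0.5), 3 / sqrt(n_dwell))
})

test_that("a zero-voltage protocol warns that conductance is unobservable", {
  pars <- channel_sim_params(voltage_protocol = list(c(1000, 0)))
  expect_warning(gen_current_trace(pars, duration_ms = 2000, seed = 5),
                 "unobservable")
})

test_that("trace simulation is deterministic in the seed and covers a protocol cycle", {
  pars <- channel_sim_params()
  expect_error(gen_current_trace(pars, duration_ms = 2000, seed = 1),
               "protocol cycle")
  a <- gen_current_trace(pars, duration_ms = 11000, seed = 6)
  b <- gen_current_trace(pars, duration_ms = 11000, seed = 6)
  expect_identical(a$trace$i_pA, b$trace$i_pA)
  expect_identical(a$states, b$states)
})
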