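test_that("conductance is current over voltage with the polarity convention", {
  n <- 20
  tr <- current_trace(seq(0, by = 0.5, length.out = n), rep(25.6, n),
                      rep(80, n), 2000)
  expect_equal(conductance_series(tr), rep(320, n))
  tr2 <- current_trace(seq(0, by = 0.5, length.out = n), rep(-25.6, n),
                       rep(-80, n), 2000)
  expect_equal(conductance_series(tr2), rep(320, n))
})

test_that("near-zero-voltage samples are masked, not treated as zero conductance", {
  n <- 30
  v <- c(rep(80, 10), rep(0, 10), rep(-80, 10))
  i <- c(rep(25.6, 10), rep(0, 10), rep(-25.6, 10))
  tr <- current_trace(seq(0, by = 0.5, length.out = n), i, v, 2000)
  g <- conductance_series(tr)
  expect_true(all(is.na(g[11:20])))
  expect_true(all(g[c(1:10, 21:30)] == 320))
  tr0 <- current_trace(seq(0, by = 0.5, length.out = n), i, rep(0, n), 2000)
  expect_error(conductance_series(tr0), "no polarized")
})

test_that("idealization recovers the state sequence at high accuracy", {
  pars <- channel_sim_params(baseline_sd = 3.2)   # SNR ~ 8 at 80 mV
  sim <- gen_current_trace(pars, duration_ms = 60000, seed = 21)
  id <- idealize(sim$trace)
  expect_length(id$levels_pS, 1)
  expect_lt(abs(id$levels_pS - 320), 15)
  acc <- mean(((id$states > 0) == (sim$states > 0))[id$valid])
  expect_gte(acc, 0.95)
})

test_that("an always-closed trace idealizes to all-closed with zero open probability", {
  pars <- channel_sim_params(open_rate = 0, baseline_sd = 1)
  sim <- gen_current_trace(pars, duration_ms = 11000, seed = 22)
  expect_warning(id <- idealize(sim$trace), "no channel")
  expect_true(all(id$states == 0L))
  expect_equal(id$open_probability, 0)
})

test_that("estimated open probability matches the Markov stationary law", {
  pars <- channel_sim_params(open_rate = 50, close_rate = 50,
                             baseline_sd = 3)
  sim <- gen_current_trace(pars, duration_ms = 60000, seed = 23)
  id <- idealize(sim$trace)
  expect_lt(abs(id$open_probability - 0.5), 3 / sqrt(60 * 50))
})

test_that("windowed modal conductance sits at the true level in nearly all windows", {
  sim <- gen_current_trace(channel_sim_params(), duration_ms = 100000,
                           seed = 24)
  w <- windowed_modal_conductance(sim$trace)
  expect_equal(unique(w$window_length), 2500)
  good <- !w$flagged
  expect_gte(mean(abs(w$modal_g[good] - 320) <= 10), 0.9)
})

test_that("a channel-free trace flags every window with modal zero", {
  pars <- channel_sim_params(open_rate = 0, baseline_sd = 1)
  sim <- gen_current_trace(pars, duration_ms = 22000, seed = 25)
  suppressWarnings(w <- windowed_modal_conductance(sim$trace))
  expect_true(all(w$flagged))
  expect_true(all(w$modal_g == 0))
})

test_that("a two-level channel yields a bimodal histogram with both peaks listed", {
  pars <- channel_sim_params(conductance_levels = c(135, 540))
  sim <- gen_current_trace(pars, duration_ms = 100000, seed = 26)
  id <- idealize(sim$trace)
  expect_length(id$levels_pS, 2)
  w <- windowed_modal_conductance(sim$trace, ideal = id)
  pk <- attr(w, "peaks_pS")
  expect_true(any(abs(pk - 135) <= 15))
  expect_true(any(abs(pk - 540) <= 15))
})

test_that("recording summaries report median, ranges and pore diameters", {
  sim <- gen_current_trace(channel_sim_params(), duration_ms = 50000,
                           seed = 27)
  w <- windowed_modal_conductance(sim$trace)
  s <- ephys_summary(w)
  expect_lt(abs(s$median_modal_g_pS - 320), 15)
  expect_lt(abs(s$d_nm_point - 1.46), 0.1)
  expect_true(all(s$g_typical_pS >= s$g_range_pS[1] &
                    s$g_typical_pS <= s$g_range_pS[2]))
})
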