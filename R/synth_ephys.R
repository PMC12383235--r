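#' Sampled single-channel current trace under a step-voltage protocol
#'
#' @param t_ms Sample times, ms (uniform at `sampling_rate`).
#' @param i_pA Current, pA.
#' @param v_mV Command voltage per sample, mV (|v| <= 200).
#' @param sampling_rate Hz.
#' @param filter_cutoff Low-pass cutoff applied to the recording, Hz
#'   (used to set the minimum resolvable event duration).
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(t_ms, i_pA, v_mV, sampling_rate,
                          filter_cutoff = NA_real_) {
  n <- length(t_ms)
  stopifnot(length(i_pA) == n, length(v_mV) == n, sampling_rate > 0)
  if (any(abs(v_mV) > 200)) stop("|voltage| above 200 mV")
  dt <- diff(t_ms)
  if (n > 1 && any(abs(dt - 1000 / sampling_rate) > 1e-6))
    stop("samples are not uniform at the stated rate")
  structure(list(t_ms = as.numeric(t_ms), i_pA = as.numeric(i_pA),
                 v_mV = as.numeric(v_mV), sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff),
            class = "current_trace")
}

#' Channel gating simulation parameters
#'
#' Two-state (closed/open) continuous-time Markov gating with
#' exponential dwell times; several open conductance levels may share
#' the single closed state, with the level drawn independently at each
#' opening.  Defaults emulate the recording conditions used for
#' Abeta42 channels: 2 kHz sampling, 0.2 kHz low-pass filtering, long
#' open dwells, and a step protocol visiting -80, 0 and +80 mV.
#'
#' @param conductance_levels Open-level conductances, pS (in (0, 2000]).
#' @param level_probs Probability of each level at an opening.
#' @param open_rate,close_rate Opening/closing rates, 1/s.
#' @param baseline_sd Baseline current noise SD, pA.
#' @param drift_amplitude Slow sinusoidal baseline drift amplitude, pA.
#' @param sampling_rate Hz; must exceed `2 * filter_cutoff`.
#' @param filter_cutoff Low-pass -3 dB cutoff, Hz (linear-phase FIR).
#' @param voltage_protocol List of `c(duration_ms, mV)` segments,
#'   cycled for the duration of the trace.
#' @return List of class `channel_sim_params`.
#' @export
channel_sim_params <- function(conductance_levels = 320,
                               level_probs = NULL,
                               open_rate = 5, close_rate = 5,
                               baseline_sd = 3, drift_amplitude = 0.5,
                               sampling_rate = 2000, filter_cutoff = 200,
                               voltage_protocol = list(c(2500, -80),
                                                       c(500, 0),
                                                       c(2500, 80))) {
  stopifnot(all(conductance_levels > 0), all(conductance_levels <= 2000),
            open_rate >= 0, close_rate > 0,
            baseline_sd >= 0, drift_amplitude >= 0,
            sampling_rate > 2 * filter_cutoff, filter_cutoff > 0)
  if (is.null(level_probs))
    level_probs <- rep(1 / length(conductance_levels), length(conductance_levels))
  stopifnot(length(level_probs) == length(conductance_levels),
            abs(sum(level_probs) - 1) < 1e-9)
  structure(list(conductance_levels = conductance_levels,
                 level_probs = level_probs,
                 open_rate = open_rate, close_rate = close_rate,
                 baseline_sd = baseline_sd,
                 drift_amplitude = drift_amplitude,
                 sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 voltage_protocol = voltage_protocol),
            class = "channel_sim_params")
}

# voltage per sample from the cycled step protocol
protocol_voltage <- function(protocol, t_ms) {
  durs <- vapply(protocol, `[`, numeric(1), 1)
  vs <- vapply(protocol, `[`, numeric(1), 2)
  cyc <- sum(durs)
  tm <- t_ms %% cyc
  edges <- cumsum(c(0, durs))
  idx <- findInterval(tm, edges, rightmost.closed = FALSE)
  idx[idx > length(vs)] <- length(vs)
  vs[idx]
}

#' Simulate a single-channel current trace
#'
#' Gating is sampled from the continuous-time Markov chain on the time
#' grid; current is `g_state * V(t)` plus sinusoidal drift and Gaussian
#' noise, then zero-phase low-pass filtered at the stated cutoff with a
#' linear-phase FIR filter.  The ground-truth state sequence (0 =
#' closed, k = open at level k) is returned with the trace.
#'
#' @param params [channel_sim_params()].
#' @param duration_ms Trace duration; must cover at least one protocol
#'   cycle.
#' @param seed Integer seed (mandatory).
#' @return List with `trace` (a [current_trace()]), `states`
#'   (integer per sample), and `params`.
#' @export
gen_current_trace <- function(params, duration_ms, seed) {
  stopifnot(inherits(params, "channel_sim_params"))
  if (missing(seed)) stop("seed is mandatory")
  cyc <- sum(vapply(params$voltage_protocol, `[`, numeric(1), 1))
  if (duration_ms < cyc) stop("duration must cover at least one protocol cycle")
  dt_ms <- 1000 / params$sampling_rate
  t_ms <- seq(0, duration_ms - dt_ms, by = dt_ms)
  v <- protocol_voltage(params$voltage_protocol, t_ms)
  if (all(v == 0)) warning("zero voltage throughout: conductance is unobservable")
  n <- length(t_ms)
  with_seed(seed, {
    states <- integer(n)
    if (params$open_rate > 0) {
      p_open <- params$open_rate / (params$open_rate + params$close_rate)
      open <- stats::runif(1) < p_open
      lev <- if (open) sample.int(length(params$conductance_levels), 1,
                                  prob = params$level_probs) else 0L
      t_cur <- 0
      while (t_cur < duration_ms) {
        rate <- if (lev > 0L) params$close_rate else params$open_rate
        dwell <- stats::rexp(1, rate) * 1000
        idx <- which(t_ms >= t_cur & t_ms < t_cur + dwell)
        states[idx] <- lev
        t_cur <- t_cur + dwell
        lev <- if (lev > 0L) 0L else
          sample.int(length(params$conductance_levels), 1,
                     prob = params$level_probs)
      }
    }
    g <- ifelse(states > 0L, params$conductance_levels[pmax(states, 1L)], 0)
    i <- g * v / 1000                                  # pS * mV -> pA
    if (params$drift_amplitude > 0)
      i <- i + params$drift_amplitude * sin(2 * pi * t_ms / 10000)
    if (params$baseline_sd > 0)
      i <- i + stats::rnorm(n, 0, params$baseline_sd)
    if (params$filter_cutoff < params$sampling_rate / 2) {
      w <- params$filter_cutoff / (params$sampling_rate / 2)
      fir <- signal::fir1(32, w)
      fir <- fir / sum(fir)                          # exact unit DC gain
      i <- signal::filtfilt(fir, i)
    }
    list(trace = current_trace(t_ms, i, v, params$sampling_rate,
                               params$filter_cutoff),
         states = states, params = params)
  })
}
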