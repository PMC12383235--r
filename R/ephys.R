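#' Per-sample conductance from a current trace
#'
#' `g = i / v`, in pS, after subtracting a baseline current.  The sign
#' convention makes an open channel positive at both polarities.
#' Samples with `|v| < mask_mV` are masked (`NA`): conductance is
#' unobservable near 0 mV, and masked samples are excluded from
#' statistics rather than treated as zero conductance.
#'
#' @param trace A [current_trace()].
#' @param baseline_pA Baseline (all-closed) current to subtract, pA.
#' @param mask_mV Mask threshold on |v|, mV.
#' @return Numeric vector of conductances, pS, `NA` where masked.
#' @export
conductance_series <- function(trace, baseline_pA = 0, mask_mV = 5) {
  stopifnot(inherits(trace, "current_trace"))
  ok <- abs(trace$v_mV) >= mask_mV
  if (!any(ok)) stop("no polarized epochs: all samples masked")
  g <- rep(NA_real_, length(trace$i_pA))
  g[ok] <- (trace$i_pA[ok] - baseline_pA) / trace$v_mV[ok] * 1000  # pA/mV -> pS
  g
}

#' Idealize a single-channel trace into open/closed states
#'
#' Baseline is the median current over `baseline_window_ms` (an
#' all-closed epoch).  Open levels are found as modes of the
#' baseline-subtracted conductance density; states are assigned by
#' half-amplitude thresholds between adjacent levels, and events
#' shorter than two filter time constants (`2 / (2 pi f_c)`) are merged
#' into their neighbours, since the low-pass filter cannot resolve
#' them.  Masked (near-0 mV) samples carry the previous state forward
#' and are excluded from the open-probability estimate.
#'
#' @param trace A [current_trace()].
#' @param baseline_window_ms `c(start, end)` of an all-closed baseline
#'   window, ms.  By default the near-0 mV epochs of the step protocol
#'   are used: the channel signal vanishes there, so they expose the
#'   amplifier offset and drift regardless of gating.
#' @param mask_mV Voltage mask threshold, mV.
#' @param min_separation_sd Minimum separation of an open level from
#'   baseline, in units of the baseline noise SD (in pS).
#' @return List of class `idealization`: `states` (0 closed, k open at
#'   `levels_pS[k]`), `levels_pS`, `baseline_pA`, `open_probability`,
#'   `noise_sd_pS`, `g_pS`, `valid` (logical mask of polarized
#'   samples).
#' @export
idealize <- function(trace, baseline_window_ms = NULL, mask_mV = 5,
                     min_separation_sd = 4) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(baseline_window_ms)) {
    in_bw <- abs(trace$v_mV) < mask_mV
    if (!any(in_bw)) in_bw <- trace$t_ms <= 250
  } else {
    in_bw <- trace$t_ms >= baseline_window_ms[1] &
      trace$t_ms <= baseline_window_ms[2]
  }
  if (!any(in_bw)) stop("baseline window contains no samples")
  baseline <- stats::median(trace$i_pA[in_bw])
  g <- conductance_series(trace, baseline_pA = baseline, mask_mV = mask_mV)
  valid <- !is.na(g)
  gv <- g[valid]
  v_typ <- stats::median(abs(trace$v_mV[valid]))
  noise_sd_pS <- stats::mad(trace$i_pA[in_bw]) / v_typ * 1000
  # conductance density modes: closed peak near 0 plus open level(s)
  dens <- stats::density(gv, bw = max(noise_sd_pS / 2, 5), n = 1024)
  y <- dens$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[y[pk] >= 0.05 * max(y)]          # drop shoulder/transition modes
  pk <- pk[order(y[pk], decreasing = TRUE)]
  lv <- dens$x[pk]
  levels <- sort(lv[lv > min_separation_sd * noise_sd_pS])
  # suppress shoulder modes closer than the noise scale
  if (length(levels) > 1) {
    keep <- c(TRUE, diff(levels) > 3 * noise_sd_pS)
    levels <- levels[keep]
  }
  if (!length(levels)) {
    warning("no channel detected: no level beyond the noise; all samples closed")
    return(structure(list(states = rep(0L, length(g)),
                          levels_pS = numeric(0), baseline_pA = baseline,
                          open_probability = 0,
                          noise_sd_pS = noise_sd_pS, g_pS = g, valid = valid),
                     class = "idealization"))
  }
  thr <- c((c(0, levels[-length(levels)]) + levels) / 2, Inf)
  st <- rep(0L, length(g))
  sv <- findInterval(gv, thr)               # 0 closed, k open at level k
  st[valid] <- as.integer(sv)
  # carry state across masked epochs
  if (any(!valid)) {
    last <- 0L
    for (i in seq_along(st)) {
      if (valid[i]) last <- st[i] else st[i] <- last
    }
  }
  # enforce the minimum resolvable event duration
  fc <- trace$filter_cutoff
  if (is.finite(fc) && fc > 0) {
    min_samp <- max(1L, ceiling(2 / (2 * pi * fc) * trace$sampling_rate))
    if (min_samp > 1L) {
      r <- rle(st)
      short <- which(r$lengths < min_samp)
      for (s in short) r$values[s] <- if (s > 1) r$values[s - 1] else r$values[min(s + 1, length(r$values))]
      st <- inverse.rle(r)
    }
  }
  structure(list(states = st, levels_pS = levels, baseline_pA = baseline,
                 open_probability = mean(st[valid] > 0L),
                 noise_sd_pS = noise_sd_pS, g_pS = g, valid = valid),
            class = "idealization")
}

#' Windowed modal conductance
#'
#' Splits the trace into consecutive windows (2500 ms by default; the
#' shorter 1000-ms presentation window is available through
#' `window_ms`), histograms the open-state conductance samples in each
#' window (10 pS bins), and reports the centre of the highest bin as
#' the window's modal conductance — the per-window single data point
#' used to summarize a recording.  Windows with no open samples report
#' `modal_g = 0` and are flagged.  Closed samples are excluded by
#' default (`open_only = TRUE`; otherwise the mode is trivially 0);
#' negative conductance samples are clipped into the zero bin rather
#' than discarded so open probability stays unbiased.  Samples within
#' `edge_exclude` samples of a state transition are left out of the
#' histogram (the filter smears them between levels).
#'
#' @param trace A [current_trace()].
#' @param window_ms Window length, ms.
#' @param bin_pS Histogram bin width, pS.
#' @param ideal Optional precomputed [idealize()] result.
#' @param open_only Histogram open-state samples only.
#' @param edge_exclude Samples dropped on each side of a transition.
#' @return `data.frame` with one row per window: `window_start`,
#'   `window_length`, `modal_g`, `open_probability`, `n_open`,
#'   `flagged`; the full-trace open-conductance histogram peaks are in
#'   `attr(, "peaks_pS")`.
#' @export
windowed_modal_conductance <- function(trace, window_ms = 2500, bin_pS = 10,
                                       ideal = NULL, open_only = TRUE,
                                       edge_exclude = 3L) {
  stopifnot(inherits(trace, "current_trace"), window_ms > 0, bin_pS > 0)
  dur <- length(trace$i_pA) / trace$sampling_rate * 1000
  if (dur < window_ms) stop("trace shorter than one window")
  if (is.null(ideal)) ideal <- idealize(trace)
  g <- pmax(ideal$g_pS, 0)                  # clip negatives into the zero bin
  use <- ideal$valid
  if (open_only) use <- use & ideal$states > 0L
  if (edge_exclude > 0L) {
    tr <- which(diff(ideal$states) != 0L)
    if (length(tr)) {
      drop <- unique(unlist(lapply(tr, function(i)
        max(1, i - edge_exclude + 1L):min(length(g), i + edge_exclude))))
      use[drop] <- FALSE
    }
  }
  starts <- seq(0, dur - window_ms, by = window_ms)
  rows <- lapply(starts, function(s0) {
    in_w <- trace$t_ms >= s0 & trace$t_ms < s0 + window_ms
    sel <- in_w & use
    n_open <- sum(in_w & ideal$valid & ideal$states > 0L)
    po <- mean(ideal$states[in_w & ideal$valid] > 0L)
    if (!any(sel)) {
      return(data.frame(window_start = s0, window_length = window_ms,
                        modal_g = 0, open_probability = po,
                        n_open = n_open, flagged = TRUE))
    }
    gw <- g[sel]
    breaks <- seq(0, max(gw) + bin_pS, by = bin_pS)
    h <- graphics::hist(gw, breaks = breaks, plot = FALSE)
    data.frame(window_start = s0, window_length = window_ms,
               modal_g = h$mids[which.max(h$counts)],
               open_probability = po, n_open = n_open, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(use)) {
    ga <- g[use]
    breaks <- seq(0, max(ga) + bin_pS, by = bin_pS)
    h <- graphics::hist(ga, breaks = breaks, plot = FALSE)
    loc <- which(diff(sign(diff(c(-1, h$counts, -1)))) == -2)
    big <- loc[h$counts[loc] >= 0.1 * max(h$counts)]
    attr(out, "peaks_pS") <- h$mids[big]
  }
  out
}

#' Summary of a conductance recording
#'
#' Median and spread of the per-window modal conductances, with both
#' the min/max range and the 20th-80th percentile "typical" range, and
#' the corresponding pore diameters under the access-resistance model.
#'
#' @param wstats Result of [windowed_modal_conductance()].
#' @param model A [pore_model()].
#' @return List: `median_modal_g_pS`, `g_range_pS`,
#'   `g_typical_pS` (20-80%), `d_nm_point`, `d_nm_range`,
#'   `d_nm_typical`.
#' @export
ephys_summary <- function(wstats, model = pore_model()) {
  g <- wstats$modal_g[!wstats$flagged]
  if (!length(g)) stop("no unflagged windows")
  med <- stats::median(g)
  rng <- range(g)
  typ <- unname(stats::quantile(g, c(0.2, 0.8)))
  safe_d <- function(x) ifelse(x > 0, hille_diameter(pmax(x, 1e-9), model), NA_real_)
  list(median_modal_g_pS = med, g_range_pS = rng, g_typical_pS = typ,
       d_nm_point = safe_d(med), d_nm_range = safe_d(rng),
       d_nm_typical = safe_d(typ))
}
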