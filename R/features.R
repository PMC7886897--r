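#' Spike times from a voltage trace
#'
#' Upward crossings of the detection threshold with a refractory period;
#' used for counting and timing. Spike-threshold *measurement* is done
#' separately by [ap_threshold()].
#'
#' @param t time base (ms).
#' @param v voltage (mV).
#' @param threshold detection level (mV).
#' @param refractory minimum spike separation (ms).
#' @return Spike times (ms).
#' @export
detect_spikes <- function(t, v, threshold = -20, refractory = 1) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  if (!length(up)) return(numeric(0))
  times <- t[up]
  keep <- c(TRUE, diff(times) >= refractory)
  # enforce refractory sequentially
  out <- numeric(0); last <- -Inf
  for (tt in times) if (tt - last >= refractory) { out <- c(out, tt); last <- tt }
  out
}

#' Action-potential threshold by the second-derivative criterion
#'
#' The threshold is the membrane potential at the maximum of the second
#' time derivative on the rising phase preceding the spike peak (within a
#' 5-ms pre-peak window). The trace is smoothed with a Savitzky-Golay
#' filter (default width 0.3 ms) before differentiation, since the raw
#' second difference at a 0.025-ms step is noise-prone.
#'
#' @param t time base (ms).
#' @param v voltage (mV).
#' @param spike_time time of the spike (ms), e.g. from [detect_spikes()].
#' @param window pre-peak search window (ms).
#' @param smooth_ms Savitzky-Golay window (ms); 0 disables smoothing.
#' @return Threshold voltage (mV), or `NA` with a warning if no rising
#'   phase is found.
#' @export
ap_threshold <- function(t, v, spike_time, window = 5, smooth_ms = 0.3) {
  dt <- t[2] - t[1]
  ipk0 <- which(t >= spike_time)[1]
  if (is.na(ipk0)) { warning("no rising phase found"); return(NA_real_) }
  # locate the actual peak after the detection crossing
  span <- ipk0:min(length(v), ipk0 + round(3 / dt))
  ipk <- span[which.max(v[span])]
  i0 <- max(1, ipk - round(window / dt))
  seg <- v[i0:ipk]
  if (length(seg) < 7 || max(seg) <= seg[1]) {
    warning("no rising phase found"); return(NA_real_)
  }
  if (smooth_ms > 0) {
    np <- max(5, 2 * floor(round(smooth_ms / dt) / 2) + 1)
    if (np < length(seg)) seg <- signal::sgolayfilt(seg, p = 3, n = np)
  }
  d2 <- diff(diff(seg))
  if (max(d2) <= 1e-6) { warning("no rising phase found"); return(NA_real_) }
  idx <- which.max(d2) + 1
  seg[idx]
}

#' Action-potential shape features
#'
#' Amplitude (peak minus threshold), half-width (duration at the midpoint
#' between threshold and peak) and afterhyperpolarization depth (threshold
#' minus post-peak minimum before the next spike).
#'
#' @param t time base (ms).
#' @param v voltage (mV).
#' @param spike_time spike time (ms).
#' @param next_spike time of the following spike (ms) bounding the AHP
#'   search, or `Inf`.
#' @return List with `threshold`, `peak`, `amplitude`, `half_width`, `ahp`
#'   (all mV except `half_width` in ms); `NA` fields for truncated spikes.
#' @export
ap_shape <- function(t, v, spike_time, next_spike = Inf) {
  dt <- t[2] - t[1]
  thr <- ap_threshold(t, v, spike_time)
  if (is.na(thr)) return(list(threshold = NA_real_, peak = NA_real_,
                              amplitude = NA_real_, half_width = NA_real_,
                              ahp = NA_real_))
  ipk0 <- which(t >= spike_time)[1]
  span <- ipk0:min(length(v), ipk0 + round(3 / dt))
  ipk <- span[which.max(v[span])]
  peak <- v[ipk]
  if (ipk >= length(v) - 2)
    return(list(threshold = thr, peak = NA_real_, amplitude = NA_real_,
                half_width = NA_real_, ahp = NA_real_))
  vhalf <- (thr + peak) / 2
  # half-width: crossing times around the peak, linear interpolation
  il <- ipk; while (il > 1 && v[il] > vhalf) il <- il - 1
  ir <- ipk; while (ir < length(v) && v[ir] > vhalf) ir <- ir + 1
  tl <- t[il] + (vhalf - v[il]) / (v[il + 1] - v[il]) * dt
  tr <- t[ir - 1] + (vhalf - v[ir - 1]) / (v[ir] - v[ir - 1]) * dt
  hw <- tr - tl
  iend <- if (is.finite(next_spike)) max(which(t < next_spike)) else length(v)
  ahp_min <- min(v[ipk:iend])
  list(threshold = thr, peak = peak, amplitude = peak - thr,
       half_width = hw, ahp = thr - ahp_min)
}

#' Spike-train statistics
#'
#' @param spikes spike times (ms).
#' @param window `c(t0, t1)` analysis window (ms).
#' @param isi_breaks histogram breaks for the ISI distribution (ms).
#' @return List with `n`, `rate` (Hz, count/duration), `isi` (ms) and
#'   `isi_hist`.
#' @export
train_stats <- function(spikes, window, isi_breaks = seq(0, 500, by = 10)) {
  sp <- spikes[spikes >= window[1] & spikes <= window[2]]
  dur_s <- (window[2] - window[1]) / 1000
  isi <- diff(sp)
  h <- if (length(isi)) graphics::hist(pmin(isi, max(isi_breaks)), breaks = isi_breaks,
                             plot = FALSE)$counts
       else integer(length(isi_breaks) - 1)
  list(n = length(sp), rate = length(sp) / dur_s, isi = isi, isi_hist = h)
}

#' Peri-stimulus time histogram
#'
#' @param trains list of spike-time vectors (one per trial), ms.
#' @param onset stimulus onset (ms); bins are aligned to it.
#' @param bin bin width (ms; 40 by default).
#' @param window `c(lo, hi)` around onset (ms).
#' @param rate return rate (Hz per trial) instead of counts.
#' @return List with `mids` (bin centres relative to onset), `counts`,
#'   `rate` (Hz), `n_trials`.
#' @export
psth <- function(trains, onset, bin = 40, window = c(-1000, 1000),
                 rate = FALSE) {
  breaks <- seq(window[1], window[2], by = bin)
  rel <- unlist(lapply(trains, function(s) s - onset))
  rel <- rel[rel >= window[1] & rel < window[2]]
  counts <- graphics::hist(rel, breaks = breaks, plot = FALSE)$counts
  list(mids = breaks[-1] - bin / 2, counts = counts,
       rate = counts / length(trains) / (bin / 1000),
       n_trials = length(trains), bin = bin)
}

#' Sag and rebound measures for a hyperpolarizing step
#'
#' Sag amplitude is the difference between the early voltage minimum and
#' the late steady-state voltage during the step; the sag decay time
#' constant comes from a single-exponential fit from the minimum to the
#' step offset; rebound is quantified by the first spike delay and first
#' ISI after the step.
#'
#' @param t time base (ms).
#' @param v voltage (mV).
#' @param step_window `c(t_on, t_off)` of the step (ms).
#' @param spikes spike times of the run (for the rebound measures).
#' @return List with `sag_mV`, `sag_tau_ms`, `v_min`, `v_steady`,
#'   `first_spike_delay_ms`, `first_isi_ms`.
#' @export
sag_rebound <- function(t, v, step_window, spikes = numeric(0)) {
  on <- step_window[1]; off <- step_window[2]
  sel <- t >= on & t <= off
  tv <- t[sel]; vv <- v[sel]
  imin <- which.min(vv)
  v_min <- vv[imin]
  v_steady <- mean(vv[tv > off - (off - on) * 0.2])
  sag <- max(0, v_steady - v_min)
  sag_tau <- NA_real_
  if (sag > 0.5 && tv[imin] < off - 50) {
    ft <- tv[imin:length(tv)] - tv[imin]
    fv <- vv[imin:length(vv)]
    fit <- try(nls(fv ~ a - b * exp(-ft / tau),
                   start = list(a = v_steady, b = sag, tau = 100),
                   control = list(warnOnly = TRUE)), silent = TRUE)
    if (!inherits(fit, "try-error")) sag_tau <- coef(fit)[["tau"]]
  }
  reb <- spikes[spikes > off]
  list(sag_mV = sag, sag_tau_ms = sag_tau, v_min = v_min,
       v_steady = v_steady,
       first_spike_delay_ms = if (length(reb)) reb[1] - off else NA_real_,
       first_isi_ms = if (length(reb) > 1) reb[2] - reb[1] else NA_real_)
}

#' Firing pause after a depolarizing step
#'
#' Time from the step offset to the first spike that resumes baseline
#' firing (the first post-offset interval exceeding the baseline mean
#' ISI marks the pause; with immediate resumption the pause is about one
#' baseline ISI).
#'
#' @param spikes spike times (ms).
#' @param offset step offset time (ms).
#' @param baseline_isi mean ISI of unperturbed firing (ms).
#' @return Pause duration (ms), or `NA` if firing never resumes.
#' @export
pause_length <- function(spikes, offset, baseline_isi) {
  post <- spikes[spikes > offset]
  if (!length(post)) return(NA_real_)
  post[1] - offset
}

#' Feature errors in units of experimental SEM
#'
#' For each target feature: `|model - mean| / SEM`; missing model values
#' (`NA`) receive a large penalty.
#'
#' @param values named numeric vector of model feature values.
#' @param targets data frame with columns `feature`, `mean`, `sem`.
#' @param penalty score assigned to missing features.
#' @return Named vector of SEM-normalized errors.
#' @export
fitness <- function(values, targets, penalty = 250) {
  stopifnot(all(targets$sem > 0))
  err <- numeric(nrow(targets))
  names(err) <- targets$feature
  for (i in seq_len(nrow(targets))) {
    x <- values[[targets$feature[i]]]
    err[i] <- if (is.null(x) || is.na(x)) penalty
              else abs(x - targets$mean[i]) / targets$sem[i]
  }
  err
}

#' Input-output gain curves
#'
#' For current steps: least-squares slope of firing frequency versus
#' injected current over the positive steps (Hz/pA). For synaptic trains:
#' output burst frequency versus input frequency.
#'
#' @param x input values (pA or Hz).
#' @param y output firing rates (Hz).
#' @return List with `slope` (Hz/pA) and the fitted line.
#' @export
io_gain_curve <- function(x, y) {
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       x = x, y = y)
}

#' Four-parameter logistic fit of a gain curve in log-frequency
#'
#' `gain(f) = lo + (hi - lo) / (1 + exp(-(log f - log f50)/s))`; the
#' half-maximal frequency `f50` is the midpoint between the plateaus.
#'
#' @param freq stimulation frequencies (Hz).
#' @param gain gains.
#' @return List with `f50`, `lo`, `hi`, `slope`, and fitted values; `f50`
#'   is `NA` (with a warning) for flat curves.
#' @export
gain_sigmoid_fit <- function(freq, gain) {
  stopifnot(length(freq) >= 4)
  if (diff(range(gain)) < 0.05) {
    warning("flat gain curve: half-frequency undefined")
    return(list(f50 = NA_real_, lo = mean(gain), hi = mean(gain),
                slope = NA_real_, fitted = rep(mean(gain), length(gain))))
  }
  lf <- log10(freq)
  mid <- (min(gain) + max(gain)) / 2
  l50_0 <- lf[which.min(abs(gain - mid))]
  fit <- NULL
  for (s0 in c(0.15, 0.3, 0.6)) {
    fit <- tryCatch(minpack.lm::nlsLM(
      gain ~ lo + (hi - lo) / (1 + exp(-(lf - l50) / s)),
      start = list(lo = min(gain), hi = max(gain), l50 = l50_0, s = s0),
      lower = c(lo = -Inf, hi = -Inf, l50 = min(lf) - 1, s = 0.01),
      upper = c(lo = Inf, hi = Inf, l50 = max(lf) + 1, s = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # robust fallback: direct least squares on all four parameters
    sse <- function(p) {
      pred <- p[1] + (p[2] - p[1]) / (1 + exp(-(lf - p[3]) / max(p[4], 0.01)))
      sum((gain - pred)^2)
    }
    op <- stats::optim(c(min(gain), max(gain), l50_0, 0.3), sse)
    cf <- c(lo = op$par[1], hi = op$par[2], l50 = op$par[3],
            s = max(op$par[4], 0.01))
    pred <- cf[["lo"]] + (cf[["hi"]] - cf[["lo"]]) /
      (1 + exp(-(lf - cf[["l50"]]) / cf[["s"]]))
    return(list(f50 = 10^cf[["l50"]], lo = cf[["lo"]], hi = cf[["hi"]],
                slope = cf[["s"]], fitted = pred))
  }
  cf <- coef(fit)
  list(f50 = 10^cf[["l50"]], lo = cf[["lo"]], hi = cf[["hi"]],
       slope = cf[["s"]], fitted = stats::fitted(fit))
}

# full feature report for one current-step run of the SC model
.step_features <- function(tr, pre, dur, amp) {
  t <- tr$t; v <- tr$v[, 1]
  sp <- tr$spikes[[1]]
  base <- train_stats(sp, c(max(0, pre - 1000), pre))
  dur_stats <- train_stats(sp, c(pre, pre + dur))
  out <- list(amp = amp, ap_freq = dur_stats$rate, baseline = base$rate,
              n_spikes = dur_stats$n)
  sp_in <- sp[sp > pre & sp < pre + dur]
  if (length(sp_in) >= 1) {
    mid <- sp_in[ceiling(length(sp_in) / 2)]
    nxt <- c(sp_in[sp_in > mid], Inf)[1]
    shp <- ap_shape(t, v, mid, nxt)
    out <- c(out, shp)
  }
  if (amp < 0) {
    out <- c(out, sag_rebound(t, v, c(pre, pre + dur), sp))
  }
  if (amp > 0 && base$n > 1) {
    out$pause_ms <- pause_length(sp, pre + dur, mean(base$isi))
  }
  out
}
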