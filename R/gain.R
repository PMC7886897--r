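#' EPSC amplitude sequence for a parallel-fiber train under voltage clamp
#'
#' Clamps the stellate-cell soma (ideal clamp, -70 mV by default), delivers
#' an n-pulse train through the parallel-fiber AMPA (+ optionally NMDA)
#' synapses and measures per-pulse EPSC amplitudes as peak minus base,
#' where the base is the mean clamp current in the 1 ms preceding each
#' stimulus. By default the voltage-gated channel complement is zeroed
#' (the in silico analogue of the caesium/QX-314 internal solution used
#' for synaptic-current recordings), leaving the passive leak.
#'
#' @param model a `cmodel` (synapses are attached internally).
#' @param freq train frequency (Hz).
#' @param n_pulses pulses in the train (20 for EPSC trains).
#' @param n_syn number of parallel-fiber synapses.
#' @param v_clamp clamp potential (mV).
#' @param nmda include the NMDA component.
#' @param tm_ampa,tm_nmda optional [tm_params()] overrides.
#' @param blockers zero all voltage-gated conductances for the
#'   measurement.
#' @param onset time of the first pulse (ms).
#' @return List with `amplitudes` (pA), `normalized` (to the first EPSC),
#'   `envelope_max` (largest compound deflection from the pre-train
#'   baseline, pA), `times` (stimulus times), and the raw `trace`.
#' @export
epsc_train <- function(model, freq, n_pulses = 20, n_syn = 3,
                       v_clamp = -70, nmda = TRUE, tm_ampa = NULL,
                       tm_nmda = NULL, blockers = TRUE, onset = 100) {
  if (freq <= 0) stop("frequency must be positive")
  if (1000 / freq < model$dt) stop("pulses closer than the integration step")
  m <- model
  if (blockers) {
    g <- m$conductances; g[] <- 0
    m <- set_conductances(m, g)
  }
  m$synapses <- list()
  m <- attach_pf_synapses(m, n = n_syn, nmda = nmda,
                          tm_ampa = tm_ampa, tm_nmda = tm_nmda)
  train <- train_protocol(n_pulses = n_pulses, freq = freq, n_syn = n_syn,
                          onset = onset, post = 300)
  tr <- run_protocol(m, clamp_protocol(v = v_clamp, train = train))
  ev <- realize_events(train)
  amp <- .epsc_amplitudes(tr$t, tr$i_clamp, ev)
  # maximum compound response relative to the pre-train baseline
  base0 <- mean(tr$i_clamp[tr$t >= onset - 20 & tr$t < onset])
  span <- tr$t >= onset & tr$t <= max(ev) + 20
  env <- base0 - min(tr$i_clamp[span])
  list(amplitudes = amp, normalized = amp / amp[1], envelope_max = env,
       times = ev, trace = tr)
}

# peak-minus-base amplitude per stimulus; base = mean of the 1 ms before
# each stimulus, peak = extremum between this stimulus and the next
.epsc_amplitudes <- function(t, i, events) {
  dt <- t[2] - t[1]
  n <- length(events)
  windows <- c(diff(events), max(5, min(50, diff(range(t)) )))
  vapply(seq_len(n), function(k) {
    base_sel <- t >= events[k] - 1 & t < events[k]
    base <- mean(i[base_sel])
    win_end <- events[k] + min(windows[k], 50)
    sel <- t >= events[k] & t <= win_end
    peak <- min(i[sel])        # EPSCs are inward (negative) deflections
    base - peak                # report magnitude (positive pA)
  }, 1.0)
}

#' Synaptic gain curve over train frequency
#'
#' Gain at each frequency is the ratio between the maximum EPSC amplitude
#' in the train and the first EPSC; a four-parameter logistic in
#' log-frequency summarizes the curve and yields the half-maximal
#' frequency.
#'
#' @param model a `cmodel`.
#' @param freqs stimulation frequencies (Hz), at least 4.
#' @param n_pulses pulses per train.
#' @param ... further arguments to [epsc_train()].
#' @return List with `freq`, `gain`, `fit` (from [gain_sigmoid_fit()]) and
#'   `f50`.
#' @export
synaptic_gain_curve <- function(model, freqs = c(4, 10, 20, 50, 100, 200, 500),
                                n_pulses = 20, ...) {
  gain <- vapply(freqs, function(f) {
    e <- epsc_train(model, freq = f, n_pulses = n_pulses, ...)
    e$envelope_max / e$amplitudes[1]
  }, 1.0)
  fit <- gain_sigmoid_fit(freqs, gain)
  list(freq = freqs, gain = gain, fit = fit, f50 = fit$f50)
}
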