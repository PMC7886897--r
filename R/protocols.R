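#' Somatic current-step protocol
#'
#' @param amps_pA step amplitudes (pA); one run per amplitude.
#' @param dur step duration (ms).
#' @param pre,post padding before/after the step (ms).
#' @param holding_pA holding current applied over the whole run (pA).
#' @return Object of class `step_protocol`.
#' @export
step_protocol <- function(amps_pA, dur = 2000, pre = 1000, post = 1000,
                          holding_pA = 0) {
  stopifnot(dur > 0)
  structure(list(amps = amps_pA, dur = dur, pre = pre, post = post,
                 holding = holding_pA), class = c("step_protocol", "protocol"))
}

#' Parallel-fiber train protocol
#'
#' @param n_pulses number of pulses (>= 1).
#' @param freq train frequency (Hz).
#' @param n_syn number of parallel-fiber synapses activated.
#' @param onset time of the first pulse (ms).
#' @param post padding after the last pulse (ms).
#' @return Object of class `train_protocol`.
#' @export
train_protocol <- function(n_pulses = 10, freq = 100, n_syn = 3,
                           onset = 1000, post = 1000) {
  stopifnot(n_pulses >= 1, freq > 0)
  structure(list(n_pulses = n_pulses, freq = freq, n_syn = n_syn,
                 onset = onset, post = post),
            class = c("train_protocol", "protocol"))
}

#' Inhibitory background protocol
#'
#' 20-Hz background drive of the GABA-A synapse population, either as
#' independent periodic trains with random phase per synapse (default,
#' keeping the 20 Hz rate literal) or as independent Poisson processes.
#'
#' @param rate rate per synapse (Hz).
#' @param n_syn number of GABA-A synapses (20, 27 or 32 in the standard
#'   settings).
#' @param process `"periodic"` or `"poisson"`.
#' @param dur duration (ms).
#' @param onset start time (ms).
#' @return Object of class `background_protocol`.
#' @export
inhibitory_background <- function(rate = 20, n_syn = 32,
                                  process = c("periodic", "poisson"),
                                  dur = 3000, onset = 0) {
  stopifnot(rate > 0)
  structure(list(rate = rate, n_syn = n_syn, process = match.arg(process),
                 dur = dur, onset = onset),
            class = c("background_protocol", "protocol"))
}

#' Voltage-clamp protocol
#'
#' Ideal somatic voltage clamp (zero series resistance) with an optional
#' concurrent synaptic train.
#'
#' @param v clamp voltage (mV), within [-120, 40].
#' @param train optional [train_protocol()].
#' @param t_end run duration (ms); defaults to cover the train.
#' @return Object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(v = -70, train = NULL, t_end = NULL) {
  stopifnot(v >= -120, v <= 40)
  if (is.null(t_end)) {
    t_end <- if (is.null(train)) 500 else
      train$onset + (train$n_pulses - 1) / train$freq * 1000 + train$post
  }
  structure(list(v = v, train = train, t_end = t_end),
            class = c("clamp_protocol", "protocol"))
}

#' The standard current-injection battery
#'
#' The optimization set -- spontaneous activity (0 pA), +4, +16 and -16 pA
#' steps, 2 s each -- plus, optionally, the extended -16 to +20 pA ladder
#' in 4 pA increments used for validation.
#'
#' @param extended include the full validation ladder.
#' @return Named list of [step_protocol()] objects.
#' @export
standard_battery <- function(extended = FALSE) {
  amps <- if (extended) seq(-16, 20, by = 4) else c(0, 4, 16, -16)
  out <- lapply(amps, function(a) step_protocol(a, dur = 2000))
  names(out) <- paste0("step_", amps, "pA")
  out
}

#' The parallel-fiber train set
#'
#' Train protocols at 4, 10, 20, 50, 100, 200 and 500 Hz.
#'
#' @param n_pulses pulses per train (10 for firing protocols, 20 for EPSC
#'   trains).
#' @param n_syn activated parallel-fiber synapses.
#' @return Named list of [train_protocol()] objects.
#' @export
pf_train_set <- function(n_pulses = 10, n_syn = 3) {
  freqs <- c(4, 10, 20, 50, 100, 200, 500)
  out <- lapply(freqs, function(f)
    train_protocol(n_pulses = n_pulses, freq = f, n_syn = n_syn))
  names(out) <- paste0("f", freqs)
  out
}

#' Realize the event streams of a protocol
#'
#' Deterministic pulse times for trains; seeded random phases (periodic
#' process) or Poisson event streams for inhibitory backgrounds.
#'
#' @param protocol a protocol object.
#' @param seed random seed for stochastic backgrounds.
#' @return For trains, a numeric vector of pulse times; for backgrounds, a
#'   list of per-synapse event-time vectors.
#' @export
realize_events <- function(protocol, seed = 1) {
  if (inherits(protocol, "train_protocol")) {
    return(protocol$onset + (seq_len(protocol$n_pulses) - 1) /
             protocol$freq * 1000)
  }
  if (inherits(protocol, "background_protocol")) {
    set.seed(seed)
    period <- 1000 / protocol$rate
    out <- lapply(seq_len(protocol$n_syn), function(i) {
      if (protocol$process == "periodic") {
        phase <- runif(1, 0, period)
        ev <- seq(protocol$onset + phase, protocol$onset + protocol$dur,
                  by = period)
      } else {
        n_exp <- protocol$rate * protocol$dur / 1000
        gaps <- stats::rexp(ceiling(n_exp * 3 + 20), rate = protocol$rate / 1000)
        ev <- protocol$onset + cumsum(gaps)
      }
      ev[ev <= protocol$onset + protocol$dur]
    })
    return(out)
  }
  stop("no event stream for this protocol type")
}
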