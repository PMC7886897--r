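#' Tsodyks-Markram synapse parameters
#'
#' Presynaptic short-term plasticity parameters plus the postsynaptic
#' maximum conductance and reversal potential of one synapse type.
#'
#' @param p baseline release probability (0 < p <= 1).
#' @param tau_rec vesicle recovery time constant (ms, >= 0): depression.
#' @param tau_fac facilitation decay time constant (ms, >= 0).
#' @param g_pS maximum conductance per synapse (pS).
#' @param e_rev reversal potential (mV).
#' @return Object of class `tm_params`.
#' @export
tm_params <- function(p, tau_rec, tau_fac, g_pS, e_rev) {
  stopifnot(p > 0, p <= 1, tau_rec >= 0, tau_fac >= 0, g_pS > 0)
  structure(list(p = p, tau_rec = tau_rec, tau_fac = tau_fac,
                 g_pS = g_pS, e_rev = e_rev), class = "tm_params")
}

#' Synapse parameter library
#'
#' The three synapse types of the molecular-layer model with their
#' presynaptic (Tsodyks-Markram) parameters: the parallel-fiber AMPA
#' synapse onto stellate cells (p = 0.15, tau_rec = 35.1 ms, tau_fac =
#' 10.8 ms, 2300 pS, 0 mV), the NR2B-type NMDA component (p = 0.15,
#' tau_rec = 8 ms, tau_fac = 5 ms, 10000 pS, -3.7 mV), and the
#' alpha1-subunit GABA-A synapse between stellate cells (p = 0.42,
#' tau_rec = 38.7 ms, tau_fac = 0, 1600 pS, -65 mV). Receptor waveform
#' kinetics (`receptor`) are two-state defaults: instantaneous rise with
#' single-exponential decay for AMPA and GABA-A, slow rise and decay for
#' NMDA, with a standard sigmoidal magnesium block for NMDA.
#'
#' @return Named list with elements `pf_ampa`, `pf_nmda`, `sc_gaba`; each
#'   holds `tm` ([tm_params()]) and `receptor` (kinetic constants).
#' @export
synapse_library <- function() {
  list(
    pf_ampa = list(
      tm = tm_params(0.15, 35.1, 10.8, 2300, 0),
      receptor = list(kind = "exp", tau_rise = 0, tau_decay = 1.0,
                      mg_block = FALSE, des_per_rel = 0.7, tau_des = 100)),
    pf_nmda = list(
      tm = tm_params(0.15, 8, 5, 10000, -3.7),
      receptor = list(kind = "dualexp", tau_rise = 8, tau_decay = 195,
                      po = 0.03, act_max = 0.3,
                      mg_block = TRUE, mg = 1, mg_k = 3.57,
                      mg_gamma = 0.03)),
    sc_gaba = list(
      tm = tm_params(0.42, 38.7, 0, 1600, -65),
      receptor = list(kind = "exp", tau_rise = 0, tau_decay = 13,
                      mg_block = FALSE)))
}

#' Initial state of a Tsodyks-Markram synapse
#' @return List with resources `R = 1`, utilization `u = 0`, `t_last = NA`.
#' @export
tm_state <- function() list(R = 1, u = 0, t_last = NA_real_)

#' Event-driven Tsodyks-Markram update
#'
#' Advances the presynaptic state to `spike_time` and applies one release
#' event: between spikes the utilization `u` decays to 0 with `tau_fac`
#' and the resources `R` recover to 1 with `tau_rec`; at the spike the
#' facilitation increment `u <- u + p (1 - u)` is applied *before* release,
#' so the first release from rest equals `p`; the released fraction is
#' `u R`, which is subtracted from `R`.
#'
#' @param state a [tm_state()].
#' @param spike_time event time (ms), non-decreasing across calls.
#' @param params a [tm_params()].
#' @return List `released` (fraction of maximal conductance) and `state`.
#' @export
tm_update <- function(state, spike_time, params) {
  if (!is.na(state$t_last)) {
    dt <- spike_time - state$t_last
    if (dt < 0) stop("negative inter-spike interval")
    state$R <- 1 - (1 - state$R) *
      (if (params$tau_rec > 0) exp(-dt / params$tau_rec) else 0)
    state$u <- if (params$tau_fac > 0) state$u * exp(-dt / params$tau_fac) else 0
  }
  state$u <- state$u + params$p * (1 - state$u)
  released <- state$u * state$R
  state$R <- state$R - released
  state$t_last <- spike_time
  list(released = released, state = state)
}

#' Release sequence of a spike train through a TM synapse
#'
#' Convenience wrapper running [tm_update()] over a full train.
#'
#' @param spike_times ordered event times (ms).
#' @param params a [tm_params()].
#' @return Numeric vector of released fractions, one per spike.
#' @export
tm_release_train <- function(spike_times, params) {
  st <- tm_state()
  out <- numeric(length(spike_times))
  for (i in seq_along(spike_times)) {
    up <- tm_update(st, spike_times[i], params)
    out[i] <- up$released
    st <- up$state
  }
  out
}

#' Steady-state release at a fixed stimulation frequency
#'
#' Closed-form fixed point of the two-map (u, R) recursion at inter-spike
#' interval `1/f`; the event recursion converges to this value.
#'
#' @param f stimulation frequency (Hz).
#' @param params a [tm_params()].
#' @return Steady-state released fraction per spike.
#' @export
tm_steady_state <- function(f, params) {
  dt <- 1000 / f
  df <- if (params$tau_fac > 0) exp(-dt / params$tau_fac) else 0
  dr <- if (params$tau_rec > 0) exp(-dt / params$tau_rec) else 0
  # u_next = (u df) + p (1 - u df) at the spike
  u <- params$p / (1 - df * (1 - params$p))
  # R just before spike: R+ = R- (1 - u); recovery between spikes
  r <- (1 - dr) / (1 - dr * (1 - u))
  u * r
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' Standard sigmoidal form `1 / (1 + [Mg]/K * exp(-gamma V))`; tends to 1
#' as `[Mg] -> 0` and increases monotonically with depolarization.
#'
#' @param v membrane potential (mV).
#' @param mg magnesium concentration (mM).
#' @param k half-blocking concentration scale (mM).
#' @param gamma voltage sensitivity (1/mV).
#' @return Unblocked fraction in (0, 1].
#' @export
nmda_block <- function(v, mg = 1, k = 3.57, gamma = 0.062) {
  stopifnot(mg >= 0)
  1 / (1 + mg / k * exp(-gamma * v))
}

#' Receptor conductance waveform from release events
#'
#' Linear superposition of event-triggered two-state waveforms: single
#' exponential decay (instantaneous rise) or bi-exponential rise/decay
#' normalized so an isolated event of released fraction `r` peaks at
#' `r * g_max`.
#'
#' @param t time points (ms).
#' @param events data frame with columns `time` and `released`.
#' @param kinetics receptor kinetics list (see [synapse_library()]).
#' @param g_max maximum conductance (pS).
#' @return Conductance (pS) at `t`.
#' @export
receptor_g <- function(t, events, kinetics, g_max) {
  g <- numeric(length(t))
  if (is.null(events) || nrow(events) == 0) return(g)
  if (is.unsorted(events$time)) stop("events must be time-ordered")
  for (i in seq_len(nrow(events))) {
    dt <- t - events$time[i]
    on <- dt >= 0
    if (kinetics$kind == "exp") {
      w <- exp(-dt[on] / kinetics$tau_decay)
    } else {
      tr <- kinetics$tau_rise; td <- kinetics$tau_decay
      tp <- tr * td / (td - tr) * log(td / tr)
      norm <- exp(-tp / td) - exp(-tp / tr)
      w <- (exp(-dt[on] / td) - exp(-dt[on] / tr)) / norm
    }
    g[on] <- g[on] + events$released[i] * g_max * w
  }
  g
}

#' Switch off short-term facilitation or depression
#'
#' `STF_off` multiplies the facilitation time constant by 10; `STD_off`
#' sets the recovery time constant to 0 (instant vesicle recovery).
#'
#' @param params a [tm_params()].
#' @param mode `"STF_off"`, `"STD_off"`, or `"none"`.
#' @return Modified [tm_params()].
#' @export
stp_switch <- function(params, mode = c("none", "STF_off", "STD_off")) {
  mode <- match.arg(mode)
  if (mode == "STF_off") params$tau_fac <- params$tau_fac * 10
  if (mode == "STD_off") params$tau_rec <- 0
  params
}

# internal: build a solver synapse entry
.make_synapse <- function(comp, type, events = numeric(0), src = NULL,
                          delay = 0.5, lib = synapse_library(),
                          tm_override = NULL) {
  s <- lib[[type]]
  tm <- if (is.null(tm_override)) s$tm else tm_override
  rec <- s$receptor
  list(comp = comp,
       rec_kind = if (rec$kind == "exp") 0L else 1L,
       g_pS = tm$g_pS, erev = tm$e_rev,
       tau_rise = max(rec$tau_rise, 1e-3), tau_decay = rec$tau_decay,
       mg_block = isTRUE(rec$mg_block),
       mg = if (is.null(rec$mg)) 0 else rec$mg,
       mg_k = if (is.null(rec$mg_k)) 3.57 else rec$mg_k,
       mg_gamma = if (is.null(rec$mg_gamma)) 0.062 else rec$mg_gamma,
       po = if (is.null(rec$po)) 1 else rec$po,
       act_max = if (is.null(rec$act_max)) 1 else rec$act_max,
       des_per_rel = if (is.null(rec$des_per_rel)) 0 else rec$des_per_rel,
       tau_des = if (is.null(rec$tau_des)) 50 else rec$tau_des,
       p = tm$p, tau_rec = tm$tau_rec, tau_fac = tm$tau_fac,
       src = src, delay = delay,
       events = events, type = type, group = type)
}

#' Attach parallel-fiber synapses to a stellate-cell model
#'
#' Places `n` parallel-fiber contacts, each consisting of a co-located
#' AMPA and NMDA synapse, on the distal dendritic compartments (cycled
#' round the three distal branches, as the excitatory inputs target three
#' distal compartments).
#'
#' @param model a `cmodel`.
#' @param n number of parallel-fiber synapses.
#' @param nmda include the NMDA component (default TRUE).
#' @param tm_ampa,tm_nmda optional [tm_params()] overrides.
#' @return The updated model.
#' @export
attach_pf_synapses <- function(model, n = 3, nmda = TRUE,
                               tm_ampa = NULL, tm_nmda = NULL) {
  dist <- which(model$compartments$class == "dist_dend")
  for (i in seq_len(n)) {
    comp <- dist[(i - 1) %% length(dist) + 1]
    model$synapses[[length(model$synapses) + 1]] <-
      c(.make_synapse(comp, "pf_ampa", tm_override = tm_ampa), list(pf = i))
    if (nmda)
      model$synapses[[length(model$synapses) + 1]] <-
        c(.make_synapse(comp, "pf_nmda", tm_override = tm_nmda), list(pf = i))
  }
  model
}

#' Attach GABA-A synapses to random dendritic compartments
#'
#' Inhibitory synapses from neighbouring stellate cells are placed
#' uniformly at random (seeded) over the dendritic compartments.
#'
#' @param model a `cmodel`.
#' @param n number of synapses.
#' @param seed placement seed.
#' @param group group label used when assigning event streams.
#' @return The updated model.
#' @export
attach_gaba_synapses <- function(model, n = 32, seed = 1, group = "gaba") {
  dend <- which(model$compartments$class %in% c("prox_dend", "dist_dend"))
  set.seed(seed)
  comps <- sample(dend, n, replace = TRUE)
  for (i in seq_len(n)) {
    s <- .make_synapse(comps[i], "sc_gaba")
    s$group <- group
    model$synapses[[length(model$synapses) + 1]] <- s
  }
  model
}
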