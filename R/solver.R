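#' @name cable_solver
#' @title Implicit cable-equation integration
#' @description The compiled core advances the branched cable equation
#'   with a theta-method (Crank-Nicolson by default, backward Euler with
#'   `model$theta = 1`) at a fixed step (default 0.025 ms), staggered
#'   exponential-Euler gate updates, sub-membrane calcium pools,
#'   event-driven Tsodyks-Markram synapses and ideal voltage clamp.
NULL

# low-level dispatch into the compiled core
.run_sim <- function(model, t_end, stims = list(), clamp = NULL,
                     record = "soma.v", stride = 1L,
                     spike_threshold = -20, spike_refractory = 1) {
  sys <- assemble(model)
  comp_names <- model$compartments$name
  parse_rec <- function(suffix) {
    sel <- record[endsWith(record, suffix)]
    idx <- match(sub(paste0("\\", suffix, "$"), "", sel), comp_names)
    if (any(is.na(idx))) stop("unknown recording site in: ",
                              paste(sel[is.na(idx)], collapse = ", "))
    idx
  }
  v_comps <- parse_rec(".v")
  ca_comps <- parse_rec(".cai")
  spike_comps <- vapply(model$cells, identity, 1L)

  prot <- list(dt = model$dt, t_end = t_end, theta = model$theta,
               stim = lapply(stims, function(s)
                 list(comp = s$comp - 1L, t0 = s$t0, t1 = s$t1,
                      amp = s$amp_pA * 1e-3)),
               clamp = if (is.null(clamp)) NULL else
                 list(comp = clamp$comp - 1L, v = clamp$v,
                      t0 = clamp$t0, t1 = clamp$t1))
  rec <- list(v_comps = as.integer(v_comps - 1L),
              ca_comps = as.integer(ca_comps - 1L),
              stride = as.integer(stride),
              spike_comps = as.integer(spike_comps - 1L),
              spike_threshold = spike_threshold,
              spike_refractory = spike_refractory)
  out <- .sim_core(sys, prot, rec)
  v <- out$v
  colnames(v) <- comp_names[v_comps]
  ca <- out$ca
  if (ncol(ca)) colnames(ca) <- comp_names[ca_comps]
  spikes <- out$spikes
  names(spikes) <- names(model$cells)
  structure(list(t = out$t, dt = model$dt * stride, v = v, ca = ca,
                 i_clamp = out$i_clamp, spikes = spikes,
                 max_residual = out$max_residual),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %.0f ms @ %g ms, %d voltage site(s), %s\n",
              max(x$t), x$dt, ncol(x$v),
              paste(sprintf("%s: %d spikes", names(x$spikes),
                            vapply(x$spikes, length, 1L)), collapse = ", ")))
  invisible(x)
}

# assign event streams to synapse groups before a run
.set_events <- function(model, group, events, n_syn = Inf) {
  for (i in seq_along(model$synapses)) {
    s <- model$synapses[[i]]
    if (!s$group %in% group) next
    if (!is.null(s$pf) && s$pf > n_syn) { model$synapses[[i]]$events <- numeric(0); next }
    model$synapses[[i]]$events <-
      if (is.list(events)) events[[min(i, length(events))]] else events
  }
  model
}

# assign per-synapse background streams to a group (recycled in order)
.set_group_events <- function(model, group, streams) {
  k <- 0
  for (i in seq_along(model$synapses)) {
    if (model$synapses[[i]]$group != group) next
    k <- k + 1
    model$synapses[[i]]$events <-
      streams[[(k - 1) %% length(streams) + 1]]
  }
  model
}

#' Run a stimulation protocol on a model
#'
#' Translates a declarative protocol into solver runs. Current steps are
#' injected at the soma; train protocols drive the model's parallel-fiber
#' synapses; clamp protocols pin the somatic voltage and record the
#' electrode current; an optional inhibitory background co-drives the
#' GABA-A synapse population.
#'
#' @param model a `cmodel` (with synapses attached where the protocol
#'   needs them).
#' @param protocol a protocol object from the protocols module.
#' @param record recording sites, `"<comp>.v"` or `"<comp>.cai"`.
#' @param seed seed for stochastic protocol elements.
#' @param background optional [inhibitory_background()] applied during the
#'   run.
#' @param stride record every `stride`-th sample.
#' @return A `trace_set`, or a named list of trace sets for multi-step
#'   protocols.
#' @export
run_protocol <- function(model, protocol, record = "soma.v", seed = 1,
                         background = NULL, stride = 1L) {
  soma <- model$cells[[1]]
  if (!is.null(background)) {
    streams <- realize_events(background, seed = seed)
    model <- .set_group_events(model, "gaba", streams)
  }
  if (inherits(protocol, "step_protocol")) {
    t_end <- protocol$pre + protocol$dur + protocol$post
    one <- function(a) {
      stims <- list(list(comp = soma, t0 = protocol$pre,
                         t1 = protocol$pre + protocol$dur, amp_pA = a))
      if (protocol$holding != 0)
        stims <- c(stims, list(list(comp = soma, t0 = 0, t1 = t_end,
                                    amp_pA = protocol$holding)))
      .run_sim(model, t_end, stims, record = record, stride = stride)
    }
    if (length(protocol$amps) == 1) return(one(protocol$amps))
    out <- lapply(protocol$amps, one)
    names(out) <- paste0("step_", protocol$amps, "pA")
    return(out)
  }
  if (inherits(protocol, "train_protocol")) {
    ev <- realize_events(protocol, seed = seed)
    model <- .set_events(model, c("pf_ampa", "pf_nmda", "pc_pf"), ev,
                         n_syn = protocol$n_syn)
    t_end <- max(ev) + protocol$post
    return(.run_sim(model, t_end, record = record, stride = stride))
  }
  if (inherits(protocol, "clamp_protocol")) {
    if (!is.null(protocol$train)) {
      ev <- realize_events(protocol$train, seed = seed)
      model <- .set_events(model, c("pf_ampa", "pf_nmda", "pc_pf"), ev,
                           n_syn = protocol$train$n_syn)
    }
    clamp <- list(comp = soma, v = protocol$v, t0 = 0, t1 = protocol$t_end)
    return(.run_sim(model, protocol$t_end, clamp = clamp, record = record,
                    stride = stride))
  }
  stop("unsupported protocol")
}

#' Input resistance of a model
#'
#' Measured as the steady-state voltage deflection to a small
#' hyperpolarizing somatic current step after silencing spiking (sodium
#' conductances set to zero, the in silico tetrodotoxin analogue).
#'
#' @param model a `cmodel`.
#' @param i_pA probe current (pA, negative).
#' @param settle settling time before the probe (ms).
#' @param dur probe duration (ms).
#' @return Input resistance in GOhm.
#' @export
input_resistance <- function(model, i_pA = -2, settle = 1500, dur = 1500) {
  passive <- knockout(knockout(model, "Nav1.1"), "Nav1.6")
  soma <- passive$cells[[1]]
  tr <- .run_sim(passive, settle + dur,
                 stims = list(list(comp = soma, t0 = settle,
                                   t1 = settle + dur, amp_pA = i_pA)))
  if (length(tr$spikes[[1]]) > 0)
    stop("non-convergent rest: model still spiking without Na channels")
  v <- tr$v[, 1]
  t <- tr$t
  v0 <- mean(v[t > settle - 200 & t <= settle])
  v1 <- mean(v[t > settle + dur - 200 & t <= settle + dur])
  (v1 - v0) / i_pA   # mV/pA = GOhm
}
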