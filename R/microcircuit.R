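#' Default conductance set of the reduced Purkinje-cell stand-in
#'
#' The Purkinje cell of the microcircuit is a deliberately reduced
#' conductance-based stand-in (not a full anatomical reconstruction): a
#' soma and AIS plus three dendritic branch classes (I: main trunks, II:
#' spiny branches receiving parallel-fiber input, III: branches receiving
#' ascending-axon input and no inhibition). It reuses the ionic-channel
#' library of the stellate-cell model with densities set for intrinsic
#' pacemaking at the higher Purkinje rate and for calcium-dependent
#' burst-pause responses.
#'
#' @return Named numeric vector (`class.channel`, S/cm2).
#' @export
pc_default_conductances <- function() {
  c("soma.Nav1.1" = 0.1, "soma.Nav1.6" = 0.04, "soma.Kv3.4" = 0.08,
    "soma.Kv4.3" = 5e-4, "soma.Kir2.3" = 1e-4, "soma.Kv7" = 1.2e-4, "soma.HCN1" = 3.5e-3,
    "soma.KCa1.1" = 0.01, "soma.KCa2.2" = 2e-4, "soma.Cav2.1" = 2e-3,
    "soma.Cav3.2" = 8e-4,
    "ais.Nav1.6" = 1.0, "ais.Kv3.4" = 0.1, "ais.Kv1.1" = 0.1,
    "branch1.Kv3.4" = 4e-3, "branch1.Kv4.3" = 8e-4, "branch1.KCa1.1" = 2e-3,
    "branch1.KCa2.2" = 2e-4, "branch1.Cav2.1" = 1.5e-3,
    "branch1.Cav3.2" = 4e-4, "branch1.HCN1" = 2e-3,
    "branch2.Kv3.4" = 2e-3, "branch2.Kv4.3" = 5e-4, "branch2.KCa1.1" = 1.5e-3,
    "branch2.KCa2.2" = 2e-4, "branch2.Cav2.1" = 1.2e-3,
    "branch2.Cav3.2" = 3e-4, "branch2.HCN1" = 1e-3,
    "branch3.Kv3.4" = 2e-3, "branch3.Kv4.3" = 5e-4, "branch3.KCa1.1" = 1.5e-3,
    "branch3.KCa2.2" = 2e-4, "branch3.Cav2.1" = 1.2e-3,
    "branch3.Cav3.2" = 3e-4, "branch3.HCN1" = 1e-3)
}

#' Parallel-fiber synapse parameters of the Purkinje-cell stand-in
#'
#' The PF synapse onto the Purkinje cell carries a fast AMPA component
#' and a slow saturating component; their short-term-plasticity and
#' kinetic constants are calibrated so that the EPSC gain curve of the
#' stand-in has its half-maximal frequency near 10 Hz.
#'
#' @return List with `ampa` and `slow` entries (`tm` + `receptor`).
#' @export
pc_pf_synapse <- function() {
  list(
    ampa = list(tm = tm_params(0.15, 60, 40, 700, 0),
                receptor = list(kind = "exp", tau_rise = 0, tau_decay = 1.5,
                                mg_block = FALSE)),
    slow = list(tm = tm_params(0.15, 8, 5, 300, -3.7),
                receptor = list(kind = "dualexp", tau_rise = 15,
                                tau_decay = 400, mg_block = FALSE)))
}

#' Build the reduced Purkinje-cell model
#'
#' @param conductances named vector, defaults to
#'   [pc_default_conductances()].
#' @param g_leak leak density (S/cm2).
#' @param ... passed through to the model structure (dt, celsius...).
#' @return A `cmodel` with compartment classes `soma`, `ais`, `branch1`,
#'   `branch2`, `branch3`.
#' @export
purkinje_model <- function(conductances = pc_default_conductances(),
                           g_leak = 3e-5, dt = 0.025, celsius = 32,
                           v_init = -70) {
  um2 <- 1e-8
  cyl <- function(name, class, L, d, cm, parent)
    data.frame(name = name, class = class, L_um = L, diam_um = d,
               area_cm2 = pi * d * L * um2, cm = cm, parent = parent,
               stringsAsFactors = FALSE)
  comp <- rbind(
    cyl("soma", "soma", 25, 25, 1.0, -1),
    cyl("ais", "ais", 25, 1.2, 1.0, 1),
    cyl("b1a", "branch1", 100, 6.0, 1.5, 1),
    cyl("b1b", "branch1", 100, 6.0, 1.5, 1),
    cyl("b2a", "branch2", 250, 3.0, 1.5, 3),
    cyl("b2b", "branch2", 250, 3.0, 1.5, 3),
    cyl("b2c", "branch2", 250, 3.0, 1.5, 4),
    cyl("b3a", "branch3", 150, 2.0, 1.5, 5),
    cyl("b3b", "branch3", 150, 2.0, 1.5, 7))
  rownames(comp) <- comp$name
  chans <- .conductance_table(comp, conductances, g_leak)
  structure(list(compartments = comp, channels = chans,
                 conductances = conductances,
                 synapses = list(), cells = list(pc = 1L),
                 reversal = reversal_set(), ca = calcium_pool(),
                 celsius = celsius, dt = dt, v_init = v_init,
                 r_axial = 110, theta = 0.5),
            class = "cmodel")
}

#' Attach parallel-fiber synapses to the Purkinje-cell stand-in
#'
#' PF contacts target branch-II compartments only; each carries the fast
#' and the slow component of [pc_pf_synapse()].
#'
#' @param model a Purkinje `cmodel`.
#' @param n number of PF synapses (100 in the standard circuit).
#' @param seed placement seed.
#' @return The updated model.
#' @export
attach_pc_pf_synapses <- function(model, n = 100, seed = 1) {
  b2 <- which(model$compartments$class == "branch2")
  if (!length(b2)) stop("model has no branch-II compartments")
  set.seed(seed)
  comps <- sample(b2, n, replace = TRUE)
  syn <- pc_pf_synapse()
  for (i in seq_len(n)) {
    for (part in syn) {
      rec <- part$receptor
      model$synapses[[length(model$synapses) + 1]] <- list(
        comp = comps[i],
        rec_kind = if (rec$kind == "exp") 0L else 1L,
        g_pS = part$tm$g_pS, erev = part$tm$e_rev,
        tau_rise = max(rec$tau_rise, 1e-3), tau_decay = rec$tau_decay,
        mg_block = isTRUE(rec$mg_block), mg = 1, mg_k = 3.57,
        mg_gamma = 0.062,
        p = part$tm$p, tau_rec = part$tm$tau_rec, tau_fac = part$tm$tau_fac,
        src = NULL, delay = 0.5, events = numeric(0),
        type = "pc_pf", group = "pc_pf", pf = i)
    }
  }
  model
}

#' Attach inhibitory synapses to the Purkinje-cell stand-in
#'
#' GABA-A synapses from stellate cells are placed randomly over branch-I
#' and branch-II compartments only; branch III carries no inhibition.
#'
#' @param model a Purkinje `cmodel` (possibly embedded in a circuit).
#' @param n number of synapses.
#' @param seed placement seed.
#' @param src spike-source index (0-based cell index) for spike-driven
#'   operation, or `NULL` for externally scheduled events.
#' @param comp_offset index offset of the PC compartments inside a larger
#'   circuit model.
#' @param group synapse group label.
#' @param target target branch classes (branch III is refused).
#' @return The updated model.
#' @export
attach_pc_gaba_synapses <- function(model, n = 100, seed = 1, src = NULL,
                                    comp_offset = 0, group = "sc_pc",
                                    target = c("branch1", "branch2")) {
  if (any(target == "branch3"))
    stop("constraint error: branch III carries no inhibitory synapses")
  cls <- model$compartments$class
  ok <- which(cls %in% target)
  if (!length(ok)) stop("no eligible compartments for inhibition")
  set.seed(seed)
  comps <- sample(ok, n, replace = TRUE)
  for (i in seq_len(n)) {
    s <- .make_synapse(comps[i] + comp_offset, "sc_gaba")
    s$src <- src; s$delay <- 1.0; s$group <- group
    model$synapses[[length(model$synapses) + 1]] <- s
  }
  model
}

#' Circuit configuration
#'
#' @param n_pf_pc PF synapses on the Purkinje cell (100).
#' @param n_pf_sc PF synapses on each stellate cell (3).
#' @param n_sc_pc stellate-cell synapses on the Purkinje cell (25, 50,
#'   100, 200 or 300 in the standard settings).
#' @param n_sc_sc synapses from the second stellate cell onto the first
#'   (32).
#' @param sc_sc_enabled wire the second stellate cell.
#' @param sc_enabled wire stellate-cell inhibition at all (FALSE = "SC
#'   off" control).
#' @param reciprocal make the SC-SC connection mutual instead of one-way.
#' @param seed placement seed.
#' @return List of class `circuit_config`.
#' @export
circuit_config <- function(n_pf_pc = 100, n_pf_sc = 3, n_sc_pc = 100,
                           n_sc_sc = 32, sc_sc_enabled = FALSE,
                           sc_enabled = TRUE, reciprocal = FALSE, seed = 1) {
  stopifnot(n_pf_pc >= 0, n_pf_sc >= 0, n_sc_pc >= 0, n_sc_sc >= 0)
  structure(list(n_pf_pc = n_pf_pc, n_pf_sc = n_pf_sc, n_sc_pc = n_sc_pc,
                 n_sc_sc = n_sc_sc, sc_sc_enabled = sc_sc_enabled,
                 sc_enabled = sc_enabled, reciprocal = reciprocal,
                 seed = seed),
            class = "circuit_config")
}

# concatenate a cell's compartments/synapses into a circuit model
.append_cell <- function(circ, cell, name) {
  off <- nrow(circ$compartments)
  comp <- cell$compartments
  comp$parent <- ifelse(comp$parent == -1, -1, comp$parent + off)
  comp$name <- paste(name, comp$name, sep = ".")
  rownames(comp) <- comp$name
  circ$compartments <- rbind(circ$compartments, comp)
  ch <- cell$channels
  ch$comp <- ch$comp + off
  circ$channels <- rbind(circ$channels, ch)
  for (s in cell$synapses) {
    s$comp <- s$comp + off
    circ$synapses[[length(circ$synapses) + 1]] <- s
  }
  circ$cells[[name]] <- as.integer(off + 1)
  circ
}

#' Build the PF -> SC -> PC microcircuit
#'
#' Assembles one (optionally two) optimized stellate cells and the reduced
#' Purkinje cell into a single solver model: parallel fibers form
#' `n_pf_pc` synapses on PC branch II and `n_pf_sc` synapses on each SC;
#' the first SC inhibits the PC through `n_sc_pc` synapses on branches
#' I-II; when enabled, a second SC inhibits the first through `n_sc_sc`
#' synapses (one-way by default, reciprocal on request).
#'
#' @param config a [circuit_config()].
#' @param sc_model_1,sc_model_2 stellate-cell models (`cmodel`); the
#'   second defaults to the first.
#' @param pc_model a Purkinje `cmodel`.
#' @return A combined `cmodel` with cells `sc1`, (`sc2`,) `pc`.
#' @export
build_circuit <- function(config = circuit_config(),
                          sc_model_1 = sc_model(),
                          sc_model_2 = NULL,
                          pc_model = purkinje_model()) {
  base <- list(compartments = sc_model_1$compartments[0, ],
               channels = sc_model_1$channels[0, ],
               synapses = list(), cells = list(),
               reversal = reversal_set(), ca = sc_model_1$ca,
               celsius = sc_model_1$celsius, dt = sc_model_1$dt,
               v_init = sc_model_1$v_init, r_axial = sc_model_1$r_axial,
               theta = sc_model_1$theta)
  circ <- structure(base, class = "cmodel")

  sc1 <- attach_pf_synapses(sc_model_1, n = config$n_pf_sc)
  circ <- .append_cell(circ, sc1, "sc1")
  if (config$sc_sc_enabled) {
    sc2 <- if (is.null(sc_model_2)) sc_model_1 else sc_model_2
    sc2 <- attach_pf_synapses(sc2, n = config$n_pf_sc)
    circ <- .append_cell(circ, sc2, "sc2")
  }
  pc <- attach_pc_pf_synapses(pc_model, n = config$n_pf_pc,
                              seed = config$seed)
  circ <- .append_cell(circ, pc, "pc")

  cell_index <- function(name) which(names(circ$cells) == name) - 1L
  pc_off <- circ$cells[["pc"]] - 1L
  if (config$sc_enabled && config$n_sc_pc > 0) {
    tmp <- attach_pc_gaba_synapses(pc_model, n = config$n_sc_pc,
                                   seed = config$seed + 1,
                                   src = cell_index("sc1"),
                                   comp_offset = pc_off)
    new_syn <- tail(tmp$synapses, config$n_sc_pc)
    circ$synapses <- c(circ$synapses, new_syn)
  }
  if (config$sc_sc_enabled && config$n_sc_sc > 0) {
    sc1_dend <- which(circ$compartments$class %in%
                        c("prox_dend", "dist_dend") &
                      startsWith(circ$compartments$name, "sc1."))
    set.seed(config$seed + 2)
    comps <- sample(sc1_dend, config$n_sc_sc, replace = TRUE)
    for (i in seq_len(config$n_sc_sc)) {
      s <- .make_synapse(comps[i], "sc_gaba")
      s$src <- cell_index("sc2"); s$delay <- 1.0; s$group <- "sc_sc"
      circ$synapses[[length(circ$synapses) + 1]] <- s
    }
    if (config$reciprocal) {
      sc2_dend <- which(circ$compartments$class %in%
                          c("prox_dend", "dist_dend") &
                        startsWith(circ$compartments$name, "sc2."))
      comps <- sample(sc2_dend, config$n_sc_sc, replace = TRUE)
      for (i in seq_len(config$n_sc_sc)) {
        s <- .make_synapse(comps[i], "sc_gaba")
        s$src <- cell_index("sc1"); s$delay <- 1.0; s$group <- "sc_sc_back"
        circ$synapses[[length(circ$synapses) + 1]] <- s
      }
    }
  }
  circ$config <- config
  circ
}

# run one PF train through the circuit; returns per-cell spikes
.run_circuit_train <- function(circ, freq, n_pulses = 10, onset = 1500,
                               post = 1500, stride = 4L) {
  ev <- onset + (seq_len(n_pulses) - 1) / freq * 1000
  m <- .set_events(circ, c("pf_ampa", "pf_nmda", "pc_pf"), ev)
  t_end <- max(ev) + post
  tr <- .run_sim(m, t_end, record = "pc.soma.v", stride = stride)
  list(trace = tr, events = ev, onset = onset, t_end = t_end)
}

#' Latency of a response above baseline in a fine-binned PSTH
#'
#' First bin (after onset) whose rate exceeds the pre-stimulus baseline
#' mean by at least two baseline standard deviations, sustained for two
#' consecutive bins; reported as the bin centre.
#'
#' @param trains list of spike-time vectors.
#' @param onset stimulus onset (ms).
#' @param bin bin width (ms).
#' @param baseline_window window before onset for the baseline (ms).
#' @return Latency (ms) or `NA` if no response is detected.
#' @export
response_latency <- function(trains, onset, bin = 10,
                             baseline_window = 1000) {
  h <- psth(trains, onset, bin = bin,
            window = c(-baseline_window, baseline_window))
  pre <- h$rate[h$mids < 0]
  thr <- mean(pre) + 2 * max(sd(pre), 1e-6)
  post <- which(h$mids > 0)
  above <- h$rate[post] > thr
  runs <- which(above & c(above[-1], FALSE))
  if (!length(runs)) return(NA_real_)
  h$mids[post[runs[1]]]
}

#' Stellate-cell burst response to a parallel-fiber train
#'
#' Runs repeated trials (train onset jittered by a random fraction of the
#' pacemaker cycle, seeded) and returns the burst statistics of the
#' response: baseline rate, during-train rate, percent increase, PSTH and
#' response latency.
#'
#' @param model an SC `cmodel`.
#' @param freq train frequency (Hz).
#' @param n_pulses pulses (10).
#' @param n_syn activated PF synapses (3).
#' @param trials number of jittered trials.
#' @param seed jitter seed.
#' @param nmda include NMDA components.
#' @param gaba_n number of co-activated inhibitory synapses (0 = none);
#'   when > 0 they are driven at 20 Hz for the train duration.
#' @param psth_bin PSTH bin width (ms; 40 default).
#' @return List with `baseline_hz`, `burst_hz`, `pct_increase`,
#'   `latency_ms`, `psth`, `trials`.
#' @export
sc_burst_response <- function(model, freq = 100, n_pulses = 10, n_syn = 3,
                              trials = 8, seed = 1, nmda = TRUE,
                              gaba_n = 0, psth_bin = 40) {
  m <- model
  m$synapses <- list()
  m <- attach_pf_synapses(m, n = n_syn, nmda = nmda)
  if (gaba_n > 0) m <- attach_gaba_synapses(m, n = gaba_n, seed = seed)
  onset <- 1500
  span <- (n_pulses - 1) / freq * 1000
  set.seed(seed)
  jit <- runif(trials, 0, 60)
  runs <- lapply(seq_len(trials), function(k) {
    ev <- onset + jit[k] + (seq_len(n_pulses) - 1) / freq * 1000
    mm <- .set_events(m, c("pf_ampa", "pf_nmda"), ev, n_syn = n_syn)
    if (gaba_n > 0) {
      bg <- inhibitory_background(rate = 20, n_syn = gaba_n,
                                  dur = span + 50, onset = onset + jit[k])
      mm <- .set_group_events(mm, "gaba", realize_events(bg, seed = seed + k))
    }
    tr <- .run_sim(mm, onset + jit[k] + span + 1000, record = "soma.v",
                   stride = 8L)
    tr$spikes[[1]] - jit[k]
  })
  base_win <- c(onset - 1000, onset)
  resp_win <- c(onset, onset + span + 10)
  base <- mean(vapply(runs, function(s) train_stats(s, base_win)$rate, 1.0))
  burst <- mean(vapply(runs, function(s) train_stats(s, resp_win)$rate, 1.0))
  list(baseline_hz = base, burst_hz = burst,
       pct_increase = (burst - base) / base * 100,
       latency_ms = response_latency(runs, onset),
       psth = psth(runs, onset, bin = psth_bin),
       trials = runs)
}

#' Stellate-cell input-output gain experiment
#'
#' Output burst frequency versus PF input frequency, with optional NMDA
#' block and co-activated inhibition.
#'
#' @param model an SC `cmodel`.
#' @param freqs input frequencies (Hz).
#' @param n_syn PF synapses (3).
#' @param nmda NMDA on/off.
#' @param gaba_n co-activated GABA-A synapses (0, 20, 27 or 32).
#' @param trials trials per frequency.
#' @param seed seed.
#' @return Data frame with `freq`, `baseline_hz`, `burst_hz`,
#'   `pct_increase`.
#' @export
sc_gain_experiment <- function(model, freqs = c(4, 10, 20, 50, 100, 200, 500),
                               n_syn = 3, nmda = TRUE, gaba_n = 0,
                               trials = 6, seed = 1) {
  rows <- lapply(freqs, function(f) {
    r <- sc_burst_response(model, freq = f, n_syn = n_syn, nmda = nmda,
                           gaba_n = gaba_n, trials = trials, seed = seed)
    data.frame(freq = f, baseline_hz = r$baseline_hz, burst_hz = r$burst_hz,
               pct_increase = r$pct_increase)
  })
  do.call(rbind, rows)
}

#' Calibrate the number of PF synapses for a target burst rate
#'
#' Sweeps the PF synapse count upward and returns the smallest count whose
#' 100-Hz during-train firing rate reaches the target.
#'
#' @param model an SC `cmodel`.
#' @param target_hz target burst rate (Hz). A target of 0 needs no
#'   synapses.
#' @param max_n sweep limit.
#' @param trials,seed trial settings per count.
#' @return Integer synapse count.
#' @export
calibrate_pf_count <- function(model, target_hz, max_n = 10, trials = 4,
                               seed = 1) {
  if (target_hz <= 0) return(0L)
  for (n in seq_len(max_n)) {
    r <- sc_burst_response(model, freq = 100, n_syn = n, trials = trials,
                           seed = seed)
    if (r$burst_hz >= target_hz) return(n)
  }
  stop("target burst rate not reached with ", max_n, " synapses")
}

#' Purkinje-cell filtering experiment
#'
#' For each input frequency and circuit condition (SC off, SC -> PC, and
#' optionally SC -> SC -> PC), stimulates the circuit with a 10-pulse PF
#' train and measures the PC burst rate (during-train), the gain relative
#' to the 4-Hz response of the same condition, the post-train pause, and
#' the response latency.
#'
#' @param sc_mod stellate-cell model.
#' @param pc_mod Purkinje stand-in model.
#' @param freqs input frequencies (Hz).
#' @param n_sc_pc SC->PC synapse count.
#' @param conditions subset of `c("sc_off", "sc_pc", "sc_sc_pc")`.
#' @param trials jittered trials per point.
#' @param seed seed.
#' @return Data frame (`freq`, `condition`, `baseline_hz`, `burst_hz`,
#'   `gain`, `pause_ms`, `latency_ms`).
#' @export
run_filtering <- function(sc_mod = sc_model(), pc_mod = purkinje_model(),
                          freqs = c(4, 10, 20, 50, 100, 200, 500),
                          n_sc_pc = 100,
                          conditions = c("sc_off", "sc_pc"),
                          trials = 4, seed = 1) {
  out <- list()
  for (cond in conditions) {
    cfg <- circuit_config(n_sc_pc = n_sc_pc,
                          sc_enabled = cond != "sc_off",
                          sc_sc_enabled = cond == "sc_sc_pc",
                          seed = seed)
    circ <- build_circuit(cfg, sc_model_1 = sc_mod, pc_model = pc_mod)
    rows <- lapply(freqs, function(f) {
      set.seed(seed + round(f))
      jit <- runif(trials, 0, 25)
      runs <- lapply(seq_len(trials), function(k) {
        ev <- 1500 + jit[k] + (seq_len(10) - 1) / f * 1000
        mm <- .set_events(circ, c("pf_ampa", "pf_nmda", "pc_pf"), ev)
        tr <- .run_sim(mm, max(ev) + 1500, record = "pc.soma.v", stride = 8L)
        lapply(tr$spikes, function(s) s - jit[k])
      })
      pc_sp <- lapply(runs, `[[`, "pc")
      span <- (10 - 1) / f * 1000
      base <- mean(vapply(pc_sp, function(s)
        train_stats(s, c(500, 1500))$rate, 1.0))
      burst <- mean(vapply(pc_sp, function(s)
        train_stats(s, c(1500, 1500 + span + 10))$rate, 1.0))
      pauses <- vapply(pc_sp, function(s) {
        p <- pause_length(s, 1500 + span, 1000 / max(base, 1))
        if (is.na(p)) 1500 - span else p
      }, 1.0)
      data.frame(freq = f, condition = cond, baseline_hz = base,
                 burst_hz = burst,
                 pause_ms = mean(pauses),
                 latency_ms = response_latency(pc_sp, 1500))
    })
    tab <- do.call(rbind, rows)
    tab$gain <- tab$burst_hz / tab$burst_hz[tab$freq == 4]
    out[[cond]] <- tab
  }
  do.call(rbind, out)
}

#' EPSC gain curve of the Purkinje-cell stand-in
#'
#' Voltage-clamps the (passive-ized) Purkinje stand-in at -70 mV and
#' measures the PF-train gain curve of its calibrated PF synapse, exactly
#' as [synaptic_gain_curve()] does for the stellate cell.
#'
#' @param model a Purkinje `cmodel`.
#' @param freqs train frequencies (Hz).
#' @param n_pulses pulses per train.
#' @return List with `freq`, `gain`, `fit`, `f50`.
#' @export
pc_gain_curve <- function(model = purkinje_model(),
                          freqs = c(4, 10, 20, 50, 100, 200, 500),
                          n_pulses = 20) {
  g0 <- model$conductances; g0[] <- 0
  m <- set_conductances(model, g0)
  m$synapses <- list()
  m <- attach_pc_pf_synapses(m, n = 1)
  gain <- vapply(freqs, function(f) {
    train <- train_protocol(n_pulses = n_pulses, freq = f, n_syn = 1,
                            onset = 200, post = 300)
    tr <- run_protocol(m, clamp_protocol(v = -70, train = train))
    ev <- realize_events(train)
    amp <- .epsc_amplitudes(tr$t, tr$i_clamp, ev)
    base0 <- mean(tr$i_clamp[tr$t >= 180 & tr$t < 200])
    env <- base0 - min(tr$i_clamp[tr$t >= 200 & tr$t <= max(ev) + 20])
    env / amp[1]
  }, 1.0)
  fit <- gain_sigmoid_fit(freqs, gain)
  list(freq = freqs, gain = gain, fit = fit, f50 = fit$f50)
}
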