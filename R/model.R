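#' The 36-slot conductance layout of the stellate-cell model
#'
#' Channel x compartment-class grid of the free maximum-conductance
#' parameters. The layout (which of the 14 channels populate which of the
#' five electrotonic compartment classes) is an explicit modelling
#' assumption of this package: 11 somatic, 9 proximal-dendritic, 9
#' distal-dendritic, 4 AIS and 3 axonal slots, 36 in total. The leak is
#' fixed at 3e-5 S/cm2 on every compartment and is not a free slot.
#'
#' @return Data frame with columns `class`, `channel`, `default`, `low`,
#'   `high` (S/cm2).
#' @export
conductance_layout <- function() {
  slot <- function(class, channel, default, low = default / 10,
                   high = default * 10) {
    data.frame(class = class, channel = channel, default = default,
               low = low, high = high)
  }
  rows <- list(
    # soma: full pacemaking complement
    slot("soma", "Nav1.1", 0.10),
    slot("soma", "Nav1.6", 0.035),
    slot("soma", "Kv3.4", 0.06),
    slot("soma", "Kv4.3", 5e-4),
    slot("soma", "Kir2.3", 1e-4),
    slot("soma", "Kv7", 2e-4),
    slot("soma", "KCa1.1", 0.01),
    slot("soma", "KCa2.2", 1e-5),
    slot("soma", "Cav2.1", 1.5e-3),
    slot("soma", "Cav3.2", 8e-4),
    slot("soma", "HCN1", 7e-4),
    # proximal dendrites
    slot("prox_dend", "Kv3.4", 1e-2),
    slot("prox_dend", "Kv4.3", 8e-4),
    slot("prox_dend", "Kir2.3", 5e-4),
    slot("prox_dend", "KCa1.1", 4e-3),
    slot("prox_dend", "KCa2.2", 1e-5),
    slot("prox_dend", "Cav2.1", 8e-4),
    slot("prox_dend", "Cav3.2", 6e-4),
    slot("prox_dend", "Cav3.3", 2e-4),
    slot("prox_dend", "HCN1", 5.2e-4),
    # distal dendrites
    slot("dist_dend", "Kv3.4", 8e-3),
    slot("dist_dend", "Kv4.3", 5e-4),
    slot("dist_dend", "Kv7", 1e-4),
    slot("dist_dend", "KCa1.1", 3e-3),
    slot("dist_dend", "KCa2.2", 1e-5),
    slot("dist_dend", "Cav2.1", 5e-4),
    slot("dist_dend", "Cav3.2", 4e-4),
    slot("dist_dend", "Cav3.3", 2e-4),
    slot("dist_dend", "HCN1", 2.6e-4),
    # axon initial segment: spike initiation
    slot("ais", "Nav1.6", 1.0),
    slot("ais", "Kv3.4", 0.1),
    slot("ais", "Kv1.1", 0.1),
    slot("ais", "Cav2.1", 5e-4),
    # axon
    slot("axon", "Nav1.6", 0.03),
    slot("axon", "Kv3.4", 0.03),
    slot("axon", "Kv1.1", 0.1))
  out <- do.call(rbind, rows)
  rownames(out) <- paste(out$class, out$channel, sep = ".")
  out
}

#' Default (reference) conductance set of the stellate-cell model
#'
#' Named vector of the 36 maximum conductance densities (S/cm2), keyed
#' `class.channel`. These are the package's reference values, calibrated
#' against the recorded stellate-cell electroresponsiveness (pacemaking
#' rate, sag, rebound, f-I slope and spike shape); [optimize_conductances()]
#' refines them per morphology.
#'
#' @return Named numeric vector of length 36.
#' @export
sc_default_conductances <- function() {
  lay <- conductance_layout()
  setNames(lay$default, rownames(lay))
}

# reduce a classified morphology to the lumped compartment tree used by the
# solver: soma + 3 proximal + 3 distal dendritic compartments + AIS + axon
.reduce_morphology <- function(morph, cutoff_um = 0.6, ais_length = 28,
                               n_branch = 3) {
  n <- morph$nodes
  cls <- classify_compartments(morph, cutoff_um, ais_length)
  len <- .edge_lengths(n)
  diam <- 2 * n$radius
  area_of <- function(sel) sum(pi * diam[sel] * len[sel])
  len_of <- function(sel) sum(len[sel])

  soma_d <- mean(diam[cls == "soma"])
  soma_L <- max(len_of(cls == "soma"), soma_d)
  a_pr <- area_of(cls == "prox_dend"); l_pr <- len_of(cls == "prox_dend")
  a_di <- area_of(cls == "dist_dend"); l_di <- len_of(cls == "dist_dend")
  a_ais <- area_of(cls == "ais"); l_ais <- max(len_of(cls == "ais"), 1)
  a_ax <- area_of(cls == "axon")
  l_ax_eff <- 200  # effective (lumped) axonal cable length, um
  if (a_pr <= 0 || a_di <= 0) stop("morphology lacks a dendrite class")

  cyl <- function(name, class, L, area, cm, parent) {
    data.frame(name = name, class = class, L_um = L, diam_um = 0,
               area_cm2 = area, cm = cm, parent = parent,
               stringsAsFactors = FALSE)
  }
  um2_to_cm2 <- 1e-8
  comp <- rbind(
    cyl("soma", "soma", soma_L, soma_d * soma_L * pi * um2_to_cm2, 1.0, -1),
    cyl("ais", "ais", l_ais, max(a_ais, 10) * um2_to_cm2, 1.0, 1),
    cyl("axon", "axon", l_ax_eff, max(a_ax, 50) * um2_to_cm2, 1.0, 2))
  for (b in seq_len(n_branch)) {
    comp <- rbind(comp,
      cyl(paste0("prox", b), "prox_dend", l_pr / n_branch / 2,
          a_pr / n_branch * um2_to_cm2, 1.5, 1))
    comp <- rbind(comp,
      cyl(paste0("dist", b), "dist_dend", l_di / n_branch / 2,
          a_di / n_branch * um2_to_cm2, 1.5, nrow(comp)))
  }
  # geometric diameter consistent with area = pi * d * L
  comp$diam_um <- comp$area_cm2 / um2_to_cm2 / (pi * comp$L_um)
  rownames(comp) <- comp$name
  comp
}

#' Build a stellate-cell compartmental model
#'
#' Reduces a morphology (supplied or generated) to the five-class
#' electrical backbone -- soma, proximal and distal dendritic branches
#' (three each), AIS and axon -- and attaches the channel complement
#' defined by [conductance_layout()].
#'
#' @param morph an [morphology()] object, or `NULL` to generate one.
#' @param conductances named vector (`class.channel`, S/cm2); defaults to
#'   [sc_default_conductances()].
#' @param seed seed for the morphology generator when `morph` is `NULL`.
#' @param g_leak leak conductance density (S/cm2) applied to every
#'   compartment.
#' @param celsius simulation temperature.
#' @param dt integration step (ms).
#' @param v_init initial membrane potential (mV).
#' @param r_axial axial resistivity (Ohm cm).
#' @return An object of class `cmodel`.
#' @export
sc_model <- function(morph = NULL, conductances = sc_default_conductances(),
                     seed = 1, g_leak = 3e-5, celsius = 32, dt = 0.025,
                     v_init = -70, r_axial = 110) {
  if (is.null(morph)) morph <- generate_sc_morphology(seed = seed)
  comp <- .reduce_morphology(morph)
  chans <- .conductance_table(comp, conductances, g_leak)
  structure(list(compartments = comp, channels = chans,
                 conductances = conductances,
                 synapses = list(), cells = list(sc = 1L),
                 reversal = reversal_set(), ca = calcium_pool(),
                 celsius = celsius, dt = dt, v_init = v_init,
                 r_axial = r_axial, theta = 0.5,
                 morphology = morph),
            class = "cmodel")
}

# expand class-level conductances into per-compartment channel rows
.conductance_table <- function(comp, conductances, g_leak) {
  rows <- list()
  for (i in seq_len(nrow(comp))) {
    rows[[length(rows) + 1]] <-
      data.frame(comp = i, channel = "leak", g = g_leak)
    keys <- names(conductances)[startsWith(names(conductances),
                                           paste0(comp$class[i], "."))]
    for (k in keys) {
      g <- conductances[[k]]
      if (g <= 0) next
      ch <- sub("^[^.]+\\.", "", k)
      rows[[length(rows) + 1]] <- data.frame(comp = i, channel = ch, g = g)
    }
  }
  do.call(rbind, rows)
}

#' Replace a model's conductance set
#'
#' @param model a `cmodel`.
#' @param conductances named vector (`class.channel`, S/cm2). Values for
#'   missing slots keep their current value; set a slot to 0 to knock the
#'   channel out in that class.
#' @param g_leak optional leak override (S/cm2).
#' @return The updated model.
#' @export
set_conductances <- function(model, conductances, g_leak = 3e-5) {
  full <- model$conductances
  full[names(conductances)] <- conductances
  model$conductances <- full
  model$channels <- .conductance_table(model$compartments, full, g_leak)
  model
}

#' Knock out a channel everywhere in the model
#'
#' Sets every conductance slot of `channel` (in all compartment classes)
#' to zero -- the in silico analogue of a selective channel blocker.
#'
#' @param model a `cmodel`.
#' @param channel channel name, e.g. `"HCN1"`.
#' @return The updated model.
#' @export
knockout <- function(model, channel) {
  g <- model$conductances
  sel <- grepl(paste0("\\.", channel, "$"), names(g))
  g[sel] <- 0
  set_conductances(model, g)
}

# bake gate tables (Q10-corrected to model temperature) for the compiled core
.bake_gates <- function(spec, celsius, v0 = -120, v1 = 60, dv = 0.25) {
  lapply(spec$gates, function(g) {
    tadj <- g$q10^((g$t_ref - celsius) / 10)
    if (g$kind == "v") {
      v <- seq(v0, v1, by = dv)
      list(kind = 0L, power = g$power, v0 = v0, dv = dv,
           inf = g$inf(v, 5e-5), tau = pmax(g$tau(v, 5e-5) * tadj, 1e-3))
    } else if (g$kind == "ca") {
      p <- g$params
      list(kind = 1L, power = g$power, kd = p[["kd"]], hill = p[["hill"]],
           tau = max(p[["tau"]] * tadj, 1e-3))
    } else {
      p <- g$params
      list(kind = 2L, power = g$power, vh0 = p[["vh0"]], k = p[["k"]],
           cashift = p[["cashift"]], caref = p[["caref"]],
           tau = max(p[["tau"]] * tadj, 1e-3))
    }
  })
}

#' Assemble a model into the solver-ready representation
#'
#' Computes absolute capacitances and channel conductances, axial coupling
#' conductances `g = (pi d^2 / 4) / (R_axial L)` combined in series between
#' adjacent compartments, bakes temperature-corrected gate tables, and
#' validates tree connectivity.
#'
#' @param model a `cmodel`.
#' @return List consumed by the compiled integrator core.
#' @export
assemble <- function(model) {
  comp <- model$compartments
  nc <- nrow(comp)
  parent <- comp$parent
  roots <- sum(parent == -1)
  if (roots < 1) stop("no root compartment")
  # connectivity: every compartment reaches a root
  for (i in seq_len(nc)) {
    j <- i; seen <- 0
    while (parent[j] != -1) {
      j <- parent[j]; seen <- seen + 1
      if (seen > nc) stop("disconnected or cyclic compartments")
    }
  }
  if (any(parent >= seq_len(nc))) stop("compartments must be parent-ordered")

  # axial: half-cylinder resistances in series between centres
  half_r <- function(i) {
    L_cm <- comp$L_um[i] * 1e-4
    d_cm <- comp$diam_um[i] * 1e-4
    model$r_axial * (L_cm / 2) / (pi * d_cm^2 / 4)   # Ohm
  }
  g_ax <- numeric(nc)
  for (i in seq_len(nc)) {
    if (parent[i] == -1) next
    g_ax[i] <- 1 / (half_r(i) + half_r(parent[i])) * 1e6   # uS
  }

  lib <- builtin_channel_library()
  chl <- list()
  ca_comps <- integer(0)
  for (r in seq_len(nrow(model$channels))) {
    ch <- model$channels$channel[r]
    ci <- model$channels$comp[r]
    spec <- lib[[ch]]
    if (is.null(spec)) stop("unknown channel '", ch, "'")
    erev <- model$reversal[[spec$ion]]
    chl[[length(chl) + 1]] <- list(
      comp = ci - 1L,
      g_uS = model$channels$g[r] * comp$area_cm2[ci] * 1e6,
      erev = erev,
      is_ca = identical(spec$ion, "Ca"),
      gates = .bake_gates(spec, model$celsius))
    if (identical(spec$ion, "Ca") || ch %in% c("KCa1.1", "KCa2.2"))
      ca_comps <- union(ca_comps, ci)
  }

  pool <- model$ca
  pools <- lapply(sort(ca_comps), function(ci) {
    depth_cm <- pool$depth * 1e-4
    list(comp = ci - 1L, rest = pool$rest,
         fca = 1e-6 / (comp$area_cm2[ci] * 2 * 96485 * depth_cm),
         tau_ex = pool$tau_ex, btot = pool$btot, kf = pool$kf, kb = pool$kb)
  })

  syl <- lapply(model$synapses, function(s) {
    s$comp <- s$comp - 1L
    s$src <- if (is.null(s$src)) -1L else as.integer(s$src)
    s$g_uS <- s$g_pS * 1e-6
    s
  })

  list(parent = as.integer(ifelse(parent == -1, 0L, parent) - 1L),
       cap_nF = comp$cm * comp$area_cm2 * 1e3,
       g_axial_uS = g_ax,
       area_cm2 = comp$area_cm2,
       v_init = rep(model$v_init, nc),
       channels = chl,
       ca_pools = pools,
       synapses = syl)
}
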