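#' Reversal potentials for the stellate-cell model
#'
#' Fixed reversal potentials (mV) for each ionic species carried by the
#' channel library. Values are not recomputed from concentrations during a
#' simulation.
#'
#' @return Named list with elements `Na`, `K`, `Ca`, `h`, `leak` (mV).
#' @export
reversal_set <- function() {
  list(Na = 60, K = -84, Ca = 137.5, h = -34, leak = -48)
}

# Boltzmann steady state
.boltz <- function(v, half, k) 1 / (1 + exp(-(v - half) / k))
# bell-shaped voltage dependence for time constants
.bell <- function(v, base, amp, centre, width) {
  base + amp * exp(-((v - centre) / width)^2)
}

#' Construct a gate specification
#'
#' A gate is defined by its steady-state and time-constant functions of
#' voltage (and, for calcium-dependent gates, of the local calcium
#' concentration), the exponent with which it enters the channel open
#' fraction, and the reference temperature of its kinetics.
#'
#' @param name gate label (e.g. `"m"`, `"h"`).
#' @param power integer exponent (>= 1).
#' @param inf function of `(v, ca)` returning the steady state in `[0, 1]`.
#' @param tau function of `(v, ca)` returning the time constant (ms, > 0)
#'   at `t_ref`.
#' @param kind `"v"` for tabulated voltage gates, `"ca"` for purely
#'   calcium-dependent gates, `"bk"` for the joint voltage/calcium gate used
#'   by large-conductance calcium-activated potassium channels.
#' @param params numeric parameters for `"ca"`/`"bk"` kinds (passed to the
#'   compiled core).
#' @param q10 temperature coefficient for `tau` (default 3).
#' @param t_ref reference temperature in degrees Celsius.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(name, power, inf, tau, kind = "v", params = NULL,
                      q10 = 3, t_ref = 32) {
  stopifnot(power >= 1)
  structure(list(name = name, power = as.integer(power), inf = inf, tau = tau,
                 kind = kind, params = params, q10 = q10, t_ref = t_ref),
            class = "gate_spec")
}

#' Evaluate a gate's steady state and temperature-corrected time constant
#'
#' The time constant is scaled from the gate's reference temperature with
#' `tau(T) = tau(t_ref) * q10^((t_ref - T)/10)`; the steady state is
#' temperature independent.
#'
#' @param spec a [gate_spec()].
#' @param v membrane potential (mV).
#' @param ca calcium concentration (mM), used by calcium-dependent gates.
#' @param temp simulation temperature (degrees Celsius).
#' @return List with vectors `inf` and `tau`.
#' @export
gate_dynamics <- function(spec, v, ca = 5e-5, temp = 32) {
  inf <- spec$inf(v, ca)
  tau <- spec$tau(v, ca) * spec$q10^((spec$t_ref - temp) / 10)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("gate '", spec$name, "': non-positive time constant")
  list(inf = inf, tau = tau)
}

.channel <- function(name, ion, gates) {
  structure(list(name = name, ion = ion, gates = gates),
            class = "channel_spec")
}

#' Built-in ionic channel library
#'
#' Returns the 14 channel mechanisms of the stellate-cell model: transient
#' and persistent-type sodium channels (Nav1.1, Nav1.6), the potassium
#' complement (Kv3.4, Kv4.3, Kv1.1, Kir2.3, Kv7, and the calcium-activated
#' KCa1.1 and KCa2.2), high- and low-voltage-activated calcium channels
#' (Cav2.1, Cav3.2, Cav3.3), the hyperpolarization-activated HCN1 current,
#' and the ohmic leak. Kinetics are Hodgkin-Huxley style parameterizations
#' in the tradition of cerebellar compartmental models (granule, Golgi and
#' Purkinje cell literature), authored at a reference temperature of 32
#' degrees Celsius with Q10 = 3 available for rescaling. Every kinetic
#' constant can be overridden through the model configuration.
#'
#' Kinetic character per isoform:
#' \itemize{
#'   \item Nav1.1: fast transient Na (m^3 h), spike upstroke.
#'   \item Nav1.6: lower-threshold Na with incomplete inactivation (0.5\%
#'     non-inactivating fraction), supplying the persistent current that
#'     sustains pacemaking; concentrated in the AIS.
#'   \item Kv3.4: high-threshold fast delayed rectifier (n^2), spike
#'     repolarization.
#'   \item Kv4.3: A-type (a^3 b) with subthreshold inactivation; delays
#'     rebound spikes.
#'   \item Kv1.1: low-threshold slow rectifier (n^4).
#'   \item Kir2.3: inward rectifier, steeply closing with depolarization.
#'   \item Kv7: slow M-type current.
#'   \item KCa1.1 (BK): joint voltage/calcium activation, half-activation
#'     voltage shifting -25 mV per decade of calcium.
#'   \item KCa2.2 (SK): purely calcium-dependent (Hill coefficient 4).
#'   \item Cav2.1 (P/Q): high-voltage-activated (m^2), main calcium source.
#'   \item Cav3.2 / Cav3.3: low-voltage-activated T-type (m^2 h), fast and
#'     slow variants; rebound burst generators.
#'   \item HCN1: activated by hyperpolarization, sag and pause regulation.
#'   \item leak: gateless ohmic conductance.
#' }
#'
#' @return Named list of `channel_spec` objects (length 14).
#' @export
builtin_channel_library <- function() {
  lib <- list(
    Nav1.1 = .channel("Nav1.1", "Na", list(
      gate_spec("m", 3,
                function(v, ca) .boltz(v, -35, 5.5),
                function(v, ca) .bell(v, 0.04, 0.25, -38, 25)),
      gate_spec("h", 1,
                function(v, ca) .boltz(v, -58, -6),
                function(v, ca) .bell(v, 0.30, 6.0, -58, 20)))),
    Nav1.6 = .channel("Nav1.6", "Na", list(
      gate_spec("m", 3,
                function(v, ca) .boltz(v, -40, 5),
                function(v, ca) .bell(v, 0.04, 0.25, -42, 25)),
      gate_spec("h", 1,
                function(v, ca) 0.003 + 0.997 * .boltz(v, -55, -4.5),
                function(v, ca) .bell(v, 0.50, 8.0, -60, 20)))),
    Kv3.4 = .channel("Kv3.4", "K", list(
      gate_spec("n", 2,
                function(v, ca) .boltz(v, -22, 7),
                function(v, ca) .bell(v, 0.30, 1.0, -15, 25)))),
    Kv4.3 = .channel("Kv4.3", "K", list(
      gate_spec("a", 3,
                function(v, ca) .boltz(v, -45, 9),
                function(v, ca) .bell(v, 0.30, 1.5, -50, 30)),
      gate_spec("b", 1,
                function(v, ca) .boltz(v, -70, -6.5),
                function(v, ca) .bell(v, 12, 50, -70, 25)))),
    Kv1.1 = .channel("Kv1.1", "K", list(
      gate_spec("n", 4,
                function(v, ca) .boltz(v, -32, 9),
                function(v, ca) .bell(v, 1.0, 8.0, -40, 35)))),
    Kir2.3 = .channel("Kir2.3", "K", list(
      gate_spec("a", 1,
                function(v, ca) .boltz(v, -95, -10),
                function(v, ca) .bell(v, 0.3, 0.7, -95, 30)))),
    Kv7 = .channel("Kv7", "K", list(
      gate_spec("n", 1,
                function(v, ca) .boltz(v, -42, 8.5),
                function(v, ca) .bell(v, 50, 130, -50, 25)))),
    KCa1.1 = .channel("KCa1.1", "K", list(
      gate_spec("m", 1,
                function(v, ca) {
                  vh <- -10 - 25 * log10(pmax(ca, 1e-12) / 1e-2)
                  .boltz(v, vh, 10)
                },
                function(v, ca) rep(1, length(v)),
                kind = "bk",
                params = c(vh0 = -10, k = 10, cashift = 25,
                           caref = 1e-2, tau = 1)))),
    KCa2.2 = .channel("KCa2.2", "K", list(
      gate_spec("z", 1,
                function(v, ca) {
                  r <- (pmax(ca, 1e-12) / 4e-4)^4
                  r / (1 + r)
                },
                function(v, ca) rep(8, length(v)),
                kind = "ca",
                params = c(kd = 4e-4, hill = 4, tau = 8)))),
    Cav2.1 = .channel("Cav2.1", "Ca", list(
      gate_spec("m", 2,
                function(v, ca) .boltz(v, -22, 5.5),
                function(v, ca) .bell(v, 0.1, 0.6, -25, 20)))),
    Cav3.2 = .channel("Cav3.2", "Ca", list(
      gate_spec("m", 2,
                function(v, ca) .boltz(v, -48, 5.5),
                function(v, ca) .bell(v, 1.0, 3.0, -50, 25)),
      gate_spec("h", 1,
                function(v, ca) .boltz(v, -73, -4.5),
                function(v, ca) .bell(v, 12, 45, -73, 25)))),
    Cav3.3 = .channel("Cav3.3", "Ca", list(
      gate_spec("m", 2,
                function(v, ca) .boltz(v, -46, 6),
                function(v, ca) .bell(v, 4, 12, -50, 25)),
      gate_spec("h", 1,
                function(v, ca) .boltz(v, -72, -5),
                function(v, ca) .bell(v, 80, 180, -70, 30)))),
    HCN1 = .channel("HCN1", "h", list(
      gate_spec("h", 1,
                function(v, ca) .boltz(v, -75, -6.5),
                function(v, ca) .bell(v, 60, 220, -80, 25)))),
    leak = .channel("leak", "leak", list())
  )
  lib
}

#' Ionic current density of a channel
#'
#' Ohmic form `I = G_max * prod(g_i^p_i) * (V - E_ion)`, outward positive.
#' Calcium channels use the fixed calcium reversal potential (no
#' Goldman-Hodgkin-Katz rectification).
#'
#' @param spec a `channel_spec`.
#' @param gates_state numeric vector of gate states, one per gate, in
#'   `[0, 1]`.
#' @param g_max maximum conductance density (S/cm2).
#' @param v membrane potential (mV).
#' @param reversals a [reversal_set()].
#' @return Current density in mA/cm2.
#' @export
channel_current <- function(spec, gates_state, g_max, v,
                            reversals = reversal_set()) {
  if (is.null(reversals[[spec$ion]]))
    stop("unknown ion '", spec$ion, "'")
  stopifnot(length(gates_state) == length(spec$gates))
  open <- 1
  for (i in seq_along(spec$gates)) {
    s <- gates_state[i]
    if (s < 0 || s > 1) stop("gate state outside [0, 1]")
    open <- open * s^spec$gates[[i]]$power
  }
  g_max * open * (v - reversals[[spec$ion]])
}

#' Construct a sub-membrane calcium pool
#'
#' A single shell below the membrane accumulates calcium entering through
#' high- and low-voltage-activated calcium channels, exchanges it with a
#' parvalbumin-like buffer, and extrudes it back to the resting
#' concentration with first-order kinetics.
#'
#' @param rest resting calcium concentration (mM).
#' @param depth shell depth (um).
#' @param tau_ex extrusion time constant (ms).
#' @param btot total buffer concentration (mM).
#' @param kf buffer forward (binding) rate (1/mM/ms).
#' @param kb buffer backward (unbinding) rate (1/ms).
#' @return An object of class `calcium_pool`.
#' @export
calcium_pool <- function(rest = 5e-5, depth = 0.2, tau_ex = 6,
                         btot = 0.05, kf = 0.04, kb = 1e-3) {
  structure(list(rest = rest, depth = depth, tau_ex = tau_ex,
                 btot = btot, kf = kf, kb = kb,
                 ca = rest,
                 bound = if (kb > 0) btot * kf * rest / (kf * rest + kb) else 0),
            class = "calcium_pool")
}

#' Advance a calcium pool by one time step
#'
#' Reference (R) implementation of the update used by the compiled core:
#' influx proportional to `-I_Ca * area / (2 F * shell volume)`, single
#' buffer species with mass-action kinetics, first-order extrusion toward
#' the resting concentration. The concentration never becomes negative.
#'
#' @param pool a [calcium_pool()].
#' @param i_ca calcium current density (mA/cm2, outward positive; influx is
#'   negative).
#' @param area membrane area (cm2) -- enters only through the shell volume,
#'   so the per-concentration update is area independent.
#' @param dt time step (ms).
#' @return The updated pool.
#' @export
step_calcium <- function(pool, i_ca, area, dt) {
  stopifnot(dt > 0)
  depth_cm <- pool$depth * 1e-4
  influx <- max(0, -i_ca / (2 * 96485 * depth_cm))  # mM/ms
  bfree <- pool$btot - pool$bound
  dbound <- (pool$kf * pool$ca * bfree - pool$kb * pool$bound) * dt
  bound_new <- pool$bound + dbound
  if (bound_new < 0) { dbound <- dbound - bound_new; bound_new <- 0 }
  if (bound_new > pool$btot) {
    dbound <- dbound - (bound_new - pool$btot); bound_new <- pool$btot
  }
  pool$bound <- bound_new
  pool$ca <- pool$ca + (influx - (pool$ca - pool$rest) / pool$tau_ex) * dt -
    dbound
  pool$ca <- max(pool$ca, 1e-12)
  pool
}
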