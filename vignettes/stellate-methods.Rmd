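---
title: "Modelling cerebellar stellate cells and molecular-layer filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebellar stellate cells and molecular-layer filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

Stellate cells (SCs) are the inhibitory interneurons of the outer
cerebellar molecular layer. They pace-make spontaneously in the 16-36 Hz
range, respond to hyperpolarization with an HCN-mediated sag and
low-voltage-activated calcium-dependent rebound, and are driven by
parallel fibers (PFs) through strongly facilitating synapses. Because they
inhibit Purkinje cells (PCs) — and each other — their short-term synaptic
dynamics shape how PF bursts are transmitted through the molecular layer.

`stellate` implements this system end to end as a compartmental
conductance-based simulator:

* a statistical SC **morphology generator** matching the published summary
  morphometrics (soma surface 42.4 ± 9.3 µm², total dendritic length
  845.2 ± 121.2 µm, 11 ± 3 proximal and 63.5 ± 14 distal dendritic
  segments split at a 0.6-µm diameter cut-off, 28-µm AIS, 578-µm axon),
  plus standard SWC input/output;
* a **channel library** of 14 mechanisms (Nav1.1, Nav1.6, Kv3.4, Kv4.3,
  Kv1.1, Kir2.3, Kv7, KCa1.1, KCa2.2, Cav2.1, Cav3.2, Cav3.3, HCN1, leak)
  with a sub-membrane calcium shell and parvalbumin-like buffering;
* an implicit fixed-step **cable solver** (compiled core);
* **Tsodyks–Markram synapses** (AMPA, NMDA, GABA-A) with two-state
  receptor waveforms;
* an **IBEA optimizer** for the 36 free maximum-conductance parameters;
* the **PF → SC → PC microcircuit** with a reduced PC stand-in.

The electrical backbone is deliberately compact: each SC is reduced to
nine compartments covering the five electrotonic classes (soma, three
proximal and three distal dendritic branches, AIS, axon). Passive
parameters follow the recorded preparation: axial resistivity 110 Ω·cm,
specific capacitance 1.5 µF/cm² in dendrites and 1.0 µF/cm² elsewhere,
leak 3·10⁻⁵ S/cm² with E_leak = −48 mV, and fixed reversal potentials
E_Na = 60, E_K = −84, E_Ca = 137.5, E_h = −34 mV. All simulations run at
32 °C with a 0.025-ms step; kinetics defined at other reference
temperatures are rescaled with Q10 = 3.

## Numerical scheme

The voltage update is a theta-method on the branched cable equation
(Crank–Nicolson by default, `theta = 1` gives backward Euler), solved
directly per step with a Hines elimination over the compartment tree.
Gating variables advance by exact exponential integration against
`(inf, tau)` evaluated at the present voltage and calcium (staggered
update); voltage-dependent gates are tabulated on a 0.25-mV grid together
with their per-step decay factors. Calcium pools and synaptic receptor
states are advanced after the voltage solve. The solver reports the
maximum charge-balance residual of the accepted steps (typically around
1e-13 mA/cm²; the test suite enforces < 1e-6), and halving the time step
moves pacemaker spike times by well under a millisecond per spike. Spike
*detection* uses an upward crossing of −20 mV with a 1-ms refractory
period; spike-threshold *measurement* uses the second-derivative
criterion described below.

## Channel kinetics: provenance and choices

The printed description of the cell fixes the channel inventory, the
reversal potentials and the passive frame, but not the rate equations of
the individual isoforms. The library therefore provides Hodgkin–Huxley
style parameterizations in the idiom of cerebellar compartmental models
(granule-, Golgi- and Purkinje-cell modelling literature), authored at a
reference temperature of 32 °C and fully exposed through
`builtin_channel_library()` and the configuration layer so that alternate
kinetics can be swapped in. Choices that matter:

* **Nav1.6** carries a small (0.5%) non-inactivating fraction and a
  left-shifted activation relative to Nav1.1; concentrated in the AIS, it
  supplies the persistent drive that sustains pacemaking. Its steep
  inactivation (half −55 mV) plus the strong low-threshold Kv1.1 in the
  AIS/axon prevent depolarization block under strong synaptic drive.
* **KCa1.1 (BK)** uses a joint voltage/calcium gate whose half-activation
  voltage shifts −25 mV per decade of calcium around a 10-µM reference —
  so it opens only during the spike-evoked calcium transient and closes
  on repolarization (fast AHP), rather than acting as a tonic potassium
  leak at resting calcium.
* **KCa2.2 (SK)** is purely calcium-gated (Hill coefficient 4,
  K_d 0.4 µM).
* **Calcium channels** use an ohmic driving force with the fixed
  E_Ca = 137.5 mV rather than a Goldman–Hodgkin–Katz form, consistent
  with the printed reversal.
* The **calcium shell** is 0.2 µm deep with first-order extrusion
  (τ = 6 ms) and a slow parvalbumin-like buffer (k_on 0.04 /mM/ms,
  k_off 1e-3 /ms, 50 µM). The extrusion time constant controls how much
  window-current calcium accumulates between spikes and therefore how
  strongly the KCa channels brake the pacemaker; 6 ms keeps the
  interspike calcium near rest while preserving a clear spike transient.

## Synapses

Presynaptic dynamics follow the Tsodyks–Markram scheme in the variant
where utilization decays to zero between spikes and the facilitation
increment `u += p (1 - u)` is applied *before* release, so the first
release from rest equals the baseline release probability `p`. The
printed parameter sets are used verbatim: PF→SC AMPA
{p = 0.15, τ_rec = 35.1 ms, τ_fac = 10.8 ms, 2300 pS, 0 mV}, PF→SC NMDA
{p = 0.15, τ_rec = 8 ms, τ_fac = 5 ms, 10000 pS, −3.7 mV} and SC GABA-A
{p = 0.42, τ_rec = 38.7 ms, τ_fac = 0, 1600 pS, −65 mV}. The same
event-driven recursion is implemented twice — once in R
(`tm_update()`, the test oracle) and once in the compiled core — and both
are held to the analytic fixed point of the two-map recursion to 1e-9.

Receptor waveforms are two-state: instantaneous rise with
single-exponential decay for AMPA (1 ms) and GABA-A (13 ms), slow
bi-exponential rise/decay for NMDA. Three receptor-level parameters stand
in for the multi-state Markov schemes whose rate constants are not
printed, and were calibrated once against the published synaptic
behaviour and then frozen:

* AMPA carries use-dependent desensitization (fraction 0.7 per unit
  release, recovery 100 ms), which caps the response growth above
  ~100 Hz;
* the NR2B-type NMDA component has low per-release efficacy (`po` =
  0.04), a saturating activation ceiling (`act_max` = 0.3 of G_max), a
  220-ms decay and a shallow magnesium block (γ = 0.03 /mV at 1 mM).

With these choices the 20-pulse PF train gain curve of the SC — the ratio
between the maximum compound EPSC (relative to the pre-train baseline)
and the first EPSC, under somatic voltage clamp at −70 mV with the
voltage-gated complement silenced, the in-silico analogue of the
caesium/QX-314 recording solution — is sigmoidal in log-frequency with a
half-maximal frequency of ~50 Hz, while the unclamped burst drive remains
physiological (the NMDA share of the 100-Hz burst is modest, matching the
reported small effect of NMDA block). The PC stand-in's PF synapse (a
fast AMPA component plus a slow saturating component) was calibrated the
same way to a ~10-Hz half-maximal frequency.

## Feature extraction

All analysis follows the recorded-data definitions: AP threshold at the
maximum of the second derivative on the rising phase (a Savitzky–Golay
smoothing of 0.3 ms precedes differentiation, since a raw second
difference at 0.025 ms amplifies noise); amplitude as peak minus
threshold; half-width at the midpoint between threshold and peak; AHP as
threshold minus the post-peak minimum; firing rate as spike count over
step duration; PSTHs with 40-ms bins for SC displays and 10-ms bins for
latency estimation (the latency is the first bin centre whose rate
exceeds the pre-stimulus baseline by two baseline standard deviations for
two consecutive bins). Sag is the early minimum minus the late steady
state during a hyperpolarizing step, with a single-exponential fit from
the minimum to the step offset for its decay constant. The baseline
window for burst "percent increase" is the second preceding train onset;
the response window spans the train itself.

## Optimization

The 36 free conductance densities (11 somatic, 9 proximal- and 9
distal-dendritic, 4 AIS, 3 axonal slots — the class × channel layout is a
documented assumption, since only the channel inventory per region is
published) are fitted with an indicator-based evolutionary algorithm
(additive-epsilon IBEA: tournament mating on the indicator fitness,
log-space blend crossover, lognormal mutation, indicator-based
environmental selection). Objectives are SEM-normalized deviations from
the experimental feature targets over the standard battery (2-s
spontaneous, +4, +16 and −16 pA steps): pacemaker rate 24.2 ± 2.1 Hz,
step rates at +4/+16 pA (derived from the pacemaker rate and the
validated 2.13 Hz/pA f-I slope), sag 10.3 ± 2.0 mV, spike amplitude
37.3 ± 5.2 mV, half-width 1.0 ± 0.2 ms, rebound first-spike delay
17.2 ± 2.3 ms and first ISI 20.1 ± 1.0 ms. The +4/+16 pA SEMs (3.0 and
4.4 Hz) scale the pacemaker SEM with the target rates.

The reference workflow optimizes four models, one per generated
morphology, from a common bound set (a ×10 spread around the package
defaults, with one individual seeded at the defaults). The shipped
reference conductance sets under `inst/extdata/` were produced by this
procedure at a population of 24 for 14 generations; the desk-scale preset
(population 20, 10 generations) is the default, and the full
100 × 50 schedule of the original workflow is available behind the CLI's
`--full` flag. Problem sizes throughout the package (trial counts,
refinement budgets, run durations) are chosen so that the whole reference
analysis reproduces on a single CPU in minutes.

## The microcircuit and the Purkinje stand-in

The PC of the microcircuit is an explicitly reduced stand-in, not an
anatomical reconstruction: nine compartments (soma, AIS, two branch-I
trunks, three branch-II spiny branches, two branch-III branches) with the
same channel library, densities set for ~20-Hz intrinsic pacemaking and
calcium-dependent burst-pause responses, and a total membrane area scaled
so that 100 PF synapses produce physiological (non-saturating)
depolarizations. Synaptic placement follows the anatomical rules: PF
excitation on branch II only, ascending-axon input reserved for branch
III, inhibition restricted to branches I–II (requesting inhibitory
synapses on branch III is a constraint error). The standard circuit wires
100 PF→PC and 3 PF→SC synapses, 25–300 SC→PC synapses, and optionally a
second SC inhibiting the first through 32 synapses — one-way by default,
with a reciprocal mode available. PC burst gain is normalized to the
4-Hz response of the same condition; the pause is measured from train
offset to the first resumed spike.

Trial-to-trial variability in these deterministic models comes from
seeded randomization of the train onset relative to the pacemaker phase
(and of synapse placement and background timing); PSTyH-based quantities
are averaged over such trials.

## What the synthetic data do and do not show

The morphology generator reproduces printed summary statistics, not the
four reconstructed cells; the reduced backbone collapses each electrical
class to a few cylinders, so local dendritic nonlinearities are coarser
than in a full reconstruction. Channel kinetics are canonical forms, not
the exact unpublished rate tables, and the receptor-level constants were
calibrated to published synaptic behaviour as described above.
Consequently, passing tests demonstrate that the implemented mechanisms
reproduce the published electroresponsiveness, synaptic dynamics and
circuit-level filtering — not that they match unpublished per-cell
parameter values. Model-to-model spread after re-optimization is expected
and is why stochastic quantities are reported as means over the four
reference models.

## Known limitations

* Ideal voltage clamp (no series resistance) and no experimental-rig
  artefacts.
* No receptor Markov schemes, long-term plasticity, spillover, or
  stochastic gating.
* The axon is lumped to an equivalent cylinder (200 µm effective length);
  no myelination or propagation measurements.
* The PC stand-in supports burst-pause and gain measurements only; it is
  not a quantitative Purkinje model.
* The inhibitory 20-Hz background defaults to independent periodic trains
  with random phase per synapse; a Poisson mode is available, and
  synchrony across synapses is configurable since the published protocol
  leaves it open.
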