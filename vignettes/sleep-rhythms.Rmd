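---
title: "Modelling sleep-stage rhythms in a thalamocortical network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sleep-stage rhythms in a thalamocortical network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`somnotc` simulates a thalamocortical loop of four cell populations:
excitatory pyramidal (PY) and inhibitory (INH) cortical neurons, each
reduced to an axosomatic plus a dendritic compartment, and one-compartment
thalamocortical relay (TC) and thalamic reticular (RE) neurons. At full
scale the network holds 500 PY, 100 INH, 100 TC and 100 RE cells, connected
topographically: each presynaptic cell innervates a contiguous block of
targets around its mapped index, with configurable radius per projection
and no wraparound at the edges (a finite cortical slab, not a torus).

Each cell integrates Hodgkin–Huxley-style currents:

* **All types** — transient Na⁺ (m³h) and delayed-rectifier K⁺ (n⁴)
  spiking currents with Traub-style rate functions shifted by a per-type
  `v_traub`; an ohmic leak; and a potassium leak `g_KL`, the principal
  target of neuromodulation.
* **TC** — a low-threshold Ca²⁺ current I_T (m²h; activation half-voltage
  −59 mV, slope 6.2 mV; inactivation −83 mV, −4 mV) that converts release
  from hyperpolarization into a burst of spikes, and a
  hyperpolarization-activated mixed cation current I_h with a
  calcium-regulated four-state scheme: voltage gating C↔O (half-activation
  −75 mV), binding of a messenger by intracellular Ca²⁺ (forward rate
  k₁·[Ca]⁴), and locking of open channels into a higher-conductance state
  OL (current `g_h (O + g_inc·OL)(V − E_h)`, `g_inc = 2`, `E_h = −40` mV).
* **RE** — the reticular variant of I_T (half-voltages −52/−80 mV).
* **PY/INH dendrite** — persistent Na⁺ (fast Boltzmann activation, half
  −42 mV), muscarinic K⁺ (I_Km), Ca²⁺-dependent K⁺ (I_KCa, activation rate
  proportional to [Ca]ᵢ), and a high-voltage-activated Ca²⁺ current that
  feeds a first-order calcium pool
  (`d[Ca]/dt = −k·I_Ca + ([Ca]_rest − [Ca])/τ_Ca`).

Calcium reversal potentials follow the Nernst relation at 36 °C.
Temperature acceleration is folded into fixed φ factors
(6.96/3.74 for I_T, 2.95 for the Mainen-style dendritic rates).

Synapses are kinetic two-state receptors driven by rectangular transmitter
pulses (0.5 mM for 0.3 ms per presynaptic spike; overlapping pulses
saturate rather than stack, since the gating variable represents a
concentration). AMPA (α = 1.1 mM⁻¹ms⁻¹, β = 0.19 ms⁻¹), NMDA with the
standard magnesium block `1/(1 + exp(−0.062 V)·[Mg]/3.57)`, GABA-A
(α = 5, β = 0.18), and a second-messenger GABA-B cascade
(K₁…K₄ = 0.52, 0.0013, 0.098, 0.033; K current activation `G⁴/(G⁴+100)`).
Recurrent PY→PY AMPA depresses: at each presynaptic spike the resource is
updated as `E ← 1 − (1 − E(1−U)) exp(−Δt/τ_D)` and scales the weight.
Cortical excitatory synapses additionally release spontaneous miniature
EPSPs from a renewal process whose hazard rises from zero after each
presynaptic spike and saturates at a configured maximum; mini times are
drawn from counter-based per-connection substreams, so a run is a pure
function of (config, seed) and resizing one projection never reshuffles
another's draws.

## Neuromodulation and the sleep-stage schedule

Stages are defined by three dimensionless levels — acetylcholine (ach),
histamine (ha) and GABA — with wake as the reference (all 1). The
schedule is piecewise constant with linear ramps (default 5 s) centred on
stage boundaries; the default protocol is five equal stages
(wake, N2, N3, REM, N2) filling 360,000 ms. Levels map to parameters
through three linear gains, all identity at wake:

* `g_KL_eff = g_KL (1 + κ_ach(1 − ach) + κ_ha(1 − ha))`, clamped at 0.
  Histamine gains are zero for cortical types; the large TC gains
  (κ_ach = 11, κ_ha = 3) span the relay cells' full operating range, from
  depolarized tonic firing in wake to burst-capable hyperpolarization in
  N2 and near-silence in N3. The REM combination (ach = 1.2, ha = 0.1)
  lands between wake and N2, giving wake-like activated dynamics.
* cortical AMPA weights scale as `1 + λ(1 − ach)` (λ = 0.3): lower
  acetylcholine strengthens recurrent excitation.
* GABA-A weights scale directly with the gaba level.

These gains are calibration constants, not measurements; they were chosen
once so that the four regimes of the acceptance suite emerge (spindles in
N2, slow oscillation in N3, activated wake/REM), and they are fully
exposed in the config.

## Numerics

Fixed global step, default `dt = 0.025` ms. Within a step: neuromodulator
levels are interpolated; synaptic states advance by the exact exponential
solution for piecewise-constant transmitter; gating variables relax
exponentially toward their voltage-dependent steady states
(`x ← x∞ + (x − x∞) e^(−dt/τ)`), which keeps them in [0, 1] for any dt;
calcium and the GABA-B cascade use exact updates of their linear ODEs;
voltages are updated semi-implicitly with start-of-step conductances
(a linear solve — exact 2×2 for the two-compartment cells), which is
robust against the very large axosomatic Na⁺/K⁺ densities; spikes are
threshold crossings (0 mV, 2 ms refractory) and schedule transmitter
pulses for the following steps. Time is derived from a global step index,
so a checkpointed-and-resumed run is bit-identical to an uninterrupted
one. Removable singularities in the alpha/beta rate functions are
evaluated by their series limit near the singular voltage.

The scheme is first-order accurate overall. For event-locked activity,
halving dt moves spike times by well under 0.5 ms; a free-running tonic
cell accumulates phase error linearly in both time and dt (measured:
worst-case deviation halves with each step halving). The default step is
a deliberate speed/accuracy compromise at the stiff axosomatic
conductances; the convergence tests in the suite quantify, rather than
assume, this behaviour.

## LFP forward models

Two observables are computed. The *summed-voltage* LFP is the arithmetic
mean (not the raw sum, so amplitude is population-size invariant) of PY
dendritic potentials — the classic first approximation. The *biophysical*
LFP places every compartment and a recording electrode in a 1-D geometry
(20 µm pitch, dendrites 500 µm above somata, electrode centred 1000 µm
above the somatic layer by default) and sums transmembrane currents
weighted by point-source transfer resistances `R = 1/(4πσr)`
(σ = 0.3 S/m). Because each one-compartment cell's total transmembrane
current is zero, only the cortical soma–dendrite dipoles contribute; the
per-cell dipole current equals the axial current `g_c (V_s − V_d)`. With
at most two compartments per cell the line-source refinement would change
little, which is why the point-source form is the default. A minimum
electrode–compartment distance of 10 µm is enforced (the point source
diverges at r → 0).

Spectral analysis uses Hann-tapered short-time periodograms scaled as
one-sided PSD (so integrating power over frequency recovers the windowed
variance), with band integrals over slow-oscillation (0.1–1 Hz), spindle
(7–14 Hz) and alpha (8–13 Hz) bands by default.

## The axosomatic 3/4 rescale

The cortical parameter set descends from a lineage in which the
axosomatic compartment was solved algebraically, without capacitance.
This package always integrates the soma with capacitance
(`soma_variant = "capacitive"`); to retain the legacy parameter scale,
every axosomatic maximal conductance is multiplied by exactly 3/4 at
build time, uniformly for PY and INH. The config stores legacy values;
`effective_cell_params()` exposes both. The `legacy_algebraic` enum value
only labels parameter sets — the algebraic solver itself is out of scope.

## Fixtures: what they emulate, and what they do not

Four reduced scenarios make every regime testable in minutes on one core
(test problem sizes: 1-cell, 8-cell, 60-cell and 80-cell networks run for
3–36 simulated seconds):

* `single_tc_rebound` — one TC cell hyperpolarized by a −1.5 µA/cm²
  current step for one second and released: the I_T de-inactivation →
  rebound burst that seeds spindles.
* `re_tc_spindle_pair` — a 4+4 RE–TC circuit at N2 levels. It oscillates
  at ~11.5 Hz with roughly two orders of magnitude more spindle-band
  power than the same circuit at wake levels (which runs fast and weak,
  ~21 Hz). The TC leak baseline is slightly lower than the network
  default because the isolated circuit lacks tonic corticothalamic
  drive. Limitations: at this scale and with no noise sources in the
  thalamus the oscillation is continuous — the waxing-and-waning epoch
  envelope of full-scale spindles appears only at stronger TC→RE
  coupling, at the cost of the wake contrast, and is therefore not part
  of the fixture's default behaviour.
* `cortical_slab_n3` — 50 PY + 10 INH at N3 levels. Minis ignite Up
  states; use-dependent depression of PY→PY AMPA terminates them and
  gates re-ignition, producing network-wide active/silent alternation
  with dominant power below 1 Hz. Setting `u_depression = 0` removes the
  terminator: the slab locks into a permanent active state and the
  silent fraction collapses to zero — the mechanistic control for the
  role of depressing recurrent excitation in slow-wave generation. The
  depression constants (network default U = 0.25, τ_D = 4000 ms; the
  isolated slab uses U = 0.3, τ_D = 5000 ms) are deliberately
  stronger/slower than the fast-depression values often quoted for
  cortical synapses: at these 60–80 cell scales, weaker depression
  yields Up-state recurrence in the 1–2 Hz delta range, and the slower
  resource dynamics are what push the rhythm into the <1 Hz
  slow-oscillation band. Up states here are briefer and more synchronous
  than in large heterogeneous networks.
* `full_reduced_cycle` — the whole network at 1/10 scale (50/10/10/10)
  through the five-stage protocol at 1/10 duration. The acceptance
  contrast is between adjacent stages, as in the full-scale protocol's
  descent into sleep: spindle-band power rises from wake to the first
  N2 (~an order of magnitude) and slow-oscillation power from N2 to N3.
  Known limitation: the reduced thalamus is bistable between a fast
  tonic loop and the spindle mode, so stage entries carry hysteresis —
  the second N2 (entered from REM) can show spindles grouped at <1 Hz
  rather than a clean N2 spectrum. Corticothalamic minis provide the
  noise that lets transitions escape the tonic branch.

Passing these tests shows that the implemented mechanisms generate the
right regimes and respond to neuromodulator levels in the right
direction at desk scale; it does not certify quantitative spectra at
full scale, where larger populations, heterogeneity and slower protocols
smooth all of these rhythms.

## Design choices

* Per-connection conductances are the configured per-target totals
  divided by each target's realized in-degree, so boundary cells receive
  comparable total drive; switchable by supplying per-edge weights.
* Boundary handling is truncation, matching finite-slab models.
* Synaptic delays default to 0 ms (one constant per projection is
  supported).
* Unknown config keys are hard errors: a misspelt parameter must never
  silently fall back to a default.
* The spike threshold (0 mV) and refractory period (2 ms) define raster
  events only; they do not feed back into the dynamics.
* Initial conditions: −68 mV (cortex, TC) and −70 mV (RE) with every
  gate at its steady state; analyses exclude a 500 ms settling window by
  default.

## Known limitations

Norepinephrine, orexin and serotonin are not modelled. There is no
spindle- or slow-wave event detector beyond band power. The run is
serial; determinism and checkpointing are designed so a parallel engine
could replace the inner loop without changing the contract. Channel
kinetic constants are tabulated
(`channel_param_table()`, `inst/extdata/channel_params.tsv`) but the
functional forms are fixed in compiled code.
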