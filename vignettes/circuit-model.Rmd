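---
title: "A biophysical model of disinhibition-gated plasticity at the Schaffer collateral-CA1 synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biophysical model of disinhibition-gated plasticity at the Schaffer collateral-CA1 synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ca1plast)
```

## The circuit and the question

`ca1plast` simulates a minimal feedforward circuit of the hippocampal CA1
region built from three point compartments:

* an **O-cell** — an oriens-lacunosum-moleculare (OLM) GABAergic
  interneuron carrying presynaptic α7 nicotinic acetylcholine receptors;
* an **I-cell** — a fast-spiking stratum-radiatum interneuron driven by
  Schaffer collateral (SC) glutamate, providing feedforward inhibition;
* **E_D** — a passive dendritic compartment of a CA1 pyramidal neuron with
  AMPA, NMDA and GABA_A receptors, the site of the plastic SC synapse.

The wiring is strictly feedforward: SC glutamate excites the I-cell and
E_D; ACh activates the O-cell's α7 receptors; the O-cell inhibits the
I-cell; the I-cell inhibits E_D. The scientific question the model
addresses is how *disinhibition* — silencing of the I-cell, either
directly or through cholinergic activation of the OLM cell — gates
long-term potentiation of the SC–CA1 synapse.

## Membrane and receptor models

The O- and I-cells are Hodgkin–Huxley neurons (transient Na⁺, delayed
rectifier K⁺, leak), with the O-cell additionally carrying a persistent
Na⁺ current, a two-component hyperpolarization-activated inward current
and a constant applied current `I_app = -260 pA`:

$$C_m \frac{dV}{dt} = -I_\mathrm{leak} - I_K - I_{Na} - I_p - I_h -
I_\mathrm{syn} + I_\mathrm{app}.$$

E_D is passive: $C\,dV/dt = -I_\mathrm{leak} - I_\mathrm{syn}$. Units are
fixed internally as mV, ms, pA, nS and pF throughout, which closes the
voltage equation dimensionally (pA/pF = mV/ms) with no conversion
factors. Gate variables use the α/β form $dx/dt = \alpha_x(1-x) -
\beta_x x$ or the steady-state form $dx/dt = (x_\infty - x)/\tau_x$;
removable singularities of the rate functions (e.g. at V = −27 mV for the
O-cell's $\alpha_n$) are evaluated by an explicit branch returning the
analytic limit whenever $|V - V_0| < 10^{-6}$ mV.

Synaptic channels follow two-state binding kinetics
$dr/dt = \alpha [T] (1-r) - \beta r$, with currents $I = \bar g\, r\,
(V - E)$; the NMDA current carries the voltage-dependent magnesium block
$B(V) = (1 + e^{-0.062 V} [\mathrm{Mg}^{2+}]/3.57)^{-1}$. The α7 receptor
activates with a Hill steady state
$r_\infty = [\mathrm{ACh}]^{1.73} / (EC_{50}^{1.73} +
[\mathrm{ACh}]^{1.73})$ approached with a 5-ms time constant.

Transmitter release is stationary and sigmoidal: the I-cell releases GABA
as a steep function of its membrane potential (half-activation +2 mV), so
release effectively happens only during action potentials; the O-cell
terminal releases GABA as an extremely steep function of its cytosolic
calcium (half-activation 4×10⁻⁵ mM, width 10⁻⁶ mM), i.e. as a switch
thrown by calcium-induced calcium release (CICR). The CICR subsystem
couples cytosolic calcium (fed by the calcium fraction of the α7 current)
to an internal store through channels whose open probability is
$w_\infty^3$ with $w_\infty = \mathrm{Ca}_i/(\mathrm{Ca}_i + k_d)$; the
cytosol–store exchange is antisymmetric, so with influx and decay disabled
total calcium is conserved (a unit test asserts this).

## The plasticity rule

The strength of the SC–E_D synapse is its AMPAR maximal conductance
$\bar g_\mathrm{AMPA}$, driven by dendritic calcium (in µM) entering
through NMDA receptors ($d\mathrm{Ca}/dt = -\xi \alpha I_\mathrm{NMDA} -
\mathrm{Ca}/12$):

$$\frac{d\bar g_\mathrm{AMPA}}{dt} = \eta(\mathrm{Ca})\left(
\Omega(\mathrm{Ca}) - \sigma (\bar g_\mathrm{AMPA} - g_0)\right),$$

where $\eta$ is a monotone calcium-dependent learning rate and $\Omega$
is a difference of two steep sigmoids (steepness 900 µM⁻¹) centred on the
potentiation onset θ↑ = 0.34 µM and the depression onset θ↓ = 0.31 µM.
Between the onsets AMPARs are removed at rate γ↓; above θ↑ insertion at
γ↑ dominates. The learning rate multiplies the decay term as well, so at
rest (`Ca = 0`, η ≈ 10⁻⁴) the conductance relaxes toward `g0 = 4 nS`
with a time constant of roughly 2.5×10⁶ ms — this is what makes
potentiation long-lived but not bistable, and it is also what the
windowed integrator exploits (below).

Two preset calibrations exist, differing only in γ↑ and in the
current-to-concentration factor ξ, following the published parameter
table: `"copairing"` (γ↑ = 0.0687 nS/ms, ξ = 0.006 µM/(ms·pA)) for the
full-circuit ACh-pairing experiments, and `"disinhibition"` (γ↑ = 0.0699,
ξ = 0.045) for the dendrite-only glutamate+GABA experiments.

### Two classifiers of plasticity

Because crossing θ↑ is necessary but not sufficient for net potentiation
(time spent between the onsets removes AMPARs), the package provides two
analysis quantities:

* `find_theta_pot()` — the **potentiation threshold** θ_pot: the peak
  calcium at which the settled net change of a single glutamate+GABA
  pairing flips sign, located by bisection on the initial conductance
  (which maps monotonically onto peak calcium). At default parameters
  this gives θ_pot ≈ 0.36 µM > θ↑.
* `weighted_area_ratio()` — the learning-rate-weighted ratio of the
  trapezoidal calcium integral above θ↑ to the integral between the
  onsets. Values above ≈ 3 mark potentiation. Unlike θ_pot it also
  classifies multi-source calcium transients correctly: the test suite
  constructs a two-pulse case (second calcium source switched on 80 ms
  after the pairing) in which neither pulse crosses θ_pot yet the synapse
  potentiates, and the ratio identifies it.

## Integration

The coupled system is integrated with forward Euler at `dt = 0.02 ms`
(the published step; halving it changes the conductance endpoints by
less than 0.5 %). Voltage noise, when enabled, is Euler–Maruyama:
an additive $\sqrt{dt}\,\zeta$ term with per-cell amplitudes
(1.1, 0.1, 0.3) on the voltage updates only, reproducible through R's
RNG seed. Trajectories with $|V| > 200$ mV abort with a diagnostic.

Protocols lasting tens of minutes with one stimulus per minute are run
with `windowed_integrate()`: a 2-s window is simulated around each
stimulus event from the relaxed resting state, and between windows — when
every fast variable is at rest and calcium is zero — the conductance is
propagated analytically, $g(t{+}\Delta) = g_0 + (g - g_0)
e^{-\eta(0)\sigma\Delta}$, which is exact there. The windowed and full
integrations agree to well below 1 % (the test suite checks ~10⁻¹⁰ on a
12-minute protocol), and the windowed path is ~50× faster. The window
must out-last the slowest fast process (the E_D membrane constant is
100 ms; the O-cell GABA release episode lasts ~120 ms); a window whose
end state has not returned to rest triggers an error suggesting a longer
window.

## Calibration decisions

Three places required the package to make a decision where the published
description is internally inconsistent; they are implemented as explicit,
documented calibrations rather than silent fits:

* **I-cell synaptic weights.** The circuit mechanism requires two stated
  behaviors: one SC glutamate pulse must evoke a *volley* (≥ 2 spikes) in
  the I-cell, and OLM GABA release must be able to *silence* the
  SC-evoked I-cell response. In our integration the literature values
  (7 and 14 nS) produce exactly one spike — the second is marginally
  subthreshold — which destroys the baseline neutrality of the copairing
  protocol; conversely any AMPA conductance large enough for the volley
  escapes suppression at 14 nS. Both behaviors are satisfied by scaling
  the two weights by a single minimal factor 8/7, to
  `g_ampa_I = 8` and `g_gaba_I = 16 nS` (preserving their 1:2 ratio).
  With that calibration the baseline event is plasticity-neutral to
  machine precision and the pairing windows *emerge*: the lower
  potentiation boundary comes out at 10.33 ms and the early depression
  onset at −18.1 ms without any further adjustment.
* **O-cell resting potential.** With the published parameters and the
  only quiescent sign convention for `I_app`, the O-cell rests at
  −57.1 mV rather than the stated −60 mV. The value is reported as
  computed; the leak reversal is not retuned. The α7 peak current is
  similarly ~106 pA rather than the stated 35 pA; the printed conductance
  (3 nS) is kept because the knockout comparison (reduction to 1.7 nS)
  presupposes it.
* **EPSC measurement.** The EPSC is the peak of
  $|I_\mathrm{AMPA} + I_\mathrm{NMDA}|$ on E_D within 200 ms of a
  glutamate pulse, with the membrane free-running. A voltage-clamp
  read-out mode exists (`clamp_ed`) but reproduces the reported
  amplitudes less well. End-of-window EPSCs are read on the pulse
  delivered at the window-end minute, i.e. with the end-of-window
  conductance.

### A knife edge in the CICR subsystem

The duration of the O-cell GABA release episode — which sets the upper
boundaries of the pairing windows — sits just below a saddle-node
bifurcation: at the published cytosolic decay constant of 12 ms the
release shuts off ~124 ms after the ACh pulse, while at ≥ 12.05 ms the
CICR positive feedback becomes self-sustaining and release never stops.
Near such a bifurcation the shutdown time is hypersensitive: it moves by
~5 % per halving of the integration step and diverges under
sub-percent parameter changes. The upper window boundaries we compute
(~117 ms for the single-pulse potentiation window, ~157 ms for the end of
late depression, ~118 ms for doublets) are therefore reported as
computed, 10–20 % below the published ones, and the package deliberately
does not tune the decay constant toward them. The boundaries governed by
the *onset* of the release episode (≈ 10.4 ms) and by the second-spike
latency (≈ −19 ms) are robust and reproduce the published values closely.

### Scan conventions

The pairing-lag scans classify a lag as potentiating, depressing or
neutral with a threshold of 0.05 nS on the conductance change measured
60 ms after the last stimulus onset (≈ 5 % of the maximal single-pairing
response; any threshold between 0.03 and 0.06 nS yields the same
boundaries). Region boundaries are located by bisection of the
classification change to 0.05 ms and reported at the bracket midpoint.
For single glutamate+GABA pairings, where the calcium tail outlives the
60-ms epoch, the trajectory *endpoint* (settled conductance, read after
600 ms) is used for the worked-example values; `single_pairing_delta()`
returns both readings.

The EPSC normalization used for display maps a series affinely onto
[100, 150]: $100 + (E - E_\min)(150-100)/(E_\max - E_\min)$ — the only
dimensionally consistent reading of the published expression. When
replicates are averaged the normalization is applied to the pooled
series; applying it per replicate before averaging is possible by calling
`normalize_epsc()` inside the replicate callback.

## What the protocols emulate — and what they do not

The stimulation protocols are square (or alpha-function) transmitter
concentration pulses: glutamate 1 mM × 5 ms (copairing) or × 1 ms
(disinhibition), ACh 1 mM × 5 ms, GABA matched to glutamate. They stand
in for extracellular stimulation of the SC pathway, optogenetic
activation of septal cholinergic fibres and optogenetic silencing of
somatostatin interneurons in the corresponding slice experiments. What
they do not capture: transmitter diffusion and uptake kinetics, vesicle
depletion and short-term facilitation, dendritic cable structure,
stochastic channel gating, and recurrent connections from the pyramidal
cell back onto the interneurons. Passing tests therefore demonstrate the
internal consistency of the model and the reproduction of its published
simulation endpoints — not quantitative agreement with slice
electrophysiology, whose EPSC amplitudes enter only as calibration
anchors.

Problem sizes used throughout the package's own checks: disinhibition
protocols are simulated for 12–45 model minutes (windowed), pairing scans
over lags −40…360 ms at 5-ms grids refined by bisection, and replicate
averages over 3–10 seeds. These are the published experiment sizes;
nothing is scaled below them except the copairing duration/frequency
scans, which use 1–3-minute pairing windows (the published 4–8-minute
windows behave identically but more slowly).

## Known limitations

* The copairing-side upper window boundaries inherit the CICR knife edge
  discussed above; treat their absolute values as implementation-
  sensitive to ±20 %.
* The published rightward shift of the depression region in the GABA
  amplitude–timing phase map with increasing conductance state is *not*
  reproduced: in this implementation the depression band moves to
  earlier GABA lags as the conductance grows, because a stronger synapse
  drives calcium through the depression band sooner. The phase map's
  state dependence as such is robust.
* EPSC peak amplitudes carry the forward-Euler gate overshoot
  (≈ +0.5 % at dt = 0.02 ms) and should be compared across runs at a
  fixed step.
* The noise model reproduces mean behavior of the published noisy
  simulations qualitatively; no attempt is made to match their exact
  trajectories, which depend on the generator.
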