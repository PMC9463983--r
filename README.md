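# ca1plast

Biophysical simulation of disinhibition-gated synaptic plasticity at the
Schaffer collateral–CA1 synapse.

## The problem

Acetylcholine released onto hippocampal OLM (oriens-lacunosum-moleculare)
interneurons can gate long-term potentiation of the Schaffer collateral
(SC) input to CA1 pyramidal cells. The proposed mechanism is *feedforward
disinhibition*: α7 nicotinic receptors on the OLM terminal trigger
calcium-induced calcium release (CICR) and GABA release onto a
fast-spiking interneuron, silencing the feedforward inhibition that
normally caps dendritic depolarization. The unmasked NMDA-receptor
calcium influx then drives a calcium-based AMPAR plasticity rule.

`ca1plast` implements this three-cell circuit — Hodgkin–Huxley OLM cell
(O) and fast-spiking interneuron (I), passive pyramidal dendritic
compartment (E_D) — with kinetic AMPA/NMDA/GABA_A/α7 receptor models,
the CICR subsystem, and the plasticity rule

    dg/dt = η(Ca) · ( Ω(Ca) − σ (g − g0) ),

where Ω(Ca) is a difference of steep sigmoids at the depression onset
θ↓ = 0.31 µM and potentiation onset θ↑ = 0.34 µM, and η(Ca) is a
monotone learning rate. It ships every in-silico protocol of the study
it models: cholinergic copairing (with Δt scans and 2-Hz doublets),
dendritic disinhibition, single-pairing analyses (the potentiation
threshold θ_pot and the learning-rate-weighted calcium area ratio
(A↑/A↓)_w), and GABA amplitude–timing phase maps. It is aimed at
computational neuroscientists studying interneuron control of plasticity.

## Worked example

Eight minutes of dendritic disinhibition (GABA pulses omitted from the
once-per-minute glutamate+GABA pairing between minutes 5 and 13):

```r
library(ca1plast)
p   <- circuit_params("disinhibition")
run <- run_disinhibition(p, period_min = 8, total_min = 15)
run
#> ca1plast windowed protocol run (ed_only): 15 events, window 2000 ms
#>   EPSC pulses: 15  range: 172.78 - 367.76 pA
#>   final g_ampa: 8.8254 nS
#>   g at end of window: 8.8296 nS
```

The AMPAR conductance grows from its 4-nS baseline to 8.83 nS by the end
of the window, and the EPSC (peak |I_AMPA + I_NMDA| per pulse) rises from
172.8 pA to 367.8 pA and stays potentiated. A single glutamate+GABA
pairing delivered from that potentiated state:

```r
sp <- single_pairing_delta(p, g_init = run$g_end_window)
#> ca_max 0.392 uM; g -> 8.943 nS; ratio 9.05
```

Peak calcium (0.392 µM) crosses the potentiation threshold
(`find_theta_pot(p)` ≈ 0.36 µM), the synapse potentiates further, and
the weighted area ratio (9.05 > 3) classifies the pairing accordingly —
this is what keeps the synapse potentiated under continued paired
stimulation, whereas after a 5-minute window it decays back.

The circuit side is run the same way: `run_copairing()` (flat baseline,
sustained EPSC boost after ≥ 8 min of ACh–SC pairing, abolished when the
α7 conductance is reduced from 3 to 1.7 nS) and `scan_pairing_dt()`
(potentiation confined to glutamate lags ≈ 10–120 ms after ACh).

See the vignette (`vignettes/circuit-model.Rmd`) for the model equations,
units, calibration decisions and known limitations, including the
parameter knife edges the pairing-window boundaries sit on. A thin
command-line wrapper over the protocol runners is installed at
`inst/cli/ca1plast.R`.

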