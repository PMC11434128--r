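# somnotc

Conductance-based simulation of thalamocortical dynamics across sleep
stages, for computational neuroscientists studying how neuromodulators
shape sleep rhythms — spindles, slow oscillations, and wake/REM-like
activated states — in a biophysically explicit network.

The model is a four-population thalamocortical loop: 500 two-compartment
cortical pyramidal cells (PY), 100 cortical interneurons (INH), 100
one-compartment thalamocortical relay cells (TC) and 100 reticular nucleus
cells (RE), coupled by topographic AMPA/NMDA, GABA\_A and GABA\_B kinetic
synapses. Each membrane obeys

```
C_m dV/dt = - Σ_i g_i m_i^p h_i^q (V - E_i) - g_KL (V - E_K) - I_syn + I_axial
```

with Hodgkin–Huxley spiking currents everywhere; a low-threshold calcium
current I\_T (`m²h`, rebound bursts) and a calcium-regulated
hyperpolarization-activated current I\_h in the thalamus; and persistent
Na⁺, muscarinic K⁺, Ca²⁺-dependent K⁺ and high-voltage-activated Ca²⁺
currents on cortical dendrites. Recurrent PY→PY AMPA depresses
(`E ← 1 − (1 − E(1−U)) e^(−Δt/τ_D)`) and releases spontaneous miniature
EPSPs — the machinery behind cortical slow waves.

Sleep stages are imposed by a schedule of acetylcholine, histamine and
GABA levels that scale potassium leak conductances and synaptic weights
(wake → N2 → N3 → REM → N2 over 360 s by default, with linear ramps).
Two LFP forward models are provided: the mean intracellular dendritic
voltage, and a point-source transfer-resistance model
`φ(t) = Σ_k I_k(t) / (4πσ r_k)` over all compartmental transmembrane
currents. Spectrogram and band-power analysis (slow-oscillation 0.1–1 Hz,
spindle 7–14 Hz, alpha 8–13 Hz) quantify the rhythms.

## Worked example: spindles in the reticular–relay loop

```r
library(somnotc)

cfg <- make_fixture("re_tc_spindle_pair", seed = 1)   # small RE+TC circuit, N2 levels
run <- run_simulation(cfg)
print(run)
#> somnotc run: 11000 ms from t0=0 ms, seed 1
#>   spikes: 1488, samples: 11000

lfp <- summed_voltage_lfp(run$traces[, 1:4])   # mean TC voltage (mV)
x <- lfp[run$sample_t > 1000]                  # drop the settling second
x <- x - mean(x)

spec <- lfp_spectrogram(x, fs = 1000, window_s = 2, overlap = 0.75)
dominant_frequency(x, 1000, fmin = 4)
#> [1] 11.5
median(band_power(spec, c(7, 14)))
#> [1] 35.95
```

The circuit oscillates at 11.5 Hz — inside the 7–14 Hz spindle band.
The same circuit under wake levels runs fast and weak:

```r
wake <- run_simulation(make_fixture("re_tc_spindle_pair", stage = "wake"))
xw <- summed_voltage_lfp(wake$traces[, 1:4])[wake$sample_t > 1000]
sw <- lfp_spectrogram(xw - mean(xw), 1000, window_s = 2, overlap = 0.75)
median(band_power(sw, c(7, 14)))
#> [1] 0.146
```

— over two hundred times less spindle-band power than under N2 levels.
`plot_raster(run)` and `plot_spectrogram(spec)` draw the standard figures;
`stage_band_report(run)` tabulates per-stage band power for a full
multi-stage run. Other fixtures probe the remaining regimes:
`single_tc_rebound` (low-threshold rebound burst), `cortical_slab_n3`
(sub-1 Hz Up/Down slow oscillation, abolished by setting the depression
use fraction to zero) and `full_reduced_cycle` (the five-stage protocol
at 1/10 scale).

## Command line

A thin CLI ships in `inst/scripts/somnotc`:

```sh
somnotc fixture full_reduced_cycle --out cycle.yaml
somnotc run --config cycle.yaml --seed 1 --out cycle.rds
somnotc analyze cycle.rds --report bands.json --raster-plot raster.png
```

## Configuration

`default_config()` returns the full parameter tree (populations, channel
densities, synaptic conductances, schedule, neuromodulator gains,
integration settings, LFP geometry); `write_config()`/`load_config()`
serialize it to YAML with strict validation — unknown keys are errors.
Channel kinetic constants are tabulated in
`inst/extdata/channel_params.tsv`. See the vignette
(`vignettes/sleep-rhythms.Rmd`) for the model description, numerical
scheme, calibration rationale and known limitations.
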