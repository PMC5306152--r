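# lfpsim

Ground-truth extracellular potential synthesis for a layered
thalamocortical column.

Validating analyses of multielectrode recordings — current source
density estimation, component decomposition, laminar population
analysis, spike/LFP studies — requires *ground truth*: data where every
internal variable of the generating system is known. `lfpsim` is an R
toolkit for building such benchmarks around the measurement model used
for simulated cortical-column recordings:

- **Column model** — the 14-population registry of a thalamocortical
  column (12 cortical populations across layers 2/3–6 plus
  thalamocortical relay and nucleus reticularis; 3560 cells and 211 490
  cortical segments at full size, 10% and arbitrary scaled versions),
  with somas placed uniformly in a 400 μm-diameter cylinder and
  stand-in stick morphologies, one segment per section.
- **Stimuli and activity** — the 28 published stimulation protocols
  (sinusoidal thalamic drive `I(t) = I_inj sin(2πf(t−t₀)) Θ(t−t₀)` at
  2–200 Hz, and a 3 nA/2 ms pulse), plus a synthetic activity generator
  that emits per-segment transmembrane currents and voltages on a
  0.1 ms time base. The generator is a *contract-satisfying stand-in*,
  not a biophysical simulator: per cell the currents sum to zero at
  every sample (Kirchhoff's current law), labelled per-channel
  components (NMDA, AMPA, GABA A, capacitive, passive, potassium,
  sodium, calcium, T-type, anomalous rectifier, other) sum exactly to
  the total, and spike trains lock to the stimulus.
- **NSDF store** — reader, writer and validator for the Neuroscience
  Simulation Data Format v1.0 HDF5 layout: compound morphology arrays,
  uniform current/voltage arrays, variable-length spike arrays, map
  arrays linked via HDF5 Dimension Scales, and unit attributes.
- **Forward model** — the point-source approximation

  φ(x, t) = 1/(4πσ) · Σₙ Iₙ(t) / |x − xₙ|,

  with σ = 0.3 S/m by default, sources at segment midpoints, electrodes
  anywhere (laminar probes, planar MEA grids, or free-form layouts from
  a text table), and per-population / per-current-type contribution
  decomposition. With currents in nA, distances in μm and σ in S/m, φ
  comes out in mV.
- **Signal ops** — LFP extraction with a 2nd-order Butterworth low-pass
  (100 Hz default; causal or zero-phase two-pass), bilinear plane
  interpolation for MEA displays, and raster preparation (up markers
  for excitatory cells, down for inhibitory, colours per population).

## Worked example

A desk-scale run of the pulse protocol (preset 24) at 1% model size and
100 ms, recorded by the default 28-contact laminar probe at 92.6 μm
spacing:

```r
library(lfpsim)
cfg <- run_config(preset_id = 24, seed = 1, size_fraction = 0.01,
                  stop = 100, out_dir = "demo")
path <- cmd_generate(cfg)
#> registry: 14 populations, 36 cells, 2344 segments
#> kirchhoff residual (relative): 3.73e-15
#> validation: 86 checks, 0 violation(s)
res <- cmd_lfp(cfg, path)
#> wrote 28 traces x 1000 samples to demo/dataset_24_potential.tsv
print(res$lfp)
#> <potential_recording> 28 electrodes x 1000 samples (mV), sigma = 0.3 S/m, filter = butterworth order 2, 100 Hz, zero_phase_two_pass
```

The generated NSDF file holds 2344 segments' currents and voltages for
36 cells; the Kirchhoff residual reported is the largest per-cell
current imbalance relative to the cell's current scale (float error
only), and the validator confirms layout, Dimension Scales links, units
and closure. The LFP matrix is 28 electrodes × 1000 samples in mV; at
this 1% scale the peak LFP magnitude is a few μV (0.00373 mV on
contact L16 here), two orders below full-scale recordings, as expected
from the reduced source count.

The same pipeline is available from the shell:

```sh
exec/lfpsim generate --config cfg.json --out demo/dataset_24.h5
exec/lfpsim validate --nsdf demo/dataset_24.h5
exec/lfpsim lfp --config cfg.json --nsdf demo/dataset_24.h5
exec/lfpsim plot --config cfg.json --nsdf demo/dataset_24.h5
```

Exit codes: 0 ok, 1 validation failure, 2 usage error.

## Layout

- `R/` — registry/geometry, stimuli, activity synthesis, NSDF store,
  forward model, signal ops, pipeline.
- `src/` — C bridge to the HDF5 Dimension Scales API and
  variable-length datasets (links against `Rhdf5lib`).
- `exec/lfpsim` — command-line entry point.
- `vignettes/ground-truth-lfp.Rmd` — the methods vignette: model
  assumptions, parameter choices, what the synthetic generator does and
  does not emulate.
- `tests/testthat/` — unit, property and acceptance suites.
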