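---
title: "Ground-truth LFP synthesis for a layered cortical column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ground-truth LFP synthesis for a layered cortical column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpsim)
```

## The measurement-modelling problem

Extracellular recordings sample the summed electric field of thousands
of neurons with a handful of electrodes. Methods that interpret such
recordings — current source density (CSD) reconstruction, independent
component analysis of laminar profiles, laminar population analysis,
spike sorting — can only be *validated* against data where the
generating sources are fully known. `lfpsim` builds such ground-truth
benchmarks: it lays out a layered thalamocortical column in space,
synthesizes per-segment transmembrane currents that satisfy the
structural constraints real compartmental simulations obey, persists
everything in the NSDF/HDF5 exchange layout, and forward-models the
extracellular potential at arbitrary electrode arrays.

The package deliberately separates the *measurement model* (exact,
physics-based, the part analyses depend on) from the *activity model*
(a statistical stand-in). Everything downstream of the currents —
geometry, forward model, file format, filtering — is implemented to
specification; the currents themselves are synthetic.

## The column model

The column comprises 14 populations: twelve cortical (layer 2/3
pyramidal regular-spiking and fast-rhythmic-bursting cells plus three
superficial interneuron types; layer 4 spiny stellate cells; layer 5
tufted intrinsic-bursting and regular-spiking pyramids; deep basket,
axoaxonic and low-threshold-spiking interneurons; layer 6 nontufted
pyramids) and two thalamic (thalamocortical relay, TCR, and nucleus
reticularis, nRT). `build_registry()` returns the registry with
per-population section counts, cell counts and soma depth ranges; the
full model has 3560 cells and 211 490 cortical segments, and
`size_fraction` scales the per-population counts (rounding half up,
minimum one cell) — the 10% model of 356 cells is exact under this
rule, which is only genuinely exercised at other fractions.

One registry value deserves a flag: the TCR row's section/cell counts
are read here as 139 sections and 100 cells. The ancestral
conductance-based model is often described with 137 compartments per
relay cell; we record 139 as-is rather than silently correcting, since
thalamic populations are excluded from the default (cortical-only)
forward model anyway.

Coordinates: depth runs along z in μm with the pia at z = 0 and z
increasing downward, and the column axis passes through x = y = 0, so
electrode and source coordinates share one frame. Somas are placed
uniformly *per unit volume* in a 400 μm-diameter cylinder: radius
drawn as R√u (uniform per unit area in the disk), depth uniform in
each population's layer range. The closed-form check E[x²+y²] = R²/2
is asserted by a property test over 10⁴ placements.

Morphologies are stereotyped stand-ins, not reconstructions: each cell
receives exactly one segment per section; pyramidal cells get a soma
plus a vertical apical stick rising toward the pia (stopping at 10% of
the soma depth so it never crosses the pia) and a short basal chain;
interneurons, stellate and thalamic cells get compact radial dendrites
of 40–80 μm. Their only contracts are segment count, soma position and
layer-consistent vertical extent. Analyses that depend on detailed
dendritic geometry (e.g. fine spatial structure of the LFP within tens
of μm of a cell) should not be benchmarked against these shapes.

## Stimulation protocols

`preset_registry()` mirrors the 28 published dataset configurations:
eight oscillation frequencies (200, 100, 50, 25, 12.5, 8, 4, 2 Hz; the
12.5 Hz run stops at 690 ms, the rest at 700 ms) with and without
infragranular depolarization (1 nA to layer-5 pyramids, 0.75 nA to
layer-6; halved for the 10% model), six 12.5 Hz replay/variant
protocols, and six pulse protocols (3 nA for 2 ms into the TCR cells).
Presets 24–28 use the 10% model and record per-channel current
components. (The source material is internally inconsistent about
which datasets carry components — one passage says 22–24 — and the
registry follows the tabulated 24–28.)

The sinusoid is `I(t) = I_inj · sin(2πf(t−t₀)) · Θ(t−t₀)` with f in Hz
and t in ms, so the phase argument is `2πf(t−t₀)/1000`; this is stated
explicitly because the protocols mix Hz and ms. The pulse occupies the
half-open interval [t₀, t₀+width), so at the 0.1 ms step a 2 ms pulse
spans exactly 20 samples with no double counting.

## The synthetic activity generator

`synthesize_activity()` is *not* a biophysical simulator; no
conductances, connectivity or membrane dynamics are integrated. It is a
generator of activity that satisfies, by construction, the contracts
real simulation output obeys, so that the measurement chain and any
analysis built on it can be tested against known ground truth:

- **Kirchhoff closure.** Every synaptic-like event adds an
  alpha-kernel current sink on one segment balanced by a distributed
  source over the cell's remaining segments; every spike adds a brief
  (≤2 ms) triphasic soma current; every per-cell component array is
  re-centred across segments at each sample. The per-cell current sum
  is zero to accumulated float error (measured residual ~10⁻¹⁵
  relative).
- **Exact decomposition.** When a preset records components, the total
  current is *computed as* the sum of the eleven labelled component
  arrays (nmda, ampa, gaba_a, capacitive, passive, potassium, sodium,
  calcium, ca_T_low_threshold, anomalous_rectifier, other), so
  component closure is exact by construction.
- **Stimulus locking.** Per-cell spike trains are inhomogeneous
  Poisson with rate `baseline · class_factor + gain · drive(t) +
  8 Hz/nA · depol`, where drive(t) is the rectified, normalized
  stimulus waveform (pulses are convolved with a 5 ms decay to emulate
  an evoked-response envelope). Before the stimulus the rate is
  stationary at baseline.
- **Determinism.** All randomness sits behind one seed; identical
  (preset, seed) give bit-identical arrays and spike lists.

Free parameters the protocols do not constrain were fixed once at
field-plausible values and are exposed as arguments: baseline firing
rate 2 Hz (inhibitory cells ×1.2, TCR ×1.5), stimulus gains of
25–80 Hz at full drive, synaptic input rate 30 Hz per cell, AMPA/NMDA
kernel time constants 2/10 ms with a 70/30 amplitude split, GABA A
6 ms, and a depolarization-to-rate gain of 8 Hz per nA. The membrane
voltage is bookkeeping, not dynamics: a smoothed, scaled echo of the
cell's summed synaptic input around −65 mV.

What passing tests therefore do and do not show: they certify the
measurement chain (geometry → currents → potential → file → filter) and
every structural invariant of the data, but they say nothing about
network dynamics — oscillation entrainment, latency ladders across
layers, or realistic LFP spectra. Runs whose dense arrays would exceed
a configurable memory budget (default 1 GiB) are refused up front with
the budget named.

## NSDF persistence

`write_nsdf()` lays the data out exactly as the published collection:
compound morphology rows (x0, y0, z0, x1, y1, z1, d) under
`data/static/morphology/<pop>`, currents and voltages as 2-D arrays
(rows = segments, columns = samples) under `data/uniform/<pop>/i` and
`/v`, spike times as variable-length rows (one per cell, empty rows
allowed for silent cells) under `data/event/<pop>/spikes`, and id
lists under `map/...` attached to their data arrays through the HDF5
Dimension Scales mechanism. Units ride as array attributes ("nA",
"mV", "ms", "um"); file-level attributes carry the NSDF version
("1.0"), start time, time step, time unit and provenance (software,
method, creator, license). The exact attribute-name vocabulary required
by NSDF v1.0 is not fully enumerated in our sources; the validator
treats this list as required and everything else as optional.

Per-channel component arrays are stored as sibling datasets of `/i`
named by channel label — an extension over the published figure, which
shows only `/i` and `/v` — and are flagged in the file metadata under
`component_arrays`. Datasets are written contiguous and uncompressed,
so write∘read round trips are bit-exact; `rhdf5` reverses dimension
order relative to the file's C order, which the reader and writer
absorb symmetrically.

Since `rhdf5` does not expose the Dimension Scales API or
variable-length float datasets, `src/` carries a small C bridge that
calls `H5DSset_scale`/`H5DSattach_scale`/`H5DSis_attached` and
`H5Tvlen_create` from the HDF5 high-level library bundled with
`Rhdf5lib`. Files written this way show proper dimension scales in
generic HDF5 browsers and h5py.

`validate_nsdf()` checks: required file attributes, a monotone uniform
time base, required per-population paths, row-count consistency between
data and map arrays, unit attributes, Dimension Scales linkage, the
per-cell Kirchhoff residual (threshold configurable, default 10⁻⁹
relative) and component closure. Each injected corruption class — row
removal, a rescaled segment current, a deleted unit attribute, a
detached scale — is detected by a dedicated test.

## Forward model

`extracellular_potential()` implements the point-source sum with
sources at segment midpoints in an infinite homogeneous resistive
medium (σ = 0.3 S/m default) observed by ideal point electrodes. The
units contract — currents in nA, distances in μm, σ in S/m, potential
in mV with no explicit conversion factor — holds because
1 nA/(S m⁻¹ μm) = 10⁻³ V, and is pinned by a closed-form test: 1 nA at
100 μm gives 1/(4π·0.3·100) ≈ 2.6526×10⁻³ mV.

The default selection is the *cortical* populations' total current;
thalamic populations (TCR, nRT) sit 4900–5200 μm deep and are excluded
unless named. `contribution()` restricts to any (population set,
component set) subset; superposition over a partition reproduces the
total to 10⁻¹⁰ relative, and the optimized matrix-product
implementation is held equal to a naive electrode × segment × sample
triple loop on small fixtures.

Singularities: an electrode falling exactly on a source midpoint would
produce an infinite potential. Rather than silently moving electrodes,
the distance is clamped below by half the segment diameter (the
physical source has finite extent); the clamp is configurable, and
setting it to zero turns coincidence into an explicit error.

Electrode constructors cover the published layouts: a laminar probe of
28 contacts at 92.6 μm spacing along depth, and a 16×20 MEA grid in a
plane 25 μm from the column axis. The MEA pitch is not part of the
published geometry, so `mea_grid()` requires it explicitly; the grid is
centred on the cortical depth midline (850 μm) by default. Free-form
1D/2D/3D layouts load from a plain-text `label x y z` table.
Line-source models, slice media and frequency-dependent propagation are
out of scope (extension points only).

## Signal operations

The LFP is the low-pass component of the extracellular potential; the
convention followed here is a 2nd-order Butterworth at 100 Hz. The
published material does not state pass direction or edge handling, so
both application modes are provided and recorded in the recording's
provenance: `zero_phase_two_pass` (forward-backward; squared magnitude,
no phase lag — the display default, matching common LFP practice) and
`causal_single_pass`. Analytic anchors: a 250 Hz tone against a 100 Hz
cutoff attenuates to 1/√(1+2.5⁴) ≈ 0.158 single-pass and ≈ 0.025
two-pass. Edges are handled by odd-reflective padding of five
settling lengths (`5·fs/cutoff` samples), keeping start-up transients
below 10⁻⁹ of the trace scale; the cutoff must lie below the Nyquist
frequency (5000 Hz at the 0.1 ms base).

MEA frames are displayed by bilinear interpolation on the regular
electrode grid (exact at electrode sites); rasters order cells by
registry population order with up/down markers for
excitatory/inhibitory cells.

## Numerical and design choices

- Scaled registries round half up with a one-cell floor per population;
  degenerate zero-cell registries are tolerated by the placement code.
- Per-cell balancing subtracts the across-segment mean at each sample;
  a single-segment cell would be forced to zero current (no population
  has fewer than 50 sections, so this is theoretical).
- RNG state is saved and restored around every seeded operation, so
  library calls do not disturb the caller's RNG.
- Chunking/compression are deliberately off; round-trip equality is
  asserted bit-for-bit.
- Replay protocols (input-spike drive) reuse the 12.5 Hz modulation
  machinery for their rate envelope and store their input-spike event
  lists under `data/event/input`; a `none` stimulus yields zero drive.

## Problem sizes used in the test suite

Tests run the generator at desk scale — typically three populations
with a handful of cells (≈400–2300 segments) over 30–100 ms, and a 1%
column over 100 ms for the end-to-end pipeline — chosen so the full
suite completes in about a minute while still exercising every
contract at realistic array shapes. The preset registry always
describes the full published values; desk-scale runs override only
`size_fraction` and `stop` through the run configuration.

## Known limitations

- The activity generator reproduces structural contracts, not
  dynamics; spectra, latencies and population interactions are not
  faithful.
- Stand-in morphologies are sticks; near-field spatial detail is not
  meaningful.
- Only the NSDF subset instantiated by this layout is supported
  (uniform sampling, one segment per section); nonuniform blocks and
  simulator-native conversions are out of scope.
- The infinite homogeneous medium is the only volume conductor
  implemented.
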