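# snsvta

Volume-conductor and axon modelling of sacral nerve stimulation (SNS) in R.

SNS treats faecal incontinence with a quadripolar lead implanted in a sacral
foramen. Little of the induced current spread is observable, so contact
configuration is chosen by trial and error. `snsvta` implements the
modelling chain that makes the spread computable: a labelled voxel tissue
volume, implanted lead + pulse-generator geometry, a quasi-static field
solve, and biophysical axon models driven by the computed extracellular
potential. The result for each stimulation setting is the percentage of a
standard 40-fibre arrangement that fires 1:1 with the pulse train, and a
binary volume-of-tissue-activated (VTA) raster viewed down the lead axis.

The core pieces:

- **Field**: `solve_potential()` solves div(sigma grad V) = 0 on the voxel
  grid (7-point finite volume, harmonic-mean face conductances,
  incomplete-Cholesky preconditioned CG in C++; relative residual 1e-8).
  Cathode voxels are Dirichlet at -amplitude, the return (IPG or a second
  contact) at 0 V, everything else zero-flux. Conductivities: fat and colon
  0.01 S/m, bone 0.02 S/m.
- **Axons**: `build_axon()` / `simulate_axon()` implement a double-cable
  myelinated fibre (nodes of Ranvier with fast Na+, persistent Na+ and slow
  K+ conductances; MYSA/FLUT/STIN passive internodes under myelin), 5.7 um
  diameter, 100 mm long, integrated by backward Euler with the
  extracellular drive Ve(t) = field x amplitude x square-pulse train
  (14 Hz, 1 V, 0.21 ms pulses).
- **Activation**: `run_configuration()` runs 4 rows x 10 parallel fibres at
  0.5 mm spacing around the lead and reports `percent_activated`
  (`fires_one_to_one()` per fibre); `compute_vta_map()` rasters activation
  over transverse offsets; `sweep_configurations()` covers both lead models
  (3093 with its long 10.2 mm contact 1, and 3889) in monopolar and bipolar
  settings; `compare_models()` reports the contrasts.
- **Anatomy**: `make_synthetic_pelvis()` generates the parametric pelvic
  stand-in (fat background, sacral slab with foramen channels, colon tube)
  used throughout; `contours_to_volume()` lofts hand-drawn-style per-slice
  contours into voxel solids.

## Worked example

```r
library(snsvta)
tissue <- make_synthetic_pelvis(seed = 1)     # 150 x 150 x 120 mm, 1.15 mm voxels
lead   <- make_electrode(3093)
plc    <- placement(c(48, 75, 55), c(1, 0, 0))  # tip, axis: through a foramen
ipg    <- ipg_spec(c(110, 32, 60))

stim <- stim_config("monopolar", cathode = 0, duration_ms = 3 * 1000 / 14)
res  <- run_configuration(tissue, lead, plc, stim, axon_grid_spec(), ipg = ipg)
print(res)
#> sns_activation: lead 3093, monopolar cathode 0 (IPG return)
#>   35.0% of 40 fibres fire 1:1 (clearance 1 mm)
```

35.0% means 14 of the 40 fibres (10 on each side of the lead, 1.6-6.1 mm
from its axis) fired exactly once per stimulus pulse at 1 V; the percentage
moves in steps of 2.5 (one fibre). Sweeping all settings of both leads:

```r
df <- sweep_configurations(tissue, plc, ipg)   # 12 rows, ~15 min on 1 CPU
compare_models(df)$long_contact_effect
```

reproduces the configuration effects: the long 10.2 mm contact used as
cathode activates substantially less tissue than a 3 mm contact at the same
amplitude (its potential varies more slowly along the fibres, so the second
spatial difference driving excitation is smaller), while monopolar and
bipolar settings with the same cathode differ little. `compare_models()` on
`published_percentages_csv()` (the published per-setting table, shipped as
a fixture) gives the reference contrasts: -15 points monopolar, -10 points
bipolar.

A YAML-driven entry point (`run_from_config()`, CLI in `inst/cli/snsvta.R`)
runs configured sweeps and writes the summary CSV, NIfTI/VTK field volumes,
VTA PNGs and a manifest of all resolved defaults.

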