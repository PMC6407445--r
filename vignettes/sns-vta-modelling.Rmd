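---
title: "Modelling the volume of tissue activated by sacral nerve stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the volume of tissue activated by sacral nerve stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snsvta)
```

## The problem

Sacral nerve stimulation (SNS) treats faecal incontinence by driving current
through a quadripolar lead implanted in a sacral foramen. Which nerve fibres
respond depends on the lead model, the choice of cathode contact, monopolar
versus bipolar return, and the tissue surrounding the lead. `snsvta`
implements the full modelling chain used to study these questions: a
volume-conductor solve of the stimulation-induced electric potential coupled
to biophysical models of myelinated axons, summarised as the percentage of a
standard fibre arrangement that fires 1:1 with the pulse train and as a
binary volume-of-tissue-activated (VTA) raster viewed down the lead axis.

## The model chain

**Tissue volume.** The pelvis is represented as a labelled voxel grid with
per-label conductivity: fat 0.01 S/m (the background), bone 0.02 S/m and
colon 0.01 S/m, values tabulated at the 14 Hz stimulation frequency. Because
no imaging data ship with the package, `make_synthetic_pelvis()` generates a
parametric stand-in with the same gross structure as a segmented pelvic
scan: a 150 x 150 x 120 mm fat volume at 1.15 mm isotropic voxels (echoing
the in-plane MRI resolution the pipeline emulates), one sacral bone slab
transverse to the lead axis pierced by four fat-filled foramen channels
(6 mm diameter, ~20 mm apart), and one colon tube. A seed jitters the
channel centres and tube path by up to 0.5 mm, so different seeds sample
mildly different anatomy while identical seeds reproduce bit-identical
volumes. `contours_to_volume()` provides the companion segmentation path:
closed per-slice polygons are converted to a solid by linear interpolation
of per-slice signed-distance fields, a reproducible stand-in for proprietary
surface lofting; a stack of n identical cross-sections yields a solid of
exactly n slice thicknesses.

What the synthetic anatomy does *not* emulate: registered patient geometry,
muscle/nerve-sheath/CSF compartments, curved lead trajectories, or the
encapsulation layer around chronic implants. Tests passing on this anatomy
validate the machinery and the *relative* effects of contact configuration;
absolute percentages on real anatomy would differ within the tolerance
documented below.

**Hardware.** `make_electrode()` defines the two quadripolar leads: model
3093 (three 3 mm contacts and one 10.2 mm contact as contact 1, gaps
1.5 mm) and model 3889 (four 3 mm contacts, gaps 3 mm), both 1.27 mm in
diameter, contacts indexed 0 from the tip. The published geometry does not
state the tip-to-contact-0 distance or the shaft length in tissue; defaults
are 1.5 mm and contact end + 10 mm, both configurable. The implanted pulse
generator (IPG) is a 55 x 60 x 10 mm cuboid. `rasterize_hardware()` labels
voxels by a centre-inside test (no partial-volume weighting; band edges are
accurate to one voxel).

**Field solve.** `solve_potential()` discretises the quasi-static
(purely resistive) potential problem, div(sigma grad V) = 0, with a 7-point
finite volume on the voxel grid and harmonic-mean face conductances. The
active cathode voxels are held at -amplitude, the return (IPG in monopolar
mode, a second contact in bipolar mode) at 0 V; all other hardware and the
outer boundary are zero-flux. Constant-voltage stimulation fixes only the
potential difference, so pinning the return at 0 V is a convention. The
symmetric positive-definite system is solved by incomplete-Cholesky
preconditioned conjugate gradient to a relative residual of 1e-8 from a
zero initial guess, in C++. A discrete maximum principle (all potentials
within the Dirichlet range) is asserted on every solve.

Because the lead (1.27 mm) is thinner than the default voxel (1.15 mm), the
naive scheme places the Dirichlet surface at the hardware voxel centres and
understates the potential around the lead by 7-8% (measured against a
0.5 mm reference solve in a homogeneous block). Faces between driven
hardware and tissue therefore use an embedded-boundary correction: the face
conductance is sigma x area / d with d the distance from the tissue voxel
centre to the *analytic* hardware surface, clamped to [0.05, 1] voxel. With
the correction the 1.15 mm near-field agrees with the refined solve to
1-3%.

**Axon model.** `build_axon()` constructs a double-cable myelinated fibre:
a repeating 11-compartment internodal pattern (node of Ranvier, MYSA, FLUT,
6 x STIN, FLUT, MYSA) with separate axolemma and myelin membranes and an
explicit periaxonal space. Nodes carry fast Na+, persistent Na+ and slow K+
conductances plus leak (rates tabulated at 36 degC with Q10 scaling
available); paranodal and internodal compartments are passive. The complete
per-diameter geometric and electrical parameter set of the published
double-cable model is shipped as plain-text tables in `inst/extdata`; the
SNS pipeline uses the 5.7 um fibre, 100 mm long (0.5 mm internodes, 201
nodes), long enough to span the modelled nerve course.

`simulate_axon()` integrates the cable equations with backward Euler
(interleaved intracellular/periaxonal unknowns; pentadiagonal symmetric
positive-definite system refactorised each step) under the extracellular
drive Ve(t) = unit-field x amplitude x s(t), where s(t) is the monophasic
square pulse train. The published stimulus states 14 Hz and 1 V but not the
pulse width; the default is 0.21 ms, the conventional clinical SNS setting,
and it is configurable. Spikes are upward crossings of -20 mV with a 1 ms
lockout at a recording node placed 10 nodes from the distal (sealed) end to
avoid end artefacts. The resting state is computed once per morphology by
relaxing the unstimulated fibre for 50 ms and is cached.

Numerical choices that matter: the user time step (default 0.005 ms,
capped at 0.025 ms) is used from each pulse onset until 15 ms after it;
quiet inter-pulse spans are integrated at a coarse 0.025 ms implicit step
(the fastest passive time constant is ~0.3 ms, so backward Euler remains
accurate), and once every compartment is within 0.05 mV of rest the state
is relaxed analytically to the next onset. Both accelerations are verified
against uniform fine stepping in the test suite (identical spike counts,
spike times within 0.15 ms). With a deterministic integrator, drive and
initial state, every simulation is exactly reproducible.

**Activation summaries.** `place_axon_grid()` arranges the standard fibre
set: four rows (superior, inferior, lateral, medial to the lead) of ten
100 mm fibres at 0.5 mm spacing, parallel to the lead. The published
arrangement states the spacing but not the lead-to-first-fibre distance;
the default clearance is 1.0 mm from the lead surface, echoed in run
metadata. Axon midpoints are aligned axially with the midpoint of the
active-contact span (again a documented assumption). `run_configuration()`
solves the field once at unit drive, samples it at every compartment
centre, simulates each fibre, applies the 1:1 criterion (exactly one spike
per pulse window) and reports the activated percentage, a multiple of
2.5 points for 40 fibres. `compute_vta_map()` repeats this for one fibre
per transverse offset (default +/-5 mm at 0.5 mm), giving the black/white
activation raster. Trains are cut to 3 pulses (214.3 ms) for routine runs;
the 1:1 outcome is duration-invariant for this periodic drive, which the
suite spot-checks against 14-pulse (1 s) trains.

## Reproduction scope and tolerances

The published percentages were produced on a patient-MRI-derived mesh that
cannot be reproduced; this package substitutes the parametric anatomy and
documents the unstated parameters above. Percentages are therefore compared
at +/-10 points (the published activation quantum is 2.5 points), while the
*contrasts* that constitute the published findings are checked directly: the
10.2 mm contact used as monopolar cathode activates >= 15 points less than
a 3 mm contact; as bipolar cathode about 10 points less; monopolar and
bipolar settings otherwise differ by <= 10 points; and the 3 mm contacts of
a lead are mutually equivalent. At the defaults above the absolute
percentages run somewhat below the published table (the synthetic foramen
and the unstated clearance/pulse width dominate this offset); the contrasts
are reproduced. No generator parameter was adjusted against the published
values.

Problem sizes used by the shipped checks: the full sweep runs 12 settings
(two leads) on the 130 x 130 x 104 grid with 40 fibres each at 3-pulse
trains; solver oracles run on ~50 mm blocks; axon oracles on 30-40 mm
fibres. These sizes keep a complete run on one CPU within tens of minutes
while leaving every scientific check at full fidelity.

## Design decisions on open points

- Regular-grid finite volume instead of tetrahedral FEM: the published
  meshes are irreproducible, while voxel finite volume is deterministic and
  testable against analytic oracles (concentric spheres, linearity,
  superposition, maximum principle) and respects the same physics.
- Insulators are zero face-conductance (natural Neumann), not meshed holes;
  inactive contacts are insulating.
- The outer pelvis boundary is insulating in all modes (as stated for the
  published model); the monopolar return is the IPG alone.
- Foramen channel interiors take the fat conductivity (unstated in the
  source); configurable.
- The published table labels the second lead "3389" in places and "3889" in
  others; the package treats both as model 3889.
- Between-slice lofting uses linear signed-distance blending; it is
  monotone (larger contours give supersets) and converges to analytic
  volumes under grid refinement, both under test.

## A worked run

```{r}
library(snsvta)
tissue <- make_synthetic_pelvis(seed = 1)
lead <- make_electrode(3093)
plc <- placement(c(48, 75, 55), c(1, 0, 0))  # through a foramen channel
ipg <- ipg_spec(c(110, 32, 60))
stim <- stim_config("monopolar", cathode = 0, duration_ms = 3 * 1000 / 14)
grid <- axon_grid_spec()
res <- run_configuration(tissue, lead, plc, stim, grid, ipg = ipg)
res$percent_activated

# full two-lead sweep and comparison against the published table
df <- sweep_configurations(tissue, plc, ipg)
compare_models(df)
compare_models(published_percentages_csv())
```

## Known limitations

- The anatomy is parametric; no registration to patient geometry, and only
  three tissue classes.
- Purely resistive tissue at the 14 Hz-tabulated conductivities: no
  capacitive, dispersive or electrode-interface effects.
- Single fibre diameter (5.7 um) and unconnected straight axons; no
  fascicle structure or reflex circuitry.
- Voxel-centre rasterisation bounds geometric error by one voxel; the
  embedded-boundary correction addresses the driven surfaces only.
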