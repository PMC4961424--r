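---
title: "Methods: monodomain AF simulation, DF mapping and virtual ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: monodomain AF simulation, DF mapping and virtual ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`afsim` implements an in-silico study of atrial fibrillation (AF) on
left-atrium-like surface meshes: a monodomain reaction-diffusion model with
the Courtemanche-Ramirez-Nattel (CRN) human atrial myocyte as the reaction
term, AF electrical remodeling, conduction-velocity calibration, ramp-pacing
AF induction, dominant-frequency (DF) mapping by FFT, extraction and virtual
ablation of high-DF areas, and the accompanying nonparametric statistics.
This vignette records the model, its assumptions, the numerical choices, and
the design decisions taken where the problem was genuinely open.

## Cell model and AF remodeling

The reaction term is the CRN model (21 state variables: membrane potential,
15 gates, 5 intracellular/SR concentrations), implemented from the published
equations. AF electrical remodeling multiplies four maximal conductances:
Ito x 0.2, IKur x 0.5, ICaL x 0.6, IK1 x 1.5 (`remodeling_preset("af_remodeled")`).
All other currents are untouched, and the multipliers act strictly
multiplicatively (asserted in the tests).

**Validation.** The compiled integrator is checked against an independent
plain-R transcription of the same published equations integrated by
`deSolve::lsoda`: resting potential within 2 mV, action-potential peak within
2 mV, APD90 within 5 ms.

**APD90 calibration protocol.** The remodeled model is calibrated to an
APD90 of 210-220 ms. The pacing rate and beat count behind that figure are
not part of the model definition, so we fixed them from the physiology: a
single 1-Hz test stimulus delivered to the fully equilibrated cell, APD90
measured from the maximum-dV/dt instant to 90% repolarization relative to
the beat's own peak and pre-upstroke diastolic potential. Under this
protocol the remodeled model gives ~213.5 ms. Trains at 1 Hz drift a few ms
lower per beat (the CRN model's well-known slow intracellular-concentration
drift, not a rate-adaptation effect), and 2-Hz steady-state pacing gives
~188 ms; both alternatives are documented here so the calibration is
reproducible and unambiguous:

```{r}
measure_apd90(pace_cell(remodeling_preset("af_remodeled"),
                        cycle_length = 1000, n_beats = 1))
```

## Numerical scheme

The monodomain equation dV/dt = D lap(V) - (Iion + Istim)/Cm is solved by
operator splitting:

* **Diffusion**: explicit step on V with a cotangent-weighted
  Laplace-Beltrami operator under barycentric lumped mass (one third of each
  incident triangle per node). Negative cotangent weights (obtuse pairs) are
  clamped to zero; rows sum to zero over conducting nodes, which yields
  no-flux boundaries and exact conservation of the area-weighted mean of V
  under pure diffusion (a tested invariant). A CFL-type bound
  `D * dt * max(diag) < 0.5` selects the macro step from
  {0.05, 0.025, 0.01, 0.005} ms at operator construction.
* **Reaction**: Rush-Larsen exponential updates for the twelve
  voltage-gated gates (tabulated steady states and rate factors on a
  0.05-mV grid), forward Euler for V, the calcium-handling gates and the
  concentrations. Each node adapts its own substep: 10 substeps when its
  |dV/dt| exceeds 10 mV/ms (upstroke), 2 when it exceeds 1 mV/ms, else a
  single macro step. The admissible step range is 0.005-0.05 ms.

The per-node adaptive substepping replaces a global adaptive step: with
thousands of desynchronized nodes some node is always in its upstroke, so a
global controller would lock the whole tissue to the smallest step and make
desk-scale runs infeasible; per-node banks preserve the accuracy where it
matters. The scheme's self-convergence contract is tested: APD90 computed at
a 0.05-ms versus 0.005-ms macro step differs by < 1 ms, and halving the step
changes V by < 0.01 mV over 1 ms of quiescence.

## Synthetic left-atrial geometry

Patient CT meshes are emulated by a parametric generator
(`make_synthetic_la()`): a subdivided-icosahedron shell scaled to ellipsoid
semi-axes, four pulmonary-vein (PV) ostia extruded as short tubes, an open
mitral annulus, a smooth appendage protrusion, and seeded 3-D Gaussian
surface jitter (with local untangling of any inverted faces). The
anteroposterior extent is ~48 mm, the echocardiographic LA dimension of a
persistent-AF population; the other semi-axes are dilated accordingly, and
the surface area lands near 15,000 mm^2, typical of dilated
atria. The mesh is closed and orientable with exactly five boundary loops
(Euler characteristic -3), and every geometry is bit-for-bit reproducible
from its seed.

**Mesh roughness is the reentry substrate.** At desk-scale resolution the
sub-grid conduction heterogeneity of real atrial tissue has to be carried
by the mesh itself: the raw jittered triangulation — including its obtuse
triangle pairs (whose clamped cotangent weights act as sparse micro-blocks)
and a small number of sliver triangles at the PV–LA junctions — is what
lets ramp pacing break waves and anchor reentry. Regularizing it
(`quality_repair = TRUE`, which enforces a 15-degree minimum triangle
angle) produces a textbook-quality mesh on which the same protocol induces
nothing. The default is therefore the unrepaired mesh; numerical stability
does not depend on the angle floor, because negative cotangent weights are
clamped and the macro step is chosen from the operator's CFL bound. The
default surface area (~15.4k mm^2) sits at the upper edge of the plausible
range for a dilated persistent-AF atrium; both choices trade textbook mesh
aesthetics for the arrhythmia substrate and are asserted as such in the
test suite.

The ten anatomical sections (R1 septum, R2 anterior wall, R3 appendage,
R4 peri-mitral, R5 posterior inferior, R6 posterior wall, R7-R10 the four
PVs) are assigned by generator landmarks: PV tubes keep their tags, every
other node joins the geodesically nearest landmark (shortest paths on the
edge graph), which makes each section contiguous. The real study divided
sections manually on patient anatomy; any landmark layout is an
approximation of that figure.

What the generator does **not** emulate: wall thickness, fiber orientation,
regional ionic heterogeneity, true CT-derived shape detail. Passing tests on
these geometries show the pipeline's correctness and the qualitative
dynamics, not patient-level realism.

## Conduction-velocity calibration

The diffusion coefficient is calibrated on a 25 mm x 2.5 mm planar strip at
the target edge length: pace one end at 500-ms cycle length, measure CV
between two mid-line probes 10 mm apart on the third beat, iterate D until
the CV is within 2% of target (0.4 m/s by default; 0.5 and 0.6 m/s for the
higher-CV experiments). The delivered default for the reference 0.25-mm
strip is D = 0.0822 mm^2/ms. CV scales approximately as sqrt(D), which the
calibration exploits and a test verifies.

## Desk-scale dynamics and their limits

At the desk-scale mesh resolution (~2.3-mm edges, ~2,650 nodes) the discrete
wavefront pays a conduction-safety penalty at short coupling intervals.
Measured on calibration strips: the 1:1 rate-following cutoff is ~230 ms at
2.2-mm edges versus ~185 ms at 0.25-mm edges, and — decisively — only the
near-continuum tissue can conduct decrementally at ~25-ms diastolic
intervals, which is how fine-scale tissue escapes the 2:1 conduction lock
during a 200-ms ramp and fragments into fibrillation. Coarse tissue locks
into spatially concordant 2:1 conduction under the classical 200/190/180-ms
ramp (conducted intervals 360-400 ms, generous recovery everywhere) and the
activity collapses the moment pacing stops, for any geometry.

The desk-scale induction preset therefore preserves the *mechanism* rather
than the printed numbers: the ramp (same structure, eight beats per train)
is placed just above the measured desk-resolution vulnerability window —
300/285/270 ms, straddling the cliff between stable 1:1 conduction
(~280 ms), irregular meandering conduction (~300 ms) and 2:1 block
(<= 260 ms). Pacing into this window produces spatially discordant block on
the rough synthetic atria and launches sustained reentry (~3 Hz) in a
majority of geometry seeds, mirroring at desk scale the fine-scale ramp
pacing into *its* vulnerable window. `straight_pacing()` defaults to the
classical 200/190/180-ms protocol (4560 ms total); `run_study()`'s
desk-scale configuration uses the scaled preset, and
`study_config(paper_scale = TRUE)` restores the classical one. Absolute DF
values at desk scale are accordingly ~3 Hz rather than the 5-8 Hz of
GPU-scale AF; the DF mapping, high-DF-area extraction, ablation and
statistics machinery is exact and scale-independent.

## DF mapping

The "virtual action potential" entering the spectra is the raw membrane
potential sampled at 1 kHz, mean-removed and Hann-windowed; the DF is the
argmax of the periodogram in a 1-20 Hz band (config-exposed), ties broken
toward the lower frequency, silent nodes (peak-to-peak < 1 mV) carrying an
NA sentinel. Window length sets the frequency resolution (1/6 Hz for the
full-protocol 6-s windows). The "highest 10% DF area" is interpreted as the
top fraction of *tissue area* ranked by nodal DF (not a DF-value
percentile): nodes are sorted by DF descending (ties by index) and selected
greedily until their lumped areas first reach the target fraction, which
makes the 10/15/20% ablation extents well defined and reproducible and
bounds the selected-area error by one node-area granule.

## Virtual ablation and outcome classification

Ablation removes the masked nodes from the conduction graph entirely (zero
flux with every neighbor) and freezes their ionic state at rest — a total
conduction block, the strict reading of a "non-conduction condition". Trials
branch independently from the checkpoint at the end of each DF window; masks
at 10/15/20% are nested by construction. Outcomes within the follow-up:

* `AF_terminated` — no activation anywhere for 200 consecutive ms;
* `AT_conversion` — the final 2-s window classifies as organized: at >= 90%
  of 20 area-stratified seeded probe nodes the inter-activation-interval
  coefficient of variation is < 10% and the probe DFs agree within one
  frequency bin (the event time is the start of the first 2-s stretch whose
  interval criterion holds);
* `AF_maintained` — otherwise.

The AT criterion is an operationalization of "changed to atrial
tachycardia", which the source protocol never quantified; thresholds are
config-exposed.

## Statistics

Regional spatiotemporal stability is quantified exactly as in the study
design: the windows x regions table of % High DF Area per geometry; the
Friedman test with windows as blocks and regions as treatments (spatial
consistency); the temporal coefficient of variation (100 x sd/mean across
windows) per region; Kruskal-Wallis across the ten sections; a Welch t-test
pooling per-geometry-per-region CoVs of the historically unstable group
(PVs, appendage, peri-mitral) against the remaining walls; and a Pearson
chi-square (no continuity correction) on the fractions x
{maintained, changed-or-terminated} ablation table. The engines are the
standard `stats::` routines; every statistic is cross-checked against
textbook formula oracles in the tests. No multiple-testing correction is
applied, matching the study design; alpha = 0.05.

## Study orchestration and problem sizes

`run_study()` chains the stages per geometry seed and writes all tables
(regional % High DF Area per window, trial outcomes, the Table-2-style
summary), VTK DF fields, and a JSON report; geometries are cached as RDS
checkpoints so a crashed run resumes. The desk-scale defaults — 3
geometries of ~2,650 nodes, three 2-s DF windows, three ablation fractions,
short post-ablation follow-up — were chosen so the full study and the test
suite complete in minutes on one CPU; the full protocol (nine 6-s windows
every 30 s, 30-s follow-ups, 280-s episodes) is available behind
`study_config(paper_scale = TRUE)` and is orders of magnitude heavier.
Determinism: a (config, seed) pair fixes every output, including probe
selection in the classifier and the synthetic geometries.

## Known limitations

* Homogeneous, isotropic monolayer: no wall thickness, fibers, or regional
  electrophysiology (a stated property of the modeled system, but a real
  limitation for clinical interpretation).
* Desk-scale resolution caps the propagated rate (previous section), so
  absolute DF values and episode dynamics are a scaled analog, not a
  reproduction, of the GPU-scale study.
* The AT/AF discriminator is a documented invention; different thresholds
  shift the AT-vs-maintained split.
* PLY I/O is ASCII-only; recordings and checkpoints persist as RDS rather
  than HDF5.
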