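# afsim

In-silico atrial fibrillation (AF) on left-atrium-like surface meshes, for
computational cardiac electrophysiologists studying the spatiotemporal
behaviour of dominant-frequency (DF) sites and the effect of ablating them.

The package implements the full pipeline of such a study:

* **Cell model** — the Courtemanche–Ramirez–Nattel human atrial myocyte with
  persistent-AF electrical remodeling (Ito ×0.2, IKur ×0.5, ICaL ×0.6,
  IK1 ×1.5), calibrated to an APD90 of 210–220 ms.
* **Tissue model** — the monodomain equation
  ∂V/∂t = D∇²V − (I_ion + I_stim)/C_m on triangulated surfaces: a
  cotangent-weighted Laplace–Beltrami operator with lumped mass, explicit
  diffusion, Rush–Larsen/forward-Euler reaction with per-node adaptive
  substeps (0.005–0.05 ms), D calibrated so a planar wave travels at
  0.4 m/s.
* **Synthetic geometry** — seeded left-atrium-like shells (≈48-mm
  anteroposterior extent, four pulmonary-vein ostia, open mitral annulus,
  appendage, CT-like surface roughness), partitioned into the ten standard
  LA sections R1–R10 (septum, anterior wall, appendage, peri-mitral,
  posterior walls, four PVs).
* **AF induction** — straight ramp pacing from a high-septal patch,
  activity detection, AF/AT/quiescent classification.
* **DF analysis** — per-node periodogram DF maps in analysis windows
  T1…Tk, "high DF area" masks at 10/15/20% of tissue area, regional
  % High DF Area tables.
* **Virtual ablation** — high-DF areas rendered non-conducting at the end
  of each window; outcomes tabulated as AF maintained / AT conversion /
  AF terminated with a chi-square comparison across ablation extents.
* **Statistics** — temporal coefficient of variation, Friedman test of
  spatial consistency, Kruskal–Wallis across sections, Welch t-test of the
  PV/appendage/peri-mitral group against the other walls.

The solver core is compiled (Rcpp); a desk-scale study (three ~2,600-node
atria, three DF windows, three ablation fractions) runs in minutes on one
CPU. See the methods vignette (`vignettes/afsim-methods.Rmd`) for the
model, the numerical scheme, and how desk-scale dynamics relate to
GPU-scale AF.

## Worked example

```r
library(afsim)

# 1. remodeled cell: action potential duration at 90% repolarization
apd <- measure_apd90(pace_cell(remodeling_preset("af_remodeled"),
                               cycle_length = 1000, n_beats = 1))
apd
#> [1] 213.4518          # ms, inside the 210-220 calibration band

# 2. tissue: conduction velocity with the delivered default diffusion
strip_cv(default_diffusion(), resolution = 0.25)$cv
#> [1] 0.4048583         # m/s, within 5% of the 0.4 target

# 3. a synthetic atrium, partitioned into the ten sections
la <- partition_regions(make_synthetic_la())
la
#> <surface_mesh> 2603 nodes, 5099 triangles, 15373.2 mm^2, 5 boundary loops,
#>  2603 labeled nodes

# 4. induce AF, map DF, ablate the top 10% DF area
cal <- calibrate_diffusion(0.4, round(mean_edge_length(la), 1))
op  <- build_diffusion_operator(la, diffusion_field(cal$D))
prot <- straight_pacing(la, cycle_lengths = c(300, 285, 270))
w <- matrix(c(9000, 11000), 1)
ep <- induce_af(op, remodeling_preset("af_remodeled"), prot,
                follow_ms = 6000, windows = w)
dm <- compute_df_map(ep$recording, w[1, ])
trial <- run_ablation_trial(op, ep$checkpoints[[1]], dm, fraction = 0.10,
                            follow_ms = 4000)
trial
#> <ablation_trial> 10% ablation, 259 nodes: AF_terminated at 0.5 s
```

The percentages printed by `tabulate_outcomes()` are per-fraction outcome
rates; `defrag_or_term_rate` is the share of trials in which AF either
organized into AT or terminated — the study's headline effectiveness
measure for DF-guided ablation.

A full study is one call:

```r
report <- run_study(study_config(geometry_seeds = c(1, 5, 13),
                                 out_dir = "study_out"))
report   # Friedman p per geometry, temporal CoV by region, outcome table
```

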