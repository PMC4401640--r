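# polarflow

Quantitative analysis of flow-driven endothelial cell polarity and vessel
regression in planar vascular networks, built for the postnatal mouse retina
plexus and any comparable 2D microvascular preparation.

During developmental remodelling, superfluous vessel segments regress,
leaving empty collagen-IV basement-membrane sleeves ("regression profiles"),
while endothelial cells polarize axially against blood flow — the vector
**p** from the nucleus centre of mass to the Golgi apparatus points
upstream. `polarflow` implements the whole measurement chain behind these
observations:

* **Network reconstruction** — medial-axis skeletonization of segmented
  lumen/matrix masks with per-segment radius profiles from the Euclidean
  distance transform (`skeletonize()`, `build_graph()`,
  `annotate_segments()`).
* **Haemodynamics** — a 1D Poiseuille network solver: per-segment
  conductance G = π r⁴ / (8 μ L), Kirchhoff node balance, wall shear stress
  τ = 4 μ |Q| / (π r³), oriented flow directions (`solve_flow()`,
  `wall_shear()`, `classify_flow()`).
* **Axial polarity** — per-cell angle to flow θ ∈ [0°, 180°], the scalar
  product s = |p|·cos θ (negative = against flow), the against-flow window
  fraction (180° ± 45°), circular statistics, and sign-stratified linear
  regressions of s on τ (`pair_points()`, `assign_to_segments()`,
  `angle_and_scalar()`, `region_stats()`, `shear_regressions()`).
* **Regression profiles** — detection of matrix-positive, lumen-deficient
  segments, staging along the four-step regression sequence (selection →
  stenosis → retraction → resolution), apoptosis colocalization by a 10 μm
  distance rule, and counts per vascularized area (`detect_profiles()`,
  `colocalize_apoptosis()`, `regression_counts()`,
  `low_flow_association()`).
* **Spatial profiling** — cell density, branchpoint density, and
  length-weighted mean wall shear stress as functions of distance from the
  optic nerve (`radial_profile()`, `marker_density()`).
* **Synthetic retinas** — a generator with planted ground truth
  (`gen_config()`, `generate_network()`, `plant_regression_and_apoptosis()`,
  `generate_cells()`, `render_masks()`) whose defaults describe a P6 mouse
  retina: ~16,000 endothelial cells, a Poisson mean of 78.1 apoptotic
  events, and a 4.82% apoptosis–regression colocalization rate. Every
  analysis stage is validated by recovering what the generator planted.

The methods vignette (`vignettes/polarflow-methods.Rmd`) documents the
models, parameter defaults, numerical choices, and limitations.

## Worked example

Generate a default synthetic P6 retina, solve flow, and run the analyses:

```r
library(polarflow)

cfg <- gen_config(seed = 42)           # default synthetic P6 retina
net <- generate_network(cfg)
print(net)
#> <vessel_network> 2916 nodes, 4738 segments (artery: 160, capillary: 4320, sprouting_front: 98, vein: 160)
#>   total centerline length 163718 um, vascularized area 1238379 um^2

planted <- plant_regression_and_apoptosis(net, cfg)
flow    <- solve_haemodynamics(planted$network)
cells   <- generate_cells(planted$network, cfg, flow)$cells

cells <- assign_to_segments(cells, planted$network)
cells <- angle_and_scalar(cells, planted$network, flow)
region_stats(cells)$by_region[, c("region", "n", "frac_against", "mean_pmag")]
#>                          region     n frac_against mean_pmag
#> artery                   artery  1091        0.879      4.98
#> capillary             capillary 13217        0.860      5.02
#> sprouting_front sprouting_front     0           NA      5.02
#> vein                       vein  1381        0.831      5.04
#> all                         all 15689        0.859      5.02

profiles <- detect_profiles(planted$network)
res <- colocalize_apoptosis(profiles, planted$network, planted$events)
#> regression profiles: 77; colocalized with apoptosis: 3.90%

radial_profile(planted$network, cells, flow, profiles, bin_width = 200)[
  , c("r_lo", "r_hi", "cell_density", "branchpoint_density", "mean_tau")]
#>   r_lo r_hi cell_density branchpoint_density mean_tau
#> 1    0  200        0.018              0.0019    0.723
#> 2  200  400        0.016              0.0021    0.216
#> 3  400  600        0.014              0.0022    0.094
#> 4  600  800        0.012              0.0026    0.038
#> 5  800 1000        0.010              0.0022    0.013
```

Reading the output: ~86% of cells point against flow (most strongly along
arteries), 77 regression profiles are detected of which 3.9% colocalize with
an apoptotic event in this replicate, endothelial cell density and mean wall
shear stress fall with distance from the optic nerve while branchpoint
density rises — the transition from remodelled to primitive plexus.

`run_pipeline()` chains simulate → (optional render/extract) → flow →
polarity → profile → regression from a YAML config and writes all artifacts
plus a JSON run report; `inst/exec/polarflow` is a thin command-line wrapper
(`polarflow run --config cfg.yaml --seed 1 --outdir out`).

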