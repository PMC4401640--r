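---
title: "Quantifying flow-driven endothelial polarity and vessel regression with polarflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flow-driven endothelial polarity and vessel regression with polarflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

During postnatal development the mouse retina builds a dense primitive
capillary plexus and then prunes it: superfluous segments regress, leaving
empty collagen-IV basement-membrane sleeves ("regression profiles"), while
high-flow routes stabilise into arteries and veins. Two quantitative
observations anchor the migration-driven model of this remodelling:

1. regression is largely apoptosis-independent — in a whole P6 retina of
   roughly 16,000 endothelial cells only on the order of 78 cleaved-caspase-3
   events are found, and only ~5% of regression profiles colocalize with one;
2. endothelial cells polarize axially *against* blood flow — the vector from
   the nucleus centre of mass to the Golgi apparatus points upstream, more
   strongly the higher the wall shear stress.

`polarflow` implements the full measurement chain behind such numbers as a
reusable, tested pipeline: vascular-network reconstruction with radii from
segmented masks, one-dimensional Poiseuille haemodynamics, nucleus-to-Golgi
polarity statistics relative to local flow, radial profiling, and
regression-profile detection/staging with apoptosis colocalization. Because
no deposited imaging data exist for this kind of study, the package also
contains a first-class synthetic-retina generator with planted ground truth;
every downstream stage is validated by recovering what was planted.

## The synthetic retina

`generate_network()` builds a planar plexus as a radial spoke-and-mesh
construction: arterial and venous spokes alternate around the optic nerve
head, concentric capillary rings connected by staggered radial capillaries
form a honeycomb-like mesh of degree-3 branch points (a polar "brick wall"),
and blind-ended sprout stubs decorate the rim. This is a geometric stand-in,
not a biophysical growth model: it reproduces the *statistical* structure
the analyses consume — calibre hierarchy, flow topology with one inlet per
artery and one outlet per vein, a capillary bed at a set spacing, an
unperfused sprouting front — with exactly known topology and geometry.
Degree-2 nodes are merged at generation time so the emitted graph is in the
same normal form that centerline extraction recovers.

Defaults (`gen_config()`) describe a P6 retina: radius 1000 um, 5 arteries
and 5 veins, 30 um capillary spacing, radii 12/15/3.5 um for
arteries/veins/capillaries, 16,000 endothelial cells, a Poisson mean of 78.1
apoptotic events, a planted regression rate of 2% of capillary segments, and
an apoptosis-regression colocalization rate of 4.82%. The cell total,
apoptosis mean, and colocalization rate are the study's reported values;
the geometric parameters are typical P6 morphometry. Where a generator
choice was genuinely open we fixed it once:

* **Cell count.** Exactly `n_cells_target` nuclei are emitted (the generator
  conditions on the observed total); a planted radial density gradient makes
  central density twice the peripheral one, matching the observed decline of
  cell density with distance from the optic nerve.
* **Polarity.** Directions are sampled in 2D (flat-mount convention) from a
  von Mises distribution centred 180 degrees from the local flow direction;
  the concentration `kappa` (default 4) is the single knob for "robust"
  polarization. Cells on unperfused segments get uniform directions.
  Magnitudes are truncated-normal (mean 5 um, sd 1.5 um).
* **Regression stages.** Planted segments draw a stage from `stage_mix`
  (default 10/30/30/30% over selection/stenosis/retraction/resolution).
  Stage 1 precedes any visible morphology, so it exists only in the ground
  truth; recovery metrics are defined over the detectable stages 2-4.
  Stage 2 dips the radius profile to 30% over the middle third; stage 3 sets
  the lumen fraction in (0.05, 0.45); stage 4 empties lumen and cells while
  retaining matrix.
* **Colocalization identifiability.** The number of colocalized profiles is
  the randomized rounding of `coloc_rate x n_detectable` (unbiased across
  replicates); colocalized events sit at segment arc midpoints (plus 1 um
  jitter) so they cannot accidentally flag a neighbouring profile, and the
  remaining events are placed uniformly along the non-regressing vasculature
  *excluding* the `coloc_dist` corridor around detectable profiles. Without
  that exclusion the planted rate would not be identifiable by any
  distance-rule detector, because chance encounters would inflate it.
* **Inlets/outlets.** Each trunk vessel terminates in its own boundary node
  on a small circle at the optic nerve head; coincident nodes would collapse
  inlets and outlets into one node and make boundary pressures ill-defined.

What the generator does **not** emulate: intensity noise and point-spread
blur (masks are binary, as the upstream segmentation step would produce),
pericytes and macrophages, 3D vessel crossings, and time. Passing recovery
tests therefore demonstrates correctness of the measurement chain on
idealised segmented data, not robustness to segmentation error.

## Network extraction

`skeletonize()` reduces the largest connected component of a binary mask to
a unit-width medial skeleton and returns the Euclidean distance transform
(EBImage) alongside. Thinning is Zhang-Suen with two additions that matter
on vascular masks: (i) ridge anchoring — local maxima of the distance
transform may never be deleted, which prevents parallel thinning from
eroding the spine of wide blind-ended branches entirely; (ii) a sequential
simple-point pass that shrinks the 2-px diagonal staircases Zhang-Suen
leaves into single-pixel paths without changing topology. Sub-resolution
background holes (rasterization slivers at junctions, default < 25 px) are
filled first; genuine mesh openings are orders of magnitude larger.

`build_graph()` turns the skeleton into a `vessel_network`: pixels with
other than two neighbours become nodes (adjacent node pixels cluster to
their centroid), maximal paths become segments, and the radius profile is
the distance map along the path minus half a pixel (the transform reaches
the nearest *background pixel centre*, half a pixel beyond the boundary).
The per-segment `mean_radius` excludes the 3 px nearest each node, where
distance-transform radii inflate at junctions. Three artefact-repair passes
follow, each with a stated rationale: spur pruning (default 4 px), fusion of
short internal segments (thinning splits an X crossing into two T's
separated by roughly the vessel width, so the threshold adapts to the local
radius), and removal of the tiny self-loops that fusion can leave. Finally
centerlines are smoothed (5-vertex moving average, endpoints pinned) so
tangents — later used as local flow directions — are not quantized to pixel
steps. Tracing visits pixels in lexicographic order; extraction is
deterministic.

On rendered synthetic plexuses this recovers the generated topology exactly
in 20/20 test seeds and radii to a median error of ~0.3 um at 1 um/px.

## Haemodynamics

`solve_flow()` treats each perfused segment (lumen fraction at or above
`lumen_cutoff`, default 0.5 — operationalising "perfusion-negative" vessel
segments) as a Poiseuille resistor with conductance G = pi r^4 / (8 mu L)
and solves the Kirchhoff conservation system with Dirichlet pressures at
inlets (default 60 Pa) and outlets (0 Pa), Newtonian viscosity
mu = 3.5e-3 Pa s. Blind side-branches are pruned beforehand and carry
exactly zero flow; components without boundary nodes are held at outlet
pressure with a warning. `wall_shear()` adds tau = 4 mu |Q| / (pi r^3) and
per-vertex oriented unit flow directions. The absolute pressure scale is
arbitrary — no boundary values are published for the real retina — so all
downstream comparisons are ordinal in tau (low/high classification,
rank-based association, regression slopes); this is also why no
haematocrit-dependent viscosity correction is applied. `classify_flow()`
labels segments strictly below the `low_q` (default 0.25) quantile of tau
as low-shear; ties fall to "high", so an all-equal shear field has no "low"
segments.

Units: coordinates and radii in um, pressures in Pa, flows in um^3/s,
shear in Pa. These combine consistently without conversion factors.

## Polarity statistics

The axial polarity vector of a cell is p = Golgi - nucleus (um).
`pair_points()` performs greedy globally-nearest one-to-one matching within
10 um for mask-derived point sets; the generator emits matched pairs
directly. `assign_to_segments()` assigns each nucleus to the segment with
the nearest centerline; because the nearest *vertex* can belong to a
neighbouring segment close to a junction, the assignment is refined by exact
point-to-polyline distance over the nearest segment and all segments sharing
a node with it, with ties to the lower segment id.

`angle_and_scalar()` measures theta, the angle in [0, 180] degrees between
p and the oriented flow direction at the cell's nearest polyline vertex
(vertex-local, so curved segments are handled), and the scalar product
s = |p| cos(theta). The sign convention follows the field: s < 0 means
polarized against flow. Note s carries length units (um) — it is the
projection of the polarity vector on the flow direction, not a dot product
with the shear vector — so the gradients reported by `shear_regressions()`
(OLS of s on tau, stratified by sign of s and pooled) have units um/Pa.
The "against flow" window is theta in [135, 180], *closed* at 135; the
window is conventionally printed as 180 +/- 45 degrees without a boundary
rule, and the closed choice is asserted in tests. `region_stats()` reports
both the pooled per-cell fraction and, when a replicate column is present,
the mean of per-replicate fractions, since either averaging convention is
defensible.

Group comparisons (`misalignment_near_regression()`, low- vs high-shear and
regression-adjacent vs not; `low_flow_association()`, profiles vs low-shear
segments) use seeded permutation tests. The association statistic is the
mean rank of tau among profile segments rather than a function of the
dichotomized 2x2 table: a (near-)continuous statistic keeps the null
distribution of the p-value close to uniform, which the calibration tests
verify (type-I error 5% +/- 2% over 200 null replicates at 499
permutations). The 2x2 table and Haldane-Anscombe-corrected odds ratio are
still reported for interpretability.

## Regression detection and colocalization

`detect_profiles()` declares a segment a regression profile iff it retains
basement membrane and is lumen-deficient: lumen fraction below the
continuity threshold (0.95) or a focal stenosis dip (minimum radius below
0.5x the segment median). Stages are assigned by ordered, mutually
exclusive rules: resolution (no lumen, no resident cells), retraction
(disrupted lumen), stenosis (continuous lumen with a dip). The band of
lumen fractions between the disconnection and continuity thresholds is
classed as retraction — lumen breakage in progress — a choice the staging
rules leave open. All thresholds are config-exposed defaults, stated as
package decisions: the morphological definitions in the literature are
qualitative. A segment with no lumen but no retained matrix is *not* a
profile (the matrix requirement is the definition).

`colocalize_apoptosis()` flags a profile iff any apoptotic event lies
within `coloc_dist` (default 10 um — one cell-body radius) of its
centerline, and reports the percentage plus its complement; with zero
profiles the percentage is undefined (NA), never 0. Whether the original
quantification used a distance rule or visual overlap is unstated; the
10 um rule is our operationalisation.

## Radial profiling

`radial_profile()` bins cell density (nuclei/um^2 of vascularized area),
branchpoint density, length-weighted mean wall shear stress, and regression
density by distance from the optic centre (default 100 um bins).
Vascularized area uses the graph convention sum(L x 2r), so profiles work on
graph-only inputs; `stack_vascularized_area()` provides the raster-mask
alternative (positive lumen pixels x pixel area) — the two differ by
junction overlaps and rasterization, typically a few percent. Segments
straddling a bin edge are apportioned by arc length, which makes bin
merging exactly additive (tested). Empty bins report NA densities rather
than dividing by zero.

## Numerical and reproducibility choices

* One master seed drives everything; each stochastic stage (network, plant,
  cells, each permutation test) derives a fixed substream, so stages can be
  regenerated independently and identical configurations are byte-identical
  on disk (asserted on the network JSON).
* Network JSON is schema-versioned and serialised at full double precision;
  write-then-read is the identity.
* The sparse pressure solve uses a direct factorization (Matrix); node
  conservation residuals sit at ~1e-11 of max |Q| on 5,000-segment
  plexuses, comfortably inside the 1e-8 contract.
* The von Mises sampler is the Best-Fisher rejection algorithm; its test
  oracle (the window mass) is computed independently by numerical
  integration of the density.
* Degenerate inputs fail loudly with classed conditions
  (`polarflow_config_error`, `polarflow_input_error`,
  `polarflow_precondition_error`, `polarflow_unsolvable_error`,
  `polarflow_parse_error`).

## Problem sizes used in the test and acceptance suites

Whole-retina recovery (cell count, apoptosis count, colocalization) runs at
the full default P6 scale: ~4,700 segments, 16,000 cells, 5-8 replicates.
Property suites run on compact plexuses (radius 220-300 um, 100-300
segments) where brute-force oracles — exhaustive nearest-polyline search,
hand-solved Kirchhoff systems, closed-form window masses — are exact and
fast; mask round-trips use 20 such retinas at 1 um/px, and permutation
calibration uses 200 null replicates at 499 permutations. These sizes were
chosen so each oracle remains airtight at desk scale.

## Known limitations

The 1D Poiseuille model ignores pulsatility, haematocrit partitioning, and
3D lumen geometry; its shear field is meaningful ordinally, not in absolute
Pa. The generator's plexus is statistically, not developmentally, realistic;
in particular sprout-front remodelling dynamics, Golgi fragmentation, and
3D layering are out of scope. Mask-path statistics inherit a small dilution
from junction ambiguity in cell assignment (quantified in the pipeline
round-trip test). Stage-1 "selection" is by definition invisible to any
static morphological detector, including this one.
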