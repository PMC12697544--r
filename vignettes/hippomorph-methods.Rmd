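---
title: "Measuring hippocampal subfield borders on labeled postmortem MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hippocampal subfield borders on labeled postmortem MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippomorph)
```

## The problem

Hippocampal subfield segmentation protocols for in vivo MRI lean on
heuristics distilled from small sets of histology-validated reference
specimens: in which order subfields appear along the long axis, where the
subicular subregion borders sit on a coronal slice, how far CA1 extends
around the dark band (SRLM), how the SUB–CA1 border drifts medially toward
the tail. Extracting those heuristics from annotated label maps has mostly
been manual — lines drawn in a viewer, slices counted by eye. hippomorph
turns the measurements themselves into tested, deterministic code that
operates on 3D integer label maps (NIfTI-1) with the eight labels SUB, PrS,
PaS, CA1, CA2, CA3, DG and SRLM, plus a per-case landmark sidecar.

Every function takes or returns plain tibbles, so a cohort analysis is a
pipe of measurement calls followed by the statistics layer.

## Coordinate conventions

All measurements run in one canonical frame: `+x` medial→lateral, `+y`
inferior→superior, `+z` anterior→posterior, so a coronal slice is a fixed
`z`. `load_label_volume()` constructs this frame from the NIfTI
qform/sform plus a hemisphere flag (lateral is `+R` for a right
hippocampus, `−R` for a left one); mirroring a file's stored data and
flipping the flag reproduces the identical canonical volume, which is what
makes every measurement hemisphere-invariant by construction.

Slice indices are 1-based, following R convention. Distances between
slices `z1 < z2` are `(z2 − z1) × dz` mm — inter-slice distance, not an
inclusive count; published slice-count arithmetic does not state which
convention it used, so this choice is documented here rather than claimed
to be the source's. At the native 0.2 mm isotropic resolution of
ultra-high-field postmortem MRI, five slices are 1 mm.

Landmarks (anterior tip, posterior tip of the uncal apex, most posterior
slice) require visual identification of uncal tissue and are therefore
always supplied as a sidecar, never auto-detected.

## Appearance and disappearance (extent module)

A subfield *appears* on the first slice holding a connected cluster of at
least 4 voxels of its label, with 8-connectivity (corners or edges). When
the slice immediately anterior to a candidate lacks segmentation coverage,
a single voxel suffices on that candidate — a cluster rule cannot be
trusted across a histology gap. Two special rules: SUB's appearance is the
anterior-tip slice itself by definition (a QC warning fires if that slice
carries no SUB voxel), and DG appears on the first slice where a DG
component is *fully enclosed* by DG/SRLM in its 8-neighbourhood, mirroring
how the dentate is recognized on MRI by the dark band surrounding it.

*Disappearance* is simply the last segmented slice — no cluster threshold,
because posterior extent was recorded from the last annotated slice, and
mirroring the 4-voxel rule there would be an invention. Gap handling
differs too: the anterior coverage fallback never applies posteriorly.

Head length is anterior tip → uncal apex; total length is anterior tip →
posterior tip; the ratio is head/total × 100. A posterior tip flagged
undeterminable yields `NA` total and ratio while head length is still
reported, mirroring how real cases drop out of individual analyses.

## Subicular-complex proportions (subicular module)

On body slices chosen at 10…50 % of total length posterior to the uncal
apex, the medial–lateral composition of the subicular complex is measured
along a mid-cortical centerline from the SUB–CA1 interface to the medial
extreme of the most medial present region. The manual procedure drew
piecewise-linear lines "bisecting" the cortex with breakpoints at visual
inflection points; "inflection point" has no algorithmic definition, so
the centerline here is the medial-axis skeleton of the SUB∪PrS∪PaS mask
(Zhang–Suen thinning, spurs under 3 voxels pruned), which is deterministic,
curvature-adaptive, and equal to the bisecting line in the straight-strip
limit. Whether the manual measure was chord length or curvilinear length
is ambiguous in the source material; the skeleton path approximates the
curvilinear reading, and that choice is flagged here rather than hidden.

Two numerical details matter:

* **End erosion.** Thinning retracts the skeleton by about half the ribbon
  thickness at each end. The path is therefore extended along its end
  tangents (quarter-voxel steps, stopping half a step into the boundary
  shell), with ~1-voxel-spaced intermediate points so that narrow end
  regions (PaS can be only a few voxels wide) receive their full share.
* **Chain-metric bias.** Summing axial/diagonal pixel steps overestimates
  digitized curve length by up to ~8 % depending on orientation. Path
  coordinates are smoothed with a 7-point moving average (ends anchored)
  before segment lengths are summed; the window was chosen on digitized
  straight lines across orientations (max error < 0.8 %) against the
  curvature bias it introduces (~0.5 % at a 20-voxel radius). On a
  quarter-annulus of centerline radius 20 voxels the remaining length
  error is ~2.9 %.

Region percentages are path-length shares, with segments at a region
change split half-half between the neighbours. Present-region percentages
sum to 100 ± 0.1 by construction; when PaS is absent, PrS absorbs its
share, as the composition data show posteriorly.

## SRLM projection (srlm_projection module)

The "flashlight" measure asks what fraction of the SRLM band lateral to
the most medial DG point each CA subfield's projection covers. The
metaphor defines no metric, so projection is realized as nearest-CA-voxel
assignment (in-plane Euclidean distance), with distance ties broken by the
fixed priority CA3 > CA2 > CA1 — the tie set is the one-voxel shell where
two subfields meet, so the priority affects at most that shell, and a
fixed order keeps runs reproducible. "Lateral to" is the half-plane
`x ≥ medial_dg_x`.

When the SUB–CA1 interface itself lies lateral to the medial DG point, the
interface midpoint is projected onto the band and all band voxels medial
of that projection (ordered along the band's skeleton path from its medial
end) stay unassigned — the proportions then deliberately sum to less than
one. The exact extent of the unassigned stretch is pictorial in the source
material; the band-path rule is this package's concrete reading.

## SUB–CA1 border position (border module)

The medial anchor is found by taking the most medial CA3-or-DG voxel
(whichever subfield reaches further medially) and marching straight down
from the most inferior such voxel until SUB or CA1 is hit; if nothing is
hit inferiorly a superior march is attempted with a warning (folded
geometry). The border line is vertical through the *mean* x of the CA1
voxels 8-adjacent to SUB — the "midpoint, if at an angle" — with mean
rather than median so the estimator moves continuously under voxel jitter.
Widths use a voxel-edge convention laterally (lateral edge at max x + 0.5
voxel), applied to both references so the ratio is insensitive to the
convention to first order; whether the manual width was centre-to-centre
or edge-to-edge is unstated, and the difference is bounded by one voxel.
Relative position is signed: a border medial of the anchor is negative,
which real cohorts do produce at the 20 mm level.

Measurements target one slice posterior to the uncal apex ("0 mm") and
20 mm posterior to the apex, searching alternately ±1, ±2, … slices within
±3 mm when the target slice is unusable, and reporting the offset absent
beyond that — the same inclusion window used when measuring real cases
with patchy coverage.

## Digitations (digitations module)

Digitation counting operationalizes a visual judgement, so every threshold
is an explicit constant in `digitation_config()`: superior-surface profile
`y_top(x)` over the grey-matter footprint, 3-column moving-average
smoothing, peaks with prominence ≥ 2 voxels (a flat surface counts as one
digitation). CA3's relation to the digitations uses the fraction of CA3
superior-strip columns within a quarter of the median peak spacing of a
peak: ≥ 70 % `on_top`, ≤ 30 % `in_between`, otherwise `both`. Position
(medial/midpoint/lateral) is the area-weighted CA3 centroid against thirds
of the footprint extent. The defaults classify constructed slices with
bumps ≥ 3× the prominence threshold at 100 % accuracy; they are
deliberately tunable because the underlying category boundaries are a
judgement call, not an estimate.

The slice analyzed is the most anterior one where CA3 enters the superior
CA strip (strictly above the DG/SRLM roof in its own or an adjacent
column); a flag allows profiling any other slice.

## Statistics (cohort_pipeline module)

The cohort layer reproduces the analysis design used with such cohorts:
Mann–Whitney U for dementia status (all cases) and sex (non-dementia cases
only), Spearman rank correlations for age, fixation time and postmortem
interval (non-dementia cases only), with Benjamini–Hochberg FDR control
applied *within* each analysis family — one family per length measure
(head, total, ratio) and one per border offset × reference width — at a
0.05 significance level on adjusted p-values.

`mann_whitney_u()` reports `U = min(U_a, U_b)` from midranks. The exact
two-sided p is the fraction of all `choose(n_a+n_b, n_a)` group labelings
whose folded statistic is at most the observed one; the min() folding
already counts both tails, which reproduces the standard exact two-sided
p (verified against `wilcox.test` on tie-free data). `auto` switches to a
normal approximation with tie and continuity correction above 16 total
observations; its null rejection rate at 13 + 13 sits near 0.043.
`spearman_rho()` uses exact permutation enumeration up to n = 8 and the t
approximation beyond. `benjamini_hochberg()` delegates to
`stats::p.adjust(method = "BH")`; tests verify it against the step-up
formula directly. Missing covariates drop a case from the affected test
only, with per-cell n reported; tests with fewer than two observations per
group (or three pairs) are reported as skipped rather than silently
omitted.

## The phantom

`phantom_spec()`/`phantom_generate()` build a hippocampus-like label
volume with exhaustively known ground truth. The cross-section is a
concentric construction: a DG disc, an SRLM annulus around it, a C-shaped
CA ribbon partitioned by angle (CA1 lateral → CA2 superior → CA3 medial,
opening inferiorly), and an inferior plate carrying PaS | PrS | SUB
medially and continuing laterally as CA1, so the SUB–CA1 border is a
vertical interface at a known column that can ramp medially with z. Head
slices flatten the superior ring surface onto a base and add sinusoidal
digitation bumps. Defaults: 120 × 120 × 250 voxels at 0.2 mm (a ~43 mm
specimen with a 16.8 mm head, ratio 39 %); subfield extents echo the mean
appearance/disappearance distances reported for histology-annotated
cohorts (CA1 2.0 mm after SUB, DG 3.6 mm later, then CA3, then CA2;
PaS ~16.4 mm long; border ramp from 25 % of the full width at 0 mm toward
slightly negative posteriorly); subicular splits default to the reported
overall composition means (≈46/39/15 %).

Noise channels — per-slice dropout (coverage gaps) and boundary jitter —
are applied *after* ground truth is computed, so recovery under noise
quantifies robustness rather than redefining truth. Identical spec and
seed give bit-identical volumes.

What the phantom does **not** emulate: uncal substructure (the apex exists
only as a landmark plane), tail curvature (no re-slicing along the axis),
cortical thickness variation, partial-volume mixtures, and rater
disagreement. Passing recovery tests therefore demonstrates that the
measurement operations are correct on their own geometric terms, not that
they absorb every pathology of real histology-derived maps; the coverage
and jitter channels probe the two failure modes the real data are known
for (missing sections, wobbly borders).

Sector phantoms (`sector_phantom_spec()`) place the SRLM and CA sectors on
an arc in the lateral half-plane so the expected projection proportions
are exactly the angular fractions — the oracle for the projection module.

## Problem sizes and numerical tolerances in the test suite

The recovery suites run 100 random zero-noise phantoms for extents
(recovered exactly), 50 for subicular splits (mean absolute error
≈ 0.3 percentage points, tolerance ±3), 50 random sector phantoms for
projection (MAE ≈ 0.014, tolerance 0.03), and 100 ramp phantoms for the
border (recovered to machine precision, tolerance ±2 points); statistics
oracles enumerate all labelings up to n = 10 and all permutations up to
n = 8, and 1,000 simulated null cohorts bound the Mann–Whitney stage's
type-I error within [0.035, 0.065]. Random phantoms use 100–120² × 200–240
volumes, the same order as the default, keeping the full suite under a few
minutes on one core.

## Known limitations

* The skeleton centerline approximates curvilinear length; its residual
  bias (~3 % on tight arcs) is inherent to the digitized-path estimator
  and is characterized, not corrected.
* Digitations are counted on a single smoothed height profile; deeply
  folded heads where the superior surface is not a function of x would
  need a mesh-based definition.
* The statistics layer intentionally implements only the nonparametric
  design above — no mixed models, no survival analysis, no multi-protocol
  harmonization beyond a dataset-id column.
* Printed cohort statistics from real specimens depend on per-case values
  in supplementary material and on manual landmarking; the package
  reproduces the *procedures* and validates them on phantoms rather than
  attempting to reproduce those cell values.
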