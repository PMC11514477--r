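---
title: "Quantifying inactive-X replication dynamics with xirep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inactive-X replication dynamics with xirep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xirep)
```

## The measurement problem

The inactive X chromosome (Xi) replicates as a synchronous burst in
mid-S phase: for roughly 80 minutes, essentially all replication signal
in the nucleus concentrates on the H3K27me3/macroH2A-marked Barr body.
Dissecting how macroH2A1 controls this burst requires a battery of
image-derived quantities — how many origins fire at once (nano-scale
replication foci per Xi), how fast forks move (nucleotide analogue
incorporation per active replisome), how much licensed helicase the Xi
carries in G1 (loading coefficients), how its chromatin loops change
(DNA-halo radius), and how long the pattern persists in live cells.
`xirep` implements each of these as a small, testable measurement with
explicit conventions, plus a synthetic-microscopy generator that plants
known effect sizes so that every pipeline stage can be validated
against ground truth.

## Data containers

Images are `voxel_image` objects: a named list of co-registered
channel arrays (`dim = c(ny, nx, nz)`; 2D means `nz = 1`) with a
physical voxel size in micrometres, `(z, y, x)` ordered. Regions are
`region_mask` objects whose physical size is always the true-voxel
count times the voxel volume — exactly, with no smoothing or contour
interpolation. Everything tabular — per-cell measurements, curves,
peak tables, growth series — flows as tibbles, so pipelines compose
with the pipe and summarise with dplyr; results with structure
(loading curves, cV curves, line profiles, reports, comparisons) carry
S3 classes with `autoplot()` and `tidy()`/`glance()` methods.

## Segmentation conventions

Thresholds use the **triangle method** on a 256-bin histogram: a line
is drawn from the histogram peak to the far tail and the threshold is
the bin with maximal perpendicular distance to it. The histogram is
always computed on the full stack (or the full masked region), never
per slice, because the downstream masks are applied across the whole
Z-stack. A constant region has no histogram geometry and raises an
error rather than returning a silently full or empty mask;
`segment_xi()` interprets that degenerate case as "homogeneous
H3K27me3" and returns no Xi (such cells are excluded from Xi
analyses).

Connectivity is 26-neighbourhood in 3D (8 in 2D) throughout.
Nucleus segmentation fills interior holes and splits connected
components; components below 50 µm³ are dropped and components above
400 µm³ — the signature of two touching nuclei merged into one blob —
are kept but flagged `needs_review` with a warning, never silently
merged or split. Xi segmentation thresholds H3K27me3 *within* the
nucleus and the number of supra-threshold clusters above 0.5 µm³ is the
Xi copy number. Neither minimum volume has a canonical published
value; both defaults are set an order of magnitude below the
structures they guard and are user-configurable.

The **control ROI** (ROI2) used by loading coefficients must match the
Xi region in voxel count, lie fully inside the nucleus, and avoid both
the Xi and the bright constitutive-heterochromatin chromocenters. A
rigid translation of the Xi mask cannot satisfy this when the "Xi
region" is the union of two territories on opposite sides of the
nucleus, so `control_roi()` instead grows a compact blob — the
Xi-count nearest admissible voxels around a seeded random centre. The
voxel-count match is exact and placement is reproducible by seed. When
no chromocenter mask is available, the top 2% DAPI intensities inside
the nucleus stand in for the condensed heterochromatin to exclude.

G1 gating keeps EdU-negative cells whose DAPI sum falls within ±15% of
the lowest mode of the population's DAPI-sum density — the 2C peak.
The half-width is a convention, not a published value; it requires at
least 10 cells before a mode is trusted.

S-phase **pattern classification** is a rule-based stand-in for visual
scoring: no supra-background focal signal → `non_S`; at least 40% of
the focal signal inside the Xi → `mid_xi`; focal signal concentrated
in chromocenters → `late`; otherwise `early`. The thresholds have no
published values (the original scoring was manual), so classifier
accuracy on labelled synthetic populations is a measured quantity in
the test suite, not a guarantee about real data.

## Foci picking

`pick_foci_3d()` follows the local-maximum semantics of interactive 3D
spot pickers. A *maximum centre* is one voxel or a contiguous
equal-intensity plateau brighter than all of its 26-neighbours. The
implementation floods voxels in descending intensity order: a voxel
with no labelled neighbour opens a new peak; a voxel joining two peaks
marks the (highest) saddle of the lower one, and if that peak's
intensity range above the saddle is below the **tolerance** it merges
into its higher neighbour — otherwise both survive and the watershed
boundary separates their basins. Plateaus resolve naturally (fragments
merge at zero prominence), so each focus corresponds to exactly one
maximum centre; the centre of a plateau is the voxel nearest the
plateau centroid, ties broken lexicographically in (z, y, x). Region
growing stops at the surrounding minima or at the **background**
level; the brightest **fraction f** percent of each basin is kept as
the focus body, and foci with fewer than the minimum voxel count are
dropped. `count_nano_rfi()` then counts foci whose centre lies in the
Xi mask and whose volume is at least 0.0002 µm³ (the published
exclusion for unspecific background), applied after touching-foci
separation. Default parameters — background from the triangle
threshold inside the search mask, tolerance 10% of the in-mask dynamic
range, fraction f = 50 — are declared conventions: the original
plugin's parameter names are published but its values are not.

Voxel anisotropy is respected when converting voxel counts to µm³;
neighbourhoods remain voxel-topological. The detector's count is
checked in the test suite against an exhaustive oracle that enumerates
every voxel and tests plateau-maximality against all 26 neighbours,
and is invariant under affine intensity maps when background and
tolerance are rescaled accordingly.

PLA spots are counted on the **maximum-intensity projection**: 2D
local maxima inside the nucleus whose topographic prominence exceeds
the threshold (the assays used "> 40"), excluding maxima whose summit
touches the frame border. A summit never challenged by a higher peak
gets its height above the in-mask minimum as prominence, so a
threshold above every spot's height correctly yields zero.

## Intensity metrics

Two projection conventions coexist, matching the underlying
workflows: EdU/PCNA ratios and histone/protein levels use **3D sum
intensities** over the stack; PLA densities, loading coefficients and
the Xi relative area operate on **maximum-intensity projections**.
Each function documents its convention; `loading_coefficient()`
projects internally, and the intended workflow places ROI2 on the
projected masks (placing a 3D ROI and projecting afterwards would let
its shadow overlap the Xi's shadow).

The loading coefficient is
`[S(target, ROI1)/S(DAPI, ROI1)] / [S(target, ROI2)/S(DAPI, ROI2)]`
on the projection; it equals 1 identically on uniform fields for any
admissible ROI2 (a property the tests assert over 1000 seeded
placements). G1 curves normalise per-(condition, time) means by the
control mean at the first time point. Control normalisation throughout
uses the pooled control mean; per-cell values and medians are kept so
robust summaries remain available. The coefficient of variation uses
the population standard deviation (divisor *n*; configurable), and
`cv_norm` divides by the pretreatment frame, so `cv_norm[1] = 1` by
construction — an all-constant pretreatment frame makes the
normalisation undefined and is reported as such.

## DNA halo, FISH profiles and morphometry

`measure_halo()` segments the total area (scaffold + halo) above an
estimated background (border mean + 3 SD) and the scaffold by a
triangle threshold *restricted to the foreground pixels*: on the raw
three-level image (background, halo, scaffold) the triangle geometry
would place the cut between background and halo, but within the
foreground the halo and scaffold are the two populations and the split
lands between them. Both thresholds are overridable, and a manual
scaffold threshold below the total threshold is rejected as
inconsistent. Halo area, radius and circularity follow
`Ah = At − As`, `R = sqrt(Ah/pi)` and `4πA/P²`; the perimeter is the
4-direction Cauchy–Crofton estimate `(π/8)(n0 + n90 + (n45+n135)/√2)`
from boundary-crossing counts, which keeps digitised circles within
0.02 of circularity 1. Values above 1 (digitisation overshoot) are
clamped, with the raw value retained.

FISH line profiles cast rays outward from evenly spaced scaffold
boundary points, directed from the scaffold centroid through the
boundary point — effectively the outward normal for the near-convex
scaffolds produced here. Averaging 36 rays per cell replaces the
original one-manual-line-per-cell protocol; this is a deliberate
deviation for reproducibility. Profiles are max-normalised per cell,
distance 0 is the scaffold border, and background comes from seeded
random rays through off-cell areas. Rays leaving the image are
truncated with a warning.

Hypotonic 3D morphometrics report the equivalent-sphere diameter from
the voxel volume, the bounding z extent, the mean lateral (XY)
bounding extent, and the surface area via a smoothed-gradient coarea
estimator: the mask indicator is smoothed with an isotropic (in
physical units) Gaussian of σ = 1.2× the largest voxel dimension and
`Σ|∇|·voxel volume` integrates to the surface area. On a digitised
5 µm-radius sphere this lands within a few percent of `4πr²`. The
equivalent-sphere diameter is volume-preserving by construction, so
the flattening signature of hypotonically spread nuclei is carried by
the lateral extent (larger) and z extent (smaller), not by the
equivalent diameter. Nuclear roundness is `4A/(π·major²)` with the
major axis from second central moments (including the pixel
self-moment), giving 1 for circles and b/a for ellipses; line-like
masks are rejected as degenerate.

## Dynamics and the fork-speed model

Live-imaging sequences are per-frame labels; Xi-pattern persistence is
the length of the single contiguous `xi_pattern` run times the frame
interval, onset is the lag from the first S frame. Multiple disjoint
runs raise an error (reported, never merged), and runs touching the
first or last frame are flagged censored and excluded from cohort
means by default — whether the published means excluded censored runs
is unstated, so the choice is explicit and reversible.

Doubling time inverts the printed growth-rate formula: `log2(nx/n0)/t`
is dimensionally a rate (doublings per hour), and the quantity named
"doubling time" is its reciprocal; both are returned. S-phase duration
multiplies the doubling time by the S-phase cell fraction.

The fork-speed model is pure arithmetic:
`v = L / (T × N × (2 if bidirectional) × waves)` nucleotides per
minute per fork. With the mouse X (171.03 Mb), 80 min and 138
bidirectional origins this gives 7.75×10³ nt/min — printed to two
significant figures elsewhere as ≈ 7.7–7.8×10³. Whether the Xi fires
its origins in one or in two-to-three consecutive waves is left open
by the data; `waves` is an explicit model parameter (speed scales as
1/waves) and no value is asserted. The compensation index
`(n_kd/n_ctrl) × relative speed` summarises whether origin loss and
fork acceleration cancel: values near 1 are duration-neutral.

## Genomics and reporting

Peak densities are peaks per megabase per chromosome, optionally
normalised by the total peak count so that `Σ density × Mb = 1`
exactly. BED intervals are 0-based half-open; reproducible peaks are
the joint intersections across peak sets (GenomicRanges behind the
module surface), kept when the overlap spans the minimum width —
zero-length touching never counts. The minimum overlap defaults to
1 bp (the published criterion is unstated) and is configurable.

Group comparisons default to the **unpaired** Wilcoxon rank-sum form:
although the figures cite a "paired two-sample Wilcoxon test", the
reported group sizes differ across conditions, and pairing is
undefined for unequal n; a paired option exists for genuinely paired
designs. P-values are exact for combined n ≤ 25 without ties and
normal-approximated with continuity/tie correction otherwise. Star
bands follow the printed convention: `*` for p in [0.005, 0.05), `**`
for [0.0005, 0.005), `***` below 0.0005, `n.s.` at or above 0.05 —
asserted at the boundary values in the tests. Reports carry N, mean,
SD, SEM and 95% CI per (metric, condition), all from the same sample.

## The synthetic generator: what it emulates and what it does not

`make_nucleus_image()` renders ellipsoidal nuclei (default ~10 µm
diameter, flattened to 5 µm in z) with uniform DAPI, bright
chromocenters, and one or two Xi territories (~3–4 µm across,
elevated H3K27me3) — two Xi per nucleus by default, matching the
tetraploid-like karyotype where ~95% of cells show two Barr bodies.
The published foci means are treated as per-Xi counts (the counting
was performed within the Xi ROI). Default sampling mirrors the
confocal settings (50 nm pixels, 290 nm z-step); the cohort analyses
in the tests and the acceptance script run at 100 nm lateral sampling,
a problem-size choice that leaves every ratio metric unchanged.

Replication foci are Gaussian spots. The rendered point-spread
function is anisotropic — lateral σ of two pixels, axial σ no smaller
than one z-step — because any microscope's axial PSF is wider than its
lateral one; rendering isotropic 0.1 µm spots onto 290 nm z-steps
would make axially separated spots indistinguishable (no sampled
intensity dip between them). `make_xi_volume()`, the substrate for
nano-foci counting, therefore defaults to super-resolution-style
sampling (40 nm / 125 nm), the regime in which the real nanoRFi were
resolved, and places foci on a jittered lattice whose spacing
guarantees a 4σ minimum separation in PSF-normalised coordinates; a
`crowded` flag drops the constraint to stress the separator, and
requesting more foci than the lattice capacity is an error rather than
a silent constraint violation. In full nucleus fields (confocal
sampling) the Xi foci are placed *without* the spacing constraint:
mid-S nano-foci are below confocal resolution — the very reason the
original counting needed 3D-SIM — and in those fields they serve
pattern and sum emulation, not counting.

Per-cell foci counts are Poisson around the preset mean unless
`fixed_counts` pins them, which makes exact worked examples possible.
EdU is a fixed fraction of PCNA voxel-wise, multiplied by the preset's
progression factor inside the Xi, so the planted Xi EdU/PCNA ratio is
exact by construction before noise; S-phase nuclei also carry a
diffuse replisome pool. PLA spots are planted with the Xi fold
defined in spots-per-DAPI units (the same units the measurement uses),
with a minimum projected separation so spots remain countable.
Intensities are arbitrary 16-bit-style counts — all pipeline metrics
are ratios — and noise is Poisson (gain 1) by default, with Gaussian
and noise-free options.

Two desk-scale distortions matter for interpretation. First, the
synthetic Xi occupies a far larger fraction of the nucleus (~20% of
the replication signal) than a real Xi does (a few percent), so the
*whole-nucleus* EdU/PCNA ratio of a knockdown rises measurably with
the Xi ratio; the faithful statement of "nuclear progression is
unchanged" is that the ratio *outside the Xi* stays at 1, and that is
what the acceptance suite asserts. Second, the generator does not
model optics beyond Gaussian spots — no SIM reconstruction artifacts,
photobleaching, or condition-dependent nuclear shape — so passing
tests demonstrate that the measurements recover what was planted under
controlled noise, not that they are robust to every pathology of real
microscopy.

## Problem sizes and numerical choices

The test suite and acceptance script use cohort sizes chosen as the
package's own desk-scale study conditions: 20 Xi volumes per condition
for nano-foci recovery (fixed planted counts 138/140/95, Poisson
noise, 3% tolerance), 25 cells per G1 time point for the
loading-coefficient trajectory (5% tolerance on the 4.44/2.77
endpoints), 100 nuclei per condition for PLA means (±1 spot), 50 cells
for the Xi density fold (±0.2), 50 cells per condition for the
EdU/PCNA increases (±3 percentage points) and 30 per condition for the
Mcm2-phosphoS108 reduction (±3 points). Determinism is strict:
identical parameters and seed give bit-identical images, labels and
placements (verified by test), and every stochastic step takes an
explicit seed.

Degenerate inputs fail loudly by design: constant histograms, empty
masks, zero denominators (PCNA, DAPI, control means), non-growing
growth series, missing normalisation anchors, undersized G1
populations, impossible ROI placements and self-intersecting halo
boundaries all raise informative errors rather than producing
plausible numbers.

## Known limitations

* The pattern classifier's thresholds are conventions standing in for
  manual scoring; its measured accuracy applies to the synthetic
  mixtures it was tested on.
* The generator's condition presets cover the effect sizes the
  pipeline measures; effects it does not model (nuclear roundness
  changes, photobleaching, chromatin texture beyond chromocenters)
  cannot be recovered from it.
* Halo scaffold/total segmentation uses a declared two-threshold
  scheme; the original thresholding protocol is not published in
  enough detail to reconstruct.
* Fork-speed estimates inherit every assumption of the arithmetic
  model: constant fork speed, simultaneous origin activity within a
  wave, and full bidirectionality.
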