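---
title: "Methods: quantitative 3D islet mapping across tissue cuboids"
author: "isletmapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative 3D islet mapping across tissue cuboids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmapper)
```

## The problem

Antibody penetration limits whole-mount immunolabelling to cm-scale
tissue blocks, so a human organ is mapped by cutting it on a printed
slicing matrix into cuboids, labelling and imaging each cuboid by
mesoscopic optical tomography (isotropic voxels, about 21 µm at the
zoom used for pancreas), and stitching the per-cuboid results back into
one organ frame. For the endocrine pancreas this yields, for every
islet of Langerhans, its 3D position, volume, axis lengths and shape —
data that stereology can only extrapolate from sections. `isletmapper`
implements the computational half of that pipeline: contrast
conditioning, islet segmentation and spot detection, 3D morphometry,
autofluorescence-based anatomy extraction, islet density and
size-category statistics, spatial clustering, and catalog stitching,
plus a synthetic phantom generator that provides exact ground truth for
every stage.

## Data model

A `VoxelGrid` is one channel of one cuboid: a 3D array in (x, y, z)
order with an isotropic voxel size in µm and the physical origin of the
cuboid corner. Voxel `(i, j, k)` (1-based) has its centre at
`origin + (c(i, j, k) - 0.5) * voxelSize`. A `LabelVolume` carries
integer object labels (0 = background, contiguous 1..K). A `CuboidMeta`
records a cuboid's slicing-grid index, grid pitch and physical offset;
the default lateral pitch of 5500 × 3300 µm matches a
0.55 cm × 0.33 cm slicing matrix, and the third component is the z
block height for cuboids cut in two to fit the scanner. All exported
coordinates are physical (x, y, z) µm relative to the cuboid (local) or
organ (global) corner.

## Enhancement

Reconstructed volumes are conditioned per z-slice: min–max display
rescaling, contrast limited adaptive histogram equalization (CLAHE)
with 32 px tiles for the immunolabel channel and 16 px tiles for the
anatomy channel, and, for the immunolabel channel, fusion of low-,
middle- and high-range clipped/stretched copies. The historical
pipeline applies these operators to projection images before
tomographic reconstruction; reconstruction is out of scope here, so the
same operators are applied to the slices of reconstructed volumes —
same algorithms, different domain, which matters only in so far as the
noise statistics differ. Two choices are not reported anywhere and are
therefore package parameters: the CLAHE clip limit (default 0.01 of the
tile pixel count, a conservative standard value) and the fusion
combiner (pixelwise arithmetic mean of the three stretched copies — the
simplest monotone fusion; the windows are configurable). CLAHE here
partitions each slice into tiles of the stated pixel size (the trailing
tile absorbs any remainder), clips each tile histogram with uniform
redistribution of the excess, and maps pixels through bilinear
interpolation of the neighbouring tile CDFs; a two-tile configuration
reproduces a hand-computed histogram-equalization-plus-blend oracle
exactly, which is how the implementation is tested.

## Segmentation

Islets are iso-surfaced by thresholding the enhanced, baseline-
subtracted immunolabel channel. Thresholds in the original workflow
were set manually per sample and are not published; the default here is
Otsu's threshold computed over the nonzero voxels, with a manual
override. Touching islets are split by a seeded watershed on the
Euclidean distance transform: candidate seeds are distance-transform
maxima; they are accepted greedily (highest first, ties broken by
lexicographic voxel index) subject to a minimum separation equal to the
region-growing seed diameter of 110 µm — the mean 3D diameter of the
average human islet — less half a voxel of lattice-quantization slack.
Separation is enforced only within a connected component, so every
component keeps at least one seed and well-separated islets can never
lose theirs to a neighbour. Objects under 5 voxels are removed
(voxel count is authoritative; at 21 µm voxels this corresponds to
46.3 × 10³ µm³).

Spot detection is scale-matched Laplacian-of-Gaussian blob detection at
σ = d/(2√3) for the expected diameter d = 110 µm. The "quality" of a
spot is defined constructively (the commercial definition is
undocumented): the scale-normalized negative-Laplacian response divided
by the response an ideal isolated Gaussian blob of the expected
diameter and unit contrast would produce, so quality ≈ the blob's
contrast, and the default cutoff of 1 keeps spots at least as strong as
a unit-contrast matched blob. Two pruning rules keep one spot per
object: maxima closer than 1.3 expected diameters are merged (a solid
blob larger than the matched scale produces a ring of maxima whose
antipodal spacing stays below that bound up to roughly 1.8× the
expected diameter), and of two maxima with no intervening response
valley — the response along the joining segment never dropping below
70% of the lower maximum — only the higher survives. On the default
phantom population this keeps spot counts within a few percent of the
segmentation count; islets beyond roughly twice the expected diameter
are the residual failure mode of any single-scale detector.

The tissue mask smooths the anatomy channel with a 15 µm Gaussian and
thresholds it (Otsu by default, manual override), keeping the largest
component plus any component of at least 5 voxels. The specimen
outline, drawn manually in the original workflow, is automated as a
morphological closing with a Euclidean ball of 10 voxels (computed via
two distance transforms on a padded grid) followed by per-slice hole
filling; the closure provably contains the tissue mask. Hypointense
regions (vessel and duct lumens, fat) are the exact set difference
`outline & !tissue` — the partition identities
`hypointense ∪ tissue = outline` and `hypointense ∩ tissue = ∅` hold
voxel-exactly — with components of at least 5 voxels labelled and
classified by Wadell sphericity: spherical (fat-like) at ≥ 0.7, tubular
(lumen-like) at ≤ 0.5. The tubular cutoff is deliberately 0.5 rather
than a smaller value because long thin cylinders score higher on the
Wadell scale than intuition suggests (a 40:1 cylinder scores about
0.47). Intra-islet hemorrhage is the anatomy channel masked onto the
islet labels and thresholded; red-blood-cell autofluorescence inside an
islet is summed as that islet's hemorrhage volume, and voxels outside
islets are never counted.

## Morphometry

Volume is voxel count × voxel volume, exactly. Axis lengths are
world-axis-aligned ellipsoid-equivalent lengths, `2·sqrt(5·var)` of the
voxel-centre coordinates along each axis (a solid ellipsoid of semi-axis
a has coordinate variance a²/5), and the mean 3D diameter is the mean
of the three axis lengths — the x/y/z convention is used rather than
PCA principal lengths because downstream statistics average axis
lengths along the world axes. Surface area is the area of the 0.5-level
isosurface of the object's binary mask after resampling onto the
voxel-corner lattice with an 8-voxel box mean, triangulated by marching
tetrahedra with linear interpolation; the corner resampling removes
most of the staircase bias of meshing raw binary data (digitized
spheres of radius 5–20 voxels land within ~2–3% of 4πr², and a 4:1
prolate ellipsoid within ~1% of its analytic area) while keeping flat
faces in place. Objects too small to reach the 0.5 level on the corner
lattice fall back to meshing the raw binary field. Consequences worth
knowing: sphericity of the smallest objects is biased high — digitized
balls of radius ~2.5–3 voxels (objects around 100 voxels) can reach
1.09–1.12, and the nominal ≤ 1.05 discretization band holds only for
objects upward of roughly 250 voxels; and for ~3-voxel objects the
variance-based axis lengths carry a ±10% discretization error that
averages out over a population.

## Quantification

Islets are binned into size categories with left-open, right-closed
intervals — exactly the semantics of the interval-cut routine used for
the published distributions — over either the fourteen doubling volume
edges (0 to 1.024 × 10⁸ µm³) or the eleven diameter edges (0 to
328.4 µm). A value of 0 or above the last edge has no category; rather
than dropping over-range islets silently, density reports carry them in
an explicit overflow row (a strict mode reproduces the plain drop).
Densities are normalized in two modes, always both: against the outline
volume (the full specimen envelope, including non-tissue-filled
regions — the mode used for cross-species comparisons) and against the
tissue volume (envelope minus hypointense regions). Sphericity
summaries group by the size categories or by a single volume split,
default 9 × 10⁶ µm³, the threshold above which shape differences
between diabetic and non-diabetic islets are of interest.

## Clustering

Islet centroids are clustered by single linkage with a 300 µm cutoff:
labels are the connected components of the graph joining every pair of
centroids within 300 µm (for this rule a threshold graph and a
dendrogram cut are the same partition; the implementation uses graph
components, and the test oracle is an independent union-find).
Distances are centroid-to-centroid. A cluster with strictly more than
100 members is a high islet density region (HIDR), anything else a
LIDR; `hidrFraction` reports the fraction of all islets contributed by
HIDRs. ROI comparison places cubes of 48 voxels (1.008 mm at
21 µm/voxel, volume 1.024 mm³) on HIDR centroids and at seeded random
positions inside the cuboid, counts islets by centroid inclusion, and
normalizes by ROI volume; out-of-bounds ROIs are clipped with the
volume adjusted. The default of 10 random ROIs mirrors the scale of a
ten-cuboid comparison; it is a sampling parameter, not a calibrated
value.

## Stitching

Placement is metadata-driven: a cuboid's catalog is mapped to organ
coordinates by adding its physical origin (grid index × pitch), and
volumes are pasted at voxel-aligned offsets with overlap treated as an
error. No image registration is attempted — the original workflow
aligned cuboids manually on vascular continuity, and for phantoms the
cuts are ideal, so grid arithmetic is exact; a registration refinement
is deliberately out of scope. Objects cut by a slicing plane appear in
each adjacent cuboid flagged by face contact. By default they stay
separate records (matching the published analysis); with
`merge_boundary = TRUE`, records in face-adjacent cuboids that touch
the shared face with lateral centroid offset ≤ 55 µm are merged —
volumes summed, centroids volume-weighted, axis lengths recombined by
the parallel-axis rule (exact for the variance definition above);
surface area and sphericity are not recombinable from parts and become
NA on merged records.

## The phantom generator

Every stage is validated against synthetic cuboids and multi-cuboid
organs with exact ground truth. The generator emulates: ellipsoidal
islets with log-normal mean 3D diameters (median 110 µm, geometric SD
1.35, truncated to 63–250 µm — below 3 voxels an object is
unresolvable at 21 µm; above 250 µm placement becomes impractical at
realistic densities), bounded anisotropy (axis ratio ≤ 1.5), a textured
tissue block or organ ellipsoid in the autofluorescence channel, bright
vessel tubes, dark spherical and tubular holes carved from both
channels, red-blood-cell blobs inside a configurable fraction of
islets, spatial islet clusters built by sequential attachment so that
nearest-neighbour spacing stays within the cluster's linkage distance,
and organ-level slicing into abutting cuboids with per-part truncation
bookkeeping. Rasterization is voxel-centre-in-solid with max-combine —
the simplest rule with a provable volume bound; rasterized volumes of
objects with ≥ 100 voxels track the analytic ellipsoid volume within
15%, but small objects deviate more (an 88-voxel sphere can be +17%),
which is a property of any centre-sampling rule at 2–3 voxel radii.
Placement is rejection sampling with a hard cap of 10 000 retries and a
2-voxel surface gap — deterministic failure rather than silent overlap.
Clusters keep a 350 µm default clearance from background islets so the
planted cluster structure is exactly recoverable at the 300 µm cutoff.
Peripheral clusters (organ mode) seed at ≥ 80% normalized organ radius,
emulating surface-proximal islet clusters without claiming biological
fidelity. Noise is additive Gaussian clipped at zero; the channels'
contrast levels are free parameters because no intensity statistics for
human pancreas autofluorescence are published. The default islet
contrast of ~2 over background is an analytic calibration: it places
the quality-1 spot cutoff so the detectable band of the matched-scale
response (roughly 65–220 µm solid spheres) covers the diameter
population.

What passing phantom tests does and does not show: the phantom has
sharp object boundaries, no point-spread blur, no reconstruction
artifacts, spatially white noise and known contrast, so recovery there
demonstrates the correctness of the algorithms (splitting, measurement,
bookkeeping, stitching), not robustness to the optical and
reconstruction imperfections of real tomography data, where manual
thresholds and visual QC remain necessary.

## Problem sizes and determinism

The validation suite runs single-threaded on modest phantoms: one
256³-voxel cuboid with 200 islets for segmentation/spot recovery,
64³-voxel cuboids in a 2×2×2 organ for stitching, 500-point patterns
for the clustering oracle, and point-pattern (non-rendered) phantoms
for cluster statistics — the generator's truth-only mode produces
geometry bit-identical to the rendered one for the same seed. All
stochastic steps are seeded: identical seeds give bit-identical
phantoms, segmentations and reports. `scripts/acceptance.R` re-derives
the package's operating points and recovery rates from scratch under a
caller-supplied seed.

## Known limitations

- Auto-thresholding (Otsu) stands in for per-sample manual thresholds;
  reports should state which was used.
- Single-scale spot detection under- or over-counts objects far from
  the 110 µm design scale (see Segmentation).
- Surface-area and sphericity estimates are biased for objects under a
  few hundred voxels (see Morphometry).
- Stitching assumes ideal cuts; real cutting deformation is not
  corrected.
- The generator does not simulate projection acquisition, PSF blur or
  refraction artifacts.
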