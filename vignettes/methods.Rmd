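---
title: "Registering stereocilia and quantifying immunogold label: models and choices"
author: "goldBundle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering stereocilia and quantifying immunogold label}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldBundle)
```

## The problem and the data model

Immunogold EM localizes a protein as discrete 10-nm gold beads near the
epitope. In a FIB-SEM volume of a hair bundle, segmentation yields two
label fields: towers (each stereocilium or kinocilium as one integer
material, 0 = background) and a gold mask. Because every stereocilium has
its own position and orientation — and because the biologically meaningful
circumferential reference is the mechanosensitive (MET) axis of its column,
not the microscope frame — bead positions are only comparable after each
tower is registered to a common template. The pipeline's job is that
registration and the subsequent counting.

Assumptions the model makes:

* towers are near-cylindrical and elongated, so a PCA leading eigenvector
  is a meaningful axis and a (height, radius) pair is a fair summary;
* tower bases stand on a (roughly) common plane — this is what disambiguates
  up from down;
* the MET direction of a column is adequately captured by the line through
  the column's tower centroids in the horizontal plane, oriented from the
  short row toward the kinocilium row (tip links themselves are not resolved
  in these volumes);
* beads sit close to the surface of the cilium they label, so a
  nearest-surface rule assigns them correctly.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `resizeFactor` | 1/4 | — | xy downscaling of the tower volume before geometry; nearest-neighbour, voxel size rescaled so physical coordinates are unchanged |
| `borderSamplingFactor` | 1/10 | — | fraction of border voxels sampled per tower; all geometry runs on the samples |
| `gold2towerAssociationMethod` | NN | — | k-NN vote over border samples, or DT (distance transform over the label volume) |
| `nNearestNeighbors` | 10 | — | k for the NN vote |
| `minDistThr` | 100 | µm | bead exclusion distance; at bundle scale (a few µm) it never triggers, i.e. exclusion is off unless deliberately lowered |
| `meanshiftBandwidth` | 0.3 | rad | Gaussian angular kernel width for mode seeking on the sphere; ~17°, wide enough to pool per-tower axis scatter, far narrower than the 180° separating the two sign clusters |
| `nHtBins` | 5 | — | histogram height bins; the last bin is the above-tip volume |
| `nAzBins` | 4 | — | azimuth sectors (anterior, posterior, two lateral) |
| `segmentTargetHeight` | 0.2 | µm | target segment height for the density analysis; the per-row segment count is `round(H / 0.2)`, half away from zero, minimum 1 |

The bead distance threshold and the resize factor are the two parameters a
user is most likely to touch: the former to actually exclude stray beads,
the latter to trade geometric resolution against speed (at 1/4 of a
~2.4-nm pixel the working resolution is ~10 nm in xy, comparable to one
bead diameter).

## Numerical choices

* **Upward rule.** The published description of the up/down disambiguation
  can be read two ways: score the *minimum* projections of each tower (the
  bases align to a plane) or the maxima (the "extremities opposite" the
  aligned end). The minima reading is implemented as the default
  (`upwardRule = "minima"`); the alternative is available as
  `upwardRule = "maxima"`. Ties (scores equal within 1e-9, e.g. two
  identical towers) break toward the candidate with the larger mean
  per-tower maximum projection — towers extend upward — then
  lexicographically, so the result is deterministic.
* **Sector indexing.** Sector 1 is *centred* on north with boundaries at
  odd multiples of 180°/nAzBins (for four sectors: ±45° around north), so
  the four sectors read naturally as anterior / lateral / posterior /
  lateral. The edge-aligned alternative (sector 1 starting at north) is
  kept behind `sectorAlignment = "edge"`. Beads exactly on the axis go to
  sector 1 deterministically.
* **Height binning.** Shaft bins partition [0, H] half-open with the top
  edge closed; z > H falls in the above-tip bin, which `foldAboveTip()`
  adds to the tip segment. Beads marginally below the base plane (possible
  after registration of a tilted tower) are clamped into segment 1 and
  counted in the histogram's `clamped` slot with a warning, never dropped —
  count conservation is checked at every stage.
* **Mean shift.** Iteration stops when the spherical displacement is below
  1e-6 rad; exceeding 500 iterations is an error rather than a silent
  truncation. Converged modes within bandwidth/2 of an earlier mode are
  merged. Because PCA eigenvector signs are basis-dependent, the random
  sign flip makes the two antipodal clusters approximately equal; the mode
  centre consequently wobbles by a fraction of the per-tower axis scatter
  between runs in different frames, which is why orientation recovery is
  specified to degrees, not arc-seconds.
* **Degenerate inputs.** All-coincident point clouds fail PCA loudly;
  near-isotropic clouds set an `illConditioned` attribute (second
  eigenvalue within 20% of the first). Columns with fewer than two linked
  towers, or with coincident xy centroids, get no azimuth and their towers
  are excluded from registration (they remain in the tower set and in the
  overview figures, drawn gray). Coplanar hull input falls back to the
  planar 2D hull with a warning.
* **Resize of the gold volume.** The tower volume is resized; the gold
  mask is not. Both frames are physical (µm), so centroids extracted at
  full resolution live in exactly the same coordinate system as the
  resized towers, and voxel-scale beads survive — nearest-neighbour
  downsampling of a label mask deletes most single-voxel objects, and a
  10-nm bead is about one voxel even at the acquisition pixel size once
  resized.
* **Density normalization.** When cells are pooled, the density divides by
  the pooled cilium count (beads per µm² *per cilium* over the cumulative
  data), not per cell; the inversion identity
  `density × segment area × n_cilia = folded counts` holds to machine
  precision and is asserted in the tests.

## What the synthetic generator emulates — and what it does not

`generateBundle()` renders capped cylinders with bases on a common plane,
rows at ranked heights (defaults 2.0 / 1.2 / 0.8 / 0.45 µm, radii ~0.1 µm,
0.45 µm spacing, 8 × 8 × 16 nm voxels), a per-tower axis tilt jitter
(default 3°) so the synthetic towers are not unrealistically parallel, an
optional global rotation applied before voxelization, and Table-style
link/usage files. `placeValidationBeads()` adds exactly one single-voxel
bead per stereocilium in a row-specific pattern — tall row at the tip on
the face away from the middle row, middle row at mid-height on the face
away from the tall row, short row near the base, none on the kinocilium —
with the expected tower and (segment, sector) cell recorded analytically
from the construction. Tip/base placement at 95% / 5% of height and
mid-height at 55% are fixture conventions chosen to sit mid-bin under the
default 4+1 binning.

The generator emulates segmentation *output*, not EM data: no intensity
texture, no segmentation roughness beyond voxelization, no membrane coats,
no bead clustering or chance antibody background, perfectly known row
membership. Passing the validation suite therefore demonstrates that the
geometry, association, registration and binning are correct on data that
satisfy the model's assumptions; it does not certify performance on
imperfect segmentations (partially imaged cilia, touching towers, beads
midway between neighbours), which is exactly what the usage table and the
distance threshold exist to manage on real data.

## Problem sizes

The shipped tests and the acceptance script use bundles of 3–5 columns at
16–24 nm (tests) or 8–16 nm (acceptance validation bundle) voxels — volumes
of roughly 10⁵–10⁷ voxels that run the full pipeline in seconds while
keeping several voxels across each cilium radius after the default 1/4
resize. These sizes are the package's chosen validation conditions;
real cells (multi-GB volumes, hundreds of stereocilia across six cells)
run through the identical code path, only larger.

## Known limitations

* Translation-only slice alignment: the acquisition software's rotational
  component is deliberately out of scope, and sequential MI chaining can
  accumulate drift over long stacks.
* The MET sense (which end of the column line is "ahead") relies on the
  link table's row ordering; if a column lacks both its extreme rows the
  fitted line's orientation rests on the interior rows alone.
* Radius is a mean border distance, which under-reports the true radius on
  coarse grids (border voxel centres sit inside the surface by up to half
  a voxel); heights are similarly quantized by the milling step. Template
  registration cancels most of this within a row, but absolute densities
  inherit a voxel-scale bias.
* The convex hull summarises the registered row surface; it cannot
  represent concavities (e.g. tapered stereocilia necks).
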