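---
title: "Segmenting stacked-microtiter-plate microCT scans with plateCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting stacked-microtiter-plate microCT scans with plateCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateCT)
```

## The problem

Bulk microCT digitisation mounts many discrete specimens — typically
fragmentary skeletal remains destined for destructive sampling — in the
wells of stackable microtiter plates (24-, 48- or 96-well formats) and scans
the whole stack in one volume. The bottleneck is downstream: hundreds of
specimens per scan must be segmented away from the plastic mount, cropped,
meshed, and — critically — exported under their externally assigned IDs
(museum accession numbers, trial codes) without manual file naming.

plateCT is a headless library plus CLI for exactly this. Its inputs are the
reconstructed greyscale volume (a headerless raw file or a folder of TIFF
slices, with a plain-text `.info` sidecar carrying the voxel size), and one
CSV sheet per plate whose grid of cells mirrors the physical well layout.
Its outputs are per-specimen 8-bit TIFF stacks in three modes (raw crop,
binary mask, masked "processed" crop), a PLY surface mesh per specimen in
millimetres, and a manifest tying every file back to its plate, well and ID.

## The segmentation model

CT volumes of plated specimens show a three-peak greyscale histogram: air
near 0, the plastic mount at a low-intermediate level, and the (denser)
specimens well above both. Two effects complicate a naive global threshold:

* **Partial-volume averaging.** Voxels straddling two materials take
  intermediate values, producing a blurred "halo" at object margins; a hard
  threshold erodes surfaces.
* **Noise.** Fast, high-throughput scan protocols accept elevated noise, so
  parts of the mount can leak above a single global threshold.

plateCT therefore segments in three steps:

1. **Cel-shading** (optional): `celShade()` quantises greys downward into
   bins of width $C$, $X_\mathrm{new} = X - (X \bmod C)$. Binning groups the
   mount into few histogram bins, making the cut-off easier to place and
   suppressing noise; it can also erode margins, so it is off by default and
   the base is a user choice. The operation is idempotent and never
   increases a value. Two conventions exist for "how many grey levels
   remain" on a 255-level 8-bit scale: $\lfloor 255 / C \rfloor$ (25 for
   $C = 10$; the count of full bins, and the number conventionally quoted)
   and direct enumeration of distinct outputs over 0..255 (26 for $C = 10$,
   because a partial top bin remains). `celShadeLevels()` exposes both.
2. **Greyscale bracketing**: `bracketThreshold()` keeps exactly the voxels
   inside $[T_\mathrm{lower}, T_\mathrm{upper}]$. The two one-sided
   thresholds deployed together select the specimen peak while excluding
   mount below and bright artefacts above. (One could equally define the
   *outside* of a bracket as foreground; plateCT fixes foreground = inside,
   which is the variant consistent with "specimens are the densest
   material in the bracket".)
3. **Blobbing**: `labelBlobs()` takes maximal 3D connected components of the
   mask and discards components below `minBlobSize` voxels — residual mount
   flecks and noise specks fall below the smallest real specimen.
   Connectivity defaults to 26 so diagonally touching fragments of one bone
   stay one specimen; 6 and 18 are available. Blob ids are assigned in
   raster order (slices, then rows, then columns) of each component's first
   voxel, so outputs are reproducible run to run.

The working volume is a stride-downsampled template (`readVolume()` with
`downsampleFactor`): voxel $(i,j,k)$ of the template is voxel
$(if, jf, kf)$ of the source. Stride sampling (rather than interpolation)
was chosen because the template only guides the segmentation — exports
always re-crop the original full-resolution data — and because it composes
exactly (stride $a$ then $b$ equals stride $ab$), which the tests exploit.
Block-mean averaging is available behind `method = "mean"`.

## Plate detection and label assignment

Plates are stacked along z with empty gaps between them. A slice is
*occupied* iff its foreground pixel count is at least `minBlobSize` (the
same working-resolution quantity as the blob filter); maximal runs of
occupied slices are the plates (`detectPlates()`), and a plate's centre is
the midpoint of its run — a half-integer for even runs, used only for
plate/grid pairing, never as an index. Note the detected span tracks where
*thresholded specimen pixels* are: the one or two outermost cap slices of
the shallowest specimen can fall under the per-slice minimum, so spans are
slightly tighter than the raw specimen extent.

Each plate's CSV sheet becomes a `LabelGrid`; blank cells mark empty wells.
Cell $(r, c)$ starts at $((c - \tfrac12)p_x,\ (r - \tfrac12)p_y)$ and the
user-supplied transform is applied in the fixed order **flips (about the
grid centre) → rotation (about the grid centre) → translation**; the order
is a convention the package fixes and documents, since only a documented
order makes transforms reproducible from a config file. `cornerLabels()`
surfaces the four corner IDs (after flips) for the human check that the
scan is not mirrored; no auto-correction is attempted.

`assignLabels()` matches each blob to the nearest non-empty cell centre of
its plate in x-y Euclidean distance (2D within each plate, since grids are
planar). Implementing the match blob→cell with per-cell multiplicity
realises the two awkward cases with one rule:

* **Empty wells** never receive a blob (their cells are simply absent from
  the candidate set).
* **Doubled wells** (two fragments in one well, e.g. damage in transfer)
  produce $k > 1$ blobs matched to one cell; they receive suffixed labels
  `label_1 … label_k` by ascending distance — deterministic and sortable.

Blobs farther than `maxMatchDistance` (default $0.75 \min(p_x, p_y)$) from
every cell, and all blobs when no CSV is supplied, degrade to sequential
numeric labels `specimen_0001, …` — data is never silently dropped. Ties
between equidistant cells resolve to the first cell in row-major order.

## Export and meshing

Exports map each blob's working-resolution bounding box back to full
resolution (`scaleBboxToFull()`: bounds times the stride, plus a 2-voxel
margin so halos survive, clamped to the volume) and re-read only that crop
from the source file(s). The working mask is upscaled by nearest-neighbour
block replication, restricted to the blob. The three stack modes satisfy
`processed == raw * mask / 255` voxelwise by construction, and the tests
assert it on every phantom export.

Meshes are extracted from the blob's binary mask at iso-level 0.5 with one
voxel of zero padding, so border-touching specimens still close. plateCT
uses the marching-cubes family's tetrahedral variant: each grid cell is
subdivided into the six Kuhn tetrahedra sharing the cell's main diagonal, a
subdivision that is globally face-consistent across the lattice. On a
binary field the resulting piecewise-linear surface is therefore provably
**watertight** (every edge incident to exactly two faces) — the classic
256-case cube tables are topologically ambiguous on faces with two diagonal
foreground corners and can leak holes exactly on the binary masks this
package feeds them. Surface vertices sit at edge midpoints (the 0.5
interpolant between a 0 and a 1 node), so flat regions land on the same
half-voxel offset planes classic marching cubes produces; no smoothing is
applied, preserving the segmentation at the cost of a blocky texture. On a
digital sphere of radius 10 voxels the enclosed mesh volume agrees with the
foreground voxel count to about 0.3%.

`recentreAndScale()` translates the vertex centroid to the origin and
multiplies by `voxelSize / 1000`, converting voxel units to millimetres
(voxel size is carried in microns, mm is what mesh tools expect).
`writePLY()` emits binary little-endian PLY by default (float32 vertices,
uchar-counted uint32 face lists) with an ASCII option; comment lines record
label, voxel size and units.

Point clouds (`maskToPointCloud()`) are either filled (one point per
foreground voxel — cardinality equals the mask's voxel count) or hollow.
Hollowing keeps boundary voxels including internal void surfaces; the
default is the 3D 26-neighbourhood morphological boundary (a voxel is
surface iff any neighbour is background), with a per-slice 2D edge variant
(`method = "slice"`) that additionally drops voxels exposed only in z.
The 3D rule is the one whose output the brute-force surface oracle in the
test suite reproduces exactly, and it is what makes the "3×3×3 block
hollows to its 26 non-centre voxels" identity hold.

## The phantom: what it emulates, and what it does not

`generatePhantom()` builds fully ground-truthed synthetic scans so every
downstream stage is testable without any real data:

* mount-greyscale slabs stacked in z with empty gaps (defaults: 2 plates,
  14 slices thick, 8-slice gaps);
* a rows × cols array of cylindrical well cavities per slab (default 4 × 6,
  the 24-well format, at a 16-voxel pitch);
* ellipsoidal specimens (base radius 4–6 voxels, axis ratios 0.5–1,
  jittered up to 1.5 voxels off the well centre) in each occupied well;
* material greys 0 / 31 / 114 for air / mount / specimen — the three-peak
  histogram structure of a real bulk scan of bone in plastic plates;
* Gaussian blur (σ = 0.8 voxel) **before** additive noise, so object
  margins carry a smooth partial-volume halo; then Gaussian noise
  (σ = 3 grey levels, truncated at 3σ and clipped to [0, 255]).

The blur and radius defaults were chosen together once: σ near one voxel is
a typical partial-volume scale, and specimens a few voxels across must
retain enough pure-interior volume that the specimen histogram mode stays
at its material level — larger blur on such small objects drags the mode
down, which is a property of tiny objects, not of real bone fragments that
span dozens of voxels. Doubled-well mode places two compact specimens
(radius 0.65 of the minimum, near-spherical) at fixed diagonal offsets with
a shared jitter, so the blurred pair always blobs apart; empty-well mode
leaves a well (and its CSV cell) empty.

The phantom does **not** model ring artefacts, beam hardening, cone-beam
geometry, anisotropic voxels, or specimens overlapping the mount in
density. Passing tests therefore demonstrate the correctness of the
pipeline's logic — geometry, matching, conservation, round trips — not
robustness to every real-world scan pathology; thresholds on real data
remain a user judgement, aided by cel-shading.

The segmentation settings used throughout the phantom tests (cel base 6,
bracket lower bound 52) mirror a realistic operating point for this
histogram: base 6 groups the mount peak into few bins and 52 sits between
the mount and specimen peaks.

## Numerical and interface conventions

* Arrays are indexed `[z, y, x]` (slice, row, column), 1-based; z is the
  stacking axis. Continuous coordinates place voxel $i$'s centre at
  $i - 0.5$, so a volume spans $[0, n]$ — centroids, cell centres and mesh
  vertices share this frame. Bounding boxes are 1-based inclusive.
* Raw files are voxel-major with x fastest; TIFF folders are stacked in
  natural (numeric-aware) filename order, overridable by an explicit
  `slice_order` in the `.info` file.
* `.info` is UTF-8 `key=value`; `voxel_size_um` is mandatory (its absence
  raises a typed, recoverable condition so callers can supply the value and
  regenerate the file); unknown keys are tolerated.
* Bit depths 8/16/32 are supported; everything is linearly min–max rescaled
  to 8-bit before export (constant input maps to 0). The rescale is
  monotone, so threshold order relations survive.
* A mask with no foreground yields an empty blob list (not an error), an
  empty point cloud, and a typed "nothing to mesh" condition from the
  mesher.
* Specimen labels become output directory names through an ASCII character
  map (anything outside `[A-Za-z0-9._-]` becomes `_`); a post-sanitisation
  collision is a hard error since labels are unique upstream.

## Problem sizes in the test-suite

The suite validates on phantoms of 1–3 plates with 4 × 6 (and smaller)
well arrays at ~50–100 voxels per axis, oracle comparisons on 100 random
16³ masks, 200 random slice-count sequences and 12³ surface shapes, and
meshes up to a radius-10 digital sphere — sizes at which the brute-force
oracles remain exact and the whole suite runs in well under a minute,
while exercising every code path the full-scale pipeline uses.

## Worked example

```{r example, eval = FALSE}
td <- tempfile()
ph <- generatePhantom(phantomConfig(seed = 1))
writePhantom(ph, td)

cfg <- runConfig(
  input = file.path(td, "volume"),
  celBase = 6, tLower = 52, tUpper = 255, minBlobSize = 20,
  plateCSVs = file.path(td, sprintf("plate_%02d.csv", 1:2)),
  transforms = lapply(ph$truth$grids, function(g) g@transform),
  outDir = file.path(td, "out"))
manifest <- runPipeline(cfg)
head(manifest)
```

## Known limitations

* Segmentation is global bracket thresholding only — multiphase specimens,
  or specimens overlapping the mount in density, need different tooling.
* Grid-to-plate alignment is manual (a transform in the config); there is
  no automatic registration, and mirror-image scans are only *surfaced*
  via corner labels, not corrected.
* Meshes are unsmoothed and undecimated by design; post-process elsewhere
  if visual quality matters more than fidelity.
* No DICOM or vendor container parsing: point the raw reader at the
  payload with explicit dimensions.
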