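---
title: "Storage and retrieval methods for serial-section EM volumes"
author: "emvault authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storage and retrieval methods for serial-section EM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emvault)
```

# The problem

Serial-section electron microscopy images a brain-tissue block as a stack
of ultrathin slices (tens of nanometres thick) at nanometre in-plane
resolution. The resulting volumes are far larger than any client can hold
— a 470,000 × 425,000 px × 50-layer 8-bit stack is 9.08 TiB uncompressed
(`datasetInfo(470000, 425000, 50)`) — yet a proofreader only ever looks at
a monitor-sized window at one scale. Dense segmentation multiplies the
problem: every neurite cross-section in every layer is an object to store
and query. `emvault` is a self-contained implementation of a storage
design for both data kinds, with the retrieval cost of a browse action
bounded by the viewport, never by the volume.

# Image model

## Tiling

Each layer is partitioned into fixed-size tiles (`TileGrid`; default
2048 × 2048, configurable, square). Tiles overlapping the layer edge are
padded with 0 to full size, so every stored tile has identical shape
(`partitionLayer`). Padding is never confused with data: the property
tests check that regions with no source pixels are exactly 0 at every
pyramid level.

## Pyramid

Two downsampling schemes exist for tiled pyramids: shrink every tile
(mipmap-style; tile count constant, tile size falls 4× per level) or keep
tile size fixed and shrink the tile *count*. The store uses the second
(`downsampleQuad`/`buildPyramid`): four neighboring level-L tiles are
mosaicked, box-downsampled by two, and become one level-L+1 tile. A
low-resolution browse then touches few tiles rather than many tiny ones.
The first scheme is retained as `downsampleMethod1` purely for
comparison; both use the same filter, so a mipmap level-1 tile equals its
quadrant of the quad mosaic — a cross-check in the tests.

The pyramid tops out at

```{r}
# level-0 grid of the reference acquisition, tiled at 2048
g <- TileGrid(470000, 425000)
computeMaxLevel(g@rows, g@cols)
```

`maxLevel = ⌈log₂ max(rows, cols)⌉` with `rows`/`cols` the **tile-grid**
dimensions, not pixel dimensions — the only reading under which the top
level is a single tile per layer. It is computed by repeated integer
halving rather than a floating `log2`, so near-power-of-two grids land on
the correct side. Layers are pyramided independently; there is no
downsampling across the layer axis.

## Downsampling filter

No specific kernel is mandated by the storage design, so the package
fixes one and states it: a 2 × 2 box mean, accumulated in integers, with
round-half-up (`floor((sum + 2) / 4)`). It is deterministic,
order-independent, and testable against an independent whole-image
oracle: stitching level L and comparing with a direct box reduction of
the layer by `2^L` agrees within ±L gray levels (each level contributes
at most one rounding step of drift). Absent quadrants at odd grid edges
are treated as zero tiles (padding, not clipping).

# Spatial indexing

Tile addresses serialize as `"layer_row_col_level"` with fixed-width
zero-padded fields (5/5/5/2 digits), chosen so lexicographic byte order
equals tuple order; that is what makes prefix scans spatially meaningful
in any ordered key-value store.

A browse viewport carries `(x1, y1, w1, h1, layer, magnitude)`.
`magnitudeToLevel` buckets the display scale by exact power-of-two
threshold comparisons — magnitude exactly `2^-n` maps to level `n`,
magnitudes above 1/2 (including above 1) to level 0, and anything at or
below `2^-maxLevel` clamps to `maxLevel`. Floating logarithms are
deliberately avoided: `log2(0.125)` style boundary cases must not wobble.

`viewportToTileKeys` applies the floor formulas
`r1 = ⌊y1/h⌋ … c2 = ⌊(x1+w1)/w⌋` and emits every row/column combination,
row-major. Conventions the formulas imply, made explicit here:

- coordinates are in the selected level's own pixel space (the level-L
  layer is the level-0 layer scaled by `2^-L`); indices are 0-based;
- the viewport is closed on the right/bottom: an edge exactly on a tile
  boundary pulls in the adjacent tile there, but not on the left/top —
  equivalently, tiles behave as half-open rectangles `[rh, (r+1)h)`;
- `r2`/`c2` are clamped to the level's grid when the viewport overhangs
  the layer; a viewport entirely outside yields no keys rather than an
  error.

The property suite checks the result against an exhaustive
rectangle-intersection oracle over randomized grids and viewports, and
that the key count is bounded by `(⌈h1/h⌉+1)(⌈w1/w⌉+1)`.

# The store

Backends implement four primitives — `kvPut`, `kvGet` (point lookup),
`kvPrefixScan` (lexicographic), `kvFilterScan` (attribute equality) —
the contract a wide-column cluster database offers the retrieval design.
Two implementations ship: an in-memory map and a one-file-per-key
directory store; a conformance suite runs identically against both.
Distributed deployment, replication and sharding are out of scope;
`datasetInfo` documents the raw-volume arithmetic that motivates them.

Tiles travel as standard byte streams: lossless PNG, baseline JPEG
(quality 85 by default — a conventional setting for EM tiles, not a
derived one), or a raw debug format. Tests default to PNG so every
end-to-end invariant is bit-exact; the JPEG path asserts shape/dtype
fidelity and cross-decoder compatibility instead. An absent tile on read
is a soft `NULL`, not an error: viewport arithmetic may legitimately
address padded or unstored space.

# Segmentation model

A *primitive* is one 2D region's outer boundary polygon plus attributes:
globally unique `primitiveId` (UUID), parent `objectId`, type, centroid
(recomputable polygon centroid), color, links to primitives of the same
object in adjacent layers (`nodeLinks`), and synaptic partner objects
(`synapseLinks`, carried but never inferred). Contours are traced from
label images (`EBImage::bwlabel` + `ocontour`), oriented
counter-clockwise; inner boundaries (holes) are out of scope. Contours
cost far less than voxel masks, allow overlapping structures, and need no
multiscale copies.

## Block storage and retrieval

`blocksForPrimitive` assigns a primitive to every level-0 block its
bounding box intersects — a cheap, safe superset of exact
polygon-rectangle intersection, consistent with storing a crossing
primitive entirely in each block. `storePrimitives` writes the full JSON
payload once per block under `"layer_row_col_id"`, with `object_id` as
the filterable attribute; re-writing an id with a different payload is an
integrity error, and a secondary index `objectId → record key` is
maintained alongside.

`retrieve2d` turns a native-scale viewport into block prefixes (level
fixed at 0 — primitives are never downsampled, so the key carries no
level field), prefix-scans, and deduplicates by `primitiveId` (the only
stable identity), returning ids in deterministic order. Semantics are
block-granular by design: the result is sandwiched between the exact
polygon-intersection set and the set of all primitives in
viewport-intersecting blocks, and the tests pin it to the full-scan
oracle at block granularity.

`retrieve3d` assembles an object in layer order two ways — the reference
attribute filter scan, and the fast secondary-index walk — and the tests
require both to return identical results on randomized stores. The
reference path is kept as the semantic definition, the index as an
optimization.

`linkAdjacent` cross-links primitives of one object in adjacent layers
when their filled contours overlap (nonzero rasterized intersection;
rasterization = pixel centers inside the polygon plus the boundary
pixels themselves, via `mgcv::in.out`).

# Cache

The client cache has three levels: L1 holds decoded pixel matrices in
memory, L2 holds encoded bytes on local disk, L3 is the remote fetch
contract (any function from key string to bytes). A miss at L1/L2 fills
both lower levels on the way back, so every L1 entry is also in L2 at
insert time. Correctness is *cache transparency*: whatever level serves a
request, the pixels equal a direct remote fetch, and remote failures
propagate rather than being masked by stale data.

Prefetch considers the square rings around the viewport's tile span out
to `prefetchRadius` (the square prefetch unit sized by the viewport's
longest side, expressed in tiles), plus the span's positions on adjacent
layers and pyramid levels (depth 1 each by default — browsing moves
through layers and scales as well as across the plane). The published
picture of priority is qualitative — nearer first, browsing direction
first — and the package realizes it with the minimal formula that
reproduces both rules:

```
score = ring_distance − direction_weight × alignment
```

with Chebyshev ring distance (square rings), alignment the normalized
dot product of the tile-center offset with the pan direction, and
`direction_weight = 0.5` by default. Ties break row-major; the plan is
truncated to `prefetchBudget` (bandwidth is finite) and excludes cached
keys. For cross-layer/level candidates the layer/level offset is added
to the score — no metric across layer and level is prescribed anywhere,
so the package makes the simplest monotone choice and documents it.
Eviction is the same geometry in reverse: while over capacity, drop the
entry with the greatest ring distance from the current viewport (off-
plane entries add their layer/level offset), ties by least recent use;
in-span entries outlive all others. Capacities are configuration, not
doctrine: no quantitative "too far" exists to inherit, so the defaults
(64 decoded tiles in memory, 256 encoded on disk) are stated rather than
derived. Inserts enforce capacity immediately using the last-seen browse
state (pure LRU before any state is known), so the capacity invariant
holds after every operation, not only after explicit eviction calls.

`browseSession` replays a trajectory (get → prefetch → evict per step)
and reports per-level hit rates over user requests, total remote
fetches including prefetch, and peak sizes. Prefetch is a performance
mechanism, not a semantic one: the tests assert transparency under
arbitrary interleavings, and separately that a panning trajectory gains
L1 hit rate over the same trajectory with prefetch disabled.

# Synthetic data

`generateLabelStack` emulates the *shape* of dense segmentation: seed
points partition each layer by the nearest-seed rule (a Voronoi
tessellation), a zero-valued membrane of configurable width carves the
interfaces, and seeds drift per layer (random walk, `objectDrift` px) so
each label is one coherent 3D object whose sections cross block
boundaries. Fragments smaller than 4 px that the carving occasionally
shaves off are absorbed into the membrane, so the recorded ground truth
is exactly what a contour representation can carry. The manifest stores,
per object and layer, connected-component counts, pixel areas and
consecutive-layer overlaps — later recovered exactly by extraction, 3D
retrieval and adjacency linking in the end-to-end tests.

`generateEMStack` renders bright textured interiors (per-object base
intensity plus a smooth modulation) over dark membranes with Gaussian
noise, clipped to 8 bits. What it does *not* emulate: real EM texture
statistics, imaging artifacts, registration error, non-convex or
branching-within-layer morphology, organelles, or anisotropy. Passing
tests therefore demonstrate the correctness of storage, indexing,
retrieval and caching on realistically *structured* data — not
segmentation quality on real micrographs, which is upstream of this
package's scope.

Defaults describe the standard fixture (8 layers of 4096², 30 objects,
drift 8 px/layer, noise SD 10, membrane 3 px). The test suite runs the
same generator at smaller sizes — typically 2–4 layers of 96²–192² with
5–8 objects, and property sweeps on grids of at most a few hundred
pixels — chosen so the whole suite completes in well under a minute per
file while still exercising multi-tile, multi-block, multi-layer
geometry. Everything is reproducible byte-for-byte from the spec seed;
generators save and restore the caller's RNG state.

# Numerical and design notes

- Pixel values are integers 0–255 throughout; downsampling uses exact
  integer arithmetic (`floor((sum + 2)/4)`), so results are
  platform-independent.
- Rounding is half-up (`floor(x + 0.5)`), not banker's rounding; the
  checkerboard mean 127.5 becomes 128.
- Polygon centroids use the shoelace formula with a vertex-mean fallback
  for degenerate (near-zero-area) contours such as 1-px-wide bars.
- Key fields are fixed-width (grids up to 99,999 tiles per side, levels
  to 99); widths are an artifact convention, documented with the format.
- Magnitudes above 100% clamp to level 0; magnitudes at or below the top
  level's threshold clamp to `maxLevel`.
- UUIDs are drawn from the session RNG, so pipelines are reproducible
  under `set.seed()`.

# Known limitations

- Single-channel 8-bit imagery only; no multiscale segmentation; no
  registration or stitching (inputs are assumed aligned).
- Block membership by bounding box over-approximates exact polygon
  intersection; a primitive can be returned for a viewport its polygon
  does not touch (block-granularity semantics, stated above).
- Holes in segmentation regions are not represented (outer boundaries
  only).
- The on-disk backend is a plain directory: fine at desk scale, no
  substitute for a real cluster store at acquisition scale.
- Concurrency: prefetch correctness is defined by cache transparency;
  there are no ordering guarantees between prefetch completions, and the
  store offers no multi-writer control.
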