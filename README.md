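# emvault

A desk-scale storage and retrieval engine for serial-section electron
microscopy (EM) volumes and their contour-based segmentation results,
written as an R package in Bioconductor style.

Connectome reconstruction images sequential ultrathin brain-tissue slices
at nanometre resolution; a single stack can reach terabytes (a 470,000 ×
425,000 px × 50-layer 8-bit acquisition is already 9.08 TiB raw), while a
client only ever displays a monitor-sized window of it. `emvault`
implements the storage design that makes such browsing cheap, and keeps it
small enough to run, test and study on one machine:

- **Tile pyramid (volume model).** Each layer is cut into fixed-size
  blocks (default 2048²; edges zero-padded). Levels are built by
  downsampling 2×2 tile quads with a box mean, so tile size stays constant
  and the tile count shrinks fourfold per level up to
  `maxLevel = ⌈log₂ max(rows, cols)⌉`, where `rows × cols` is the level-0
  tile grid — at the top, a whole layer is one tile.
- **Spatial key-value index.** A tile is addressed
  `"layer_row_col_level"` (fixed-width, zero-padded, so byte order is
  tuple order). A viewport `(x₁, y₁, w₁, h₁)` at display scale *magnitude*
  resolves to keys by pure arithmetic: the magnitude buckets onto a level
  (`2⁻ⁿ < mag ≤ 2⁻ⁿ⁺¹ → level n−1`), and
  `r₁=⌊y₁/h⌋, r₂=⌊(y₁+h₁)/h⌋, c₁=⌊x₁/w⌋, c₂=⌊(x₁+w₁)/w⌋` span the
  needed rows and columns — O(#keys), independent of volume size, each key
  a constant-time point lookup.
- **Segmentation store.** Each 2D segmentation region is one *primitive*:
  its outer contour plus attributes (object id, type, centroid, color,
  links). Primitives are stored under `"layer_row_col_id"` once per image
  block their bounding box touches, duplicated in full. 2D viewport
  queries are block prefix scans with duplicate removal; 3D objects are
  assembled by an attribute filter scan on the object id (with an
  equivalent, faster secondary index).
- **Three-level cache.** Memory (decoded tiles) → local disk (encoded
  tiles) → remote store, with promotion on miss, square-ring prefetch
  prioritized by `ring_distance − w·alignment` with the pan direction, and
  farthest-first eviction.
- **Synthetic data.** A seeded generator of EM-like texture stacks and
  drifting-tessellation label stacks with a ground-truth manifest, so the
  whole pipeline is testable offline.

The pluggable key-value backend (put/get, lexicographic prefix scan,
attribute filter scan) mirrors the operations a wide-column cluster store
provides; distributed deployment is out of scope here by design.

## Worked example

```r
library(emvault)

# a 470,000 x 425,000 px layer tiled at 2048^2
g <- TileGrid(470000, 425000)
c(g@rows, g@cols)                 # 208 230
computeMaxLevel(g@rows, g@cols)   # 8

# browsing at 10% display scale uses pyramid level 3
magnitudeToLevel(0.10, 8)         # 3

# a 4200 x 1500 viewport at native scale needs exactly six tiles
vp <- Viewport(1000, 1000, 4200, 1500, layer = 0, magnitude = 1)
sapply(viewportToTileKeys(vp, g, 8), formatTileKey)
# "00000_00000_00000_00" "00000_00000_00001_00" "00000_00000_00002_00"
# "00000_00001_00000_00" "00000_00001_00001_00" "00000_00001_00002_00"

# raw size of the reference acquisition
info <- datasetInfo(470000, 425000, 50)
round(info$uncompressedTB, 2)     # 9.08  (TiB, uncompressed)
c(info$extentMmX, info$extentMmY, info$extentUmZ)  # 2.35 2.125 2.5
```

The six keys are rows 0–1 × columns 0–2 of level 0 — the viewport's corner
arithmetic (`⌊5200/2048⌋ = 2`, `⌊2500/2048⌋ = 1`) in key form. The dataset
numbers say a desk cannot hold the raw volume, which is exactly why the
store serves tiles, not layers.

A full in-memory round trip:

```r
spec <- SyntheticSpec(seed = 1, layers = 2, layerSize = c(512L, 512L),
                      nObjects = 10)
stack <- generateLabelStack(spec)
em <- generateEMStack(spec, stack$labels)

grid <- TileGrid(512, 512, 128)
meta <- VolumeMetadata(2, grid, codec = "png")
store <- memoryBackend()
ingestVolume(em, meta, store, CodecConfig("png"))

seg <- memoryBackend()
for (l in 1:2)
  storePrimitives(seg, extractPrimitives(stack$labels[[l]], l - 1L), grid)
length(retrieve2d(seg, Viewport(0, 0, 511, 511), grid))  # distinct primitives
retrieve3d(seg, "1")   # object 1, layers in order
```

## Command line

`inst/cli/emvault.R` wraps the same functions:

```sh
Rscript inst/cli/emvault.R fixture --out /tmp/fix --layers 2 --size 512 --objects 10
Rscript inst/cli/emvault.R ingest --input /tmp/fix --store /tmp/store --tile-size 128 --codec png
Rscript inst/cli/emvault.R view --store /tmp/store --x 100 --y 100 --w 300 --h 200 --out crop.png
Rscript inst/cli/emvault.R seg ingest --store /tmp/store --labels /tmp/fix
Rscript inst/cli/emvault.R seg query3d --store /tmp/store --object 1
Rscript inst/cli/emvault.R browse-sim --store /tmp/store --steps 8
```

Exit codes: 0 success, 2 usage/input error, 1 internal error.

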