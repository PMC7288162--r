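#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Fixed-size tile grid of one layer
#'
#' Describes how a single serial-section layer of `layerWidth` x
#' `layerHeight` pixels is partitioned into fixed-size tiles of
#' `tileW` x `tileH` pixels. The level-0 grid has
#' `rows = ceiling(layerHeight / tileH)` tile rows and
#' `cols = ceiling(layerWidth / tileW)` tile columns; tiles overhanging the
#' layer edge are zero-padded to full size.
#'
#' @slot tileW,tileH tile width and height in pixels.
#' @slot rows,cols number of tile rows / columns at level 0.
#' @slot layerWidth,layerHeight layer dimensions in pixels.
#' @export
setClass("TileGrid", representation(
  tileW = "integer", tileH = "integer",
  rows = "integer", cols = "integer",
  layerWidth = "integer", layerHeight = "integer"
))

setValidity("TileGrid", function(object) {
  msg <- character()
  if (object@tileW < 1L || object@tileH < 1L)
    msg <- c(msg, "tile dimensions must be positive")
  if (object@layerWidth < 1L || object@layerHeight < 1L)
    msg <- c(msg, "layer dimensions must be positive")
  if (object@rows != ceiling(object@layerHeight / object@tileH))
    msg <- c(msg, "rows must equal ceiling(layerHeight / tileH)")
  if (object@cols != ceiling(object@layerWidth / object@tileW))
    msg <- c(msg, "cols must equal ceiling(layerWidth / tileW)")
  if (length(msg)) msg else TRUE
})

#' Construct a TileGrid
#'
#' @param layerWidth,layerHeight layer dimensions in pixels.
#' @param tileW tile width in pixels (default 2048).
#' @param tileH tile height in pixels (defaults to `tileW`; the default
#'   tile is square).
#' @return A [TileGrid-class] object.
#' @examples
#' TileGrid(4096, 4096)            # 2 x 2 tiles of 2048^2
#' TileGrid(3000, 3000, tileW = 2048)
#' @export
TileGrid <- function(layerWidth, layerHeight, tileW = 2048L, tileH = tileW) {
  new("TileGrid",
      tileW = as.integer(tileW), tileH = as.integer(tileH),
      rows = as.integer(ceiling(layerHeight / tileH)),
      cols = as.integer(ceiling(layerWidth / tileW)),
      layerWidth = as.integer(layerWidth),
      layerHeight = as.integer(layerHeight))
}

#' Address of one image tile
#'
#' A tile is addressed by `(layer, row, col, level)`: the serial-section
#' layer, the tile row/column within that pyramid level's grid, and the
#' pyramid level (0 = native resolution). All indices are 0-based. The
#' string form is the store row key, `"layer_row_col_level"` with
#' fixed-width zero-padded fields (see [formatTileKey()]).
#'
#' @slot layer,row,col,level 0-based integer indices.
#' @export
setClass("TileKey", representation(
  layer = "integer", row = "integer", col = "integer", level = "integer"
))

setValidity("TileKey", function(object) {
  v <- c(object@layer, object@row, object@col, object@level)
  if (any(is.na(v)) || any(v < 0L)) "all key fields must be >= 0" else TRUE
})

#' Construct a TileKey
#' @param layer,row,col,level 0-based indices.
#' @return A [TileKey-class] object.
#' @export
TileKey <- function(layer, row, col, level = 0L) {
  new("TileKey", layer = as.integer(layer), row = as.integer(row),
      col = as.integer(col), level = as.integer(level))
}

setMethod("show", "TileKey", function(object) {
  cat(sprintf("TileKey(layer=%d, row=%d, col=%d, level=%d) \"%s\"\n",
              object@layer, object@row, object@col, object@level,
              formatTileKey(object)))
})

#' One image tile with its address
#'
#' Pixels are an integer matrix of exactly `(tileH, tileW)` with values in
#' 0..255; indexing is `pixels[y + 1, x + 1]`. Tiles cut at the layer edge
#' are padded with 0 (black) to full size.
#'
#' @slot key a [TileKey-class].
#' @slot pixels integer matrix `(tileH, tileW)`, values 0..255.
#' @export
setClass("Tile", representation(key = "TileKey", pixels = "matrix"))

setValidity("Tile", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric/integer matrix")
  if (anyNA(p)) return("pixels must not contain NA")
  if (min(p) < 0 || max(p) > 255) return("pixels must lie in 0..255")
  TRUE
})

#' Construct a Tile
#' @param key a [TileKey-class].
#' @param pixels integer matrix (tileH, tileW), values 0..255.
#' @return A [Tile-class] object.
#' @export
Tile <- function(key, pixels) {
  storage.mode(pixels) <- "integer"
  new("Tile", key = key, pixels = pixels)
}

setMethod("show", "Tile", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Tile %s  %dx%d px, range [%d, %d]\n",
              formatTileKey(object@key), d[1], d[2],
              min(object@pixels), max(object@pixels)))
})

#' Volume-level metadata
#'
#' Everything needed to address a stored volume: the per-layer tile grid,
#' the number of layers, the pyramid depth, bit depth, physical voxel size
#' and the tile codec. `maxLevel` is derived from the level-0 grid as
#' `ceiling(log2(max(rows, cols)))`, the level at which a whole layer fits
#' in a single tile.
#'
#' @slot nLayers number of serial-section layers.
#' @slot grid a [TileGrid-class].
#' @slot maxLevel top pyramid level.
#' @slot bitDepth bits per pixel (8).
#' @slot voxelSize numeric (x, y, z) voxel size in nanometres.
#' @slot codec tile codec name ("png", "jpeg" or "raw").
#' @export
setClass("VolumeMetadata", representation(
  nLayers = "integer", grid = "TileGrid", maxLevel = "integer",
  bitDepth = "integer", voxelSize = "numeric", codec = "character"
))

setValidity("VolumeMetadata", function(object) {
  msg <- character()
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (object@maxLevel != computeMaxLevel(object@grid@rows, object@grid@cols))
    msg <- c(msg, "maxLevel must equal computeMaxLevel(rows, cols)")
  if (length(object@voxelSize) != 3L) msg <- c(msg, "voxelSize must be length 3")
  if (length(msg)) msg else TRUE
})

#' Construct VolumeMetadata
#'
#' @param nLayers number of layers (>= 1).
#' @param grid a [TileGrid-class].
#' @param bitDepth bits per pixel; only 8 is supported.
#' @param voxelSize (x, y, z) voxel size in nanometres.
#' @param codec default tile codec.
#' @return A [VolumeMetadata-class] object.
#' @export
VolumeMetadata <- function(nLayers, grid, bitDepth = 8L,
                           voxelSize = c(5, 5, 50), codec = "png") {
  new("VolumeMetadata", nLayers = as.integer(nLayers), grid = grid,
      maxLevel = computeMaxLevel(grid@rows, grid@cols),
      bitDepth = as.integer(bitDepth), voxelSize = as.numeric(voxelSize),
      codec = codec)
}

setMethod("show", "VolumeMetadata", function(object) {
  g <- object@grid
  cat(sprintf(paste0(
    "VolumeMetadata: %d layer(s) of %dx%d px\n",
    "  tile %dx%d, level-0 grid %d rows x %d cols, maxLevel %d\n",
    "  %d-bit, voxel %.3g x %.3g x %.3g nm, codec %s\n"),
    object@nLayers, g@layerWidth, g@layerHeight, g@tileW, g@tileH,
    g@rows, g@cols, object@maxLevel, object@bitDepth,
    object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
    object@codec))
})

#' A rectangular browse viewport
#'
#' The client viewport `(x1, y1, w1, h1)` on layer `layer`, displayed at
#' scale `magnitude` (fraction of native resolution). Coordinates are in
#' the pixel space of the pyramid level selected by the magnitude (the
#' level-L layer is the level-0 layer scaled by `2^-L`). The viewport is a
#' closed rectangle: an edge touching a tile boundary includes the adjacent
#' tile row/column, matching the floor formulas of the index computation.
#'
#' @slot x1,y1 top-left corner in level pixels (>= 0).
#' @slot w1,h1 viewport width and height in level pixels (> 0).
#' @slot layer 0-based layer index.
#' @slot magnitude display scale, > 0; values > 1 clamp to level 0.
#' @export
setClass("Viewport", representation(
  x1 = "numeric", y1 = "numeric", w1 = "numeric", h1 = "numeric",
  layer = "integer", magnitude = "numeric"
))

setValidity("Viewport", function(object) {
  msg <- character()
  if (object@w1 <= 0 || object@h1 <= 0) msg <- c(msg, "w1 and h1 must be > 0")
  if (object@x1 < 0 || object@y1 < 0) msg <- c(msg, "x1 and y1 must be >= 0")
  if (object@layer < 0L) msg <- c(msg, "layer must be >= 0")
  if (!(object@magnitude > 0)) msg <- c(msg, "magnitude must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Viewport
#' @param x1,y1 top-left corner in level pixels.
#' @param w1,h1 viewport size in level pixels.
#' @param layer 0-based layer index.
#' @param magnitude display scale as a fraction of native resolution.
#' @return A [Viewport-class] object.
#' @export
Viewport <- function(x1, y1, w1, h1, layer = 0L, magnitude = 1) {
  new("Viewport", x1 = as.numeric(x1), y1 = as.numeric(y1),
      w1 = as.numeric(w1), h1 = as.numeric(h1),
      layer = as.integer(layer), magnitude = as.numeric(magnitude))
}

setMethod("show", "Viewport", function(object) {
  cat(sprintf("Viewport (%g, %g) %gx%g  layer %d, magnitude %g\n",
              object@x1, object@y1, object@w1, object@h1,
              object@layer, object@magnitude))
})

#' One 2D segmentation contour ("primitive")
#'
#' The unit of segmentation storage: a closed outer-boundary polygon of one
#' connected segmentation region in one layer, plus its attributes. The
#' contour is an n x 2 matrix of (x, y) level-0 pixel coordinates, traced
#' counter-clockwise; the first vertex implicitly follows the last.
#' Primitives sharing `objectId` stack across layers into one 3D object.
#'
#' @slot primitiveId globally unique id (UUID string).
#' @slot objectId parent 3D-object id.
#' @slot objectType one of "neuron", "mitochondrion", "synapse", "other".
#' @slot contour n x 2 numeric matrix of (x, y) vertices, n >= 3.
#' @slot layer 0-based layer index.
#' @slot centroid polygon centroid (x, y); recomputable from the contour.
#' @slot color integer RGB triple in 0..255.
#' @slot nodeLinks primitive ids of linked primitives in adjacent layers of
#'   the same object.
#' @slot synapseLinks object ids of synaptically connected objects.
#' @export
setClass("Primitive", representation(
  primitiveId = "character", objectId = "character", objectType = "character",
  contour = "matrix", layer = "integer", centroid = "numeric",
  color = "integer", nodeLinks = "character", synapseLinks = "character"
))

.primitiveTypes <- c("neuron", "mitochondrion", "synapse", "other")

setValidity("Primitive", function(object) {
  msg <- character()
  if (nrow(object@contour) < 3L) msg <- c(msg, "contour needs >= 3 vertices")
  if (ncol(object@contour) != 2L) msg <- c(msg, "contour must be n x 2")
  if (!object@objectType %in% .primitiveTypes)
    msg <- c(msg, sprintf("objectType must be one of %s",
                          paste(.primitiveTypes, collapse = ", ")))
  if (length(object@centroid) != 2L) msg <- c(msg, "centroid must be (x, y)")
  if (length(object@color) != 3L) msg <- c(msg, "color must be RGB")
  if (object@layer < 0L) msg <- c(msg, "layer must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Primitive
#'
#' The contour is re-oriented counter-clockwise if needed and the centroid
#' is computed from the polygon unless supplied.
#'
#' @param contour n x 2 matrix of (x, y) vertices.
#' @param layer 0-based layer index.
#' @param objectId parent object id.
#' @param objectType structure type.
#' @param primitiveId unique id; a fresh UUID by default.
#' @param centroid (x, y) centroid; computed from the contour if `NULL`.
#' @param color RGB triple; derived from `objectId` if `NULL`.
#' @param nodeLinks,synapseLinks link attributes (may be empty).
#' @return A [Primitive-class] object.
#' @export
Primitive <- function(contour, layer, objectId, objectType = "neuron",
                      primitiveId = makeUUID(), centroid = NULL,
                      color = NULL, nodeLinks = character(),
                      synapseLinks = character()) {
  contour <- ensureCCW(as.matrix(contour))
  if (is.null(centroid)) centroid <- polygonCentroid(contour)
  if (is.null(color)) color <- objectColor(objectId)
  new("Primitive", primitiveId = primitiveId,
      objectId = as.character(objectId), objectType = objectType,
      contour = contour, layer = as.integer(layer),
      centroid = as.numeric(centroid), color = as.integer(color),
      nodeLinks = nodeLinks, synapseLinks = synapseLinks)
}

setMethod("show", "Primitive", function(object) {
  cat(sprintf(
    "Primitive %s  object %s (%s), layer %d, %d vertices, centroid (%.1f, %.1f)\n",
    substr(object@primitiveId, 1, 8), object@objectId, object@objectType,
    object@layer, nrow(object@contour),
    object@centroid[1], object@centroid[2]))
})
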