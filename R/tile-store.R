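# Tile persistence: encoded tiles live in a KV backend under their
# spatial string keys; volume metadata travels as a JSON sidecar.

#' Store one tile
#'
#' Encodes the tile with `cfg` and writes it under its formatted key.
#' Overwrites are idempotent (last write wins).
#'
#' @param store a [KVBackend-class].
#' @param key the tile's [TileKey-class] (defaults to `tile@key`).
#' @param tile a [Tile-class].
#' @param cfg a [CodecConfig-class].
#' @return the key string, invisibly.
#' @export
putTile <- function(store, tile, cfg = CodecConfig(), key = tile@key) {
  ks <- formatTileKey(key)
  b <- tryCatch(encodeTile(tile, cfg),
                error = function(e) stop(sprintf("encoding tile %s: %s", ks,
                                                 conditionMessage(e))))
  tryCatch(kvPut(store, ks, b),
           error = function(e) stop(sprintf("writing tile %s: %s", ks,
                                            conditionMessage(e))))
  invisible(ks)
}

#' Fetch tiles by key (point lookups)
#'
#' One point `kvGet` per key — no scans, so per-key cost is independent of
#' store size. Absent keys come back as `NULL` entries, not errors:
#' viewport computations may legitimately address padded or out-of-store
#' space.
#'
#' @param store a [KVBackend-class].
#' @param keys list of [TileKey-class] (or character key strings).
#' @param cfg the [CodecConfig-class] tiles were stored with.
#' @return named list (key strings) of [Tile-class] or `NULL`.
#' @export
getTiles <- function(store, keys, cfg = CodecConfig()) {
  out <- vector("list", length(keys))
  nms <- character(length(keys))
  for (i in seq_along(keys)) {
    k <- keys[[i]]
    ks <- if (is.character(k)) k else formatTileKey(k)
    nms[i] <- ks
    b <- tryCatch(kvGet(store, ks),
                  error = function(e) stop(sprintf("reading tile %s: %s", ks,
                                                   conditionMessage(e))))
    if (!is.null(b))
      out[[i]] <- Tile(parseTileKey(ks), decodeTile(b, cfg))
  }
  names(out) <- nms
  out
}

#' Write / read the volume metadata sidecar
#'
#' `volume.json` records everything needed to re-open a store: tile size,
#' level-0 grid shape, layer dimensions, layer count, max level, bit
#' depth, voxel size and codec.
#'
#' @param meta a [VolumeMetadata-class].
#' @param path file path (conventionally `<store>/volume.json`).
#' @return `writeVolumeMetadata`: the path, invisibly;
#'   `readVolumeMetadata`: a [VolumeMetadata-class].
#' @export
writeVolumeMetadata <- function(meta, path) {
  g <- meta@grid
  obj <- list(
    n_layers = meta@nLayers,
    tile_w = g@tileW, tile_h = g@tileH,
    layer_width = g@layerWidth, layer_height = g@layerHeight,
    rows = g@rows, cols = g@cols,
    max_level = meta@maxLevel, bit_depth = meta@bitDepth,
    voxel_size_nm = meta@voxelSize, codec = meta@codec)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writeVolumeMetadata
#' @export
readVolumeMetadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("no volume metadata at %s", path))
  o <- jsonlite::fromJSON(path)
  grid <- TileGrid(o$layer_width, o$layer_height, o$tile_w, o$tile_h)
  VolumeMetadata(o$n_layers, grid, bitDepth = o$bit_depth,
                 voxelSize = o$voxel_size_nm, codec = o$codec)
}

#' Read a single-channel 8-bit layer image
#'
#' TIFF or PNG, by file extension. Multi-channel files are reduced to
#' their first channel.
#'
#' @param path image file path.
#' @return integer matrix `(height, width)`, values 0..255.
#' @export
readLayerImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read layer image %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported layer image format \"%s\" (%s)", ext, path)))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- matrix(as.integer(roundHalfUp(img * 255)), nrow(img), ncol(img))
  m
}

#' Write a single-channel 8-bit layer image
#' @param image integer matrix, values 0..255.
#' @param path output path (.tif/.tiff or .png).
#' @return the path, invisibly.
#' @export
writeLayerImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- image / 255
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop(sprintf("unsupported layer image format \"%s\" (%s)", ext, path)))
  invisible(path)
}

# Resolve the heterogeneous layer-source argument of ingestVolume into a
# fetch function(i) -> matrix plus a layer count.
resolveLayerSource <- function(layers) {
  if (is.function(layers)) stop("supply layers as a list or file paths")
  if (is.character(layers)) {
    paths <- layers
    list(n = length(paths), fetch = function(i) {
      tryCatch(readLayerImage(paths[i]),
               error = function(e) stop(sprintf("layer %d (%s): %s", i - 1L,
                                                paths[i],
                                                conditionMessage(e))))
    })
  } else if (is.list(layers)) {
    list(n = length(layers), fetch = function(i) layers[[i]])
  } else if (is.matrix(layers)) {
    list(n = 1L, fetch = function(i) layers)
  } else stop("layers must be a list of matrices or a character vector of paths")
}

#' Ingest a layer stack into a tile store
#'
#' Partitions every layer into level-0 tiles, builds the full pyramid,
#' encodes each tile and writes it to the backend. Re-running an ingest
#' overwrites in place, so a partial ingest is resumable; with a lossless
#' codec the resulting store bytes are deterministic.
#'
#' @param layers list of integer layer matrices, or character vector of
#'   TIFF/PNG paths (one per layer, in layer order).
#' @param meta a [VolumeMetadata-class]; its grid must match the layers.
#' @param store a [KVBackend-class].
#' @param cfg a [CodecConfig-class].
#' @return ingest report: `nLayers`, `tilesPerLevel` (per-layer named
#'   vector), `totalTiles`, `encodedBytes`, `uncompressedBytes`.
#' @export
ingestVolume <- function(layers, meta, store, cfg = CodecConfig()) {
  src <- resolveLayerSource(layers)
  if (src$n < 1L) stop("no layers to ingest")
  if (src$n != meta@nLayers)
    stop(sprintf("metadata declares %d layers but %d supplied",
                 meta@nLayers, src$n))
  grid <- meta@grid
  perLevel <- pyramidTileCounts(grid)
  names(perLevel) <- as.character(seq_along(perLevel) - 1L)
  totalBytes <- 0
  nTiles <- 0L
  for (i in seq_len(src$n)) {
    img <- src$fetch(i)
    lv0 <- partitionLayer(img, grid, layer = i - 1L)
    pyr <- buildPyramid(lv0, meta)
    for (t in pyr) {
      b <- encodeTile(t, cfg)
      kvPut(store, formatTileKey(t@key), b)
      totalBytes <- totalBytes + length(b)
      nTiles <- nTiles + 1L
    }
  }
  list(nLayers = src$n, tilesPerLevel = perLevel,
       totalTiles = nTiles,
       encodedBytes = totalBytes,
       uncompressedBytes = as.numeric(grid@layerWidth) * grid@layerHeight *
         src$n * (meta@bitDepth / 8))
}

#' Fetch, stitch and crop a viewport from a store
#'
#' Resolves the viewport to tile keys, point-fetches them, stitches the
#' span and crops to the exact viewport rectangle (level pixel space).
#' Tiles absent from the store appear as black.
#'
#' @param store a [KVBackend-class].
#' @param vp a [Viewport-class].
#' @param meta the volume's [VolumeMetadata-class].
#' @param cfg the store's [CodecConfig-class].
#' @return integer matrix of `round(h1) x round(w1)` pixels (clipped to
#'   the layer extent).
#' @export
fetchViewport <- function(store, vp, meta, cfg = CodecConfig()) {
  grid <- meta@grid
  keys <- viewportToTileKeys(vp, grid, meta@maxLevel, nLayers = meta@nLayers)
  level <- magnitudeToLevel(vp@magnitude, meta@maxLevel)
  hL <- as.integer(ceiling(grid@layerHeight / 2^level))
  wL <- as.integer(ceiling(grid@layerWidth / 2^level))
  x0 <- as.integer(floor(vp@x1)); y0 <- as.integer(floor(vp@y1))
  x1 <- min(as.integer(floor(vp@x1 + vp@w1)), wL - 1L)
  y1 <- min(as.integer(floor(vp@y1 + vp@h1)), hL - 1L)
  if (x0 > x1 || y0 > y1) return(matrix(0L, 0L, 0L))
  out <- matrix(0L, y1 - y0 + 1L, x1 - x0 + 1L)
  tiles <- getTiles(store, keys, cfg)
  th <- grid@tileH; tw <- grid@tileW
  for (t in tiles) {
    if (is.null(t)) next
    ty0 <- t@key@row * th; tx0 <- t@key@col * tw
    yi <- max(y0, ty0):min(y1, ty0 + th - 1L)
    xi <- max(x0, tx0):min(x1, tx0 + tw - 1L)
    out[yi - y0 + 1L, xi - x0 + 1L] <- t@pixels[yi - ty0 + 1L, xi - tx0 + 1L]
  }
  out
}
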