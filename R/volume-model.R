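#' Maximum pyramid level for a tile grid
#'
#' The pyramid is built by repeatedly halving the tile-grid dimensions
#' (each level-L+1 tile covers a 2 x 2 quad of level-L tiles at unchanged
#' tile pixel size). The top level is `ceiling(log2(max(rows, cols)))`:
#' the first level at which the whole layer fits in a single tile.
#'
#' Computed by repeated integer halving, not a floating logarithm, so grid
#' sizes near powers of two land on the correct side of the boundary.
#'
#' @param rows,cols level-0 tile-grid dimensions (tiles, not pixels).
#' @return integer pyramid level >= 0.
#' @examples
#' computeMaxLevel(1, 1)     # 0
#' computeMaxLevel(4, 2)     # 2
#' computeMaxLevel(208, 230) # 8
#' @export
computeMaxLevel <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("rows and cols must be positive integers")
  m <- max(rows, cols)
  lev <- 0L
  while (m > 1L) {
    m <- (m + 1L) %/% 2L    # ceiling halving
    lev <- lev + 1L
  }
  lev
}

#' Tile-grid shape at a pyramid level
#'
#' @param grid a [TileGrid-class].
#' @param level pyramid level in `0..computeMaxLevel(rows, cols)`.
#' @return integer `(rows_L, cols_L)` = `ceiling(c(rows, cols) / 2^level)`.
#' @examples
#' levelGridShape(TileGrid(8192, 8192), 1)  # 2 2
#' @export
levelGridShape <- function(grid, level) {
  level <- as.integer(level)
  maxLev <- computeMaxLevel(grid@rows, grid@cols)
  if (is.na(level) || level < 0L || level > maxLev)
    stop(sprintf("level must be in [0, %d]", maxLev))
  as.integer(ceiling(c(grid@rows, grid@cols) / 2^level))
}

#' Partition one layer image into level-0 tiles
#'
#' Cuts the image into the fixed-size blocks of `grid`, row-major. Tiles
#' overhanging the right/bottom edge are padded with 0 (black) to the full
#' tile size, so every tile has identical shape.
#'
#' @param image integer matrix `(layerHeight, layerWidth)`, values 0..255;
#'   indexed `image[y + 1, x + 1]`.
#' @param grid a [TileGrid-class] matching the image dimensions.
#' @param layer 0-based layer index stamped into the tile keys.
#' @return named list of [Tile-class] (names are key strings), row-major,
#'   length `rows * cols`.
#' @export
partitionLayer <- function(image, grid, layer = 0L) {
  if (nrow(image) != grid@layerHeight || ncol(image) != grid@layerWidth)
    stop(sprintf("image is %dx%d but grid expects %dx%d (height x width)",
                 nrow(image), ncol(image), grid@layerHeight, grid@layerWidth))
  storage.mode(image) <- "integer"
  th <- grid@tileH; tw <- grid@tileW
  out <- vector("list", grid@rows * grid@cols)
  nms <- character(length(out))
  i <- 0L
  for (r in seq_len(grid@rows) - 1L) {
    for (cc in seq_len(grid@cols) - 1L) {
      px <- matrix(0L, th, tw)
      yr <- (r * th + 1L):min((r + 1L) * th, grid@layerHeight)
      xr <- (cc * tw + 1L):min((cc + 1L) * tw, grid@layerWidth)
      px[seq_along(yr), seq_along(xr)] <- image[yr, xr]
      key <- TileKey(layer, r, cc, 0L)
      i <- i + 1L
      out[[i]] <- Tile(key, px)
      nms[i] <- formatTileKey(key)
    }
  }
  names(out) <- nms
  out
}

#' Stitch tiles of one level back into a mosaic
#'
#' Inverse of [partitionLayer()] (after cropping padding): assembles the
#' row-major tile set of one layer/level into a single matrix of
#' `rows_L * tileH` x `cols_L * tileW` pixels. Missing tiles are treated
#' as all-zero.
#'
#' @param tiles list of [Tile-class] from a single layer and level.
#' @param grid the volume's [TileGrid-class].
#' @param crop if `TRUE`, crop to the level's layer extent
#'   (`ceiling(layer dims / 2^level)`), removing edge padding.
#' @return integer matrix.
#' @export
stitchTiles <- function(tiles, grid, crop = TRUE) {
  if (!length(tiles)) stop("no tiles to stitch")
  lev <- unique(vapply(tiles, function(t) t@key@level, integer(1)))
  lay <- unique(vapply(tiles, function(t) t@key@layer, integer(1)))
  if (length(lev) != 1L || length(lay) != 1L)
    stop("tiles must come from a single layer and level")
  shp <- levelGridShape(grid, lev)
  th <- grid@tileH; tw <- grid@tileW
  out <- matrix(0L, shp[1] * th, shp[2] * tw)
  for (t in tiles) {
    r <- t@key@row; cc <- t@key@col
    out[(r * th + 1L):((r + 1L) * th), (cc * tw + 1L):((cc + 1L) * tw)] <-
      t@pixels
  }
  if (crop) {
    hL <- as.integer(ceiling(grid@layerHeight / 2^lev))
    wL <- as.integer(ceiling(grid@layerWidth / 2^lev))
    out <- out[seq_len(hL), seq_len(wL), drop = FALSE]
  }
  out
}

# 2x2 box mean with round-half-up, exact in integer arithmetic:
# floor((sum of the four pixels + 2) / 4). Input dims must be even.
boxDownsample2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h %% 2L || w %% 2L) stop("box downsample needs even dimensions")
  oi <- seq(1L, h, 2L); oj <- seq(1L, w, 2L)
  s <- m[oi, oj, drop = FALSE] + m[oi + 1L, oj, drop = FALSE] +
    m[oi, oj + 1L, drop = FALSE] + m[oi + 1L, oj + 1L, drop = FALSE]
  s <- (s + 2L) %/% 4L
  storage.mode(s) <- "integer"
  s
}

# Repeated 2x box reduction: one call per level.
boxDownsampleBy <- function(m, levels) {
  for (i in seq_len(levels)) m <- boxDownsample2(m)
  m
}

#' Downsample a 2 x 2 tile quad to one next-level tile
#'
#' The pyramid construction step: four neighboring level-L tiles at
#' positions `(2r, 2c), (2r, 2c+1), (2r+1, 2c), (2r+1, 2c+1)` are placed
#' in a `2*tileH x 2*tileW` mosaic, box-downsampled by 2 (2 x 2 mean,
#' round half up), and returned as the single level-L+1 tile at `(r, c)`.
#' Quadrants absent at the grid edge are treated as all-zero, so tile size
#' is unchanged across levels and the tile count shrinks instead.
#'
#' @param tl top-left tile (required).
#' @param tr,bl,br the other quadrants, or `NULL` at grid edges.
#' @return a [Tile-class] at level `L + 1`, position `(r, c)`.
#' @export
downsampleQuad <- function(tl, tr = NULL, bl = NULL, br = NULL) {
  quads <- Filter(Negate(is.null), list(tl = tl, tr = tr, bl = bl, br = br))
  levs <- vapply(quads, function(t) t@key@level, integer(1))
  lays <- vapply(quads, function(t) t@key@layer, integer(1))
  if (length(unique(levs)) != 1L || length(unique(lays)) != 1L)
    stop("quad tiles must share one level and one layer")
  r2 <- tl@key@row; c2 <- tl@key@col
  if (r2 %% 2L || c2 %% 2L)
    stop("top-left quad tile must sit at even (row, col)")
  expect <- list(tl = c(r2, c2), tr = c(r2, c2 + 1L),
                 bl = c(r2 + 1L, c2), br = c(r2 + 1L, c2 + 1L))
  for (q in names(quads)) {
    k <- quads[[q]]@key
    if (k@row != expect[[q]][1] || k@col != expect[[q]][2])
      stop(sprintf("%s tile at (%d, %d); expected (%d, %d)",
                   q, k@row, k@col, expect[[q]][1], expect[[q]][2]))
  }
  th <- nrow(tl@pixels); tw <- ncol(tl@pixels)
  mosaic <- matrix(0L, 2L * th, 2L * tw)
  mosaic[seq_len(th), seq_len(tw)] <- tl@pixels
  if (!is.null(tr)) mosaic[seq_len(th), tw + seq_len(tw)] <- tr@pixels
  if (!is.null(bl)) mosaic[th + seq_len(th), seq_len(tw)] <- bl@pixels
  if (!is.null(br)) mosaic[th + seq_len(th), tw + seq_len(tw)] <- br@pixels
  Tile(TileKey(tl@key@layer, r2 %/% 2L, c2 %/% 2L, tl@key@level + 1L),
       boxDownsample2(mosaic))
}

#' Build the full multiresolution pyramid
#'
#' From a complete level-0 tiling (one or more layers), constructs every
#' tile of levels `1..maxLevel` by repeated quad downsampling
#' ([downsampleQuad()]). At each level the tile pixel size stays fixed and
#' the grid halves (ceiling), so the top level is a single tile per layer.
#'
#' @param tiles list of level-0 [Tile-class] objects (any number of layers;
#'   each layer must be complete).
#' @param meta the volume's [VolumeMetadata-class].
#' @return named list of all tiles, levels `0..maxLevel`, keyed by key
#'   string.
#' @export
buildPyramid <- function(tiles, meta) {
  grid <- meta@grid
  layers <- sort(unique(vapply(tiles, function(t) t@key@layer, integer(1))))
  out <- list()
  for (lay in layers) {
    lt <- Filter(function(t) t@key@layer == lay && t@key@level == 0L, tiles)
    byPos <- new.env(parent = emptyenv())
    for (t in lt) assign(sprintf("%d_%d", t@key@row, t@key@col), t, byPos)
    for (r in seq_len(grid@rows) - 1L)
      for (cc in seq_len(grid@cols) - 1L)
        if (!exists(sprintf("%d_%d", r, cc), byPos, inherits = FALSE))
          stop(sprintf("missing level-0 tile (layer %d, row %d, col %d)",
                       lay, r, cc))
    for (t in lt) out[[formatTileKey(t@key)]] <- t
    cur <- byPos
    curShape <- levelGridShape(grid, 0L)
    for (lev in seq_len(meta@maxLevel)) {
      nxt <- new.env(parent = emptyenv())
      nxtShape <- levelGridShape(grid, lev)
      getq <- function(r, cc) {
        if (r >= curShape[1] || cc >= curShape[2]) return(NULL)
        get(sprintf("%d_%d", r, cc), cur, inherits = FALSE)
      }
      for (r in seq_len(nxtShape[1]) - 1L) {
        for (cc in seq_len(nxtShape[2]) - 1L) {
          t <- downsampleQuad(getq(2L * r, 2L * cc),
                              getq(2L * r, 2L * cc + 1L),
                              getq(2L * r + 1L, 2L * cc),
                              getq(2L * r + 1L, 2L * cc + 1L))
          assign(sprintf("%d_%d", r, cc), t, nxt)
          out[[formatTileKey(t@key)]] <- t
        }
      }
      cur <- nxt
      curShape <- nxtShape
    }
  }
  out
}

#' Mipmap-style downsampling (Method I), for comparison
#'
#' The alternative pyramid scheme in which the tile count stays fixed and
#' each tile's pixel dimensions halve per level (area shrinks 4x per
#' level). Kept for parity with the quad scheme used by the store: the
#' level-1 mipmap of a tile equals that tile's quadrant content of the
#' quad-downsampled mosaic before re-tiling, because both use the same box
#' filter. Not used for storage.
#'
#' @param tile a [Tile-class].
#' @param level how many halvings to apply (0 = identity).
#' @return a [Tile-class] whose pixels are `2^level`-fold smaller per side.
#' @export
downsampleMethod1 <- function(tile, level) {
  level <- as.integer(level)
  if (level < 0L) stop("level must be >= 0")
  if (level == 0L) return(tile)
  px <- tile@pixels
  for (i in seq_len(level)) {
    if (nrow(px) < 2L || ncol(px) < 2L)
      stop("tile too small to downsample (needs >= 2x2 pixels)")
    px <- boxDownsample2(px)
  }
  Tile(TileKey(tile@key@layer, tile@key@row, tile@key@col, level), px)
}

#' Expected tile count per layer across all pyramid levels
#'
#' `sum over L of rows_L * cols_L`; for a `2^k x 2^k` level-0 grid this is
#' `(4^(k+1) - 1) / 3`.
#'
#' @param grid a [TileGrid-class].
#' @return named integer vector of per-level tile counts (names "0", "1",
#'   ...); `sum()` gives the total.
#' @export
pyramidTileCounts <- function(grid) {
  maxLev <- computeMaxLevel(grid@rows, grid@cols)
  counts <- vapply(0:maxLev, function(l) prod(levelGridShape(grid, l)),
                   numeric(1))
  names(counts) <- as.character(0:maxLev)
  as.integer(counts)
}

#' Dataset arithmetic for an uncompressed serial-section volume
#'
#' Computes the raw storage volume and the physical extent of a stack from
#' its printed acquisition parameters: pixel dimensions, layer count, bit
#' depth and voxel size.
#'
#' @param widthPx,heightPx layer dimensions in pixels.
#' @param nLayers number of serial sections.
#' @param bitDepth bits per pixel.
#' @param voxelSize numeric (x, y, z) in nanometres.
#' @return list with `uncompressedBytes`, `uncompressedTB` (binary,
#'   bytes / 2^40), `extentMmX`, `extentMmY` (mm) and `extentUmZ` (um).
#' @examples
#' info <- datasetInfo(470000, 425000, 50)
#' round(info$uncompressedTB, 2)  # 9.08
#' @export
datasetInfo <- function(widthPx, heightPx, nLayers, bitDepth = 8,
                        voxelSize = c(5, 5, 50)) {
  bytes <- as.numeric(widthPx) * heightPx * nLayers * (bitDepth / 8)
  list(
    uncompressedBytes = bytes,
    uncompressedTB = bytes / 2^40,
    extentMmX = widthPx * voxelSize[1] * 1e-6,
    extentMmY = heightPx * voxelSize[2] * 1e-6,
    extentUmZ = nLayers * voxelSize[3] * 1e-3
  )
}
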