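#' Display magnitude to pyramid level
#'
#' Buckets a display scale (fraction of native resolution) into a pyramid
#' level: magnitude above 1/2 maps to level 0; `2^-n < magnitude <= 2^-n+1`
#' maps to level `n - 1` (the boundary magnitude exactly `2^-n` maps to
#' level `n`); magnitudes at or below `2^-maxLevel` clamp to `maxLevel`,
#' and magnitudes above 1 clamp to level 0. Implemented by exact
#' power-of-two threshold comparisons (repeated halving of 1), not a
#' floating logarithm, so the bucket boundaries are hit exactly.
#'
#' @param magnitude display scale, > 0.
#' @param maxLevel the volume's top pyramid level.
#' @return integer level in `0..maxLevel`.
#' @examples
#' magnitudeToLevel(0.6, 8)   # 0
#' magnitudeToLevel(0.5, 8)   # 1
#' magnitudeToLevel(0.10, 8)  # 3
#' @export
magnitudeToLevel <- function(magnitude, maxLevel) {
  if (!is.numeric(magnitude) || is.na(magnitude) || magnitude <= 0)
    stop("magnitude must be > 0")
  maxLevel <- as.integer(maxLevel)
  lev <- 0L
  thr <- 0.5                       # exact binary fraction 2^-(lev+1)
  while (lev < maxLevel && magnitude <= thr) {
    lev <- lev + 1L
    thr <- thr / 2
  }
  lev
}

# Fixed-width key fields: lexicographic order on the strings equals
# (layer, row, col, level) tuple order, which is what makes prefix scans
# spatially meaningful. 5 digits cover grids up to 99999 tiles per side.
.keyFmt <- "%05d_%05d_%05d_%02d"
.blockFmt <- "%05d_%05d_%05d"

#' Format a tile key as its store row key
#'
#' `"layer_row_col_level"` with zero-padded fixed-width decimal fields
#' (5/5/5/2 digits), so sorting key strings byte-wise equals sorting the
#' index tuples.
#'
#' @param key a [TileKey-class].
#' @return key string, e.g. `"00003_00012_00007_02"`.
#' @export
formatTileKey <- function(key) {
  sprintf(.keyFmt, key@layer, key@row, key@col, key@level)
}

#' Parse a tile key string
#'
#' Inverse of [formatTileKey()]. Accepts unpadded digits too.
#'
#' @param s key string `"layer_row_col_level"`.
#' @return a [TileKey-class].
#' @export
parseTileKey <- function(s) {
  parts <- strsplit(s, "_", fixed = TRUE)[[1]]
  fields <- c("layer", "row", "col", "level")
  if (length(parts) != 4L)
    stop(sprintf("malformed tile key \"%s\": expected 4 fields (%s), got %d",
                 s, paste(fields, collapse = "_"), length(parts)))
  for (i in seq_along(parts))
    if (!grepl("^[0-9]+$", parts[i]))
      stop(sprintf("malformed tile key \"%s\": field \"%s\" (\"%s\") is not a nonnegative integer",
                   s, fields[i], parts[i]))
  v <- as.integer(parts)
  TileKey(v[1], v[2], v[3], v[4])
}

#' Format a segmentation block key prefix
#'
#' `"layer_row_col"` with the same fixed field widths as tile keys.
#' Primitive record keys are `"layer_row_col_id"`, so this string is the
#' prefix under which all primitives stored in that block scan out.
#'
#' @param layer,row,col 0-based indices.
#' @return block key prefix string.
#' @export
formatBlockKey <- function(layer, row, col) {
  sprintf(.blockFmt, as.integer(layer), as.integer(row), as.integer(col))
}

# Tile row/col span of a closed viewport rectangle (level pixel space):
# r1 = floor(y1/h), r2 = floor((y1+h1)/h), c1 = floor(x1/w),
# c2 = floor((x1+w1)/w), with r2/c2 clamped to the grid bounds.
# Returns NULL when the viewport lies entirely outside the grid.
viewportSpan <- function(vp, grid, level) {
  shp <- levelGridShape(grid, level)
  h <- grid@tileH; w <- grid@tileW
  r1 <- floor(vp@y1 / h); r2 <- min(floor((vp@y1 + vp@h1) / h), shp[1] - 1)
  c1 <- floor(vp@x1 / w); c2 <- min(floor((vp@x1 + vp@w1) / w), shp[2] - 1)
  if (r1 > r2 || c1 > c2) return(NULL)
  list(r1 = as.integer(r1), r2 = as.integer(r2),
       c1 = as.integer(c1), c2 = as.integer(c2), level = as.integer(level))
}

#' Tile keys covering a viewport
#'
#' The constant-time index computation: the magnitude picks the pyramid
#' level, the viewport corners divide by the tile size to give the start
#' and end tile row/column, and every `(row, col)` combination in that
#' span becomes a key. Cost is proportional to the number of returned
#' keys, never to the volume size. The end row/column are clamped to the
#' level's grid when the viewport overhangs the layer edge.
#'
#' @param vp a [Viewport-class] (coordinates in the selected level's pixel
#'   space).
#' @param grid the volume's [TileGrid-class].
#' @param maxLevel the volume's top pyramid level.
#' @param nLayers if supplied, the viewport's layer is validated against
#'   it.
#' @return list of [TileKey-class] in row-major order (possibly empty when
#'   the viewport lies wholly outside the layer).
#' @examples
#' g <- TileGrid(470000, 425000)
#' vp <- Viewport(1000, 1000, 4200, 1500, layer = 0, magnitude = 1)
#' length(viewportToTileKeys(vp, g, computeMaxLevel(g@rows, g@cols)))  # 6
#' @export
viewportToTileKeys <- function(vp, grid, maxLevel, nLayers = NULL) {
  validObject(vp)
  if (!is.null(nLayers) && (vp@layer < 0L || vp@layer >= nLayers))
    stop(sprintf("layer %d out of range [0, %d]", vp@layer, nLayers - 1L))
  level <- magnitudeToLevel(vp@magnitude, maxLevel)
  span <- viewportSpan(vp, grid, level)
  if (is.null(span)) return(list())
  keys <- list()
  for (r in span$r1:span$r2)
    for (cc in span$c1:span$c2)
      keys[[length(keys) + 1L]] <- TileKey(vp@layer, r, cc, level)
  keys
}
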