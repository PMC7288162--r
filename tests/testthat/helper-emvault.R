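# Shared fixtures and independent oracles, all built in code at test time.

randomImage <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# A small ingested volume: random layers, full pyramid in a memory store.
makeTestVolume <- function(w = 128L, h = 96L, tile = 32L, layers = 1L,
                           codec = CodecConfig("png")) {
  imgs <- lapply(seq_len(layers), function(i) randomImage(h, w))
  grid <- TileGrid(w, h, tileW = tile)
  meta <- VolumeMetadata(layers, grid, codec = codec@codec)
  store <- memoryBackend()
  ingestVolume(imgs, meta, store, codec)
  list(images = imgs, grid = grid, meta = meta, store = store, codec = codec)
}

# Independent whole-image box downsample: average non-overlapping
# 2^L x 2^L windows (zero-padded to a multiple of the window), round half
# up. Used as the oracle for the tile pyramid.
oracleBoxDownsample <- function(img, level) {
  f <- 2^level
  H <- ceiling(nrow(img) / f) * f
  W <- ceiling(ncol(img) / f) * f
  pad <- matrix(0, H, W)
  pad[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out <- matrix(0, H / f, W / f)
  for (i in seq_len(H / f))
    for (j in seq_len(W / f))
      out[i, j] <- mean(pad[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  floor(out + 0.5)
}

# Exhaustive rectangle-intersection oracle for viewport indexing: every
# tile of the level grid whose half-open rectangle [rh, (r+1)h) x
# [cw, (c+1)w) intersects the closed viewport rectangle. (Half-open tiles
# with a closed viewport is the convention the floor formulas encode: a
# viewport edge touching a tile boundary pulls in the next tile on the
# right/bottom but not on the left/top.)
oracleViewportTiles <- function(vp, grid, level) {
  shp <- levelGridShape(grid, level)
  h <- grid@tileH; w <- grid@tileW
  hits <- list()
  for (r in seq_len(shp[1]) - 1L) {
    for (cc in seq_len(shp[2]) - 1L) {
      if (r * h <= vp@y1 + vp@h1 && (r + 1) * h > vp@y1 &&
          cc * w <= vp@x1 + vp@w1 && (cc + 1) * w > vp@x1)
        hits[[length(hits) + 1L]] <- c(r, cc)
    }
  }
  hits
}

keyTuples <- function(keys) {
  t(vapply(keys, function(k) c(k@layer, k@row, k@col, k@level), integer(4)))
}

# Blocks (level 0) whose rectangles intersect an axis-aligned bbox:
# brute-force loop, independent of blocksForPrimitive's arithmetic.
oracleBlocksForBBox <- function(xr, yr, grid) {
  hits <- list()
  for (r in seq_len(grid@rows) - 1L)
    for (cc in seq_len(grid@cols) - 1L) {
      bx <- c(cc * grid@tileW, (cc + 1) * grid@tileW - 1L)
      by <- c(r * grid@tileH, (r + 1) * grid@tileH - 1L)
      if (xr[1] <= bx[2] && xr[2] >= bx[1] && yr[1] <= by[2] && yr[2] >= by[1])
        hits[[length(hits) + 1L]] <- c(r, cc)
    }
  hits
}

# A blobby multi-label image: each label is a union of random discs, so
# extracted contours are fat, hole-free, and frequently block-crossing.
randomBlobImage <- function(h, w, nLabels, rmin = 4, rmax = 10) {
  lab <- matrix(0L, h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  for (k in seq_len(nLabels)) {
    nd <- sample(1:3, 1)
    cx <- runif(1, rmax, w - rmax); cy <- runif(1, rmax, h - rmax)
    for (d in seq_len(nd)) {
      r <- runif(1, rmin, rmax)
      dx <- runif(1, -r, r); dy <- runif(1, -r, r)
      mask <- (xs - cx - dx)^2 + (ys - cy - dy)^2 <= r^2
      lab[mask] <- k
    }
  }
  lab
}

# Square contour (axis-aligned) through pixel centers.
squareContour <- function(x0, y0, side) {
  cbind(x = c(x0, x0 + side, x0 + side, x0),
        y = c(y0, y0, y0 + side, y0 + side))
}

# Independent reimplementation of the cache's viewport ring distance, for
# checking eviction order: Chebyshev distance from the viewport tile span,
# plus the layer/level offset for off-plane entries.
keyRingDistanceForTest <- function(ks, state, grid, maxLevel) {
  k <- parseTileKey(ks)
  vp <- state@viewport
  lev <- magnitudeToLevel(vp@magnitude, maxLevel)
  h <- grid@tileH; w <- grid@tileW
  r1 <- floor(vp@y1 / h); r2 <- floor((vp@y1 + vp@h1) / h)
  c1 <- floor(vp@x1 / w); c2 <- floor((vp@x1 + vp@w1) / w)
  dr <- max(r1 - k@row, k@row - r2, 0)
  dc <- max(c1 - k@col, k@col - c2, 0)
  max(dr, dc) + abs(k@layer - vp@layer) + abs(k@level - lev)
}

# KV-backend contract conformance suite, run identically against every
# backend implementation.
expect_kv_contract <- function(factory) {
  be <- factory()
  v1 <- as.raw(c(1, 2, 3)); v2 <- as.raw(c(9, 9))
  kvPut(be, "aa_1", v1, attrs = list(object_id = "x"))
  kvPut(be, "aa_2", v2, attrs = list(object_id = "y"))
  kvPut(be, "ab_1", v1, attrs = list(object_id = "x"))
  expect_identical(kvGet(be, "aa_1"), v1)
  expect_null(kvGet(be, "zz"))
  kvPut(be, "aa_1", v2)                       # last write wins
  expect_identical(kvGet(be, "aa_1"), v2)
  kvPut(be, "aa_1", v1, attrs = list(object_id = "x"))
  scan <- kvPrefixScan(be, "aa_")
  expect_identical(vapply(scan, `[[`, "", "key"), c("aa_1", "aa_2"))
  expect_identical(scan[[1]]$value, v1)
  expect_length(kvPrefixScan(be, "nope"), 0L)
  hits <- kvFilterScan(be, "object_id", "x")
  expect_setequal(vapply(hits, `[[`, "", "key"), c("aa_1", "ab_1"))
  expect_length(kvFilterScan(be, "object_id", "zz"), 0L)
  # lexicographic ordering over a shuffled key set
  keys <- sprintf("k%03d", sample(1:50))
  for (k in keys) kvPut(be, k, as.raw(1))
  expect_identical(kvKeys(be), sort(c("aa_1", "aa_2", "ab_1", keys)))
  kvDelete(be, "aa_1")
  expect_null(kvGet(be, "aa_1"))
  invisible(be)
}
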