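#' @include AllClasses.R codec.R
NULL

# Client-side three-level tile cache: L1 holds decoded pixels in memory,
# L2 holds encoded bytes on local disk, L3 is the remote store (any
# callable mapping a key string to encoded bytes). Misses promote
# downward-fetched tiles into both lower levels; prefetch pulls tiles
# near the viewport, preferring the browsing direction; eviction drops
# the tiles farthest from the current viewport first.

#' Cache configuration
#'
#' @slot l1Capacity,l2Capacity maximum tile counts for the memory and
#'   disk levels (0 disables the level).
#' @slot prefetchBudget maximum tiles fetched per prefetch step.
#' @slot prefetchRadius square-ring radius (in tiles) around the viewport
#'   span considered for prefetch.
#' @slot directionWeight weight of browsing-direction alignment in the
#'   prefetch priority (0 = distance only).
#' @slot neighborLayerDepth,neighborLevelDepth how many adjacent layers /
#'   pyramid levels are prefetched at the viewport's own tile positions.
#' @export
setClass("CacheConfig", representation(
  l1Capacity = "integer", l2Capacity = "integer",
  prefetchBudget = "integer", prefetchRadius = "integer",
  directionWeight = "numeric",
  neighborLayerDepth = "integer", neighborLevelDepth = "integer"
))

setValidity("CacheConfig", function(object) {
  msg <- character()
  if (object@l1Capacity < 0L || object@l2Capacity < 0L)
    msg <- c(msg, "capacities must be >= 0")
  if (object@prefetchBudget < 0L) msg <- c(msg, "prefetchBudget must be >= 0")
  if (object@prefetchRadius < 1L) msg <- c(msg, "prefetchRadius must be >= 1")
  if (object@directionWeight < 0) msg <- c(msg, "directionWeight must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CacheConfig
#' @param l1Capacity,l2Capacity level capacities in tiles.
#' @param prefetchBudget tiles per prefetch step.
#' @param prefetchRadius prefetch ring radius in tiles.
#' @param directionWeight direction-alignment weight (default 0.5).
#' @param neighborLayerDepth,neighborLevelDepth cross-layer / cross-level
#'   prefetch depths (default 1 each).
#' @return a [CacheConfig-class].
#' @export
CacheConfig <- function(l1Capacity = 64L, l2Capacity = 256L,
                        prefetchBudget = 16L, prefetchRadius = 2L,
                        directionWeight = 0.5,
                        neighborLayerDepth = 1L, neighborLevelDepth = 1L) {
  new("CacheConfig", l1Capacity = as.integer(l1Capacity),
      l2Capacity = as.integer(l2Capacity),
      prefetchBudget = as.integer(prefetchBudget),
      prefetchRadius = as.integer(prefetchRadius),
      directionWeight = as.numeric(directionWeight),
      neighborLayerDepth = as.integer(neighborLayerDepth),
      neighborLevelDepth = as.integer(neighborLevelDepth))
}

#' Browse state: viewport plus pan direction
#'
#' @slot viewport the current [Viewport-class].
#' @slot direction unit 2-vector of recent pan motion (`c(0, 0)` when
#'   stationary); x grows rightward, y downward.
#' @export
setClass("BrowseState",
         representation(viewport = "Viewport", direction = "numeric"))

setValidity("BrowseState", function(object) {
  n <- sqrt(sum(object@direction^2))
  if (length(object@direction) != 2L) "direction must be a 2-vector"
  else if (n > 1e-9 && abs(n - 1) > 1e-6) "direction must have norm 1 or 0"
  else TRUE
})

#' Construct a BrowseState
#' @param viewport a [Viewport-class].
#' @param direction pan direction; normalized unless zero.
#' @return a [BrowseState-class].
#' @export
BrowseState <- function(viewport, direction = c(0, 0)) {
  n <- sqrt(sum(direction^2))
  if (n > 1e-9) direction <- direction / n
  new("BrowseState", viewport = viewport, direction = as.numeric(direction))
}

#' Three-level tile cache
#'
#' Created with [newTileCache()]. Internal state (entries, LRU clocks,
#' hit counters) lives in an environment slot; the L2 level is a
#' directory of per-key encoded-tile files plus a JSON manifest, safely
#' rebuildable by deleting the directory.
#'
#' @slot config a [CacheConfig-class].
#' @slot codec the [CodecConfig-class] of the remote bytes.
#' @slot l2Dir the disk-cache directory.
#' @slot state internal environment.
#' @export
setClass("TileCache", representation(
  config = "CacheConfig", codec = "CodecConfig",
  l2Dir = "character", state = "environment"
))

#' Create a tile cache
#'
#' @param config a [CacheConfig-class].
#' @param codec the [CodecConfig-class] the remote serves bytes in.
#' @param l2Dir disk-cache directory (a fresh temporary directory by
#'   default).
#' @return a [TileCache-class].
#' @export
newTileCache <- function(config = CacheConfig(), codec = CodecConfig(),
                         l2Dir = tempfile("emvault-l2-")) {
  dir.create(l2Dir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$l1 <- new.env(parent = emptyenv())      # key -> pixels
  st$l2 <- new.env(parent = emptyenv())      # key -> TRUE (file on disk)
  st$lru1 <- new.env(parent = emptyenv())    # key -> clock of last use
  st$lru2 <- new.env(parent = emptyenv())
  st$clock <- 0L
  st$l1Hits <- 0L; st$l2Hits <- 0L; st$remoteFetches <- 0L
  st$lastState <- NULL
  new("TileCache", config = config, codec = codec,
      l2Dir = normalizePath(l2Dir), state = st)
}

setMethod("show", "TileCache", function(object) {
  st <- object@state
  cat(sprintf(
    "TileCache: L1 %d/%d tiles, L2 %d/%d tiles (%s)\n  hits L1 %d, L2 %d; remote fetches %d\n",
    length(ls(st$l1)), object@config@l1Capacity,
    length(ls(st$l2)), object@config@l2Capacity, object@l2Dir,
    st$l1Hits, st$l2Hits, st$remoteFetches))
})

#' Cache statistics
#' @param cache a [TileCache-class].
#' @return list with hit counters, remote fetch count and current level
#'   sizes.
#' @export
cacheStats <- function(cache) {
  st <- cache@state
  list(l1Hits = st$l1Hits, l2Hits = st$l2Hits,
       remoteFetches = st$remoteFetches,
       l1Size = length(ls(st$l1)), l2Size = length(ls(st$l2)))
}

l2Path <- function(cache, keyStr) file.path(cache@l2Dir, paste0(keyStr, ".bin"))

writeL2Manifest <- function(cache) {
  keys <- sortKeysC(ls(cache@state$l2, all.names = TRUE))
  writeLines(jsonlite::toJSON(list(codec = cache@codec@codec, keys = keys)),
             file.path(cache@l2Dir, "manifest.json"))
}

touch <- function(cache, lru, keyStr) {
  st <- cache@state
  st$clock <- st$clock + 1L
  assign(keyStr, st$clock, envir = st[[lru]])
}

insertL2 <- function(cache, keyStr, bytes) {
  writeBin(bytes, l2Path(cache, keyStr))
  assign(keyStr, TRUE, envir = cache@state$l2)
  touch(cache, "lru2", keyStr)
}

insertL1 <- function(cache, keyStr, pixels) {
  assign(keyStr, pixels, envir = cache@state$l1)
  touch(cache, "lru1", keyStr)
}

dropEntry <- function(cache, level, keyStr) {
  st <- cache@state
  if (level == 1L) {
    if (exists(keyStr, st$l1, inherits = FALSE)) rm(list = keyStr, envir = st$l1)
    if (exists(keyStr, st$lru1, inherits = FALSE)) rm(list = keyStr, envir = st$lru1)
  } else {
    if (exists(keyStr, st$l2, inherits = FALSE)) rm(list = keyStr, envir = st$l2)
    if (exists(keyStr, st$lru2, inherits = FALSE)) rm(list = keyStr, envir = st$lru2)
    unlink(l2Path(cache, keyStr))
  }
}

# Chebyshev ring distance of a tile key from the browse viewport's tile
# span; keys on other layers or levels add |dlayer| + |dlevel| so
# same-plane tiles always sort nearer.
keyRingDistance <- function(keyStr, state, grid, maxLevel) {
  k <- parseTileKey(keyStr)
  vp <- state@viewport
  level <- magnitudeToLevel(vp@magnitude, maxLevel)
  span <- viewportSpan(vp, grid, level)
  if (is.null(span)) return(Inf)
  dr <- max(span$r1 - k@row, k@row - span$r2, 0L)
  dc <- max(span$c1 - k@col, k@col - span$c2, 0L)
  max(dr, dc) + abs(k@layer - vp@layer) + abs(k@level - level)
}

enforceCapacity <- function(cache, grid = NULL, maxLevel = NULL) {
  st <- cache@state
  state <- st$lastState
  for (lv in c(1L, 2L)) {
    env <- if (lv == 1L) st$l1 else st$l2
    lru <- if (lv == 1L) st$lru1 else st$lru2
    cap <- if (lv == 1L) cache@config@l1Capacity else cache@config@l2Capacity
    while (length(ls(env, all.names = TRUE)) > cap) {
      keys <- ls(env, all.names = TRUE)
      dist <- if (!is.null(state) && !is.null(grid))
        vapply(keys, keyRingDistance, numeric(1), state = state,
               grid = grid, maxLevel = maxLevel)
      else rep(0, length(keys))
      stamp <- vapply(keys, function(k)
        if (exists(k, lru, inherits = FALSE)) get(k, lru) else 0L, numeric(1))
      victim <- keys[order(-dist, stamp)][1]   # farthest first, then LRU
      dropEntry(cache, lv, victim)
    }
  }
}

#' Get one tile through the cache
#'
#' L1 hit returns directly; L1 miss / L2 hit decodes from disk, promotes
#' to L1 and returns; a full miss fetches from the remote, inserts the
#' bytes into L2 and the decoded pixels into L1, and returns. Whatever
#' level serves the request, the returned pixels are identical to a
#' direct remote fetch (cache transparency). Remote failures (errors or a
#' `NULL` return) propagate with the key named; stale data never masks
#' them.
#'
#' @param cache a [TileCache-class].
#' @param key a [TileKey-class] or key string.
#' @param remote function(key string) -> raw encoded bytes.
#' @param grid,maxLevel volume geometry, used only to rank evictions when
#'   an insert overflows a level (optional).
#' @return integer pixel matrix.
#' @export
cacheGet <- function(cache, key, remote, grid = NULL, maxLevel = NULL) {
  ks <- if (is.character(key)) key else formatTileKey(key)
  st <- cache@state
  if (exists(ks, st$l1, inherits = FALSE)) {
    st$l1Hits <- st$l1Hits + 1L
    touch(cache, "lru1", ks)
    return(get(ks, st$l1))
  }
  if (exists(ks, st$l2, inherits = FALSE)) {
    st$l2Hits <- st$l2Hits + 1L
    p <- l2Path(cache, ks)
    px <- decodeTile(readBin(p, "raw", n = file.size(p)), cache@codec)
    touch(cache, "lru2", ks)
    insertL1(cache, ks, px)
    enforceCapacity(cache, grid, maxLevel)
    return(px)
  }
  bytes <- tryCatch(remote(ks), error = function(e)
    stop(sprintf("remote fetch failed for tile %s: %s", ks,
                 conditionMessage(e))))
  if (is.null(bytes))
    stop(sprintf("remote fetch failed for tile %s: remote returned no data", ks))
  st$remoteFetches <- st$remoteFetches + 1L
  px <- decodeTile(bytes, cache@codec)
  insertL2(cache, ks, bytes)
  insertL1(cache, ks, px)
  enforceCapacity(cache, grid, maxLevel)
  writeL2Manifest(cache)
  px
}

#' Direction-aware prefetch plan
#'
#' Candidate tiles are the square rings around the viewport's tile span
#' out to `prefetchRadius`, plus the span's own positions on the
#' `neighborLayerDepth` adjacent layers and `neighborLevelDepth` adjacent
#' pyramid levels. Each candidate is scored
#' `ringDistance - directionWeight * alignment` (alignment = normalized
#' dot product of the tile-center offset with the pan direction; for
#' cross-layer/level candidates the layer/level distance is added), so
#' nearer tiles come first and, under panning, tiles ahead of the motion
#' precede tiles behind it. Ties break row-major. Already-cached keys are
#' excluded and the plan is truncated to `prefetchBudget`.
#'
#' @param state a [BrowseState-class].
#' @param grid the volume's [TileGrid-class].
#' @param maxLevel the volume's top pyramid level.
#' @param cfg a [CacheConfig-class].
#' @param nLayers layer count (bounds cross-layer candidates); `Inf` to
#'   skip the bound.
#' @param cachedKeys character vector of key strings to exclude.
#' @return list of [TileKey-class], highest priority first, length <=
#'   `prefetchBudget`.
#' @export
prefetchPlan <- function(state, grid, maxLevel, cfg = CacheConfig(),
                         nLayers = Inf, cachedKeys = character()) {
  vp <- state@viewport
  level <- magnitudeToLevel(vp@magnitude, maxLevel)
  span <- viewportSpan(vp, grid, level)
  if (is.null(span)) return(list())
  shp <- levelGridShape(grid, level)
  ctr <- c((span$c1 + span$c2) / 2, (span$r1 + span$r2) / 2)
  cand <- list()
  addCand <- function(layer, r, cc, lev, extra) {
    shpL <- levelGridShape(grid, lev)
    if (r < 0L || cc < 0L || r >= shpL[1] || cc >= shpL[2]) return()
    if (layer < 0L || layer >= nLayers) return()
    dr <- max(span$r1 - r, r - span$r2, 0)
    dc <- max(span$c1 - cc, cc - span$c2, 0)
    ring <- max(dr, dc)
    off <- c(cc - ctr[1], r - ctr[2])
    nrm <- sqrt(sum(off^2))
    align <- if (nrm > 1e-9 && sum(state@direction^2) > 0)
      sum(off * state@direction) / nrm else 0
    cand[[length(cand) + 1L]] <<- list(
      key = TileKey(layer, r, cc, lev),
      score = ring + extra - cfg@directionWeight * align,
      r = r, cc = cc, layer = layer, lev = lev)
  }
  for (ring in seq_len(cfg@prefetchRadius)) {
    r0 <- span$r1 - ring; r1 <- span$r2 + ring
    c0 <- span$c1 - ring; c1 <- span$c2 + ring
    for (cc in c0:c1) { addCand(vp@layer, r0, cc, level, 0); addCand(vp@layer, r1, cc, level, 0) }
    if (r1 - r0 > 1L)
      for (r in (r0 + 1L):(r1 - 1L)) { addCand(vp@layer, r, c0, level, 0); addCand(vp@layer, r, c1, level, 0) }
  }
  for (dlay in seq_len(cfg@neighborLayerDepth))
    for (s in c(-1L, 1L))
      for (r in span$r1:span$r2)
        for (cc in span$c1:span$c2)
          addCand(vp@layer + s * dlay, r, cc, level, dlay)
  for (dlev in seq_len(cfg@neighborLevelDepth))
    for (s in c(-1L, 1L)) {
      lev2 <- level + s * dlev
      if (lev2 < 0L || lev2 > maxLevel) next
      sc <- 2^(-s * dlev)    # span positions rescale with the level
      for (r in unique(floor(span$r1 * sc):floor(span$r2 * sc)))
        for (cc in unique(floor(span$c1 * sc):floor(span$c2 * sc)))
          addCand(vp@layer, as.integer(r), as.integer(cc), lev2, dlev)
  }
  if (!length(cand)) return(list())
  keyStrs <- vapply(cand, function(x) formatTileKey(x$key), character(1))
  keep <- !duplicated(keyStrs) & !(keyStrs %in% cachedKeys)
  cand <- cand[keep]
  if (!length(cand)) return(list())
  score <- vapply(cand, `[[`, numeric(1), "score")
  r <- vapply(cand, `[[`, numeric(1), "r")
  cc <- vapply(cand, `[[`, numeric(1), "cc")
  lay <- vapply(cand, `[[`, numeric(1), "layer")
  lev <- vapply(cand, `[[`, numeric(1), "lev")
  ord <- order(score, r, cc, lay, lev)
  lapply(cand[ord][seq_len(min(cfg@prefetchBudget, length(cand)))],
         `[[`, "key")
}

#' Evict tiles far from the current viewport
#'
#' While a cache level exceeds its capacity, the entry with the greatest
#' ring distance from the current viewport span is dropped (ties by least
#' recent use). Entries inside the span are only ever evicted once no
#' outside entry remains.
#'
#' @param cache a [TileCache-class].
#' @param state the current [BrowseState-class].
#' @param grid the volume's [TileGrid-class].
#' @param maxLevel the volume's top pyramid level.
#' @return report: per-level character vectors of evicted key strings.
#' @export
evictFar <- function(cache, state, grid, maxLevel) {
  st <- cache@state
  st$lastState <- state
  before1 <- ls(st$l1, all.names = TRUE); before2 <- ls(st$l2, all.names = TRUE)
  enforceCapacity(cache, grid, maxLevel)
  writeL2Manifest(cache)
  list(l1Evicted = setdiff(before1, ls(st$l1, all.names = TRUE)),
       l2Evicted = setdiff(before2, ls(st$l2, all.names = TRUE)))
}

#' Replay a browse trajectory through the cache
#'
#' For each step: resolve the viewport's tile keys, serve them through
#' [cacheGet()] (counting per-level hits), optionally execute the
#' prefetch plan, then evict far tiles. Hit rates count user-requested
#' tiles only; `remoteFetches` counts every remote transfer including
#' prefetch.
#'
#' @param trajectory list of [BrowseState-class].
#' @param cache a [TileCache-class].
#' @param remote function(key string) -> raw bytes.
#' @param grid the volume's [TileGrid-class].
#' @param maxLevel the volume's top pyramid level.
#' @param nLayers layer count for prefetch bounds.
#' @param prefetch run the prefetch plan after each step.
#' @return session metrics: per-step and overall hit rates, remote fetch
#'   count, peak level sizes.
#' @export
browseSession <- function(trajectory, cache, remote, grid, maxLevel,
                          nLayers = Inf, prefetch = TRUE) {
  cfg <- cache@config
  st <- cache@state
  stepHit <- numeric(length(trajectory))
  stepRequests <- integer(length(trajectory))
  stepHits1 <- integer(length(trajectory)); stepHits2 <- integer(length(trajectory))
  peak1 <- 0L; peak2 <- 0L
  for (i in seq_along(trajectory)) {
    state <- trajectory[[i]]
    st$lastState <- state
    keys <- viewportToTileKeys(state@viewport, grid, maxLevel)
    h1a <- st$l1Hits; h2a <- st$l2Hits
    for (k in keys) cacheGet(cache, k, remote, grid, maxLevel)
    stepRequests[i] <- length(keys)
    stepHits1[i] <- st$l1Hits - h1a
    stepHits2[i] <- st$l2Hits - h2a
    stepHit[i] <- if (length(keys))
      (stepHits1[i] + stepHits2[i]) / length(keys) else NA_real_
    if (prefetch && cfg@prefetchBudget > 0L) {
      cached <- c(ls(st$l1, all.names = TRUE), ls(st$l2, all.names = TRUE))
      plan <- prefetchPlan(state, grid, maxLevel, cfg, nLayers, cached)
      for (k in plan) cacheGet(cache, k, remote, grid, maxLevel)
    }
    evictFar(cache, state, grid, maxLevel)
    peak1 <- max(peak1, length(ls(st$l1))); peak2 <- max(peak2, length(ls(st$l2)))
  }
  total <- sum(stepRequests)
  list(
    steps = length(trajectory),
    requests = total,
    l1HitRate = if (total) sum(stepHits1) / total else NA_real_,
    l2HitRate = if (total) sum(stepHits2) / total else NA_real_,
    hitRate = if (total) sum(stepHits1 + stepHits2) / total else NA_real_,
    stepHitRates = stepHit,
    stepRequests = stepRequests,
    stepHits = stepHits1 + stepHits2,
    remoteFetches = st$remoteFetches,
    peakL1 = peak1, peakL2 = peak2)
}
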