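# A tiny remote: serves PNG-encoded random tiles for any key, counting
# calls. Deterministic per key so transparency is checkable.
makeRemote <- function(grid, codec = CodecConfig("png")) {
  served <- new.env(parent = emptyenv())
  calls <- new.env(parent = emptyenv()); calls$n <- 0L
  fetch <- function(ks) {
    calls$n <- calls$n + 1L
    if (!exists(ks, served, inherits = FALSE)) {
      px <- matrix(sample(0:255, grid@tileH * grid@tileW, TRUE),
                   grid@tileH, grid@tileW)
      assign(ks, encodeTile(px, codec), served)
    }
    get(ks, served)
  }
  list(fetch = fetch, calls = calls,
       direct = function(ks) decodeTile(fetch(ks), codec))
}

test_that("cache promotes through the levels and stays transparent", {
  g <- TileGrid(8 * 16, 8 * 16, 16)
  rm <- makeRemote(g)
  cache <- newTileCache(CacheConfig(l1Capacity = 4, l2Capacity = 32),
                        CodecConfig("png"))
  k <- TileKey(0, 2, 3, 0)
  cold <- cacheGet(cache, k, rm$fetch)
  warm <- cacheGet(cache, k, rm$fetch)
  expect_identical(cold, warm)
  st <- cacheStats(cache)
  expect_identical(st$remoteFetches, 1L)
  expect_identical(st$l1Hits, 1L)
  # fill L1 past capacity; the first key falls out of L1 but stays in L2
  for (r in 0:5) cacheGet(cache, TileKey(0, r, 0, 0), rm$fetch)
  expect_lte(cacheStats(cache)$l1Size, 4L)
  n0 <- cacheStats(cache)$remoteFetches
  again <- cacheGet(cache, k, rm$fetch)
  expect_identical(again, cold)
  expect_identical(cacheStats(cache)$remoteFetches, n0)  # L2 hit, no remote
  expect_gte(cacheStats(cache)$l2Hits, 1L)
})

test_that("unbounded caches fetch each distinct key exactly once", {
  withr::local_seed(31)
  g <- TileGrid(8 * 8, 8 * 8, 8)
  rm <- makeRemote(g)
  cache <- newTileCache(CacheConfig(l1Capacity = 10000, l2Capacity = 10000),
                        CodecConfig("png"))
  seen <- character()
  for (i in 1:1000) {
    k <- TileKey(0, sample(0:7, 1), sample(0:7, 1), 0)
    px <- cacheGet(cache, k, rm$fetch)
    expect_identical(px, rm$direct(formatTileKey(k)))   # transparency
    seen <- c(seen, formatTileKey(k))
  }
  expect_identical(cacheStats(cache)$remoteFetches,
                   length(unique(seen)))
})

test_that("remote failures propagate with key context, never stale data", {
  g <- TileGrid(64, 64, 16)
  cache <- newTileCache(CacheConfig(), CodecConfig("png"))
  expect_error(cacheGet(cache, TileKey(0, 0, 0, 0),
                        function(ks) stop("connection refused")),
               "00000_00000_00000_00")
  expect_error(cacheGet(cache, TileKey(0, 1, 0, 0), function(ks) NULL),
               "no data")
})

test_that("every L1 entry is also in L2 at insert time", {
  g <- TileGrid(8 * 16, 8 * 16, 16)
  rm <- makeRemote(g)
  cache <- newTileCache(CacheConfig(l1Capacity = 8, l2Capacity = 64),
                        CodecConfig("png"))
  for (r in 0:7) {
    cacheGet(cache, TileKey(0, r, r, 0), rm$fetch)
    l1 <- ls(cache@state$l1); l2 <- ls(cache@state$l2)
    expect_true(all(l1 %in% l2))
  }
})

test_that("prefetch plan ranks by ring distance then browsing direction", {
  g <- TileGrid(10 * 16, 10 * 16, 16)
  cfg <- CacheConfig(prefetchBudget = 100L, prefetchRadius = 2L,
                     neighborLayerDepth = 0L, neighborLevelDepth = 0L)
  vp <- Viewport(16 * 4, 16 * 4, 31, 31)   # spans tile (4,4) .. (5,5)
  # stationary: scores depend only on ring distance; ring 1 before ring 2
  plan <- prefetchPlan(BrowseState(vp), g, 0L, cfg, nLayers = 1)
  rings <- vapply(plan, function(k)
    max(abs(c(k@row, k@col) - pmin(pmax(c(k@row, k@col), 4), 5))), numeric(1))
  expect_true(all(diff(rings) >= 0))
  expect_setequal(unique(rings), c(1, 2))
  # rightward pan: the tile right of the viewport precedes the left one
  planR <- prefetchPlan(BrowseState(vp, c(1, 0)), g, 0L, cfg, nLayers = 1)
  strs <- vapply(planR, formatTileKey, character(1))
  right <- formatTileKey(TileKey(0, 4, 6, 0))
  left <- formatTileKey(TileKey(0, 4, 3, 0))
  expect_lt(match(right, strs), match(left, strs))
  # budget truncation and cached-key exclusion
  small <- prefetchPlan(BrowseState(vp), g, 0L,
                        CacheConfig(prefetchBudget = 5L, prefetchRadius = 2L,
                                    neighborLayerDepth = 0L,
                                    neighborLevelDepth = 0L),
                        nLayers = 1)
  expect_length(small, 5L)
  excl <- prefetchPlan(BrowseState(vp), g, 0L, cfg, nLayers = 1,
                       cachedKeys = strs)
  expect_true(!any(vapply(excl, formatTileKey, character(1)) %in% strs))
})

test_that("prefetch plans never leave the grid on random states", {
  withr::local_seed(41)
  for (i in 1:40) {
    tile <- 16L
    rows <- sample(2:6, 1); cols <- sample(2:6, 1)
    g <- TileGrid(cols * tile, rows * tile, tile)
    maxLev <- computeMaxLevel(rows, cols)
    lev <- sample(0:maxLev, 1)
    shp <- levelGridShape(g, lev)
    vp <- Viewport(runif(1, 0, (shp[2] - 0.5) * tile),
                   runif(1, 0, (shp[1] - 0.5) * tile),
                   runif(1, 1, tile * 2), runif(1, 1, tile * 2),
                   layer = sample(0:2, 1), magnitude = 2^-lev)
    ang <- runif(1, 0, 2 * pi)
    plan <- prefetchPlan(BrowseState(vp, c(cos(ang), sin(ang))), g, maxLev,
                         CacheConfig(prefetchBudget = 50L), nLayers = 3)
    for (k in plan) {
      s <- levelGridShape(g, k@level)
      expect_true(k@row >= 0 && k@row < s[1])
      expect_true(k@col >= 0 && k@col < s[2])
      expect_true(k@layer >= 0 && k@layer < 3)
      expect_true(k@level >= 0 && k@level <= maxLev)
    }
  }
})

test_that("with zero direction weight the plan is non-decreasing in ring", {
  g <- TileGrid(12 * 16, 12 * 16, 16)
  vp <- Viewport(16 * 5, 16 * 5, 20, 20)
  cfg <- CacheConfig(prefetchBudget = 200L, prefetchRadius = 3L,
                     directionWeight = 0, neighborLayerDepth = 0L,
                     neighborLevelDepth = 0L)
  plan <- prefetchPlan(BrowseState(vp, c(1, 0)), g, 0L, cfg, nLayers = 1)
  rings <- vapply(plan, function(k)
    max(abs(c(k@row, k@col) - pmin(pmax(c(k@row, k@col), 5), 6))), numeric(1))
  expect_true(all(diff(rings) >= 0))
})

test_that("eviction drops the farthest tiles first and respects capacity", {
  g <- TileGrid(16 * 16, 16 * 16, 16)
  rm <- makeRemote(g)
  state <- BrowseState(Viewport(0, 0, 15, 15))    # span = tile (0,0)
  # ring distances from the span: {0, 1, 1, 2, 3}
  dists <- list(TileKey(0, 0, 0, 0),   # 0
                TileKey(0, 0, 1, 0),   # 1
                TileKey(0, 1, 1, 0),   # 1
                TileKey(0, 2, 0, 0),   # 2
                TileKey(0, 3, 3, 0))   # 3
  c4 <- newTileCache(CacheConfig(l1Capacity = 4, l2Capacity = 100),
                     CodecConfig("png"))
  c4@state$lastState <- state
  for (k in dists) cacheGet(c4, k, rm$fetch, g, 0L)  # inserts evict as needed
  evictFar(c4, state, g, 0L)
  keys <- ls(c4@state$l1)
  expect_lte(length(keys), 4L)
  expect_false(formatTileKey(TileKey(0, 3, 3, 0)) %in% keys)  # farthest gone
  expect_true(formatTileKey(TileKey(0, 0, 0, 0)) %in% keys)   # span kept
  # all entries inside the span and over capacity: LRU applies
  c1 <- newTileCache(CacheConfig(l1Capacity = 2, l2Capacity = 100),
                     CodecConfig("png"))
  c1@state$lastState <- BrowseState(Viewport(0, 0, 47, 47))  # spans 3x3
  for (k in list(TileKey(0, 0, 0, 0), TileKey(0, 0, 1, 0),
                 TileKey(0, 1, 0, 0)))
    cacheGet(c1, k, rm$fetch, g, 0L)
  keys1 <- ls(c1@state$l1)
  expect_length(keys1, 2L)
  expect_false(formatTileKey(TileKey(0, 0, 0, 0)) %in% keys1)  # oldest out
})

test_that("after eviction no retained tile is farther than an evicted one", {
  withr::local_seed(55)
  g <- TileGrid(12 * 16, 12 * 16, 16)
  rm <- makeRemote(g)
  for (trial in 1:10) {
    cache <- newTileCache(CacheConfig(l1Capacity = 6, l2Capacity = 10),
                          CodecConfig("png"))
    state <- BrowseState(Viewport(16 * sample(0:8, 1), 16 * sample(0:8, 1),
                                  20, 20))
    cache@state$lastState <- state
    for (i in 1:15)
      cacheGet(cache, TileKey(0, sample(0:11, 1), sample(0:11, 1), 0),
               rm$fetch, g, 0L)
    rep <- evictFar(cache, state, g, 0L)
    d <- function(ks) keyRingDistanceForTest(ks, state, g, 0L)
    kept1 <- ls(cache@state$l1); kept2 <- ls(cache@state$l2)
    expect_lte(length(kept1), 6L)
    expect_lte(length(kept2), 10L)
    if (length(rep$l2Evicted) && length(kept2))
      expect_lte(max(vapply(kept2, d, numeric(1))),
                 max(vapply(rep$l2Evicted, d, numeric(1))))
  }
})

test_that("browse sessions hit on revisits and profit from prefetch", {
  withr::local_seed(61)
  g <- TileGrid(12 * 16, 6 * 16, 16)
  rm <- makeRemote(g)
  maxLev <- computeMaxLevel(g@rows, g@cols)
  vp <- Viewport(20, 20, 40, 40)
  cache <- newTileCache(CacheConfig(), CodecConfig("png"))
  metrics <- browseSession(list(BrowseState(vp), BrowseState(vp)), cache,
                           rm$fetch, g, maxLev, nLayers = 1)
  expect_identical(metrics$stepHitRates[2], 1)      # full revisit hit
  # conservation: hits + misses = requests at every step
  expect_true(all(metrics$stepHits <= metrics$stepRequests))
  expect_identical(metrics$requests, sum(metrics$stepRequests))
  # monotone left-to-right pan: prefetch lifts the L1 hit rate
  traj <- lapply(0:9, function(i)
    BrowseState(Viewport(i * 16, 16, 30, 30), c(1, 0)))
  runPan <- function(prefetch) {
    rmp <- makeRemote(g)
    cachep <- newTileCache(CacheConfig(l1Capacity = 64, l2Capacity = 256,
                                       prefetchBudget = 12L),
                           CodecConfig("png"))
    browseSession(traj, cachep, rmp$fetch, g, maxLev, nLayers = 1,
                  prefetch = prefetch)
  }
  expect_gt(runPan(TRUE)$l1HitRate, runPan(FALSE)$l1HitRate)
  # capacity invariants held throughout
  expect_lte(metrics$peakL1, 64L)
  expect_lte(metrics$peakL2, 256L)
})
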