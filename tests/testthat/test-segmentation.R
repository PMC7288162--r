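test_that("a filled square extracts to one centered primitive", {
  lab <- matrix(0L, 40, 40)
  lab[11:20, 16:25] <- 7L       # 10x10 square, y 10..19, x 15..24 (0-based)
  prims <- extractPrimitives(lab, layer = 3L)
  expect_length(prims, 1L)
  p <- prims[[1]]
  expect_identical(p@objectId, "7")
  expect_identical(p@layer, 3L)
  expect_equal(p@centroid, c(19.5, 14.5))
  expect_gt(polygonSignedArea(p@contour), 0)   # counter-clockwise
  # boundary-traced contour stays on the square's border pixels
  expect_true(all(p@contour[, 1] >= 15 & p@contour[, 1] <= 24))
  expect_true(all(p@contour[, 2] >= 10 & p@contour[, 2] <= 19))
})

test_that("disjoint components of one label become separate primitives", {
  lab <- matrix(0L, 40, 60)
  lab[5:12, 5:12] <- 4L
  lab[25:35, 40:55] <- 4L
  prims <- extractPrimitives(lab)
  expect_length(prims, 2L)
  expect_identical(unique(vapply(prims, function(p) p@objectId, "")), "4")
  expect_false(prims[[1]]@primitiveId == prims[[2]]@primitiveId)
  expect_length(extractPrimitives(matrix(0L, 10, 10)), 0L)
})

test_that("rasterized contours recover >= 99% of labeled pixels", {
  withr::local_seed(21)
  for (i in 1:5) {
    lab <- randomBlobImage(80, 80, nLabels = 4)
    prims <- extractPrimitives(lab)
    for (k in sort(unique(lab[lab > 0]))) {
      want <- which(lab == k, arr.ind = TRUE)   # (row, col) 1-based
      got <- matrix(FALSE, 80, 80)
      for (p in prims) {
        if (p@objectId != as.character(k)) next
        rs <- rasterizePolygon(p@contour)
        idx <- which(rs$mask, arr.ind = TRUE)
        yy <- rs$y0 + idx[, 1]; xx <- rs$x0 + idx[, 2]  # back to 1-based
        keep <- yy >= 1 & yy <= 80 & xx >= 1 & xx <= 80
        got[cbind(yy[keep], xx[keep])] <- TRUE
      }
      recovered <- mean(got[want])
      expect_gte(recovered, 0.99)
    }
  }
})

test_that("block membership follows the bounding box", {
  g <- TileGrid(128, 128, 32)
  inside <- Primitive(squareContour(5, 5, 10), 0, "a")
  expect_identical(blocksForPrimitive(inside, g),
                   list(list(layer = 0L, row = 0L, col = 0L)))
  # bbox straddling one vertical and one horizontal boundary: 4 blocks
  straddle <- Primitive(squareContour(25, 25, 14), 0, "b")
  blocks <- blocksForPrimitive(straddle, g)
  expect_length(blocks, 4L)
  expect_setequal(vapply(blocks, function(b) paste(b$row, b$col), ""),
                  c("0 0", "0 1", "1 0", "1 1"))
  outside <- Primitive(squareContour(120, 120, 20), 0, "c")
  expect_error(blocksForPrimitive(outside, g), "extent")
})

test_that("block sets cover every contour vertex and match the bbox oracle", {
  withr::local_seed(33)
  g <- TileGrid(160, 160, 32)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    xy <- cbind(runif(n, 0, 159), runif(n, 0, 159))
    p <- Primitive(xy, 0, "o")
    blocks <- vapply(blocksForPrimitive(p, g),
                     function(b) paste(b$row, b$col), "")
    # superset of blocks containing a vertex
    vblocks <- unique(paste(floor(xy[, 2] / 32), floor(xy[, 1] / 32)))
    expect_true(all(vblocks %in% blocks))
    # equal to the independent bbox-rectangle-intersection oracle
    oracle <- vapply(oracleBlocksForBBox(range(xy[, 1]), range(xy[, 2]), g),
                     function(b) paste(b[1], b[2]), "")
    expect_setequal(blocks, oracle)
  }
})

test_that("primitives serialize to JSON and back without loss", {
  withr::local_seed(2)
  p <- Primitive(squareContour(10, 12, 8), 4, "n42", "mitochondrion",
                 nodeLinks = c("u1", "u2"), synapseLinks = "n43")
  q <- primitiveFromJSON(primitiveToJSON(p))
  expect_identical(q@primitiveId, p@primitiveId)
  expect_identical(q@objectId, "n42")
  expect_identical(q@objectType, "mitochondrion")
  expect_equal(unname(q@contour), unname(p@contour))
  expect_equal(q@centroid, p@centroid)
  expect_identical(q@nodeLinks, c("u1", "u2"))
  expect_identical(q@synapseLinks, "n43")
  # JSON-lines export/import round-trips a primitive set
  prims <- extractPrimitives(randomBlobImage(60, 60, 3), layer = 1L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  exportPrimitives(prims, path)
  back <- importPrimitives(path)
  expect_identical(vapply(back, function(x) x@primitiveId, ""),
                   vapply(prims, function(x) x@primitiveId, ""))
})

test_that("block-crossing primitives are stored duplicated in full", {
  withr::local_seed(5)
  g <- TileGrid(128, 128, 32)
  store <- memoryBackend()
  spanning <- Primitive(squareContour(25, 25, 14), 0, "big")
  rep <- storePrimitives(store, list(spanning), g)
  expect_identical(rep$nPrimitives, 1L)
  expect_identical(rep$nRecords, 4L)
  recs <- kvPrefixScan(store, "00000_")
  expect_length(recs, 4L)
  payloads <- unique(vapply(recs, function(r) rawToChar(r$value), ""))
  expect_length(payloads, 1L)     # identical full payload in every block
  # N single-block primitives -> N records; recount oracle
  singles <- lapply(1:5, function(i)
    Primitive(squareContour(2 + (i - 1) * 3, 70, 2), 0, paste0("s", i)))
  rep2 <- storePrimitives(store, singles, g)
  expect_identical(rep2$nRecords, 5L)
  expected <- sum(vapply(c(list(spanning), singles),
                         function(p) length(blocksForPrimitive(p, g)),
                         integer(1)))
  expect_identical(rep$nRecords + rep2$nRecords, expected)
  # same id, different payload: integrity error
  clash <- Primitive(squareContour(5, 5, 4), 0, "x",
                     primitiveId = spanning@primitiveId)
  expect_error(storePrimitives(store, list(clash), g), "integrity")
})

test_that("2D retrieval dedups across blocks and matches the scan oracle", {
  withr::local_seed(8)
  g <- TileGrid(128, 128, 32)
  store <- memoryBackend()
  # heavy block-crossing population: sizes up to 40 px at tile 32
  prims <- list()
  for (i in 1:40) {
    side <- runif(1, 4, 40)
    x0 <- runif(1, 0, 127 - side); y0 <- runif(1, 0, 127 - side)
    prims[[i]] <- Primitive(squareContour(x0, y0, side), 0, paste0("o", i %% 7))
  }
  rep <- storePrimitives(store, prims, g)
  crossing <- mean(vapply(prims, function(p)
    length(blocksForPrimitive(p, g)) > 1, logical(1)))
  expect_gte(crossing, 0.3)       # the population really does cross blocks
  # whole-layer viewport: every primitive exactly once despite duplication
  all2d <- retrieve2d(store, Viewport(0, 0, 127, 127), g)
  expect_length(all2d, 40L)
  expect_identical(anyDuplicated(vapply(all2d, function(p) p@primitiveId, "")),
                   0L)
  # viewport over an empty region returns nothing
  store2 <- memoryBackend()
  storePrimitives(store2, list(Primitive(squareContour(2, 2, 5), 0, "q")), g)
  expect_length(retrieve2d(store2, Viewport(96, 96, 31, 31), g), 0L)
  # randomized viewports against the full-scan block-granularity oracle
  for (i in 1:25) {
    vp <- Viewport(runif(1, 0, 100), runif(1, 0, 100),
                   runif(1, 5, 80), runif(1, 5, 80))
    got <- sort(vapply(retrieve2d(store, vp, g),
                       function(p) p@primitiveId, ""))
    vtiles <- vapply(oracleViewportTiles(vp, g, 0),
                     function(x) paste(x[1], x[2]), character(1))
    want <- sort(unlist(lapply(prims, function(p) {
      pblocks <- vapply(blocksForPrimitive(p, g),
                        function(b) paste(b$row, b$col), "")
      if (length(intersect(pblocks, vtiles))) p@primitiveId else NULL
    })))
    expect_identical(got, want)
  }
})

test_that("3D retrieval stacks layers in order, fast path == filter scan", {
  withr::local_seed(13)
  g <- TileGrid(256, 256, 32)
  store <- memoryBackend()
  # 50 synthetic objects, one primitive per layer over 2-6 layers,
  # shuffled insertion order
  nlay <- sample(2:6, 50, replace = TRUE)
  prims <- list()
  for (k in 1:50) {
    side <- runif(1, 5, 60)
    x0 <- runif(1, 0, 255 - side); y0 <- runif(1, 0, 255 - side)
    for (l in seq_len(nlay[k]) - 1L)
      prims[[length(prims) + 1L]] <-
        Primitive(squareContour(x0, y0, side), l, paste0("obj", k))
  }
  prims <- prims[sample(seq_along(prims))]
  storePrimitives(store, prims, g)
  for (k in c(1, 7, 23, 50)) {
    got <- retrieve3d(store, paste0("obj", k))
    expect_length(got, nlay[k])
    expect_identical(vapply(got, function(p) p@layer, integer(1)),
                     seq_len(nlay[k]) - 1L)
    expect_identical(anyDuplicated(vapply(got, function(p) p@primitiveId, "")),
                     0L)
  }
  # dual-implementation equivalence on every object
  for (k in 1:50) {
    fast <- retrieve3d(store, paste0("obj", k), "fast")
    ref <- retrieve3d(store, paste0("obj", k), "reference")
    expect_identical(vapply(fast, function(p) p@primitiveId, ""),
                     vapply(ref, function(p) p@primitiveId, ""))
  }
  expect_length(retrieve3d(store, "no-such-object"), 0L)
  # objects partition the stored primitive set
  ids <- unlist(lapply(listObjects(store), function(o)
    vapply(retrieve3d(store, o), function(p) p@primitiveId, "")))
  expect_identical(anyDuplicated(ids), 0L)
  expect_length(ids, length(prims))
})

test_that("adjacent-layer linking follows raster overlap", {
  withr::local_seed(17)
  # identical square extruded over 3 layers: chain L0-L1, L1-L2
  chain <- lapply(0:2, function(l)
    Primitive(squareContour(10, 10, 8), l, "n1"))
  linked <- linkAdjacent(chain)
  ids <- vapply(linked, function(p) p@primitiveId, "")
  expect_identical(linked[[1]]@nodeLinks, ids[2])
  expect_setequal(linked[[2]]@nodeLinks, ids[c(1, 3)])
  expect_identical(linked[[3]]@nodeLinks, ids[2])
  # non-overlapping contours in adjacent layers: no link
  apart <- list(Primitive(squareContour(0, 0, 5), 0, "n2"),
                Primitive(squareContour(40, 40, 5), 1, "n2"))
  linked2 <- linkAdjacent(apart)
  expect_length(linked2[[1]]@nodeLinks, 0L)
  # branching object: one parent overlapping two children
  parent <- Primitive(squareContour(10, 10, 30), 0, "n3")
  childA <- Primitive(squareContour(12, 12, 6), 1, "n3")
  childB <- Primitive(squareContour(30, 30, 6), 1, "n3")
  linked3 <- linkAdjacent(list(parent, childA, childB))
  expect_setequal(linked3[[1]]@nodeLinks,
                  c(childA@primitiveId, childB@primitiveId))
  expect_identical(linked3[[2]]@nodeLinks, parent@primitiveId)
  # raster-overlap oracle agreement on random pairs
  for (i in 1:20) {
    a <- squareContour(runif(1, 0, 50), runif(1, 0, 50), runif(1, 4, 20))
    b <- squareContour(runif(1, 0, 50), runif(1, 0, 50), runif(1, 4, 20))
    pa <- Primitive(a, 0, "nz"); pb <- Primitive(b, 1, "nz")
    lk <- linkAdjacent(list(pa, pb))
    overlap <- rasterOverlap(rasterizePolygon(a), rasterizePolygon(b))
    expect_identical(length(lk[[1]]@nodeLinks) == 1L, overlap > 0L)
  }
  expect_error(linkAdjacent(list(parent,
                                 Primitive(squareContour(1, 1, 3), 1, "zz"))),
               "single object")
})
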