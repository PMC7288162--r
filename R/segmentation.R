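# Contour-primitive segmentation storage. Each 2D segmentation region is
# stored as its outer-boundary polygon plus attributes ("primitive"). A
# primitive is written once per level-0 image block its bounding box
# intersects, duplicated in full, under the key "layer_row_col_id"; 2D
# viewport queries are block prefix scans with duplicate removal, 3D
# object assembly is an attribute filter scan on the object id (with a
# faster maintained secondary index as an equivalent alternative).

segIndexPrefix <- "i"   # secondary-index keys: "i_<objectId>_<primitiveId>"

#' Extract contour primitives from a label image
#'
#' One [Primitive-class] per connected component of each nonzero label.
#' The component's outer boundary is traced (8-connected, oriented
#' counter-clockwise) through pixel centers; the centroid is the polygon
#' centroid. Components too small to carry a 3-vertex polygon (single
#' pixels, bars under 3 boundary pixels) are skipped.
#'
#' @param labelImage integer matrix `(height, width)` of label ids;
#'   0 is background.
#' @param layer 0-based layer index.
#' @param idMap named character vector mapping label value to object id;
#'   defaults to the label value itself.
#' @param objectType type recorded on every extracted primitive, or a
#'   named vector by object id.
#' @return list of [Primitive-class] (empty for an all-background image).
#' @export
extractPrimitives <- function(labelImage, layer = 0L, idMap = NULL,
                              objectType = "neuron") {
  storage.mode(labelImage) <- "integer"
  labs <- sort(unique(as.vector(labelImage)))
  labs <- labs[labs > 0L]
  out <- list()
  for (lb in labs) {
    oid <- if (!is.null(idMap)) as.character(idMap[[as.character(lb)]])
           else as.character(lb)
    otype <- if (length(objectType) > 1L) objectType[[oid]] else objectType
    comp <- EBImage::bwlabel(labelImage == lb)
    contours <- EBImage::ocontour(comp)
    for (ct in contours) {
      if (nrow(ct) < 3L) next
      # ocontour coordinates are 0-based (first-dim, second-dim) =
      # (y, x) under this package's [y, x] matrix convention: swap.
      xy <- cbind(x = ct[, 2], y = ct[, 1])
      out[[length(out) + 1L]] <-
        Primitive(xy, layer = layer, objectId = oid, objectType = otype)
    }
  }
  out
}

#' Blocks a primitive must be stored in
#'
#' Every level-0 block whose rectangle intersects the contour's bounding
#' box, at the primitive's layer. Bounding-box membership is a cheap,
#' safe superset of exact polygon-rectangle intersection; a primitive
#' crossing block boundaries is therefore stored (entirely) in each of
#' those blocks.
#'
#' @param p a [Primitive-class].
#' @param grid the volume's [TileGrid-class].
#' @return list of `list(layer, row, col)` block addresses, row-major.
#' @export
blocksForPrimitive <- function(p, grid) {
  xs <- p@contour[, 1]; ys <- p@contour[, 2]
  if (min(xs) < 0 || min(ys) < 0 ||
      max(xs) > grid@layerWidth - 1L || max(ys) > grid@layerHeight - 1L)
    stop(sprintf("primitive %s contour outside the layer extent",
                 p@primitiveId))
  r1 <- floor(min(ys) / grid@tileH); r2 <- floor(max(ys) / grid@tileH)
  c1 <- floor(min(xs) / grid@tileW); c2 <- floor(max(xs) / grid@tileW)
  r2 <- min(r2, grid@rows - 1L); c2 <- min(c2, grid@cols - 1L)
  out <- list()
  for (r in r1:r2)
    for (cc in c1:c2)
      out[[length(out) + 1L]] <- list(layer = p@layer, row = as.integer(r),
                                      col = as.integer(cc))
  out
}

#' Serialize / deserialize one primitive as JSON
#'
#' A stable, human-inspectable single-object JSON encoding; identical
#' input yields byte-identical output, so block-duplicated records carry
#' identical payloads.
#'
#' @param p a [Primitive-class].
#' @return `primitiveToJSON`: a JSON string; `primitiveFromJSON`: a
#'   [Primitive-class].
#' @export
primitiveToJSON <- function(p) {
  obj <- list(
    primitive_id = p@primitiveId, object_id = p@objectId,
    object_type = p@objectType, layer = p@layer,
    contour = unname(p@contour), centroid = p@centroid, color = p@color,
    node_links = p@nodeLinks, synapse_links = p@synapseLinks)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @rdname primitiveToJSON
#' @param s JSON string from `primitiveToJSON`.
#' @export
primitiveFromJSON <- function(s) {
  o <- jsonlite::fromJSON(s, simplifyVector = TRUE)
  new("Primitive", primitiveId = o$primitive_id, objectId = o$object_id,
      objectType = o$object_type,
      contour = matrix(as.numeric(o$contour), ncol = 2,
                       dimnames = list(NULL, c("x", "y"))),
      layer = as.integer(o$layer), centroid = as.numeric(o$centroid),
      color = as.integer(o$color),
      nodeLinks = as.character(unlist(o$node_links)),
      synapseLinks = as.character(unlist(o$synapse_links)))
}

primitiveRecordKey <- function(p, block) {
  paste0(formatBlockKey(block$layer, block$row, block$col), "_",
         p@primitiveId)
}

#' Store primitives block-duplicated
#'
#' Each primitive is written once per block from [blocksForPrimitive()],
#' full payload duplicated, under `"layer_row_col_id"`, with `object_id`
#' as the filterable record attribute. A secondary index entry
#' (`"i_<objectId>_<primitiveId>"` -> one record key) is maintained for
#' the fast 3D path. Writing a primitive id that already exists with a
#' different payload is an integrity error.
#'
#' @param store a [KVBackend-class].
#' @param primitives list of [Primitive-class].
#' @param grid the volume's [TileGrid-class].
#' @return report: `nPrimitives`, `nRecords` (>= nPrimitives),
#'   `inflation` (records per primitive).
#' @export
storePrimitives <- function(store, primitives, grid) {
  nRecords <- 0L
  for (p in primitives) {
    payload <- primitiveToJSON(p)
    raw <- charToRaw(payload)
    blocks <- blocksForPrimitive(p, grid)
    for (b in blocks) {
      k <- primitiveRecordKey(p, b)
      prev <- kvGet(store, k)
      if (!is.null(prev) && !identical(prev, raw))
        stop(sprintf("integrity error: primitive %s already stored with a different payload",
                     p@primitiveId))
      kvPut(store, k, raw, attrs = list(object_id = p@objectId))
      nRecords <- nRecords + 1L
    }
    kvPut(store, paste(segIndexPrefix, p@objectId, p@primitiveId, sep = "_"),
          charToRaw(primitiveRecordKey(p, blocks[[1]])))
  }
  list(nPrimitives = length(primitives), nRecords = nRecords,
       inflation = if (length(primitives)) nRecords / length(primitives)
                   else NA_real_)
}

dedupSortPrimitives <- function(prims, byLayer = FALSE) {
  ids <- vapply(prims, function(p) p@primitiveId, character(1))
  prims <- prims[!duplicated(ids)]
  ids <- ids[!duplicated(ids)]
  ord <- if (byLayer) {
    layers <- vapply(prims, function(p) p@layer, integer(1))
    order(layers, ids)
  } else order(ids)
  prims[ord]
}

#' 2D retrieval: primitives under a viewport
#'
#' Computes the level-0 block span of the viewport (primitives are never
#' downsampled, so there is no level in the key), prefix-scans each block
#' prefix `"layer_row_col_"`, merges, and removes duplicates by primitive
#' id. Result order is deterministic (ascending primitive id). Semantics
#' are block-granular: a primitive is returned when its storage blocks
#' intersect the viewport's blocks.
#'
#' @param store a [KVBackend-class] holding primitive records.
#' @param vp a [Viewport-class] at native scale (magnitude is ignored;
#'   block geometry is level 0).
#' @param grid the volume's [TileGrid-class].
#' @return list of distinct [Primitive-class], sorted by primitive id.
#' @export
retrieve2d <- function(store, vp, grid) {
  span <- viewportSpan(vp, grid, 0L)
  if (is.null(span)) return(list())
  prims <- list()
  for (r in span$r1:span$r2) {
    for (cc in span$c1:span$c2) {
      pre <- paste0(formatBlockKey(vp@layer, r, cc), "_")
      for (rec in kvPrefixScan(store, pre))
        prims[[length(prims) + 1L]] <- primitiveFromJSON(rawToChar(rec$value))
    }
  }
  dedupSortPrimitives(prims)
}

#' 3D retrieval: all primitives of one object
#'
#' Assembles a 3D object from its 2D primitives, sorted ascending by
#' layer (ties by primitive id). Two implementations with identical
#' results: `"reference"` runs the backend's attribute value-filter scan
#' on `object_id` and removes block duplicates; `"fast"` walks the
#' maintained secondary index (one prefix scan plus point gets).
#'
#' @param store a [KVBackend-class] holding primitive records.
#' @param objectId the object id.
#' @param method `"fast"` (default) or `"reference"`.
#' @return list of distinct [Primitive-class] in layer order; empty for an
#'   unknown object id.
#' @export
retrieve3d <- function(store, objectId, method = c("fast", "reference")) {
  method <- match.arg(method)
  prims <- if (method == "reference") {
    lapply(kvFilterScan(store, "object_id", as.character(objectId)),
           function(rec) primitiveFromJSON(rawToChar(rec$value)))
  } else {
    pre <- paste(segIndexPrefix, as.character(objectId), "", sep = "_")
    lapply(kvPrefixScan(store, pre), function(rec) {
      key <- rawToChar(rec$value)
      primitiveFromJSON(rawToChar(kvGet(store, key)))
    })
  }
  dedupSortPrimitives(prims, byLayer = TRUE)
}

#' All object ids present in a segmentation store
#' @param store a [KVBackend-class] holding primitive records.
#' @return character vector of distinct object ids.
#' @export
listObjects <- function(store) {
  keys <- kvKeys(store)
  keys <- keys[startsWith(keys, paste0(segIndexPrefix, "_"))]
  ids <- sub(paste0("^", segIndexPrefix, "_(.*)_[^_]+-[^_]+-[^_]+-[^_]+-[^_]+$"),
             "\\1", keys)
  sort(unique(ids))
}

#' Link primitives across adjacent layers
#'
#' Cross-links primitives of one object whose filled contours overlap
#' (nonzero rasterized intersection) in adjacent layers. Links are
#' symmetric: both primitives gain the other's id in `nodeLinks`.
#'
#' @param primitives list of [Primitive-class] sharing one object id.
#' @return the list with updated `nodeLinks`, in the input order.
#' @export
linkAdjacent <- function(primitives) {
  if (!length(primitives)) return(primitives)
  oids <- unique(vapply(primitives, function(p) p@objectId, character(1)))
  if (length(oids) != 1L)
    stop("linkAdjacent expects primitives of a single object")
  layers <- vapply(primitives, function(p) p@layer, integer(1))
  rasters <- lapply(primitives, function(p) rasterizePolygon(p@contour))
  links <- vector("list", length(primitives))
  for (i in seq_along(primitives)) {
    for (j in seq_along(primitives)) {
      if (j <= i) next
      if (abs(layers[i] - layers[j]) != 1L) next
      if (rasterOverlap(rasters[[i]], rasters[[j]]) > 0L) {
        links[[i]] <- c(links[[i]], primitives[[j]]@primitiveId)
        links[[j]] <- c(links[[j]], primitives[[i]]@primitiveId)
      }
    }
  }
  mapply(function(p, l) {
    p@nodeLinks <- sort(unique(c(p@nodeLinks, unlist(l))))
    p
  }, primitives, links, SIMPLIFY = FALSE)
}

#' Export / import primitives as JSON lines
#'
#' One primitive per line, in the same field layout as the store payloads;
#' export then import round-trips the primitive set.
#'
#' @param primitives list of [Primitive-class].
#' @param path output (`exportPrimitives`) or input (`importPrimitives`)
#'   file path.
#' @return `exportPrimitives`: the path, invisibly; `importPrimitives`:
#'   a list of [Primitive-class].
#' @export
exportPrimitives <- function(primitives, path) {
  writeLines(vapply(primitives, primitiveToJSON, character(1)), path)
  invisible(path)
}

#' @rdname exportPrimitives
#' @export
importPrimitives <- function(path) {
  lapply(readLines(path, warn = FALSE), primitiveFromJSON)
}
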