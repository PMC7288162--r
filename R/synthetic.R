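# Deterministic generator of EM-like grayscale stacks and labeled object
# stacks. Labels are a nearest-seed tessellation of each layer whose seeds
# drift coherently from layer to layer, so every label forms one 3D object
# with realistic block-crossing 2D sections; the grayscale rendering draws
# dark membranes along label boundaries over bright textured interiors
# plus Gaussian noise. Everything is reproducible byte-for-byte from the
# seed, so no external data is ever needed.

#' Synthetic stack specification
#'
#' @slot seed RNG seed; the same spec always yields byte-identical output.
#' @slot layers number of serial-section layers.
#' @slot layerSize `(width, height)` of each layer in pixels.
#' @slot nObjects number of 3D objects (tessellation seeds).
#' @slot objectDrift seed drift per layer in pixels (0 = identical
#'   layers).
#' @slot noiseSigma Gaussian noise standard deviation in gray levels.
#' @slot membraneWidth approximate boundary (membrane) width in pixels.
#' @export
setClass("SyntheticSpec", representation(
  seed = "integer", layers = "integer", layerSize = "integer",
  nObjects = "integer", objectDrift = "numeric", noiseSigma = "numeric",
  membraneWidth = "integer"
))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@layers < 1L) msg <- c(msg, "layers must be >= 1")
  if (any(object@layerSize < 8L)) msg <- c(msg, "layerSize must be >= 8 px")
  if (object@nObjects < 1L) msg <- c(msg, "nObjects must be >= 1")
  if (object@objectDrift < 0) msg <- c(msg, "objectDrift must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@membraneWidth < 1L) msg <- c(msg, "membraneWidth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticSpec
#'
#' Defaults describe the standard fixture: 8 layers of 4096 x 4096 pixels
#' with 30 drifting objects. Tests use smaller instances of the same
#' generator.
#'
#' @param seed RNG seed.
#' @param layers layer count.
#' @param layerSize `(width, height)` in pixels.
#' @param nObjects object count.
#' @param objectDrift per-layer seed drift in pixels.
#' @param noiseSigma noise SD in gray levels.
#' @param membraneWidth membrane width in pixels.
#' @return a [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(seed = 1L, layers = 8L, layerSize = c(4096L, 4096L),
                          nObjects = 30L, objectDrift = 8, noiseSigma = 10,
                          membraneWidth = 3L) {
  new("SyntheticSpec", seed = as.integer(seed), layers = as.integer(layers),
      layerSize = as.integer(layerSize), nObjects = as.integer(nObjects),
      objectDrift = as.numeric(objectDrift),
      noiseSigma = as.numeric(noiseSigma),
      membraneWidth = as.integer(membraneWidth))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d layers of %dx%d px, %d objects, drift %g px/layer, noise sd %g, membrane %d px (seed %d)\n",
    object@layers, object@layerSize[1], object@layerSize[2],
    object@nObjects, object@objectDrift, object@noiseSigma,
    object@membraneWidth, object@seed))
})

# Nearest-seed label assignment over the full pixel grid, vectorized over
# pixels with one pass per seed (memory stays at a few layer-sized
# vectors).
nearestSeedLabels <- function(w, h, seeds) {
  xs <- seq_len(w) - 1L
  ys <- seq_len(h) - 1L
  best <- matrix(Inf, h, w)
  lab <- matrix(0L, h, w)
  for (i in seq_len(nrow(seeds))) {
    # separable squared distance: one outer sum per seed
    d <- outer((ys - seeds[i, 2])^2, (xs - seeds[i, 1])^2, `+`)
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- i
  }
  lab
}

# Mark pixels on a label interface (both sides) and thicken toward the
# requested membrane width with 3x3 dilations.
membraneMask <- function(lab, width) {
  h <- nrow(lab); w <- ncol(lab)
  m <- matrix(FALSE, h, w)
  dv <- lab[-h, , drop = FALSE] != lab[-1, , drop = FALSE]
  m[-h, ][dv] <- TRUE; m[-1, ][dv] <- TRUE
  dh <- lab[, -w, drop = FALSE] != lab[, -1, drop = FALSE]
  m[, -w][dh] <- TRUE; m[, -1][dh] <- TRUE
  extra <- max(0L, (width - 2L + 1L) %/% 2L)
  for (i in seq_len(extra)) {
    m2 <- m
    m2[-1, ] <- m2[-1, ] | m[-h, ]; m2[-h, ] <- m2[-h, ] | m[-1, ]
    m2[, -1] <- m2[, -1] | m[, -w]; m2[, -w] <- m2[, -w] | m[, -1]
    m <- m2
  }
  m
}

#' Generate a labeled object stack with ground truth
#'
#' Each layer is a nearest-seed tessellation of the plane: `nObjects`
#' seed points partition the layer into cells, carved apart by a
#' zero-valued membrane along cell interfaces. Seeds drift by
#' `objectDrift` pixels per layer (a per-object random walk), so label
#' `k` traces one coherent 3D object through the stack. The manifest
#' records, per object and layer, the connected-component count and pixel
#' area, and the pixel overlap between consecutive layers — the ground
#' truth later recovered by extraction, 3D retrieval and adjacency
#' linking.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `labels` (list of integer label matrices, 0 =
#'   membrane/background) and `manifest` (see above; also records the
#'   spec fields).
#' @export
generateLabelStack <- function(spec) {
  validObject(spec)
  w <- spec@layerSize[1]; h <- spec@layerSize[2]
  withSeed(spec@seed, {
    seeds <- cbind(runif(spec@nObjects, 0, w - 1), runif(spec@nObjects, 0, h - 1))
    labels <- vector("list", spec@layers)
    for (l in seq_len(spec@layers)) {
      if (l > 1L) {
        ang <- runif(spec@nObjects, 0, 2 * pi)
        seeds <- seeds + spec@objectDrift * cbind(cos(ang), sin(ang))
        seeds[, 1] <- pmin(pmax(seeds[, 1], 0), w - 1)
        seeds[, 2] <- pmin(pmax(seeds[, 2], 0), h - 1)
      }
      lab <- nearestSeedLabels(w, h, seeds)
      lab[membraneMask(lab, spec@membraneWidth)] <- 0L
      # after carving, distinct labels never touch (the membrane strips
      # both sides of every interface), so one connected-components pass
      # over the foreground labels every region of every object at once
      comp <- EBImage::bwlabel(lab > 0L)
      storage.mode(comp) <- "integer"
      sizes <- tabulate(comp[comp > 0L])
      # absorb slivers too small to carry a contour (< 4 px) into the
      # membrane: the recorded ground truth is exactly what a contour
      # representation can hold
      tiny <- which(sizes < 4L)
      if (length(tiny)) lab[comp %in% tiny] <- 0L
      labels[[l]] <- lab
    }
    compPerObj <- areaPerObj <- vector("list", spec@layers)
    for (l in seq_len(spec@layers)) {
      lab <- labels[[l]]
      comp <- EBImage::bwlabel(lab > 0L)
      storage.mode(comp) <- "integer"
      ncomp <- max(comp)
      objOfComp <- lab[match(seq_len(ncomp), comp)]
      compPerObj[[l]] <- tabulate(objOfComp, spec@nObjects)
      areaPerObj[[l]] <- tabulate(lab[lab > 0L], spec@nObjects)
    }
    overlapPerObj <- vector("list", max(spec@layers - 1L, 0L))
    for (l in seq_len(spec@layers - 1L)) {
      a <- labels[[l]]; b <- labels[[l + 1L]]
      eq <- a == b & a > 0L
      overlapPerObj[[l]] <- tabulate(a[eq], spec@nObjects)
    }
    objects <- lapply(seq_len(spec@nObjects), function(k) {
      list(object_id = as.character(k),
           components = vapply(compPerObj, `[`, integer(1), k),
           areas = vapply(areaPerObj, `[`, integer(1), k),
           adjacency_overlap = if (spec@layers > 1L)
             vapply(overlapPerObj, `[`, integer(1), k) else integer(0))
    })
    manifest <- list(
      seed = spec@seed, layers = spec@layers,
      layer_size = spec@layerSize, n_objects = spec@nObjects,
      object_drift = spec@objectDrift, noise_sigma = spec@noiseSigma,
      membrane_width = spec@membraneWidth,
      membrane_pixels = vapply(labels, function(m) sum(m == 0L), integer(1)),
      objects = objects)
    list(labels = labels, manifest = manifest)
  })
}

#' Render an EM-like grayscale stack from labels
#'
#' Bright textured interiors (per-object base intensity plus a smooth
#' low-frequency modulation), dark membranes where the label is 0, and
#' Gaussian noise of SD `noiseSigma`, clipped to 0..255. Deterministic
#' under the spec seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param labels label stack from [generateLabelStack()].
#' @return list of integer matrices, values 0..255.
#' @export
generateEMStack <- function(spec, labels) {
  w <- spec@layerSize[1]; h <- spec@layerSize[2]
  xs <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1L, times = w), h, w)
  texture <- 12 * sin(xs / 17) * cos(ys / 23)
  withSeed(spec@seed + 1L, {
    base <- 150L + (sample.int(81L, spec@nObjects, replace = TRUE) - 1L)
    lapply(labels, function(lab) {
      img <- matrix(55, nrow(lab), ncol(lab))      # membrane intensity
      fg <- lab > 0L
      img[fg] <- base[lab[fg]] + texture[fg]
      if (spec@noiseSigma > 0)
        img <- img + rnorm(length(img), 0, spec@noiseSigma)
      img <- pmin(pmax(roundHalfUp(img), 0), 255)
      storage.mode(img) <- "integer"
      img
    })
  })
}

#' Write the standard synthetic fixture to disk
#'
#' Generates the label stack and EM stack and writes one 8-bit grayscale
#' TIFF per layer (`em_####.tif`), one label TIFF per layer
#' (`labels_####.tif`, 16-bit) and the ground-truth `manifest.json`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param outDir output directory (created if needed).
#' @return fixture report: file lists, manifest path, per-layer label
#'   pixel sums.
#' @export
makeFixture <- function(spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lst <- generateLabelStack(spec)
  em <- generateEMStack(spec, lst$labels)
  emFiles <- labFiles <- character(spec@layers)
  for (l in seq_len(spec@layers)) {
    emFiles[l] <- file.path(outDir, sprintf("em_%04d.tif", l - 1L))
    writeLayerImage(em[[l]], emFiles[l])
    labFiles[l] <- file.path(outDir, sprintf("labels_%04d.tif", l - 1L))
    tiff::writeTIFF(lst$labels[[l]] / 65535, labFiles[l], bits.per.sample = 16L)
  }
  manifestPath <- file.path(outDir, "manifest.json")
  writeLines(jsonlite::toJSON(lst$manifest, auto_unbox = TRUE, digits = NA),
             manifestPath)
  list(emFiles = emFiles, labelFiles = labFiles, manifest = manifestPath,
       labelPixels = vapply(lst$labels, function(m) sum(m > 0L), integer(1)))
}

#' Read a 16-bit label TIFF written by [makeFixture()]
#' @param path label TIFF path.
#' @return integer label matrix.
#' @export
readLabelImage <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- matrix(as.integer(roundHalfUp(img * 65535)), nrow(img), ncol(img))
  m
}
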