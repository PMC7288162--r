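# Small numeric/geometry helpers shared across the package.

# floor(x + 0.5): round-half-up for nonnegative values, unlike base round()
# which rounds half to even.
roundHalfUp <- function(x) floor(x + 0.5)

#' Generate a random version-4 UUID
#'
#' Drawn from the session RNG, so ids are reproducible under `set.seed()`.
#'
#' @param n number of UUIDs.
#' @return character vector of UUID strings.
#' @export
makeUUID <- function(n = 1L) {
  hx <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i) {
    d <- sample(hx, 32L, replace = TRUE)
    d[13] <- "4"                             # version nibble
    d[17] <- sample(c("8", "9", "a", "b"), 1L)  # variant nibble
    paste0(paste(d[1:8], collapse = ""), "-", paste(d[9:12], collapse = ""),
           "-", paste(d[13:16], collapse = ""), "-",
           paste(d[17:20], collapse = ""), "-", paste(d[21:32], collapse = ""))
  }, character(1))
}

# Signed area of a closed polygon (shoelace, first vertex implicitly
# follows the last). Positive = counter-clockwise in (x, y).
polygonSignedArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Enforce counter-clockwise orientation.
ensureCCW <- function(xy) {
  if (polygonSignedArea(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  else xy
}

#' Polygon centroid
#'
#' Area-weighted centroid of a closed polygon; degenerate (near-zero area)
#' polygons fall back to the vertex mean.
#'
#' @param xy n x 2 matrix of (x, y) vertices.
#' @return numeric (x, y).
#' @export
polygonCentroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-9) return(colMeans(xy))
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

# Deterministic display color from an object id (no RNG draw).
objectColor <- function(objectId) {
  h <- sum(utf8ToInt(as.character(objectId)) * seq_along(utf8ToInt(as.character(objectId))))
  c(40L + (h * 7L) %% 200L, 40L + (h * 13L) %% 200L, 40L + (h * 29L) %% 200L)
}

# Rasterize a closed polygon onto the integer pixel grid: pixels whose
# centers fall inside the polygon, plus the pixels of the (rounded)
# vertices themselves, restricted to the polygon's bounding box.
# Returns list(x0, y0, mask) with mask[yi, xi] for pixel
# (x0 + xi - 1, y0 + yi - 1).
rasterizePolygon <- function(xy) {
  x0 <- floor(min(xy[, 1])); x1 <- ceiling(max(xy[, 1]))
  y0 <- floor(min(xy[, 2])); y1 <- ceiling(max(xy[, 2]))
  nx <- x1 - x0 + 1L; ny <- y1 - y0 + 1L
  xs <- rep(x0:x1, each = ny); ys <- rep(y0:y1, times = nx)
  bnd <- rbind(xy, xy[1, ])
  inside <- mgcv::in.out(bnd, cbind(xs, ys))
  mask <- matrix(inside, nrow = ny, ncol = nx)
  vx <- roundHalfUp(xy[, 1]) - x0 + 1L
  vy <- roundHalfUp(xy[, 2]) - y0 + 1L
  keep <- vx >= 1L & vx <= nx & vy >= 1L & vy <= ny
  mask[cbind(vy[keep], vx[keep])] <- TRUE
  list(x0 = x0, y0 = y0, mask = mask)
}

# Pixel-overlap count of two rasterized polygons (filled masks).
rasterOverlap <- function(ra, rb) {
  ax1 <- ra$x0 + ncol(ra$mask) - 1L; ay1 <- ra$y0 + nrow(ra$mask) - 1L
  bx1 <- rb$x0 + ncol(rb$mask) - 1L; by1 <- rb$y0 + nrow(rb$mask) - 1L
  x0 <- max(ra$x0, rb$x0); x1 <- min(ax1, bx1)
  y0 <- max(ra$y0, rb$y0); y1 <- min(ay1, by1)
  if (x0 > x1 || y0 > y1) return(0L)
  ma <- ra$mask[(y0 - ra$y0 + 1L):(y1 - ra$y0 + 1L),
                (x0 - ra$x0 + 1L):(x1 - ra$x0 + 1L), drop = FALSE]
  mb <- rb$mask[(y0 - rb$y0 + 1L):(y1 - rb$y0 + 1L),
                (x0 - rb$x0 + 1L):(x1 - rb$x0 + 1L), drop = FALSE]
  sum(ma & mb)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
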