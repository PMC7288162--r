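# Tile codec layer. Tiles travel as standard image byte streams: lossless
# PNG, lossy baseline JPEG (the transport format used for EM tiles in
# practice), or a raw header+payload format for debugging. PNG and raw
# round-trip bit-exactly; JPEG preserves shape and dtype only.

#' Tile codec configuration
#'
#' @slot codec one of `"png"`, `"jpeg"`, `"raw"`.
#' @slot jpegQuality integer 1..100, used by the JPEG codec only.
#' @export
setClass("CodecConfig",
         representation(codec = "character", jpegQuality = "integer"))

setValidity("CodecConfig", function(object) {
  msg <- character()
  if (!object@codec %in% c("png", "jpeg", "raw"))
    msg <- c(msg, "codec must be one of png, jpeg, raw")
  if (object@jpegQuality < 1L || object@jpegQuality > 100L)
    msg <- c(msg, "jpegQuality must be in 1..100")
  if (length(msg)) msg else TRUE
})

#' Construct a CodecConfig
#' @param codec `"png"` (lossless, the test default), `"jpeg"` (lossy,
#'   the storage/transport default for EM tiles) or `"raw"`.
#' @param jpegQuality JPEG quality 1..100 (default 85).
#' @return a [CodecConfig-class].
#' @export
CodecConfig <- function(codec = "png", jpegQuality = 85L) {
  new("CodecConfig", codec = codec, jpegQuality = as.integer(jpegQuality))
}

setMethod("show", "CodecConfig", function(object) {
  if (object@codec == "jpeg")
    cat(sprintf("CodecConfig: jpeg (quality %d)\n", object@jpegQuality))
  else cat(sprintf("CodecConfig: %s\n", object@codec))
})

#' Encode tile pixels to a byte stream
#'
#' @param tile a [Tile-class] or a bare integer pixel matrix (0..255).
#' @param cfg a [CodecConfig-class].
#' @return raw vector: a standard PNG or baseline JPEG stream, or the raw
#'   format (two little-endian int32 dims + row-major uint8 payload).
#' @export
encodeTile <- function(tile, cfg = CodecConfig()) {
  px <- if (is(tile, "Tile")) tile@pixels else tile
  switch(cfg@codec,
    png = png::writePNG(px / 255),
    jpeg = jpeg::writeJPEG(px / 255, quality = cfg@jpegQuality / 100),
    raw = {
      con <- rawConnection(raw(0), "wb")
      on.exit(close(con))
      writeBin(as.integer(dim(px)), con, size = 4L, endian = "little")
      writeBin(as.raw(t(px)), con)
      rawConnectionValue(con)
    },
    stop(sprintf("unsupported codec \"%s\"", cfg@codec)))
}

#' Decode a tile byte stream to pixels
#'
#' @param b raw vector from [encodeTile()] or any standard PNG/baseline
#'   JPEG encoder.
#' @param cfg a [CodecConfig-class] naming the codec the bytes are in.
#' @return integer pixel matrix (0..255) of the tile's shape.
#' @export
decodeTile <- function(b, cfg = CodecConfig()) {
  if (!is.raw(b) || !length(b)) stop("decode error: empty or non-raw stream")
  px <- switch(cfg@codec,
    png = tryCatch(png::readPNG(b),
                   error = function(e) stop("PNG decode error: ",
                                            conditionMessage(e))),
    jpeg = tryCatch(jpeg::readJPEG(b),
                    error = function(e) stop("JPEG decode error: ",
                                             conditionMessage(e))),
    raw = {
      if (length(b) < 8L) stop("raw decode error: truncated header")
      con <- rawConnection(b, "rb")
      on.exit(close(con))
      d <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
      payload <- readBin(con, "raw", n = prod(d))
      if (length(payload) != prod(d))
        stop("raw decode error: truncated payload")
      matrix(as.integer(payload), nrow = d[1], ncol = d[2], byrow = TRUE)
    },
    stop(sprintf("unsupported codec \"%s\"", cfg@codec)))
  if (cfg@codec != "raw") {
    if (length(dim(px)) == 3L) px <- px[, , 1]   # tolerate gray-as-RGB
    px <- matrix(as.integer(roundHalfUp(px * 255)), nrow(px), ncol(px))
  }
  storage.mode(px) <- "integer"
  px
}
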