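# Pluggable key-value backend. The store contract mirrors the operations
# the retrieval design relies on in a wide-column store: point put/get,
# lexicographic prefix scan, and a single-attribute value-filter scan.
# Two implementations: an in-memory map (tests, scratch work) and an
# embedded one-file-per-key on-disk store (persistence).

#' Virtual key-value backend
#'
#' Backends implement four primitives: [kvPut()], [kvGet()],
#' [kvPrefixScan()] and [kvFilterScan()]. Keys are strings; values are raw
#' vectors; each record may carry a small named list of scalar attributes
#' that the filter scan matches against. Prefix scans return records in
#' byte-wise (C locale) lexicographic key order, which for the fixed-width
#' spatial keys of this package is tuple order.
#'
#' @export
setClass("KVBackend", representation("VIRTUAL"))

#' @rdname KVBackend-class
#' @export
setClass("MemoryBackend", contains = "KVBackend",
         representation(data = "environment", attrs = "environment"))

#' @rdname KVBackend-class
#' @export
setClass("DiskBackend", contains = "KVBackend",
         representation(dir = "character"))

#' Create an in-memory backend
#' @return a `MemoryBackend`.
#' @export
memoryBackend <- function() {
  new("MemoryBackend", data = new.env(parent = emptyenv()),
      attrs = new.env(parent = emptyenv()))
}

#' Create (or reopen) an on-disk backend
#'
#' One file per record (`<key>.v` for the value, `<key>.a.json` for
#' attributes when present) under `dir`. Reopening an existing directory
#' sees all previously written records.
#'
#' @param dir backing directory; created if absent.
#' @return a `DiskBackend`.
#' @export
diskBackend <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  new("DiskBackend", dir = normalizePath(dir))
}

#' Store a record
#' @param backend a [KVBackend-class].
#' @param key key string.
#' @param value raw vector.
#' @param attrs named list of scalar attributes (filterable).
#' @return the backend, invisibly.
#' @export
setGeneric("kvPut", function(backend, key, value, attrs = list())
  standardGeneric("kvPut"))

#' Fetch a record's value by key
#' @param backend a [KVBackend-class].
#' @param key key string.
#' @return raw vector, or `NULL` when the key is absent.
#' @export
setGeneric("kvGet", function(backend, key) standardGeneric("kvGet"))

#' All keys in the store (lexicographic order)
#' @param backend a [KVBackend-class].
#' @return character vector.
#' @export
setGeneric("kvKeys", function(backend) standardGeneric("kvKeys"))

#' Scan records whose key starts with a prefix
#' @param backend a [KVBackend-class].
#' @param prefix key prefix string.
#' @return list of `list(key, value, attrs)`, in lexicographic key order.
#' @export
setGeneric("kvPrefixScan", function(backend, prefix)
  standardGeneric("kvPrefixScan"))

#' Scan records whose stored attribute equals a value
#' @param backend a [KVBackend-class].
#' @param attribute attribute name.
#' @param value attribute value to match (scalar, compared by equality).
#' @return list of `list(key, value, attrs)`, in lexicographic key order.
#' @export
setGeneric("kvFilterScan", function(backend, attribute, value)
  standardGeneric("kvFilterScan"))

#' Remove a record
#' @param backend a [KVBackend-class].
#' @param key key string.
#' @return the backend, invisibly.
#' @export
setGeneric("kvDelete", function(backend, key) standardGeneric("kvDelete"))

sortKeysC <- function(keys) sort(keys, method = "radix")

## ---- in-memory ----

setMethod("kvPut", "MemoryBackend", function(backend, key, value, attrs = list()) {
  stopifnot(is.character(key), length(key) == 1L, is.raw(value))
  assign(key, value, envir = backend@data)
  assign(key, attrs, envir = backend@attrs)
  invisible(backend)
})

setMethod("kvGet", "MemoryBackend", function(backend, key) {
  if (exists(key, envir = backend@data, inherits = FALSE))
    get(key, envir = backend@data) else NULL
})

setMethod("kvKeys", "MemoryBackend", function(backend) {
  sortKeysC(ls(backend@data, all.names = TRUE))
})

setMethod("kvPrefixScan", "MemoryBackend", function(backend, prefix) {
  keys <- kvKeys(backend)
  keys <- keys[startsWith(keys, prefix)]
  lapply(keys, function(k) list(key = k, value = get(k, envir = backend@data),
                                attrs = get(k, envir = backend@attrs)))
})

setMethod("kvFilterScan", "MemoryBackend", function(backend, attribute, value) {
  keys <- kvKeys(backend)
  hits <- keys[vapply(keys, function(k) {
    a <- get(k, envir = backend@attrs)
    !is.null(a[[attribute]]) && identical(as.character(a[[attribute]]),
                                          as.character(value))
  }, logical(1))]
  lapply(hits, function(k) list(key = k, value = get(k, envir = backend@data),
                                attrs = get(k, envir = backend@attrs)))
})

setMethod("kvDelete", "MemoryBackend", function(backend, key) {
  suppressWarnings({
    if (exists(key, envir = backend@data, inherits = FALSE))
      rm(list = key, envir = backend@data)
    if (exists(key, envir = backend@attrs, inherits = FALSE))
      rm(list = key, envir = backend@attrs)
  })
  invisible(backend)
})

## ---- on-disk ----

diskValuePath <- function(backend, key) file.path(backend@dir, paste0(key, ".v"))
diskAttrPath <- function(backend, key) file.path(backend@dir, paste0(key, ".a.json"))

setMethod("kvPut", "DiskBackend", function(backend, key, value, attrs = list()) {
  stopifnot(is.character(key), length(key) == 1L, is.raw(value))
  writeBin(value, diskValuePath(backend, key))
  ap <- diskAttrPath(backend, key)
  if (length(attrs)) {
    writeLines(jsonlite::toJSON(attrs, auto_unbox = TRUE), ap)
  } else if (file.exists(ap)) {
    unlink(ap)
  }
  invisible(backend)
})

setMethod("kvGet", "DiskBackend", function(backend, key) {
  p <- diskValuePath(backend, key)
  if (!file.exists(p)) return(NULL)
  readBin(p, "raw", n = file.size(p))
})

setMethod("kvKeys", "DiskBackend", function(backend) {
  f <- list.files(backend@dir, pattern = "\\.v$")
  sortKeysC(sub("\\.v$", "", f))
})

diskAttrs <- function(backend, key) {
  ap <- diskAttrPath(backend, key)
  if (!file.exists(ap)) return(list())
  jsonlite::fromJSON(paste(readLines(ap, warn = FALSE), collapse = ""),
                     simplifyVector = TRUE)
}

setMethod("kvPrefixScan", "DiskBackend", function(backend, prefix) {
  keys <- kvKeys(backend)
  keys <- keys[startsWith(keys, prefix)]
  lapply(keys, function(k) list(key = k, value = kvGet(backend, k),
                                attrs = diskAttrs(backend, k)))
})

setMethod("kvFilterScan", "DiskBackend", function(backend, attribute, value) {
  keys <- kvKeys(backend)
  hits <- keys[vapply(keys, function(k) {
    a <- diskAttrs(backend, k)
    !is.null(a[[attribute]]) && identical(as.character(a[[attribute]]),
                                          as.character(value))
  }, logical(1))]
  lapply(hits, function(k) list(key = k, value = kvGet(backend, k),
                                attrs = diskAttrs(backend, k)))
})

setMethod("kvDelete", "DiskBackend", function(backend, key) {
  unlink(c(diskValuePath(backend, key), diskAttrPath(backend, key)))
  invisible(backend)
})
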