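# Raster and table codecs. Rasters are written as (multi-page) TIFF: one
# grayscale page per band, float32 for reflectance (values in [0, 1]) and
# 8-bit for categorical layers. The simulator works on a single local metric
# grid, so no projection metadata is carried.

#' Write / read a raster as TIFF
#'
#' `writeRasterTif` writes a matrix or `[rows, cols, bands]` array as a
#' multi-page TIFF, one page per band; `readRasterTif` reads it back.
#' Float rasters hold reflectance in [0, 1] at float32 precision; `uint8`
#' rasters hold small integer codes (0..255) and round-trip bit-exactly.
#'
#' @param x numeric matrix or 3-d array.
#' @param path file path.
#' @param type `"float"` or `"uint8"`.
#' @return `writeRasterTif`: `path`, invisibly. `readRasterTif`: a matrix
#'   (single band) or `[rows, cols, bands]` array.
#' @export
writeRasterTif <- function(x, path, type = c("float", "uint8")) {
  type <- match.arg(type)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (anyNA(x)) stop("raster contains NA; encode nodata before writing")
  pages <- lapply(seq_len(dim(x)[3]), function(b) x[, , b])
  if (type == "uint8") {
    if (any(x < 0 | x > 255 | x != round(x)))
      stop("uint8 raster values must be integers in 0..255")
    pages <- lapply(pages, function(m) m / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    if (any(x < 0 | x > 1))
      stop("float raster values must lie in [0, 1]")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname writeRasterTif
#' @export
readRasterTif <- function(path, type = c("float", "uint8")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("raster not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (type == "uint8"))
  if (!is.list(pages)) pages <- list(pages)
  bad <- which(vapply(pages, function(p) !is.matrix(p) || anyNA(p),
                      logical(1)))
  if (length(bad))
    stop(sprintf("malformed raster %s: band %d unreadable", path, bad[1]))
  arr <- simplify2array(pages)
  if (type == "uint8") storage.mode(arr) <- "integer"
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1L) arr <- arr[, , 1L]
  arr
}

#' Write / read a binary maize map
#'
#' Maize maps follow the published encoding: 1 = maize, 0 = non-maize
#' (other crops and non-arable land). Nodata pixels (`NA`) are stored as
#' 255. Reading validates the encoding and rejects any other value.
#'
#' @param map integer matrix with values 1, 0 or `NA`.
#' @param path file path.
#' @return `writeMaizeMap`: `path`, invisibly. `readMaizeMap`: the map
#'   matrix with `NA` for nodata.
#' @export
writeMaizeMap <- function(map, path) {
  if (!all(map %in% c(0L, 1L) | is.na(map)))
    stop("maize map must contain only values 1 and 0 (NA for nodata)")
  enc <- map
  enc[is.na(enc)] <- 255L
  writeRasterTif(enc, path, type = "uint8")
}

#' @rdname writeMaizeMap
#' @export
readMaizeMap <- function(path) {
  m <- readRasterTif(path, type = "uint8")
  bad <- setdiff(unique(as.vector(m)), c(0L, 1L, 255L))
  if (length(bad))
    stop(sprintf("invalid maize map %s: contains value(s) %s; only 1, 0 %s",
                 path, paste(bad, collapse = ", "),
                 "(and 255 nodata) are allowed"))
  m[m == 255L] <- NA_integer_
  m
}

#' Write / read a scene stack directory
#'
#' One six-page float TIFF per acquisition (`scene_<doy>.tif`, band order
#' blue, green, red, nir, swir1, swir2) plus a six-page 8-bit cloud-flag
#' sidecar (`cloud_<doy>.tif`, 1 = contaminated). Observations that are
#' `NA` in memory (no valid value) are stored as 0 with the flag set, which
#' downstream compositing treats identically.
#'
#' @param stack a [SceneStack-class].
#' @param dir directory (created if needed).
#' @return `writeSceneStack`: `dir`, invisibly. `readSceneStack`: the
#'   restored [SceneStack-class].
#' @export
writeSceneStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stack@dates)) {
    refl <- stack@refl[, , , k]
    flags <- stack@cloud[, , , k]
    flags[is.na(refl)] <- TRUE
    refl[is.na(refl)] <- 0
    doy <- sprintf("%03d", as.integer(stack@dates[k]))
    writeRasterTif(refl, file.path(dir, paste0("scene_", doy, ".tif")),
                   type = "float")
    writeRasterTif(array(as.integer(flags), dim(flags)),
                   file.path(dir, paste0("cloud_", doy, ".tif")),
                   type = "uint8")
  }
  invisible(dir)
}

#' @rdname writeSceneStack
#' @export
readSceneStack <- function(dir) {
  sceneFiles <- sort(list.files(dir, "^scene_[0-9]+\\.tif$",
                                full.names = TRUE))
  if (!length(sceneFiles)) stop("no scene files found in ", dir)
  doys <- as.numeric(sub("^scene_([0-9]+)\\.tif$", "\\1",
                         basename(sceneFiles)))
  ord <- order(doys)
  sceneFiles <- sceneFiles[ord]; doys <- doys[ord]
  refl <- NULL; cloud <- NULL
  for (k in seq_along(sceneFiles)) {
    r <- readRasterTif(sceneFiles[k], type = "float")
    cpath <- file.path(dir, sub("^scene_", "cloud_", basename(sceneFiles[k])))
    cl <- readRasterTif(cpath, type = "uint8") == 1L
    if (is.null(refl)) {
      refl <- array(NA_real_, c(dim(r), length(sceneFiles)))
      cloud <- array(FALSE, dim(refl))
    }
    refl[, , , k] <- r
    cloud[, , , k] <- cl
  }
  new("SceneStack", dates = doys, refl = refl, cloud = cloud)
}

#' Write / read composite features
#'
#' The composite is stored as a multi-page float TIFF in period-major band
#' order (period 1 bands 1-6, ..., period 4 bands 1-6) with an 8-bit
#' validity sidecar (`<path base>_valid.tif`, one page per period).
#'
#' @param composite a [CompositeFeatures-class].
#' @param path TIFF file path for the values.
#' @param periods period windows to attach on read (defaults to
#'   [defaultPeriods()]).
#' @return `writeComposite`: `path`, invisibly. `readComposite`: the
#'   restored [CompositeFeatures-class].
#' @export
writeComposite <- function(composite, path) {
  d <- dim(composite@values)
  flat <- array(0, c(d[1], d[2], d[3] * d[4]))
  for (p in seq_len(d[4]))
    for (b in seq_len(d[3])) {
      v <- composite@values[, , b, p]
      v[is.na(v)] <- 0
      flat[, , (p - 1L) * d[3] + b] <- v
    }
  writeRasterTif(flat, path, type = "float")
  writeRasterTif(array(as.integer(composite@valid), dim(composite@valid)),
                 .validSidecar(path), type = "uint8")
  invisible(path)
}

.validSidecar <- function(path) sub("\\.tif$", "_valid.tif", path)

#' @rdname writeComposite
#' @export
readComposite <- function(path, periods = defaultPeriods()) {
  flat <- readRasterTif(path, type = "float")
  valid <- readRasterTif(.validSidecar(path), type = "uint8") == 1L
  np <- nrow(periods)
  nb <- dim(flat)[3] / np
  vals <- array(NA_real_, c(dim(flat)[1:2], nb, np))
  for (p in seq_len(np))
    for (b in seq_len(nb))
      vals[, , b, p] <- flat[, , (p - 1L) * nb + b]
  for (p in seq_len(np)) {
    bad <- !valid[, , p]
    if (any(bad))
      for (b in seq_len(nb)) {
        v <- vals[, , b, p]; v[bad] <- NA_real_; vals[, , b, p] <- v
      }
  }
  new("CompositeFeatures", values = vals, valid = valid, periods = periods)
}

.checkColumns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s %s is missing column(s): %s", what, path,
                 paste(missing, collapse = ", ")))
}

#' Write / read labeled sample tables
#'
#' CSV with columns row, col, year, class, split.
#'
#' @param samples data.frame as produced by [simulateSamples()].
#' @param path CSV path.
#' @return `writeSamples`: `path`, invisibly. `readSamples`: the data.frame.
#' @export
writeSamples <- function(samples, path) {
  .checkColumns(samples, c("row", "col", "year", "class", "split"),
                "sample table", path)
  write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSamples
#' @export
readSamples <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("row", "col", "year", "class", "split"),
                "sample table", path)
  df
}

#' Write / read region-level area tables
#'
#' CSV with columns region, year, area_ha.
#'
#' @param areas data.frame as produced by [simulateReferenceAreas()] or
#'   [areaByRegion()].
#' @param path CSV path.
#' @return `writeAreas`: `path`, invisibly. `readAreas`: the data.frame.
#' @export
writeAreas <- function(areas, path) {
  .checkColumns(areas, c("region", "year", "area_ha"), "area table", path)
  write.csv(areas, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAreas
#' @export
readAreas <- function(path) {
  if (!file.exists(path)) stop("area table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("region", "year", "area_ha"), "area table", path)
  df
}
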