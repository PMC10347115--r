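#' Multiband reflectance raster
#'
#' Lightweight container for a co-registered stack of reflectance bands:
#' a numeric array \code{rows x cols x bands} with named bands. The canonical
#' band order for five-channel UAV imagery is \code{BLUE, GREEN, RED, REG, NIR}
#' (450, 560, 650, 730, 840 nm).
#'
#' @param data numeric array of dimension \code{rows x cols x n_bands}, or a
#'   matrix for a single band. Values are reflectances, normally in [0, 1].
#' @param bands character vector of band names, one per slice of \code{data}.
#' @return An object of class \code{multiband_raster}.
#' @export
multiband_raster <- function(data, bands = c("BLUE", "GREEN", "RED", "REG", "NIR")) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3] != length(bands))
    stop("number of bands (", dim(data)[3], ") does not match band names (",
         length(bands), ")")
  dimnames(data) <- list(NULL, NULL, bands)
  structure(list(data = data, bands = bands), class = "multiband_raster")
}

#' @export
dim.multiband_raster <- function(x) dim(x$data)

#' @export
print.multiband_raster <- function(x, ...) {
  d <- dim(x$data)
  cat("<multiband_raster> ", d[1], " x ", d[2], " px, bands: ",
      paste(x$bands, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one band as a matrix
#'
#' @param raster a \code{multiband_raster}.
#' @param band band name (e.g. \code{"NIR"}) or integer index.
#' @return numeric matrix.
#' @export
get_band <- function(raster, band) {
  stopifnot(inherits(raster, "multiband_raster"))
  if (is.character(band)) {
    if (!band %in% raster$bands) stop("no such band: ", band)
    band <- match(band, raster$bands)
  }
  raster$data[, , band]
}

#' Write / read a multiband scene as a multi-page TIFF with a JSON sidecar
#'
#' The raster is stored as one 32-bit float TIFF page per band (in band order);
#' band names and any extra metadata (grid rectangles, latent traits, seed) go
#' to \code{<path>.json}. Values are clipped to [0, 1] on write, as required
#' by the TIFF encoder.
#'
#' @param raster a \code{multiband_raster}.
#' @param path output TIFF file path.
#' @param meta optional list of metadata serialized to the JSON sidecar.
#' @return \code{path}, invisibly.
#' @export
write_scene <- function(raster, path, meta = list()) {
  stopifnot(inherits(raster, "multiband_raster"))
  pages <- lapply(seq_along(raster$bands), function(b)
    pmin(pmax(raster$data[, , b], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta$bands <- raster$bands
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  bands <- if (file.exists(meta_path))
    unlist(jsonlite::read_json(meta_path)$bands)
  else paste0("band", seq_along(pages))
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (b in seq_along(pages)) {
    pg <- pages[[b]]
    arr[, , b] <- if (length(dim(pg)) == 3L) pg[, , 1] else pg
  }
  multiband_raster(arr, bands)
}

#' Canopy mask
#'
#' Per-pixel canopy map aligned to a raster: either a soft foreground
#' probability in [0, 1] or a hard {0, 1} labeling.
#'
#' @param values numeric matrix; soft values must lie in [0, 1].
#' @param binary logical; if TRUE values are validated as {0, 1}.
#' @return object of class \code{canopy_mask} (a matrix with attributes).
#' @export
canopy_mask <- function(values, binary = all(values %in% c(0, 1))) {
  stopifnot(is.matrix(values))
  if (any(values < 0 | values > 1)) stop("mask values must lie in [0, 1]")
  if (binary && !all(values %in% c(0, 1)))
    stop("binary mask must contain only 0 and 1")
  structure(values, binary = binary, class = c("canopy_mask", "matrix", "array"))
}

# plain numeric matrix of a mask (class and mask attributes stripped)
mask_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- attributes(m)["dim"]
  m
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat("<canopy_mask> ", nrow(x), " x ", ncol(x), " px, ",
      if (attr(x, "binary")) "binary" else "soft",
      ", coverage ", sprintf("%.1f%%", 100 * mean(x)), "\n", sep = "")
  invisible(x)
}

#' Write / read a canopy mask as a single-channel PNG
#'
#' Binary masks are written as {0, 255}; soft masks at 16-bit depth.
#'
#' @param mask a \code{canopy_mask}.
#' @param path PNG file path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "canopy_mask"))
  png::writePNG(mask_matrix(mask), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  canopy_mask(v, binary = all(v %in% c(0, 1)))
}
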