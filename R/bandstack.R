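#' Multiband scene container
#'
#' A `band_stack` holds co-registered 2-D grids for a set of named spectral
#' bands (optical surface reflectance plus, optionally, a thermal band),
#' together with the georeferencing needed to write the scene back out:
#' an affine geotransform, a CRS identifier, a shared nodata mask, and
#' scene-level metadata (cloud fraction, thermal kind).
#'
#' Grids are stored row-major with a top-left origin. The geotransform
#' follows the north-up affine convention
#' `c(x_origin, pixel_width, 0, y_origin, 0, -pixel_height)`:
#' the map coordinate of the centre of pixel (row `i`, col `j`), 1-based,
#' is `x = x_origin + (j - 0.5) * pixel_width`,
#' `y = y_origin - (i - 0.5) * pixel_height`.
#'
#' Masked pixels carry `NA` in every band; the mask and the band `NA`
#' patterns are kept in sync by the constructor.
#'
#' @param bands Named list of numeric matrices, all with identical
#'   dimensions. Canonical Landsat-8 names are `B2` (blue), `B3` (green),
#'   `B4` (red), `B5` (NIR), `B6` (SWIR1), `B7` (SWIR2), `B10` (thermal).
#' @param geotransform Numeric length-6 affine vector (see Details);
#'   pixel sizes must be nonzero.
#' @param crs Character CRS identifier (e.g. `"EPSG:32643"`).
#' @param nodata_mask Logical matrix, `TRUE` = invalid. Defaults to the
#'   union of `NA` cells across bands.
#' @param cloud_fraction Scene cloud fraction in `[0, 1]`.
#' @param thermal_kind `"bt"` if `B10` holds brightness temperature in
#'   kelvin, `"radiance"` if it holds TOA spectral radiance
#'   (W m^-2 sr^-1 um^-1).
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(bands,
                       geotransform = c(0, 30, 0, 0, 0, -30),
                       crs = "EPSG:32643",
                       nodata_mask = NULL,
                       cloud_fraction = 0,
                       thermal_kind = c("bt", "radiance")) {
  thermal_kind <- match.arg(thermal_kind)
  if (!is.list(bands) || length(bands) == 0L || is.null(names(bands)) ||
      any(!nzchar(names(bands)))) {
    stop("`bands` must be a non-empty named list of matrices", call. = FALSE)
  }
  dims <- lapply(bands, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("all bands must be matrices", call. = FALSE)
  }
  shp <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, shp), logical(1)))) {
    stop("all bands must share the same grid shape", call. = FALSE)
  }
  if (length(geotransform) != 6 || geotransform[2] == 0 || geotransform[6] == 0) {
    stop("geotransform must be length 6 with nonzero pixel sizes", call. = FALSE)
  }
  na_union <- Reduce(`|`, lapply(bands, is.na))
  if (is.null(nodata_mask)) {
    nodata_mask <- na_union
  } else {
    stopifnot(is.logical(nodata_mask), identical(dim(nodata_mask), shp))
    nodata_mask <- nodata_mask | na_union
  }
  bands <- lapply(bands, function(b) {
    b[nodata_mask] <- NA_real_
    storage.mode(b) <- "double"
    b
  })
  structure(
    list(
      bands = bands,
      grid_shape = as.integer(shp),
      geotransform = as.numeric(geotransform),
      crs = crs,
      nodata_mask = nodata_mask,
      cloud_fraction = as.numeric(cloud_fraction),
      thermal_kind = thermal_kind
    ),
    class = "band_stack"
  )
}

#' @export
print.band_stack <- function(x, ...) {
  cat(sprintf(
    "<band_stack> %d x %d, bands: %s\n  crs: %s | cloud: %.3f | thermal: %s | nodata: %d px\n",
    x$grid_shape[1], x$grid_shape[2], paste(names(x$bands), collapse = ", "),
    x$crs, x$cloud_fraction, x$thermal_kind, sum(x$nodata_mask)
  ))
  invisible(x)
}

#' @export
dim.band_stack <- function(x) x$grid_shape

band_names <- function(stack) names(stack$bands)

#' Extract a band grid
#'
#' @param stack A [band_stack()].
#' @param name Band name, e.g. `"B5"`.
#' @return Numeric matrix with `NA` at nodata pixels.
#' @export
get_band <- function(stack, name) {
  if (!name %in% names(stack$bands)) {
    stop(sprintf("band '%s' not present in stack (have: %s)",
                 name, paste(names(stack$bands), collapse = ", ")),
         call. = FALSE)
  }
  stack$bands[[name]]
}

require_bands <- function(stack, needed) {
  missing <- setdiff(needed, names(stack$bands))
  if (length(missing) > 0L) {
    stop(sprintf("configuration error: required band(s) missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

same_grid <- function(a, b) {
  identical(a$grid_shape, b$grid_shape) &&
    isTRUE(all.equal(a$geotransform, b$geotransform)) &&
    identical(a$crs, b$crs)
}

#' Single named indicator raster
#'
#' Wraps one ecological indicator grid (NDVI, wetness, LST in deg C, ...)
#' with its nodata mask and its ecological polarity: `"positive"` means
#' larger values indicate better ecological condition (so the indicator is
#' normalized forward), `"negative"` means the opposite (inverse
#' normalization).
#'
#' @param name Indicator identifier.
#' @param values Numeric matrix; `NA` = nodata.
#' @param polarity `"positive"` or `"negative"`.
#' @param nodata_mask Optional logical matrix, unioned with `is.na(values)`.
#' @return An object of class `indicator_raster`.
#' @export
indicator_raster <- function(name, values, polarity = c("positive", "negative"),
                             nodata_mask = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(values))
  storage.mode(values) <- "double"
  mask <- is.na(values)
  if (!is.null(nodata_mask)) mask <- mask | nodata_mask
  values[mask] <- NA_real_
  structure(
    list(name = name, values = values, nodata_mask = mask, polarity = polarity),
    class = "indicator_raster"
  )
}

#' @export
print.indicator_raster <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf("<indicator_raster> %s [%s] %d x %d, range [%.4g, %.4g], nodata %d px\n",
              x$name, x$polarity, nrow(x$values), ncol(x$values),
              suppressWarnings(min(v)), suppressWarnings(max(v)),
              sum(x$nodata_mask)))
  invisible(x)
}

#' Coerce raster-like inputs to a plain matrix
#'
#' Accepts a numeric matrix, an [indicator_raster()], a normalized
#' indicator, or an RSEI result, and returns the underlying value matrix
#' with `NA` at invalid pixels.
#'
#' @param x Raster-like object.
#' @return Numeric matrix.
#' @export
as_raster_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (inherits(x, "indicator_raster") || inherits(x, "normalized_indicator")) {
    return(x$values)
  }
  if (inherits(x, "rsei_result")) {
    return(x$rsei)
  }
  stop("cannot interpret object as a raster matrix", call. = FALSE)
}

#' Raster to long tibble
#'
#' Tidy accessor: one row per pixel with row/col indices, map coordinates
#' of the pixel centre and the value; invalid pixels are dropped.
#'
#' @param x Raster-like object (see [as_raster_matrix()]).
#' @param geotransform Optional affine vector for map coordinates.
#' @param value_name Name for the value column.
#' @return A tibble with columns `row`, `col`, `x`, `y`, and the value.
#' @export
raster_to_tibble <- function(x, geotransform = c(0, 30, 0, 0, 0, -30),
                             value_name = "value") {
  m <- as_raster_matrix(x)
  idx <- which(!is.na(m), arr.ind = TRUE)
  out <- tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    x = geotransform[1] + (idx[, 2] - 0.5) * geotransform[2],
    y = geotransform[4] + (idx[, 1] - 0.5) * geotransform[6],
    value = m[idx]
  )
  names(out)[names(out) == "value"] <- value_name
  out
}
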