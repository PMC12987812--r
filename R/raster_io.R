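#' Raster input/output
#'
#' Scenes and single-band rasters are stored as multi-page 32-bit TIFF
#' files accompanied by a JSON sidecar (`<file>.json`) that records band
#' names, per-band value ranges, the affine geotransform, CRS, nodata
#' value, cloud fraction and thermal kind. TIFF samples are stored
#' range-scaled to `[0, 1]` at 32-bit depth, so values survive a
#' write/read cycle to within about 2^-32 of each band's range and a
#' re-written file reproduces itself exactly.
#'
#' @name raster_files
NULL

RSEI_NODATA <- -9999

band_range <- function(v) {
  f <- v[is.finite(v)]
  if (length(f) == 0L) return(c(0, 1))
  lo <- min(f); hi <- max(f)
  if (hi <= lo) hi <- lo + 1
  c(lo, hi)
}

#' Write a band stack to disk
#'
#' @param stack A [band_stack()].
#' @param path Output TIFF path; the JSON sidecar is written next to it.
#' @param nodata Nodata value recorded in the sidecar (default -9999).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, nodata = RSEI_NODATA) {
  stopifnot(inherits(stack, "band_stack"))
  ranges <- lapply(stack$bands, band_range)
  pages <- mapply(function(b, r) {
    s <- (b - r[1]) / (r[2] - r[1])
    s[!is.finite(s)] <- 0
    s <- pmin(pmax(s, 0), 1)
    s
  }, stack$bands, ranges, SIMPLIFY = FALSE)
  pages <- c(unname(pages), list(stack$nodata_mask * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    format = "rsei_stack",
    band_names = names(stack$bands),
    band_ranges = ranges,
    geotransform = stack$geotransform,
    crs = stack$crs,
    nodata = nodata,
    cloud_fraction = stack$cloud_fraction,
    thermal_kind = stack$thermal_kind
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a band stack from disk
#'
#' Reads a TIFF written by [write_stack()] (using its JSON sidecar), or a
#' foreign multi-page TIFF via an explicit `band_map`.
#'
#' @param path TIFF path.
#' @param band_map Optional named integer vector mapping band names (e.g.
#'   `c(B2 = 1, B5 = 4)`) to 1-based page indices. With a sidecar present,
#'   names may also be selected by name. Requesting a band the file does
#'   not hold is a configuration error.
#' @return A [band_stack()].
#' @export
read_stack <- function(path, band_map = NULL) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    n_bands <- length(meta$band_names)
    mask <- pages[[n_bands + 1L]] > 0.5
    bands <- vector("list", n_bands)
    names(bands) <- meta$band_names
    ranges <- meta$band_ranges
    for (k in seq_len(n_bands)) {
      r <- as.numeric(ranges[[k]])
      bands[[k]] <- r[1] + pages[[k]] * (r[2] - r[1])
    }
    if (!is.null(band_map)) {
      want <- if (is.character(band_map)) band_map else names(band_map)
      missing <- setdiff(want, names(bands))
      if (length(missing) > 0L) {
        stop(sprintf("configuration error: band(s) not in file: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
      }
      bands <- bands[want]
    }
    return(band_stack(
      bands,
      geotransform = as.numeric(meta$geotransform),
      crs = meta$crs,
      nodata_mask = mask,
      cloud_fraction = as.numeric(meta$cloud_fraction %||% 0),
      thermal_kind = meta$thermal_kind %||% "bt"
    ))
  }
  # foreign TIFF: band_map required, raw [0,1] samples taken as-is
  if (is.null(band_map)) {
    stop("configuration error: no sidecar found; supply `band_map`", call. = FALSE)
  }
  bad <- band_map[band_map < 1 | band_map > length(pages)]
  if (length(bad) > 0L) {
    stop(sprintf("configuration error: band index out of range for: %s",
                 paste(names(bad), collapse = ", ")), call. = FALSE)
  }
  bands <- lapply(band_map, function(k) pages[[k]])
  names(bands) <- names(band_map)
  band_stack(bands)
}

#' Write / read a single-band raster
#'
#' @param values Numeric matrix (or raster-like object).
#' @param path Output TIFF path.
#' @param name Layer name recorded in the sidecar.
#' @param geotransform,crs Georeferencing recorded in the sidecar.
#' @return `path` invisibly for the writer; a numeric matrix for the reader.
#' @export
write_raster <- function(values, path, name = "layer",
                         geotransform = c(0, 30, 0, 0, 0, -30),
                         crs = "EPSG:32643") {
  m <- as_raster_matrix(values)
  r <- band_range(m)
  s <- (m - r[1]) / (r[2] - r[1])
  mask <- !is.finite(s)
  s[mask] <- 0
  tiff::writeTIFF(list(pmin(pmax(s, 0), 1), mask * 1), path,
                  bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(format = "rsei_raster", name = name, range = r,
         geotransform = geotransform, crs = crs, nodata = RSEI_NODATA),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path), call. = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  r <- as.numeric(meta$range)
  m <- r[1] + pages[[1]] * (r[2] - r[1])
  m[pages[[2]] > 0.5] <- NA_real_
  m
}

#' Apply surface-reflectance scaling to digital numbers
#'
#' Converts raw digital numbers of the optical bands to surface
#' reflectance with the linear Collection-2 rescaling
#' `reflectance = gain * DN + offset`. The thermal band (`B10`) passes
#' through unscaled; nodata is preserved.
#'
#' @param dn_stack A [band_stack()] holding raw digital numbers.
#' @param gain Multiplicative rescaling factor (default 2.75e-5).
#' @param offset Additive rescaling offset (default -0.2).
#' @return A [band_stack()] in reflectance units.
#' @export
apply_sr_scaling <- function(dn_stack, gain = 0.0000275, offset = -0.2) {
  stopifnot(inherits(dn_stack, "band_stack"))
  out <- dn_stack
  for (nm in names(out$bands)) {
    if (nm == "B10") next
    out$bands[[nm]] <- gain * out$bands[[nm]] + offset
  }
  out
}

#' Retain scenes below a cloud-cover threshold
#'
#' @param scenes List of [band_stack()] objects carrying `cloud_fraction`.
#' @param max_cloud Retention threshold; scenes with
#'   `cloud_fraction < max_cloud` are kept (default 0.05, i.e. under 5%).
#' @return The retained scenes, order preserved.
#' @export
filter_by_cloud <- function(scenes, max_cloud = 0.05) {
  keep <- vapply(scenes, function(s) s$cloud_fraction < max_cloud, logical(1))
  if (!any(keep)) {
    stop(sprintf("no usable scenes: all %d scene(s) have cloud fraction >= %g",
                 length(scenes), max_cloud), call. = FALSE)
  }
  scenes[keep]
}

#' Per-pixel median composite of co-registered scenes
#'
#' For each band and pixel, takes the median across scenes ignoring
#' nodata at that pixel; a composite pixel is nodata only where every
#' scene is nodata.
#'
#' @param scenes Non-empty list of co-registered [band_stack()] objects
#'   with identical band sets.
#' @return A [band_stack()].
#' @export
median_composite <- function(scenes) {
  if (length(scenes) == 0L) stop("no scenes to composite", call. = FALSE)
  ref <- scenes[[1]]
  for (s in scenes[-1]) {
    if (!same_grid(ref, s)) stop("alignment error: scenes are not co-registered", call. = FALSE)
    if (!identical(sort(names(ref$bands)), sort(names(s$bands)))) {
      stop("alignment error: scenes hold different band sets", call. = FALSE)
    }
  }
  if (length(scenes) == 1L) return(ref)
  shp <- ref$grid_shape
  bands <- lapply(names(ref$bands), function(nm) {
    arr <- vapply(scenes, function(s) s$bands[[nm]], matrix(0, shp[1], shp[2]))
    apply(arr, c(1, 2), stats::median, na.rm = TRUE)
  })
  names(bands) <- names(ref$bands)
  bands <- lapply(bands, function(b) { b[is.nan(b)] <- NA_real_; b })
  band_stack(bands, geotransform = ref$geotransform, crs = ref$crs,
             cloud_fraction = min(vapply(scenes, `[[`, numeric(1), "cloud_fraction")),
             thermal_kind = ref$thermal_kind)
}

# --- AOI handling ---------------------------------------------------------

# Flatten a GeoJSON geometry (Polygon/MultiPolygon, possibly inside a
# Feature/FeatureCollection) to a list of rings; each ring is a 2-col matrix.
geojson_rings <- function(gj) {
  if (!is.null(gj$type) && gj$type == "FeatureCollection") {
    return(unlist(lapply(gj$features, geojson_rings), recursive = FALSE))
  }
  if (!is.null(gj$type) && gj$type == "Feature") return(geojson_rings(gj$geometry))
  ring_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
  }
  if (gj$type == "Polygon") {
    return(lapply(gj$coordinates, ring_mat))
  }
  if (gj$type == "MultiPolygon") {
    return(unlist(lapply(gj$coordinates, function(poly) lapply(poly, ring_mat)),
                  recursive = FALSE))
  }
  stop(sprintf("unsupported GeoJSON geometry type '%s'", gj$type), call. = FALSE)
}

#' Read an AOI polygon from GeoJSON
#'
#' @param path GeoJSON file holding a Polygon or MultiPolygon (optionally
#'   wrapped in a Feature or FeatureCollection).
#' @return An `aoi` object (list of rings) usable by [clip_to_aoi()].
#' @export
read_aoi <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- geojson_rings(gj)
  structure(list(rings = rings), class = "aoi")
}

#' @rdname read_aoi
#' @param rings List of 2-column coordinate matrices (outer rings and
#'   holes; even-odd rule).
#' @export
aoi_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  structure(list(rings = rings), class = "aoi")
}

# Even-odd point-in-polygon across all rings.
points_in_aoi <- function(aoi, x, y) {
  count <- integer(length(x))
  for (ring in aoi$rings) {
    inside <- pracma::inpolygon(x, y, ring[, 1], ring[, 2], boundary = TRUE)
    count <- count + as.integer(inside)
  }
  count %% 2L == 1L
}

#' Clip a stack to an area of interest
#'
#' Pixels whose centres fall outside the AOI polygon become nodata
#' (pixel-centre rule), and the grid is cropped to the AOI bounding box.
#' AOI coordinates must be in the stack's CRS.
#'
#' @param stack A [band_stack()].
#' @param aoi An `aoi` object from [read_aoi()] or [aoi_polygon()].
#' @return The clipped [band_stack()].
#' @export
clip_to_aoi <- function(stack, aoi) {
  stopifnot(inherits(stack, "band_stack"), inherits(aoi, "aoi"))
  gt <- stack$geotransform
  nr <- stack$grid_shape[1]; nc <- stack$grid_shape[2]
  xs <- gt[1] + (seq_len(nc) - 0.5) * gt[2]
  ys <- gt[4] + (seq_len(nr) - 0.5) * gt[6]
  all_xy <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  inside <- points_in_aoi(aoi, xs[all_xy$col], ys[all_xy$row])
  if (!any(inside)) stop("empty intersection: AOI does not overlap the stack", call. = FALSE)
  inside_m <- matrix(FALSE, nr, nc)
  inside_m[cbind(all_xy$row, all_xy$col)] <- inside
  rows <- which(apply(inside_m, 1, any))
  cols <- which(apply(inside_m, 2, any))
  rr <- rows[1]:rows[length(rows)]
  cc <- cols[1]:cols[length(cols)]
  new_mask <- stack$nodata_mask[rr, cc, drop = FALSE] | !inside_m[rr, cc, drop = FALSE]
  bands <- lapply(stack$bands, function(b) b[rr, cc, drop = FALSE])
  new_gt <- gt
  new_gt[1] <- gt[1] + (rr[1] - 1L) * 0 + (cc[1] - 1L) * gt[2]
  new_gt[4] <- gt[4] + (rr[1] - 1L) * gt[6]
  band_stack(bands, geotransform = new_gt, crs = stack$crs,
             nodata_mask = new_mask, cloud_fraction = stack$cloud_fraction,
             thermal_kind = stack$thermal_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
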