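#' Spectral and thermal ecological indicators
#'
#' Elementwise indicator formulas for Landsat-8-like reflectance stacks.
#' Band roles: Blue = B2, Green = B3, Red = B4, NIR = B5, SWIR1 = B6,
#' SWIR2 = B7, thermal = B10. Every normalized-difference index guards its
#' denominator: where `|denominator| < eps` the pixel becomes nodata.
#'
#' @name spectral_indices
NULL

EPS_DENOM <- 1e-12

guard_div <- function(num, den, eps = EPS_DENOM) {
  out <- num / den
  out[abs(den) < eps] <- NA_real_
  out
}

#' Normalized Difference Vegetation Index
#'
#' `(NIR - Red) / (NIR + Red)`; greenness in `[-1, 1]`, positive polarity.
#'
#' @param stack A [band_stack()] in reflectance units.
#' @return An [indicator_raster()].
#' @export
ndvi <- function(stack) {
  require_bands(stack, c("B5", "B4"))
  nir <- get_band(stack, "B5"); red <- get_band(stack, "B4")
  indicator_raster("NDVI", guard_div(nir - red, nir + red), "positive")
}

#' Enhanced Vegetation Index
#'
#' `2.5 * (NIR - Red) / (NIR + 6*Red - 7.5*Blue + 1)` on 0-1 reflectance.
#'
#' @inheritParams ndvi
#' @return An [indicator_raster()].
#' @export
evi <- function(stack) {
  require_bands(stack, c("B5", "B4", "B2"))
  nir <- get_band(stack, "B5"); red <- get_band(stack, "B4"); blue <- get_band(stack, "B2")
  indicator_raster("EVI",
                   2.5 * guard_div(nir - red, nir + 6 * red - 7.5 * blue + 1),
                   "positive")
}

#' Soil-Adjusted Vegetation Index
#'
#' `1.5 * (NIR - Red) / (NIR + Red + 0.5)` (soil-brightness factor L = 0.5).
#'
#' @inheritParams ndvi
#' @return An [indicator_raster()].
#' @export
savi <- function(stack) {
  require_bands(stack, c("B5", "B4"))
  nir <- get_band(stack, "B5"); red <- get_band(stack, "B4")
  indicator_raster("SAVI", guard_div(nir - red, nir + red + 0.5) * 1.5, "positive")
}

#' Composite Vegetation Index
#'
#' Elementwise product `NDVI * EVI * SAVI`, combining greenness, canopy
#' responsiveness and soil adjustment into one vegetation-synergy
#' indicator.
#'
#' @param ndvi,evi,savi Co-registered [indicator_raster()] inputs.
#' @return An [indicator_raster()] with positive polarity.
#' @export
cvi <- function(ndvi, evi, savi) {
  if (!identical(dim(ndvi$values), dim(evi$values)) ||
      !identical(dim(ndvi$values), dim(savi$values))) {
    stop("alignment error: CVI inputs are not co-registered", call. = FALSE)
  }
  indicator_raster("CVI", ndvi$values * evi$values * savi$values, "positive")
}

#' Tasseled-cap wetness
#'
#' Fixed linear combination of the six optical bands:
#' `0.1509 B2 + 0.1973 B3 + 0.3279 B4 + 0.3406 B5 - 0.7112 B6 - 0.4572 B7`.
#'
#' @inheritParams ndvi
#' @return An [indicator_raster()] with positive polarity.
#' @export
wetness <- function(stack) {
  require_bands(stack, c("B2", "B3", "B4", "B5", "B6", "B7"))
  w <- 0.1509 * get_band(stack, "B2") + 0.1973 * get_band(stack, "B3") +
    0.3279 * get_band(stack, "B4") + 0.3406 * get_band(stack, "B5") -
    0.7112 * get_band(stack, "B6") - 0.4572 * get_band(stack, "B7")
  indicator_raster("Wetness", w, "positive")
}

#' Normalized Difference Built-up Index
#'
#' `(SWIR1 - NIR) / (SWIR1 + NIR)`.
#'
#' @inheritParams ndvi
#' @return An [indicator_raster()] with negative polarity.
#' @export
ndbi <- function(stack) {
  require_bands(stack, c("B6", "B5"))
  swir <- get_band(stack, "B6"); nir <- get_band(stack, "B5")
  indicator_raster("NDBI", guard_div(swir - nir, swir + nir), "negative")
}

#' Normalized Difference Built-up and Bare-Soil Index
#'
#' Mean of a built-up index `BI = (SWIR1 - NIR)/(SWIR1 + NIR)` and a soil
#' index `SI = (SWIR1 - SWIR2)/(SWIR1 + SWIR2)`; the dryness indicator.
#'
#' @inheritParams ndvi
#' @return An [indicator_raster()] with negative polarity.
#' @export
ndbsi <- function(stack) {
  require_bands(stack, c("B5", "B6", "B7"))
  swir <- get_band(stack, "B6"); nir <- get_band(stack, "B5"); swir2 <- get_band(stack, "B7")
  bi <- guard_div(swir - nir, swir + nir)
  si <- guard_div(swir - swir2, swir + swir2)
  indicator_raster("NDBSI", (bi + si) / 2, "negative")
}

#' Urban Index
#'
#' By default the SWIR1/NIR contrast `(SWIR1 - NIR)/(SWIR1 + NIR)`,
#' numerically identical to NDBI. Set `variant = "swir2"` for the
#' SWIR2-based form `(SWIR2 - NIR)/(SWIR2 + NIR)` used in part of the
#' urban remote-sensing literature.
#'
#' @inheritParams ndvi
#' @param variant `"swir1"` (default) or `"swir2"`.
#' @return An [indicator_raster()] with negative polarity.
#' @export
ui <- function(stack, variant = c("swir1", "swir2")) {
  variant <- match.arg(variant)
  if (variant == "swir1") {
    require_bands(stack, c("B6", "B5"))
    sw <- get_band(stack, "B6")
  } else {
    require_bands(stack, c("B7", "B5"))
    sw <- get_band(stack, "B7")
  }
  nir <- get_band(stack, "B5")
  indicator_raster("UI", guard_div(sw - nir, sw + nir), "negative")
}

#' Impervious Surface Index
#'
#' `(NDBI - NDVI) / (NDBI + NDVI)`; emphasizes sealed surfaces.
#'
#' @param ndbi,ndvi Co-registered [indicator_raster()] inputs.
#' @return An [indicator_raster()] with negative polarity.
#' @export
isi <- function(ndbi, ndvi) {
  if (!identical(dim(ndbi$values), dim(ndvi$values))) {
    stop("alignment error: ISI inputs are not co-registered", call. = FALSE)
  }
  indicator_raster("ISI", guard_div(ndbi$values - ndvi$values,
                                    ndbi$values + ndvi$values), "negative")
}

#' Thermal retrieval constants
#'
#' Constants for single-channel land surface temperature retrieval from
#' Landsat-8 band 10.
#'
#' @param lambda Effective band wavelength in metres (default 10.8e-6).
#' @param rho `h*c/k` in metre-kelvin (default 1.438e-2).
#' @param k1 Band-10 radiance calibration constant, W m^-2 sr^-1 um^-1
#'   (default 774.8853).
#' @param k2 Band-10 temperature calibration constant in kelvin
#'   (default 1321.0789).
#' @param emissivity_mode `"fixed"` (use `emissivity` everywhere) or
#'   `"ndvi_threshold"` (per-pixel emissivity from NDVI cover classes).
#' @param emissivity Fixed emissivity in `(0, 1]`, used when
#'   `emissivity_mode = "fixed"`.
#' @return A list of class `lst_constants`.
#' @export
lst_constants <- function(lambda = 10.8e-6, rho = 1.438e-2,
                          k1 = 774.8853, k2 = 1321.0789,
                          emissivity_mode = c("ndvi_threshold", "fixed"),
                          emissivity = 0.986) {
  emissivity_mode <- match.arg(emissivity_mode)
  stopifnot(lambda > 0, rho > 0, k2 > 0)
  if (emissivity <= 0 || emissivity > 1) {
    stop("domain error: emissivity must lie in (0, 1]", call. = FALSE)
  }
  structure(list(lambda = lambda, rho = rho, k1 = k1, k2 = k2,
                 emissivity_mode = emissivity_mode, emissivity = emissivity),
            class = "lst_constants")
}

# NDVI-thresholds emissivity: water 0.991, bare soil 0.966, vegetation
# 0.990; mixed pixels 0.986 + 0.004 * Pv with Pv = ((NDVI - 0.2)/0.3)^2.
ndvi_threshold_emissivity <- function(ndvi_values) {
  pv <- ((ndvi_values - 0.2) / 0.3)^2
  e <- 0.986 + 0.004 * pv
  e[ndvi_values < 0] <- 0.991
  e[ndvi_values >= 0 & ndvi_values < 0.2] <- 0.966
  e[ndvi_values > 0.5] <- 0.990
  e
}

#' Land surface temperature (single-channel retrieval)
#'
#' Retrieves LST in degrees Celsius from the thermal band. If the stack's
#' `thermal_kind` is `"radiance"`, band 10 is first converted to
#' brightness temperature `TB = k2 / ln(k1 / L + 1)`; `"bt"` means band 10
#' already holds brightness temperature in kelvin. The emissivity
#' correction is
#' `LST = TB / (1 + (lambda * TB / rho) * ln(eps)) - 273.15`,
#' with `lambda` in metres so that `lambda * TB / rho` is dimensionless.
#'
#' @param stack A [band_stack()] with band `B10`.
#' @param constants An [lst_constants()] object.
#' @param ndvi Optional [indicator_raster()]; required (or computed from
#'   the stack) when `emissivity_mode = "ndvi_threshold"`.
#' @return An [indicator_raster()] named `"LST"`, negative polarity.
#' @export
lst <- function(stack, constants = lst_constants(), ndvi = NULL) {
  require_bands(stack, "B10")
  b10 <- get_band(stack, "B10")
  tb <- if (stack$thermal_kind == "radiance") {
    constants$k2 / log(constants$k1 / b10 + 1)
  } else {
    b10
  }
  tb[tb <= 0] <- NA_real_
  eps <- if (constants$emissivity_mode == "fixed") {
    matrix(constants$emissivity, nrow(tb), ncol(tb))
  } else {
    if (is.null(ndvi)) ndvi <- ndvi(stack)
    ndvi_threshold_emissivity(ndvi$values)
  }
  if (any(eps <= 0, na.rm = TRUE)) stop("domain error: emissivity must be positive", call. = FALSE)
  lst_c <- tb / (1 + (constants$lambda * tb / constants$rho) * log(eps)) - 273.15
  indicator_raster("LST", lst_c, "negative")
}

#' Compute the full indicator set for a scene
#'
#' Convenience wrapper returning the nine spectral indicators plus LST as
#' a named list, sharing the stack's grid.
#'
#' @param stack A [band_stack()].
#' @param constants An [lst_constants()] object for the thermal retrieval.
#' @param ui_variant Urban Index band choice, see [ui()].
#' @return Named list of [indicator_raster()] objects:
#'   NDVI, EVI, SAVI, CVI, Wetness, NDBI, NDBSI, UI, ISI, LST.
#' @export
compute_indicators <- function(stack, constants = lst_constants(),
                               ui_variant = "swir1") {
  v_ndvi <- ndvi(stack)
  v_evi <- evi(stack)
  v_savi <- savi(stack)
  v_ndbi <- ndbi(stack)
  out <- list(
    NDVI = v_ndvi,
    EVI = v_evi,
    SAVI = v_savi,
    CVI = cvi(v_ndvi, v_evi, v_savi),
    Wetness = wetness(stack),
    NDBI = v_ndbi,
    NDBSI = ndbsi(stack),
    UI = ui(stack, variant = ui_variant),
    ISI = isi(v_ndbi, v_ndvi)
  )
  if ("B10" %in% names(stack$bands)) {
    out$LST <- lst(stack, constants, ndvi = v_ndvi)
  }
  out
}
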