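#' Default land-cover class spectra
#'
#' A small, physically plausible (synthetic) table of mean surface
#' reflectance per optical band and mean brightness temperature for four
#' cover classes. Vegetation is NIR-bright and cool, water is dark in the
#' infrared and coolest, built-up and bare soil are SWIR-bright and warm,
#' with built-up warmest. All package tests reference this fixture.
#'
#' @return Tibble with columns `class`, `B2`...`B7`, `bt_k`.
#' @export
default_class_spectra <- function() {
  path <- system.file("extdata", "class_spectra.csv", package = "rsei")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Synthetic scene configuration
#'
#' Describes one Landsat-8-like synthetic scene: grid size, land-cover
#' composition, class spectra, spectral and thermal noise, the spatial
#' coherence of cover patches, nodata holes and a seed.
#'
#' @param grid_shape Integer `c(rows, cols)` (default 128 x 128).
#' @param class_fractions Named proportions over
#'   `vegetation, water, built_up, bare_soil`, summing to 1.
#' @param class_spectra Spectra table as [default_class_spectra()].
#' @param spectral_noise_sd Gaussian reflectance noise sd (default 0.02).
#' @param thermal_noise_sd Gaussian brightness-temperature noise sd in
#'   kelvin (default 1).
#' @param patch_scale Gaussian smoothing length in pixels controlling
#'   patch size (default 8).
#' @param nodata_fraction Fraction of pixels carved out as nodata holes
#'   (default 0.01).
#' @param cloud_fraction Scene cloud fraction metadata (default 0).
#' @param seed Seed (default 20160101).
#' @return A `scene_config` list.
#' @export
scene_config <- function(grid_shape = c(128L, 128L),
                         class_fractions = c(vegetation = 0.35, water = 0.10,
                                             built_up = 0.35, bare_soil = 0.20),
                         class_spectra = default_class_spectra(),
                         spectral_noise_sd = 0.02,
                         thermal_noise_sd = 1,
                         patch_scale = 8,
                         nodata_fraction = 0.01,
                         cloud_fraction = 0,
                         seed = 20160101L) {
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("config error: class_fractions must sum to 1", call. = FALSE)
  }
  if (any(class_fractions < 0)) {
    stop("config error: class_fractions must be nonnegative", call. = FALSE)
  }
  opt <- as.matrix(class_spectra[, c("B2", "B3", "B4", "B5", "B6", "B7")])
  if (any(opt < 0 | opt > 1)) stop("config error: spectra must lie in [0, 1]", call. = FALSE)
  if (any(class_spectra$bt_k < 270 | class_spectra$bt_k > 340)) {
    stop("config error: brightness temperatures must lie in [270, 340] K", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 class_fractions = class_fractions,
                 class_spectra = class_spectra,
                 spectral_noise_sd = spectral_noise_sd,
                 thermal_noise_sd = thermal_noise_sd,
                 patch_scale = patch_scale,
                 nodata_fraction = nodata_fraction,
                 cloud_fraction = cloud_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Separable Gaussian blur with edge renormalization.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  smooth_axis <- function(nn) {
    B <- matrix(0, nn, nn)
    for (d in -half:half) {
      i <- seq_len(nn)
      j <- i + d
      ok <- j >= 1 & j <= nn
      B[cbind(i[ok], j[ok])] <- k[d + half + 1]
    }
    B / rowSums(B)
  }
  smooth_axis(nrow(m)) %*% m %*% t(smooth_axis(ncol(m)))
}

#' Generate a synthetic Landsat-8-like scene
#'
#' Builds a label grid of spatially coherent land-cover patches by
#' thresholding Gaussian-smoothed seeded noise at the quantiles implied
#' by the configured class fractions, then draws per-pixel reflectance
#' as class mean plus Gaussian noise (clipped to `[0, 1]`) and thermal
#' brightness temperature as class mean plus noise. Nodata holes are
#' carved from a second smoothed noise field. Deterministic per seed.
#'
#' @param config A [scene_config()].
#' @return A [band_stack()] with bands B2-B7 (reflectance) and B10
#'   (brightness temperature, kelvin), plus attribute `labels` holding
#'   the integer cover grid and `label_classes` its legend.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  spectra <- config$class_spectra
  fr <- config$class_fractions
  cls_names <- names(fr)[fr > 0]
  fr <- fr[cls_names]
  withr::with_seed(config$seed, {
    field <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc),
                           config$patch_scale)
    qs <- stats::quantile(field, cumsum(fr)[-length(fr)], names = FALSE)
    labels <- matrix(findInterval(field, qs) + 1L, nr, nc)
    row_of <- match(cls_names, spectra$class)
    if (any(is.na(row_of))) {
      stop("config error: class_fractions name a class absent from class_spectra",
           call. = FALSE)
    }
    bands <- list()
    for (b in c("B2", "B3", "B4", "B5", "B6", "B7")) {
      mu <- spectra[[b]][row_of][labels]
      v <- matrix(mu + stats::rnorm(nr * nc, sd = config$spectral_noise_sd), nr, nc)
      bands[[b]] <- pmin(pmax(v, 0), 1)
    }
    bt <- spectra$bt_k[row_of][labels] +
      stats::rnorm(nr * nc, sd = config$thermal_noise_sd)
    bands$B10 <- matrix(bt, nr, nc)
    mask <- matrix(FALSE, nr, nc)
    if (config$nodata_fraction > 0) {
      holes <- gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc),
                             max(1, config$patch_scale / 2))
      mask <- holes < stats::quantile(holes, config$nodata_fraction)
    }
    stack <- band_stack(bands, nodata_mask = mask,
                        cloud_fraction = config$cloud_fraction,
                        thermal_kind = "bt")
    attr(stack, "labels") <- labels
    attr(stack, "label_classes") <- cls_names
    stack
  })
}

#' Land-cover trajectory presets
#'
#' Class-fraction trajectories over five epochs emulating contrasting
#' urbanization histories. Water (0.10) and bare soil (0.15) are held
#' fixed; vegetation absorbs the complement of built-up growth.
#' `"monotone_decline"`: built-up grows linearly 0.2 to 0.6.
#' `"boom_bust"`: built-up 0.2, 0.5, 0.3, 0.3, 0.6.
#' `"stable"`: built-up constant at 0.3.
#'
#' @param name Preset name.
#' @param years Epoch labels (default `c(2016, 2018, 2020, 2022, 2024)`).
#' @return Tibble with one row per year: `year` and the four class
#'   fractions.
#' @export
history_preset <- function(name = c("monotone_decline", "boom_bust", "stable"),
                           years = c(2016L, 2018L, 2020L, 2022L, 2024L)) {
  name <- match.arg(name)
  built <- switch(name,
                  monotone_decline = seq(0.2, 0.6, length.out = length(years)),
                  boom_bust = c(0.2, 0.5, 0.3, 0.3, 0.6)[seq_along(years)],
                  stable = rep(0.3, length(years)))
  tibble::tibble(
    year = years,
    vegetation = 1 - built - 0.10 - 0.15,
    water = 0.10,
    built_up = built,
    bare_soil = 0.15
  )
}

#' Generate a multi-year synthetic city history
#'
#' One scene per year with that year's class fractions; scene seeds are
#' derived as `seed + epoch index` so the whole history is reproducible
#' from one seed.
#'
#' @param trajectory Tibble as returned by [history_preset()]: column
#'   `year` plus class-fraction columns.
#' @param base_config A [scene_config()] supplying everything except the
#'   fractions and seed.
#' @param seed Base seed (default the base config's seed).
#' @return A `city_history`: list with `years`, `scenes` (named list of
#'   [band_stack()]), and `trajectory`.
#' @export
generate_history <- function(trajectory, base_config = scene_config(),
                             seed = base_config$seed) {
  stopifnot(is.data.frame(trajectory), "year" %in% names(trajectory))
  if (anyDuplicated(trajectory$year)) stop("config error: years must be unique", call. = FALSE)
  cls_cols <- intersect(names(trajectory),
                        c("vegetation", "water", "built_up", "bare_soil"))
  scenes <- vector("list", nrow(trajectory))
  for (k in seq_len(nrow(trajectory))) {
    fr <- unlist(trajectory[k, cls_cols])
    cfg <- base_config
    cfg$class_fractions <- fr
    cfg$seed <- as.integer(seed + (k - 1L))
    scenes[[k]] <- generate_scene(cfg)
  }
  names(scenes) <- as.character(trajectory$year)
  structure(list(years = trajectory$year, scenes = scenes,
                 trajectory = tibble::as_tibble(trajectory)),
            class = "city_history")
}

#' @export
print.city_history <- function(x, ...) {
  cat(sprintf("<city_history> %d epochs: %s\n", length(x$years),
              paste(x$years, collapse = ", ")))
  invisible(x)
}
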