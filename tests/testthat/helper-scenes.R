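# Shared fixture builders. Everything is generated in code; no binary files.

# Band stack with explicit per-band matrices (recycled scalars allowed).
make_stack <- function(..., nr = 4, nc = 4, thermal_kind = "bt",
                       cloud_fraction = 0, nodata_mask = NULL) {
  vals <- list(...)
  bands <- lapply(vals, function(v) {
    if (is.matrix(v)) v else matrix(v, nr, nc)
  })
  band_stack(bands, nodata_mask = nodata_mask,
             cloud_fraction = cloud_fraction, thermal_kind = thermal_kind)
}

# Random reflectance stack away from index singularities.
random_stack <- function(seed, nr = 10, nc = 10, with_thermal = TRUE) {
  withr::with_seed(seed, {
    bands <- lapply(stats::setNames(1:6, c("B2", "B3", "B4", "B5", "B6", "B7")),
                    function(i) matrix(runif(nr * nc, 0.05, 0.6), nr, nc))
    if (with_thermal) bands$B10 <- matrix(runif(nr * nc, 285, 315), nr, nc)
    band_stack(bands)
  })
}

# Normalized indicator built directly (bypasses normalize_indicator) for
# composition tests that need exact values.
make_norm <- function(name, values, direction = "forward") {
  if (!is.matrix(values)) values <- matrix(values, 1)
  structure(list(name = name, values = values, direction = direction,
                 source_min = 0, source_max = 1,
                 nodata_mask = is.na(values)),
            class = "normalized_indicator")
}

# Uniform-weight field over given indicator names and grid shape.
make_equal_weight_field <- function(names, nr, nc) {
  m <- length(names)
  structure(list(
    weights = stats::setNames(lapply(names, function(x) matrix(1 / m, nr, nc)), names),
    m = m, window_size = 3L, stride = 1L, mode = "global",
    bin_count = 256L,
    global_weights = stats::setNames(rep(1 / m, m), names)
  ), class = "weight_field")
}

small_scene <- function(seed = 1, n = 64, ...) {
  generate_scene(scene_config(grid_shape = c(n, n), seed = seed, ...))
}

# Balanced group x year cell simulator for ANOVA calibration tests.
sim_cells <- function(group_eff = 0, year_eff = 0, n = 40, sd = 1, seed = 1,
                      years = 2016 + 2 * (0:4), groups = c("A", "B")) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_along(groups), function(gi) {
      purrr::map_dfr(seq_along(years), function(yi) {
        tibble::tibble(
          rsei = rnorm(n, mean = group_eff * gi + year_eff * yi, sd = sd),
          group = groups[gi], year = years[yi])
      })
    })
  })
}

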