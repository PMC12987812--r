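#' One-call RSEI computation for a scene
#'
#' Runs the full chain for a single [band_stack()]: indicator
#' computation, min-max normalization (forward for CVI and Wetness,
#' inverse for NDBSI, ISI, UI, LST), entropy weighting — global or in a
#' moving window — and composition. `model = "traditional"` instead
#' computes the four-indicator PCA baseline (NDVI, Wetness, NDBSI, LST).
#'
#' @param stack A [band_stack()] in reflectance units with a thermal band.
#' @param model `"improved"` (entropy weights, default) or
#'   `"traditional"` (PCA baseline).
#' @param window_size,stride,bin_count,window_mode Moving-window
#'   parameters, see [moving_window_weights()].
#' @param constants Thermal constants, see [lst_constants()].
#' @param clip_percentiles Percentile pair bounding the normalization
#'   range, default `c(0.01, 0.99)`; set `NULL` for exact min-max.
#'   Ratio indicators with near-singular denominators (ISI over noisy
#'   water) otherwise stretch the min-max range by orders of magnitude,
#'   collapsing the normalized grid and corrupting its entropy weight.
#' @param ui_variant Urban Index band choice, see [ui()].
#' @param seed Seed for any subsampling (PCA baseline on large rasters).
#' @return An `rsei_result`.
#' @export
compute_rsei <- function(stack, model = c("improved", "traditional"),
                         window_size = 133L, stride = NULL, bin_count = 256L,
                         window_mode = "interpolated",
                         constants = lst_constants(),
                         clip_percentiles = c(0.01, 0.99),
                         ui_variant = "swir1",
                         seed = 20160101L) {
  model <- match.arg(model)
  ind <- compute_indicators(stack, constants, ui_variant)
  if (model == "improved") {
    sel <- c("CVI", "Wetness", "NDBSI", "ISI", "UI", "LST")
    norms <- lapply(ind[sel], normalize_indicator,
                    clip_percentiles = clip_percentiles)
    wf <- moving_window_weights(norms, window_size = window_size,
                                stride = stride, bin_count = bin_count,
                                mode = window_mode)
    rsei_improved(norms, wf)
  } else {
    sel <- c("NDVI", "Wetness", "NDBSI", "LST")
    norms <- lapply(ind[sel], normalize_indicator,
                    clip_percentiles = clip_percentiles)
    rsei_traditional(norms, seed = seed)
  }
}

#' Spatial evaluation of an RSEI raster
#'
#' Global Moran's I with permutation inference, Getis-Ord Gi* hot/cold
#' spots and the ECDF table, in one call.
#'
#' @param rsei An `rsei_result` or raster matrix.
#' @param scheme Contiguity scheme (default `"queen"`).
#' @param n_permutations Moran permutations (default 999).
#' @param seed Seed.
#' @param max_pixels Graph subsampling cap, see [build_weights()].
#' @return List with `moran` (`moran_result`), `hotspots`
#'   (`hotspot_raster`) and `ecdf` (tibble).
#' @export
evaluate_rsei <- function(rsei, scheme = "queen", n_permutations = 999L,
                          seed = 20160101L, max_pixels = 20000L) {
  m <- as_raster_matrix(rsei)
  w_moran <- build_weights(m, scheme = scheme, include_self = FALSE,
                           max_pixels = max_pixels, seed = seed)
  w_gi <- build_weights(m, scheme = scheme, include_self = TRUE,
                        max_pixels = max_pixels, seed = seed)
  list(
    moran = morans_i(m, w_moran, n_permutations = n_permutations, seed = seed),
    hotspots = getis_ord_gistar(m, w_gi),
    ecdf = ecdf_export(m)
  )
}

#' Evaluate a multi-year city history
#'
#' Computes the RSEI for every epoch of a [generate_history()] result and
#' summarizes it: mean RSEI, Moran's I and its p-value, and hot/cold-spot
#' counts at the 95% level.
#'
#' @param history A `city_history`.
#' @param ... Passed to [compute_rsei()].
#' @param n_permutations,scheme,seed Passed to [evaluate_rsei()].
#' @return A `history_evaluation`: `summary` tibble (one row per year)
#'   plus the per-year `rsei_result` and evaluation objects.
#' @export
evaluate_history <- function(history, ..., scheme = "queen",
                             n_permutations = 199L, seed = 20160101L) {
  stopifnot(inherits(history, "city_history"))
  results <- lapply(history$scenes, compute_rsei, ...)
  evals <- lapply(results, evaluate_rsei, scheme = scheme,
                  n_permutations = n_permutations, seed = seed)
  summary <- tibble::tibble(
    year = history$years,
    mean_rsei = vapply(results, `[[`, numeric(1), "mean_rsei"),
    moran_i = vapply(evals, function(e) e$moran$I, numeric(1)),
    moran_p = vapply(evals, function(e) e$moran$p_value, numeric(1)),
    cold_spots_95 = vapply(evals, function(e) cold_spot_count(e$hotspots, 0.95),
                           numeric(1)),
    hot_spots_95 = vapply(evals, function(e)
      sum(e$hotspots$classes >= 2L, na.rm = TRUE), numeric(1))
  )
  structure(list(summary = summary, rsei = results, evaluations = evals,
                 trajectory = history$trajectory),
            class = "history_evaluation")
}

#' @export
print.history_evaluation <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Tidy a history evaluation
#'
#' @param x A `history_evaluation`.
#' @param ... Unused.
#' @return Its per-year summary tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.history_evaluation <- function(x, ...) x$summary

#' Plot mean RSEI trajectories
#'
#' @param object A `history_evaluation`, or a tibble with columns
#'   `year`, `mean_rsei` and optionally `city`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.history_evaluation <- function(object, ...) {
  plot_mean_rsei(object$summary)
}

#' @rdname autoplot.history_evaluation
#' @param summary Tibble with `year`, `mean_rsei`, optional `city`.
#' @export
plot_mean_rsei <- function(summary) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$year, y = .data$mean_rsei))
  if ("city" %in% names(summary)) {
    p <- p + ggplot2::aes(colour = .data$city, group = .data$city)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Year", y = "Mean RSEI") +
    ggplot2::theme_minimal()
}

#' Compare city histories with a pixel-sampled two-way ANOVA
#'
#' Draws seeded pixel samples of each epoch's RSEI for every city,
#' stacks them into a `(rsei, group, year)` table and runs
#' [two_way_anova()] with Tukey post hoc letters. Also returns the
#' mean-RSEI-by-city-by-year table.
#'
#' @param evaluations Named list of `history_evaluation` objects; names
#'   are city labels.
#' @param groups Named character vector mapping city to group label
#'   (e.g. `c(cityA = "100RC", cityB = "non-100RC")`); defaults to the
#'   city names themselves.
#' @param n_per_cell Pixel sample size per city-year cell (default 2000).
#' @param alpha Post hoc significance level.
#' @param seed Seed.
#' @return List with `means` (tibble city x year), `samples`, and
#'   `anova` (`rsei_anova`).
#' @export
compare_histories <- function(evaluations, groups = NULL, n_per_cell = 2000L,
                              alpha = 0.05, seed = 20160101L) {
  stopifnot(is.list(evaluations), !is.null(names(evaluations)))
  cities <- names(evaluations)
  if (is.null(groups)) groups <- stats::setNames(cities, cities)
  samples <- purrr::imap_dfr(evaluations, function(ev, city) {
    purrr::map_dfr(seq_along(ev$summary$year), function(k) {
      yr <- ev$summary$year[k]
      v <- sample_pixels(ev$rsei[[k]], n = n_per_cell,
                         seed = seed + 1000L * k + match(city, cities))
      tibble::tibble(rsei = v, city = city, group = unname(groups[city]),
                     year = yr)
    })
  })
  means <- samples |>
    dplyr::group_by(.data$city, .data$year) |>
    dplyr::summarise(mean_rsei = mean(.data$rsei), sd_rsei = stats::sd(.data$rsei),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "year", values_from = c("mean_rsei", "sd_rsei"))
  anova_samples <- dplyr::transmute(samples, rsei = .data$rsei,
                                    group = .data$city, year = .data$year)
  list(means = means, samples = samples,
       anova = two_way_anova(anova_samples, alpha = alpha))
}
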