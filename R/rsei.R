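#' Improved six-indicator RSEI
#'
#' Composes the Remote Sensing Ecological Index as the per-pixel convex
#' combination of six normalized indicators —
#' `RSEI(i,j) = sum_k W_k(i,j) * Y_k(i,j)` — with spatially varying
#' entropy weights. Inputs must be the six indicators CVI, Wetness,
#' NDBSI, ISI, UI and LST, normalized forward (CVI, Wetness) or inverse
#' (the rest) so larger always means ecologically better.
#'
#' @param norms Named list of six `normalized_indicator` objects with
#'   names `CVI`, `Wetness`, `NDBSI`, `ISI`, `UI`, `LST`.
#' @param weights A `weight_field` over the same indicators (from
#'   [moving_window_weights()]).
#' @return An `rsei_result`: `rsei` grid in `[0, 1]`, five-class
#'   categorical grid, `model = "improved_entropy"`, the weight field as
#'   provenance and `mean_rsei`.
#' @export
rsei_improved <- function(norms, weights) {
  expected <- c("CVI", "Wetness", "NDBSI", "ISI", "UI", "LST")
  if (!setequal(names(norms), expected)) {
    stop(sprintf("configuration error: improved RSEI needs indicators {%s}, got {%s}",
                 paste(expected, collapse = ", "),
                 paste(names(norms), collapse = ", ")), call. = FALSE)
  }
  norms <- norms[expected]
  fw <- c("CVI", "Wetness")
  for (nm in expected) {
    want <- if (nm %in% fw) "forward" else "inverse"
    if (norms[[nm]]$direction != want) {
      stop(sprintf("configuration error: %s must be normalized %s", nm, want),
           call. = FALSE)
    }
  }
  stopifnot(inherits(weights, "weight_field"))
  if (!setequal(names(weights$weights), expected)) {
    stop("configuration error: weight field does not cover the six indicators",
         call. = FALSE)
  }
  shp <- dim(norms[[1]]$values)
  acc <- matrix(0, shp[1], shp[2])
  for (nm in expected) {
    acc <- acc + weights$weights[[nm]] * norms[[nm]]$values
  }
  acc <- pmin(pmax(acc, 0), 1)
  new_rsei_result(acc, model = "improved_entropy",
                  provenance = list(weight_field = weights))
}

#' Traditional PCA-based RSEI baseline
#'
#' The classical four-indicator formulation: a principal component
#' analysis of the normalized greenness (NDVI), wetness, dryness (NDBSI)
#' and heat (LST) grids over valid pixels; the initial index is
#' `RSEI0 = 1 - PC1` and the final index rescales `RSEI0` to `[0, 1]`.
#' The sign of PC1 is oriented so the NDVI loading is negative, making
#' `1 - PC1` increase with greenness (the eigenvector sign is otherwise
#' arbitrary).
#'
#' @param norms Named list of four `normalized_indicator` objects with
#'   names `NDVI`, `Wetness`, `NDBSI`, `LST`.
#' @param max_pixels PCA is fitted on at most this many jointly-valid
#'   pixels (seeded subsample; scores are still produced for every
#'   pixel). Default 200000.
#' @param seed Seed for the subsample (default 20160101).
#' @return An `rsei_result` with `model = "traditional_pca"`, PC1
#'   loadings and explained-variance share as provenance.
#' @export
rsei_traditional <- function(norms, max_pixels = 200000L, seed = 20160101L) {
  expected <- c("NDVI", "Wetness", "NDBSI", "LST")
  if (!setequal(names(norms), expected)) {
    stop(sprintf("configuration error: traditional RSEI needs indicators {%s}",
                 paste(expected, collapse = ", ")), call. = FALSE)
  }
  norms <- norms[expected]
  vals <- lapply(norms, `[[`, "values")
  shp <- dim(vals[[1]])
  valid <- !Reduce(`|`, lapply(vals, is.na))
  idx <- which(valid)
  if (length(idx) < 5L) stop("need at least 5 valid pixels for PCA", call. = FALSE)
  X <- vapply(vals, function(v) v[idx], numeric(length(idx)))
  fit_idx <- if (length(idx) > max_pixels) {
    withr::with_seed(seed, sample(length(idx), max_pixels))
  } else {
    seq_along(idx)
  }
  pc <- stats::prcomp(X[fit_idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  if (pc$sdev[1] < 1e-12) {
    stop("degenerate variance: indicators are jointly constant", call. = FALSE)
  }
  rot1 <- pc$rotation[, 1]
  if (rot1["NDVI"] > 0) rot1 <- -rot1
  scores <- as.numeric(scale(X, center = pc$center, scale = FALSE) %*% rot1)
  rsei0 <- 1 - scores
  lo <- min(rsei0); hi <- max(rsei0)
  if (hi <= lo) stop("degenerate variance: PC1 scores are constant", call. = FALSE)
  r <- matrix(NA_real_, shp[1], shp[2])
  r[idx] <- (rsei0 - lo) / (hi - lo)
  ev_share <- pc$sdev^2 / sum(pc$sdev^2)
  new_rsei_result(r, model = "traditional_pca",
                  provenance = list(pca_loadings = rot1,
                                    explained_variance = ev_share,
                                    n_fit = length(fit_idx)))
}

new_rsei_result <- function(rsei, model, provenance) {
  structure(
    list(rsei = rsei,
         classes = classify_matrix(rsei),
         model = model,
         provenance = provenance,
         mean_rsei = mean(rsei, na.rm = TRUE)),
    class = "rsei_result"
  )
}

classify_matrix <- function(r) {
  cls <- pmin(floor(r / 0.2) + 1, 5)
  cls[!is.na(r) & (r < 0 | r > 1)] <- NA
  storage.mode(cls) <- "integer"  # keeps dim, unlike as.integer()
  cls
}

RSEI_CLASS_LABELS <- c("Very poor", "Poor", "Moderate", "Good", "Very good")

#' Five-class ecological quality classification
#'
#' Bins RSEI values into the standard quality classes: `[0, 0.2)` very
#' poor, `[0.2, 0.4)` poor, `[0.4, 0.6)` moderate, `[0.6, 0.8)` good,
#' `[0.8, 1]` very good (left-closed intervals, top edge inclusive).
#'
#' @param rsei An `rsei_result` or numeric matrix of RSEI values.
#' @return List with `classes` (integer matrix, 1-5) and `counts`
#'   (tibble: class, label, count, fraction).
#' @export
classify_rsei <- function(rsei) {
  r <- as_raster_matrix(rsei)
  cls <- classify_matrix(r)
  tab <- tabulate(cls[!is.na(cls)], nbins = 5L)
  counts <- tibble::tibble(
    class = 1:5,
    label = RSEI_CLASS_LABELS,
    count = as.integer(tab),
    fraction = if (sum(tab) > 0) tab / sum(tab) else rep(NA_real_, 5)
  )
  list(classes = cls, counts = counts)
}

#' @export
print.rsei_result <- function(x, ...) {
  cat(sprintf("<rsei_result> model %s, %d x %d, mean RSEI %.4f\n",
              x$model, nrow(x$rsei), ncol(x$rsei), x$mean_rsei))
  invisible(x)
}

#' Glance at an RSEI result
#'
#' @param x An `rsei_result`.
#' @param ... Unused.
#' @return One-row tibble: model, mean, sd, min, max, valid pixel count.
#' @export
#' @exportS3Method generics::glance
glance.rsei_result <- function(x, ...) {
  v <- x$rsei[!is.na(x$rsei)]
  tibble::tibble(
    model = x$model,
    mean_rsei = mean(v),
    sd_rsei = stats::sd(v),
    min_rsei = min(v),
    max_rsei = max(v),
    n_valid = length(v)
  )
}

#' Tidy an RSEI result into per-class counts
#'
#' @param x An `rsei_result`.
#' @param ... Unused.
#' @return Tibble with class, label, count, fraction.
#' @export
#' @exportS3Method generics::tidy
tidy.rsei_result <- function(x, ...) classify_rsei(x)$counts

#' Plot an RSEI result
#'
#' @param object An `rsei_result`.
#' @param what `"rsei"` for the continuous index, `"classes"` for the
#'   five-class map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.rsei_result <- function(object, what = c("rsei", "classes"), ...) {
  what <- match.arg(what)
  df <- raster_to_tibble(object$rsei, value_name = "rsei")
  if (what == "rsei") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$rsei)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "RSEI") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = NULL, y = NULL, title = sprintf("RSEI (%s)", object$model)) +
      ggplot2::theme_minimal()
  } else {
    df$class <- factor(RSEI_CLASS_LABELS[classify_matrix(matrix(df$rsei))],
                       levels = RSEI_CLASS_LABELS)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$class)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_brewer(palette = "RdYlGn", drop = FALSE, name = "Class") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = NULL, y = NULL, title = "Ecological quality classes") +
      ggplot2::theme_minimal()
  }
}
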