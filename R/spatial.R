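#' Contiguity weights over valid raster pixels
#'
#' Builds a spatial weights graph from pixel adjacency: rook (4-neighbour)
#' or queen (8-neighbour) contiguity over valid pixels, row-standardized.
#' Nodata holes sever adjacency. For Getis-Ord Gi* the pixel itself is
#' included in its own neighbourhood (`include_self = TRUE`).
#'
#' Rasters with more than `max_pixels` valid pixels are subsampled
#' (seeded, uniform) before graph construction; a full grid up to
#' 256 x 256 is never subsampled.
#'
#' @param raster Raster-like object (matrix with `NA`, indicator, or
#'   `rsei_result`).
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param include_self Include each pixel in its own neighbourhood.
#' @param max_pixels Subsampling cap (default 20000).
#' @param seed Seed for the subsample.
#' @return A `spatial_weights` object: sparse row-standardized matrix
#'   `W`, node coordinates, values vector and scheme metadata.
#' @export
build_weights <- function(raster, scheme = c("queen", "rook"),
                          include_self = FALSE, max_pixels = 20000L,
                          seed = 20160101L) {
  scheme <- match.arg(scheme)
  m <- as_raster_matrix(raster)
  nr <- nrow(m); nc <- ncol(m)
  valid <- which(!is.na(m))
  if (length(valid) < 2L) stop("need at least 2 valid pixels", call. = FALSE)
  if (length(valid) > max_pixels && nr * nc > 256L * 256L) {
    valid <- sort(withr::with_seed(seed, sample(valid, max_pixels)))
  }
  node_id <- matrix(0L, nr, nc)
  node_id[valid] <- seq_along(valid)
  rows <- ((valid - 1L) %% nr) + 1L
  cols <- ((valid - 1L) %/% nr) + 1L
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (scheme == "queen") {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- integer(length(rows))
    nb[ok] <- node_id[cbind(r2[ok], c2[ok])]
    hit <- ok & nb > 0L
    from <- c(from, which(hit))
    to <- c(to, nb[hit])
  }
  if (length(from) == 0L) stop("all pixels are isolated; no adjacency", call. = FALSE)
  n <- length(valid)
  if (include_self) {
    from <- c(from, seq_len(n))
    to <- c(to, seq_len(n))
  }
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  rs <- Matrix::rowSums(A)
  rs[rs == 0] <- 1
  W <- A / rs
  structure(
    list(W = W, A = A, n = n, rows = rows, cols = cols,
         values = m[valid], scheme = scheme, include_self = include_self,
         grid_shape = c(nr, nc), cell_index = valid),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %s, %d nodes, %d edges, include_self=%s\n",
              x$scheme, x$n, length(x$W@x), x$include_self))
  invisible(x)
}

moran_stat <- function(z, W) {
  # W row-standardized; I = (n / S0) * (z' W z) / (z' z)
  n <- length(z)
  s0 <- sum(W@x)
  num <- sum(z * as.numeric(W %*% z))
  (n / s0) * num / sum(z^2)
}

#' Global Moran's I with permutation inference
#'
#' Computes global Moran's I of a raster under a row-standardized
#' contiguity graph and a one-sided (clustering) permutation p-value from
#' seeded random relabellings of the values over the nodes.
#'
#' @param raster Raster-like object, or a `spatial_weights` graph whose
#'   stored values should be used.
#' @param weights Optional `spatial_weights` (built from `raster` with
#'   defaults if missing); must have `include_self = FALSE`.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Seed for the permutations.
#' @return A `moran_result`: `I`, `expected` (`-1/(N-1)`), `p_value`,
#'   `n_permutations`, `n`, `seed`.
#' @export
morans_i <- function(raster, weights = NULL, n_permutations = 999L,
                     seed = 20160101L) {
  if (inherits(raster, "spatial_weights") && is.null(weights)) {
    weights <- raster
  } else if (is.null(weights)) {
    weights <- build_weights(raster, include_self = FALSE, seed = seed)
  }
  if (weights$include_self) {
    stop("Moran's I requires a graph without self-neighbours", call. = FALSE)
  }
  x <- weights$values
  if (stats::sd(x) < 1e-15) {
    stop("degenerate variance: constant field has no spatial structure", call. = FALSE)
  }
  z <- x - mean(x)
  I_obs <- moran_stat(z, weights$W)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      moran_stat(sample(z), weights$W)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= I_obs)) / (n_permutations + 1)
  structure(
    list(I = I_obs, expected = -1 / (weights$n - 1), p_value = p,
         n_permutations = as.integer(n_permutations), n = weights$n,
         seed = as.integer(seed), scheme = weights$scheme),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), one-sided p = %.4g (%d permutations, n = %d)\n",
              x$I, x$expected, x$p_value, x$n_permutations, x$n))
  invisible(x)
}

#' Tidy a Moran's I result
#'
#' @param x A `moran_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.moran_result <- function(x, ...) {
  tibble::tibble(I = x$I, expected = x$expected, p_value = x$p_value,
                 n_permutations = x$n_permutations, n = x$n,
                 scheme = x$scheme, seed = x$seed)
}

#' Getis-Ord Gi* hot/cold-spot analysis
#'
#' Computes the Gi* z-score at every valid pixel (self-inclusive
#' neighbourhood) and classifies pixels into confidence classes at the
#' 90/95/99% levels: class `+-1` for `|z| >= 1.645`, `+-2` for
#' `|z| >= 1.96`, `+-3` for `|z| >= 2.576`, signed by the z-score; class
#' 0 otherwise. Positive classes are hotspots (high-value clusters),
#' negative classes cold spots.
#'
#' @param raster Raster-like object.
#' @param weights Optional self-inclusive `spatial_weights`.
#' @param scheme Contiguity scheme if the graph is built here.
#' @return A `hotspot_raster`: `gi_z` and `classes` matrices (on the full
#'   grid, `NA` off-graph), plus a `counts` tibble per class.
#' @export
getis_ord_gistar <- function(raster, weights = NULL, scheme = "queen") {
  if (is.null(weights)) {
    weights <- build_weights(raster, scheme = scheme, include_self = TRUE)
  }
  if (!weights$include_self) {
    stop("Gi* requires a self-inclusive graph (include_self = TRUE)", call. = FALSE)
  }
  x <- weights$values
  n <- weights$n
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  if (s < 1e-15) stop("degenerate variance: constant field", call. = FALSE)
  W <- weights$W
  wx <- as.numeric(W %*% x)
  wi <- Matrix::rowSums(W)
  w2i <- Matrix::rowSums(W^2)
  denom <- s * sqrt((n * w2i - wi^2) / (n - 1))
  z <- (wx - xbar * wi) / denom
  cls <- integer(n)
  cls[abs(z) >= 1.645] <- 1L
  cls[abs(z) >= 1.960] <- 2L
  cls[abs(z) >= 2.576] <- 3L
  cls <- cls * sign(z)
  shp <- weights$grid_shape
  zg <- matrix(NA_real_, shp[1], shp[2])
  cg <- matrix(NA_integer_, shp[1], shp[2])
  zg[weights$cell_index] <- z
  cg[weights$cell_index] <- as.integer(cls)
  counts <- tibble::tibble(class = -3:3) |>
    dplyr::mutate(count = vapply(.data$class, function(k) sum(cls == k), numeric(1)))
  structure(list(gi_z = zg, classes = cg, counts = counts,
                 scheme = weights$scheme),
            class = "hotspot_raster")
}

#' @export
print.hotspot_raster <- function(x, ...) {
  cat("<hotspot_raster> Gi* classes (count):\n")
  print(x$counts)
  invisible(x)
}

#' Cold-spot pixel count at a confidence level
#'
#' @param hotspots A `hotspot_raster`.
#' @param level Confidence level: 0.90, 0.95 (default) or 0.99.
#' @return Integer count of cold-spot pixels at that level or stronger.
#' @export
cold_spot_count <- function(hotspots, level = 0.95) {
  k <- c(`0.9` = 1L, `0.95` = 2L, `0.99` = 3L)[as.character(level)]
  if (is.na(k)) stop("level must be 0.90, 0.95 or 0.99", call. = FALSE)
  sum(hotspots$classes <= -k, na.rm = TRUE)
}

#' Empirical cumulative distribution of a raster
#'
#' Right-continuous ECDF over valid pixels, exported as a sorted table
#' of distinct values and cumulative fractions (last fraction = 1).
#'
#' @param raster Raster-like object.
#' @return Tibble with columns `value` and `cum_fraction`.
#' @export
ecdf_export <- function(raster) {
  v <- as_raster_matrix(raster)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no valid pixels", call. = FALSE)
  tab <- table(v)
  vals <- as.numeric(names(tab))
  tibble::tibble(value = vals,
                 cum_fraction = cumsum(as.numeric(tab)) / length(v))
}
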