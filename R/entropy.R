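#' Min-max normalization of an indicator
#'
#' Rescales an indicator to `[0, 1]` over the valid pixels of the whole
#' scene. Forward normalization `(X - Xmin) / (Xmax - Xmin)` is used for
#' indicators whose larger values mean better ecological condition
#' (CVI, Wetness); inverse normalization `(Xmax - X) / (Xmax - Xmin)` for
#' the rest (NDBSI, ISI, UI, LST), so that after normalization every
#' indicator points the same way.
#'
#' @param indicator An [indicator_raster()].
#' @param direction `"forward"` or `"inverse"`; defaults to the direction
#'   implied by the indicator's polarity.
#' @param clip_percentiles Optional length-2 percentile pair (e.g.
#'   `c(0.01, 0.99)`) used in place of the min/max; default `NULL` (off).
#' @return A `normalized_indicator` with fields `name`, `values`,
#'   `direction`, `source_min`, `source_max`.
#' @export
normalize_indicator <- function(indicator, direction = NULL,
                                clip_percentiles = NULL) {
  stopifnot(inherits(indicator, "indicator_raster"))
  if (is.null(direction)) {
    direction <- if (indicator$polarity == "positive") "forward" else "inverse"
  }
  direction <- match.arg(direction, c("forward", "inverse"))
  v <- indicator$values
  valid <- v[!is.na(v)]
  if (length(valid) < 2L) {
    stop(sprintf("degenerate range: indicator '%s' has < 2 valid pixels",
                 indicator$name), call. = FALSE)
  }
  if (is.null(clip_percentiles)) {
    lo <- min(valid); hi <- max(valid)
  } else {
    q <- stats::quantile(valid, clip_percentiles, names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  if (hi <= lo) {
    stop(sprintf("degenerate range: indicator '%s' is constant", indicator$name),
         call. = FALSE)
  }
  y <- if (direction == "forward") (v - lo) / (hi - lo) else (hi - v) / (hi - lo)
  y <- pmin(pmax(y, 0), 1)  # only active when percentile clipping is on
  structure(
    list(name = indicator$name, values = y, direction = direction,
         source_min = lo, source_max = hi,
         nodata_mask = indicator$nodata_mask),
    class = "normalized_indicator"
  )
}

#' @export
print.normalized_indicator <- function(x, ...) {
  cat(sprintf("<normalized_indicator> %s (%s), source range [%.4g, %.4g]\n",
              x$name, x$direction, x$source_min, x$source_max))
  invisible(x)
}

# Occupied-bin histogram entropy on values already in [0, 1].
# Returns list(entropy, n_effective, bin_count).
entropy_from_values <- function(y, bin_count = 256L) {
  if (bin_count < 2L) stop("bin_count must be >= 2", call. = FALSE)
  y <- y[!is.na(y)]
  if (length(y) == 0L) stop("empty input: no valid pixels for entropy", call. = FALSE)
  bins <- pmin(as.integer(floor(y * bin_count)) + 1L, bin_count)
  counts <- tabulate(bins, nbins = bin_count)
  occ <- counts[counts > 0L]
  n <- length(occ)
  if (n == 1L) {
    ej <- 0  # single-outcome limit: zero uncertainty
  } else {
    p <- occ / sum(occ)
    ej <- -sum(p * log(p)) / log(n)
  }
  list(entropy = ej, n_effective = n, bin_count = as.integer(bin_count))
}

#' Information entropy of a normalized indicator
#'
#' Bins the valid values into `bin_count` equal-width bins on `[0, 1]`
#' and computes the normalized Shannon entropy over the occupied bins:
#' `E = -(ln n)^-1 * sum(p_i * ln p_i)`, where `n` is the number of
#' occupied bins and `p_i` the frequency share of bin `i`. A single
#' occupied bin gives `E = 0` (zero-uncertainty limit); a uniform
#' occupancy gives `E = 1`.
#'
#' @param norm A `normalized_indicator` (or numeric vector/matrix of
#'   values in `[0, 1]`).
#' @param bin_count Number of histogram bins (default 256).
#' @return An `entropy_result` list: `name`, `entropy`, `n_effective`,
#'   `bin_count`.
#' @export
indicator_entropy <- function(norm, bin_count = 256L) {
  if (inherits(norm, "normalized_indicator")) {
    nm <- norm$name
    y <- norm$values
  } else {
    nm <- "values"
    y <- norm
  }
  res <- entropy_from_values(as.numeric(y), bin_count)
  structure(c(list(name = nm), res), class = "entropy_result")
}

#' Entropy weights for a set of indicators
#'
#' Converts indicator entropies into weights
#' `W_j = (1 - E_j) / (m - sum(E_j))`: indicators with lower entropy
#' (stronger spatial differentiation) receive larger weights, and the
#' weights sum to one. If every entropy equals one the expression is
#' singular and equal weights `1/m` are returned.
#'
#' @param entropies List of `entropy_result` objects, or a numeric vector
#'   of entropies in `[0, 1]`.
#' @return Named numeric vector of weights summing to 1.
#' @export
entropy_weights <- function(entropies) {
  if (is.list(entropies)) {
    e <- vapply(entropies, `[[`, numeric(1), "entropy")
    names(e) <- vapply(entropies, `[[`, character(1), "name")
  } else {
    e <- entropies
  }
  m <- length(e)
  if (m < 2L) stop("need at least two indicators to weight", call. = FALSE)
  if (any(e < -1e-9 | e > 1 + 1e-9)) {
    stop("entropies must lie in [0, 1]", call. = FALSE)
  }
  denom <- m - sum(e)
  if (abs(denom) < 1e-12) {
    w <- rep(1 / m, m)  # all indicators maximally entropic: no signal to rank
  } else {
    w <- (1 - e) / denom
  }
  names(w) <- names(e)
  w
}
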