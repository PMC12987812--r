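#' Spatially local entropy weights in a moving window
#'
#' Recomputes entropy weights inside square windows so that the weighting
#' adapts to local landscape structure instead of being fixed scene-wide.
#' Windows are anchored on a stride grid and clamped (shrunk) at the
#' borders; per-pixel weights are bilinearly interpolated between anchor
#' windows and renormalized to sum to one. An exact per-pixel sliding
#' mode (every pixel gets the weights of its own centred window, no
#' interpolation) is retained as the correctness reference; windows whose
#' jointly-valid fraction falls below `min_valid_frac` inherit the global
#' scene weights.
#'
#' @param norms Named list of `normalized_indicator` objects (co-registered).
#' @param window_size Odd window edge length in pixels (default 133).
#'   A window at least as large as both raster dimensions degrades to
#'   global weighting (with a notice).
#' @param stride Anchor spacing in pixels; default `round(window_size / 4)`.
#' @param bin_count Histogram bins for the entropy (default 256).
#' @param mode `"interpolated"` (default), `"exact"` or `"global"`.
#' @param min_valid_frac Minimum jointly-valid fraction of a window below
#'   which it inherits the global weights (default 0.25).
#' @return A `weight_field`: list with `weights` (named list of per-pixel
#'   weight matrices, each pixel summing to 1), `m`, `window_size`,
#'   `stride`, `mode` and `global_weights`.
#' @export
moving_window_weights <- function(norms, window_size = 133L, stride = NULL,
                                  bin_count = 256L,
                                  mode = c("interpolated", "exact", "global"),
                                  min_valid_frac = 0.25) {
  mode <- match.arg(mode)
  stopifnot(is.list(norms), length(norms) >= 2L)
  window_size <- as.integer(window_size)
  if (window_size %% 2L == 0L || window_size < 3L) {
    stop("window_size must be odd and >= 3", call. = FALSE)
  }
  if (is.null(stride)) stride <- max(1L, as.integer(round(window_size / 4)))
  vals <- lapply(norms, `[[`, "values")
  shp <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), shp), logical(1)))) {
    stop("alignment error: indicators are not co-registered", call. = FALSE)
  }
  nr <- shp[1]; nc <- shp[2]
  m <- length(vals)
  nms <- names(norms)

  gw <- entropy_weights(lapply(norms, indicator_entropy, bin_count = bin_count))
  names(gw) <- nms

  make_field <- function(weight_list, used_mode) {
    structure(list(weights = weight_list, m = m, window_size = window_size,
                   stride = as.integer(stride), mode = used_mode,
                   bin_count = as.integer(bin_count), global_weights = gw),
              class = "weight_field")
  }
  constant_field <- function() {
    make_field(stats::setNames(
      lapply(gw, function(w) matrix(w, nr, nc)), nms), "global")
  }

  if (mode == "global") return(constant_field())
  if (window_size >= nr && window_size >= nc) {
    if (mode != "global") {
      message(sprintf("window (%d) covers the full %d x %d extent; using global weights",
                      window_size, nr, nc))
    }
    return(constant_field())
  }

  h <- (window_size - 1L) %/% 2L
  weights_in_window <- function(rr, cc) {
    cells <- length(rr) * length(cc)
    ys <- lapply(vals, function(v) v[rr, cc])
    valid_all <- !Reduce(`|`, lapply(ys, is.na))
    if (sum(valid_all) < min_valid_frac * cells) return(gw)
    e <- vapply(ys, function(y) {
      y <- y[!is.na(y)]
      if (length(y) == 0L) return(1)
      entropy_from_values(y, bin_count)$entropy
    }, numeric(1))
    entropy_weights(stats::setNames(e, nms))
  }

  if (mode == "exact") {
    wmats <- stats::setNames(lapply(seq_len(m), function(k) matrix(NA_real_, nr, nc)), nms)
    for (i in seq_len(nr)) {
      rr <- max(1L, i - h):min(nr, i + h)
      for (j in seq_len(nc)) {
        cc <- max(1L, j - h):min(nc, j + h)
        w <- weights_in_window(rr, cc)
        for (k in seq_len(m)) wmats[[k]][i, j] <- w[k]
      }
    }
    return(make_field(wmats, "exact"))
  }

  pr <- unique(c(seq(1L, nr, by = stride), nr))
  pc <- unique(c(seq(1L, nc, by = stride), nc))
  aw <- array(NA_real_, c(length(pr), length(pc), m))
  for (a in seq_along(pr)) {
    rr <- max(1L, pr[a] - h):min(nr, pr[a] + h)
    for (b in seq_along(pc)) {
      cc <- max(1L, pc[b] - h):min(nc, pc[b] + h)
      aw[a, b, ] <- weights_in_window(rr, cc)
    }
  }

  interp_axis <- function(pos, anchors) {
    if (length(anchors) == 1L) {
      list(k = rep(1L, length(pos)), k2 = rep(1L, length(pos)),
           t = rep(0, length(pos)))
    } else {
      k <- findInterval(pos, anchors, all.inside = TRUE)
      k2 <- k + 1L
      list(k = k, k2 = k2, t = (pos - anchors[k]) / (anchors[k2] - anchors[k]))
    }
  }
  ax_r <- interp_axis(seq_len(nr), pr)
  ax_c <- interp_axis(seq_len(nc), pc)
  TR <- matrix(ax_r$t, nr, nc)
  TC <- matrix(ax_c$t, nr, nc, byrow = TRUE)
  KR1 <- matrix(ax_r$k, nr, nc);  KR2 <- matrix(ax_r$k2, nr, nc)
  KC1 <- matrix(ax_c$k, nr, nc, byrow = TRUE); KC2 <- matrix(ax_c$k2, nr, nc, byrow = TRUE)
  wmats <- vector("list", m)
  for (k in seq_len(m)) {
    a <- aw[, , k]
    w11 <- matrix(a[cbind(as.vector(KR1), as.vector(KC1))], nr, nc)
    w21 <- matrix(a[cbind(as.vector(KR2), as.vector(KC1))], nr, nc)
    w12 <- matrix(a[cbind(as.vector(KR1), as.vector(KC2))], nr, nc)
    w22 <- matrix(a[cbind(as.vector(KR2), as.vector(KC2))], nr, nc)
    wmats[[k]] <- (1 - TR) * (1 - TC) * w11 + TR * (1 - TC) * w21 +
      (1 - TR) * TC * w12 + TR * TC * w22
  }
  names(wmats) <- nms
  ssum <- Reduce(`+`, wmats)
  wmats <- lapply(wmats, function(w) w / ssum)
  make_field(wmats, "interpolated")
}

#' @export
print.weight_field <- function(x, ...) {
  cat(sprintf("<weight_field> %d indicators, mode %s, window %d, stride %d\n",
              x$m, x$mode, x$window_size, x$stride))
  cat("  global weights:",
      paste(sprintf("%s=%.4f", names(x$global_weights), x$global_weights),
            collapse = " "), "\n")
  invisible(x)
}

#' Tidy a weight field
#'
#' @param x A `weight_field`.
#' @param ... Unused.
#' @return Tibble with one row per pixel and indicator: `row`, `col`,
#'   `indicator`, `weight`.
#' @export
#' @exportS3Method generics::tidy
tidy.weight_field <- function(x, ...) {
  purrr::imap_dfr(x$weights, function(w, nm) {
    idx <- which(!is.na(w), arr.ind = TRUE)
    tibble::tibble(row = idx[, 1], col = idx[, 2], indicator = nm,
                   weight = w[idx])
  })
}
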