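# Independent brute-force oracle: per-pixel clamped window, histogram
# entropy and weight formula written out directly.
brute_force_weights <- function(vals, window_size, bin_count = 256L,
                                min_valid_frac = 0.25) {
  m <- length(vals)
  nr <- nrow(vals[[1]]); nc <- ncol(vals[[1]])
  h <- (window_size - 1L) %/% 2L
  ent <- function(y) {
    y <- y[!is.na(y)]
    if (length(y) == 0) return(1)
    counts <- tabulate(pmin(floor(y * bin_count) + 1L, bin_count), bin_count)
    occ <- counts[counts > 0]
    if (length(occ) == 1L) return(0)
    p <- occ / sum(occ)
    -sum(p * log(p)) / log(length(occ))
  }
  wts <- function(e) {
    d <- m - sum(e)
    if (abs(d) < 1e-12) rep(1 / m, m) else (1 - e) / d
  }
  ge <- vapply(vals, ent, numeric(1))
  gw <- wts(ge)
  out <- lapply(seq_len(m), function(k) matrix(NA_real_, nr, nc))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- max(1, i - h):min(nr, i + h)
    cc <- max(1, j - h):min(nc, j + h)
    sub <- lapply(vals, function(v) v[rr, cc])
    valid <- !Reduce(`|`, lapply(sub, is.na))
    w <- if (sum(valid) < min_valid_frac * length(rr) * length(cc)) {
      gw
    } else {
      wts(vapply(sub, ent, numeric(1)))
    }
    for (k in seq_len(m)) out[[k]][i, j] <- w[k]
  }
  names(out) <- names(vals)
  out
}

make_random_norms <- function(seed, nr, nc, names = c("A", "B", "C")) {
  withr::with_seed(seed, {
    stats::setNames(lapply(names, function(nm) {
      make_norm(nm, matrix(runif(nr * nc), nr, nc))
    }), names)
  })
}

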