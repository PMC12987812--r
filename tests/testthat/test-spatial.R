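test_that("contiguity graphs enumerate rook and queen neighbourhoods", {
  m <- matrix(runif(4), 2, 2)
  w <- build_weights(m, scheme = "rook")
  W <- as.matrix(w$W)
  expect_equal(Matrix::rowSums(w$A), rep(2, 4))   # each corner: 2 rook neighbours
  expect_true(all(W[W > 0] == 0.5))
  expect_true(isSymmetric(as.matrix(w$A)))

  m3 <- matrix(runif(9), 3, 3)
  w3 <- build_weights(m3, scheme = "queen")
  centre <- which(w3$rows == 2 & w3$cols == 2)
  expect_equal(sum(w3$A[centre, ]), 8)
  expect_true(all(as.matrix(w3$W)[centre, -centre] %in% c(0, 1 / 8)))

  # nodata severs adjacency through the hole
  mh <- matrix(runif(9), 3, 3); mh[2, 2] <- NA
  wh <- build_weights(mh, scheme = "rook")
  expect_equal(wh$n, 8)
  corner <- which(wh$rows == 1 & wh$cols == 1)
  expect_equal(sum(wh$A[corner, ]), 2)  # centre neighbour gone from rook ring

  expect_error(build_weights(matrix(c(1, NA, NA, NA), 2, 2)), "at least 2")
})

test_that("checkerboard field under rook weights gives Moran's I = -1 exactly", {
  n <- 8
  cb <- outer(seq_len(n), seq_len(n), function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  w <- build_weights(cb, scheme = "rook")
  res <- morans_i(cb, w, n_permutations = 99, seed = 1)
  expect_equal(res$I, -1, tolerance = 1e-12)
  expect_equal(res$expected, -1 / (n * n - 1))

  # direct-summation oracle on the same graph
  z <- w$values - mean(w$values)
  A <- as.matrix(w$A)
  Wm <- A / rowSums(A)
  I_direct <- (length(z) / sum(Wm)) * as.numeric(t(z) %*% Wm %*% z) / sum(z^2)
  expect_equal(res$I, I_direct, tolerance = 1e-12)
})

test_that("a clustered block field has positive, significant Moran's I", {
  m <- matrix(0, 16, 16)
  m[1:8, 1:8] <- 1
  m <- m + withr::with_seed(2, matrix(rnorm(256, sd = 0.01), 16, 16))
  res <- morans_i(m, n_permutations = 199, seed = 3)
  expect_gt(res$I, 0.5)
  expect_lt(res$p_value, 0.05)

  # clustered field beats its own random permutation
  perm <- matrix(withr::with_seed(4, sample(as.vector(m))), 16, 16)
  res_p <- morans_i(perm, n_permutations = 99, seed = 5)
  expect_gt(res$I, res_p$I)
})

test_that("Moran's I agrees with an independent reference implementation", {
  skip_if_not_installed("ape")
  m <- withr::with_seed(8, matrix(rnorm(64), 8, 8))
  w <- build_weights(m, scheme = "queen")
  ours <- morans_i(m, w, n_permutations = 99, seed = 1)
  ref <- ape::Moran.I(w$values, as.matrix(w$W), scaled = FALSE)
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$expected, ref$expected, tolerance = 1e-12)
})

test_that("Moran permutation inference is seeded and rejects constants", {
  m <- withr::with_seed(10, matrix(rnorm(100), 10, 10))
  r1 <- morans_i(m, n_permutations = 99, seed = 42)
  r2 <- morans_i(m, n_permutations = 99, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(morans_i(matrix(1, 5, 5)), "degenerate variance")
  wself <- build_weights(m, include_self = TRUE)
  expect_error(morans_i(m, wself), "without self")
})

test_that("Gi* flags a planted plateau and is antisymmetric under negation", {
  m <- withr::with_seed(21, matrix(rnorm(128 * 128, sd = 0.05), 128, 128))
  m[60:64, 60:64] <- m[60:64, 60:64] + 2
  hs <- getis_ord_gistar(m)
  centre_z <- hs$gi_z[62, 62]
  peak <- which(hs$gi_z == max(hs$gi_z, na.rm = TRUE), arr.ind = TRUE)
  expect_true(all(peak[1, ] >= 60 & peak[1, ] <= 64))  # peak inside plateau
  expect_gt(centre_z, 2.576)
  expect_equal(hs$classes[62, 62], 3L)

  hneg <- getis_ord_gistar(-m)
  expect_equal(hneg$gi_z, -hs$gi_z, tolerance = 1e-9)
  expect_equal(hneg$classes[62, 62], -3L)
  expect_equal(cold_spot_count(hneg, 0.99),
               sum(hs$classes == 3L, na.rm = TRUE))

  expect_error(getis_ord_gistar(matrix(1, 6, 6)), "degenerate")
})

test_that("Gi* z-scores are centred near zero on random fields", {
  for (seed in c(31, 32)) {
    m <- withr::with_seed(seed, matrix(rnorm(128 * 128), 128, 128))
    hs <- getis_ord_gistar(m)
    expect_lt(abs(mean(hs$gi_z, na.rm = TRUE)), 0.05)
  }
})

test_that("class boundaries follow the 90/95/99 confidence thresholds", {
  m <- withr::with_seed(33, matrix(rnorm(32 * 32), 32, 32))
  hs <- getis_ord_gistar(m)
  z <- hs$gi_z; k <- hs$classes
  expect_true(all((abs(z) < 1.645) == (k == 0L), na.rm = TRUE))
  expect_true(all(sign(z[k != 0]) == sign(k[k != 0]), na.rm = TRUE))
  expect_true(all(abs(z[abs(k) == 3]) >= 2.576, na.rm = TRUE))
})

test_that("ECDF export is a right-continuous CDF, invariant to pixel order", {
  e <- ecdf_export(matrix(c(1, 2, 3), 1, 3))
  expect_equal(e$value, c(1, 2, 3))
  expect_equal(e$cum_fraction, c(1 / 3, 2 / 3, 1))

  m <- withr::with_seed(40, matrix(runif(100), 10, 10))
  p <- matrix(as.vector(m)[withr::with_seed(41, sample(100))], 10, 10)
  expect_equal(ecdf_export(m), ecdf_export(p))
  expect_equal(dplyr::last(ecdf_export(m)$cum_fraction), 1)

  # first-order dominance: shifting the field right moves F down
  e1 <- ecdf_export(m); e2 <- ecdf_export(m + 0.5)
  F1 <- stats::stepfun(e1$value, c(0, e1$cum_fraction), right = FALSE)
  F2 <- stats::stepfun(e2$value, c(0, e2$cum_fraction), right = FALSE)
  grid <- seq(0, 1.6, by = 0.05)
  expect_true(all(F2(grid) <= F1(grid) + 1e-12))
})
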