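# Independent scalar oracles, written directly from the index definitions.
oracle <- list(
  ndvi = function(b) (b$B5 - b$B4) / (b$B5 + b$B4),
  evi = function(b) 2.5 * (b$B5 - b$B4) / (b$B5 + 6 * b$B4 - 7.5 * b$B2 + 1),
  savi = function(b) ((b$B5 - b$B4) / (b$B5 + b$B4 + 0.5)) * 1.5,
  wetness = function(b) 0.1509 * b$B2 + 0.1973 * b$B3 + 0.3279 * b$B4 +
    0.3406 * b$B5 - 0.7112 * b$B6 - 0.4572 * b$B7,
  ndbi = function(b) (b$B6 - b$B5) / (b$B6 + b$B5),
  ndbsi = function(b) ((b$B6 - b$B5) / (b$B6 + b$B5) +
                         (b$B6 - b$B7) / (b$B6 + b$B7)) / 2,
  ui = function(b) (b$B6 - b$B5) / (b$B6 + b$B5)
)
oracle_lst <- function(tb, eps, lambda = 10.8e-6, rho = 1.438e-2) {
  tb / (1 + (lambda * tb / rho) * log(eps)) - 273.15
}

test_that("spectral indices reproduce hand-computed values", {
  s <- make_stack(B2 = 0.05, B3 = 0.1, B4 = 0.1, B5 = 0.5, B6 = 0.4, B7 = 0.3,
                  nr = 2, nc = 2)
  expect_equal(ndvi(s)$values[1, 1], 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(savi(s)$values[1, 1], (0.4 / 1.1) * 1.5, tolerance = 1e-12)
  expect_equal(ndbsi(s)$values[1, 1], ((-0.1 / 0.9) + (0.1 / 0.7)) / 2,
               tolerance = 1e-12)
  # SWIR 0.4, NIR 0.2, SWIR2 0.3: BI = 1/3, SI = 1/7, NDBSI = mean
  s2 <- make_stack(B5 = 0.2, B6 = 0.4, B7 = 0.3, nr = 1, nc = 1)
  expect_equal(ndbsi(s2)$values[1, 1], (0.2 / 0.6 + 0.1 / 0.7) / 2,
               tolerance = 1e-12)
  # wetness: all-ones gives the coefficient sum; B6=B7=0 case
  w1 <- make_stack(B2 = 1, B3 = 1, B4 = 1, B5 = 1, B6 = 1, B7 = 1, nr = 1, nc = 1)
  coef_sum <- 0.1509 + 0.1973 + 0.3279 + 0.3406 - 0.7112 - 0.4572
  expect_equal(wetness(w1)$values[1, 1], coef_sum, tolerance = 1e-12)
  expect_equal(coef_sum, -0.1517, tolerance = 1e-12)
  w0 <- make_stack(B2 = 0, B3 = 0, B4 = 0, B5 = 0, B6 = 0, B7 = 0, nr = 1, nc = 1)
  expect_equal(wetness(w0)$values[1, 1], 0)
  wh <- make_stack(B2 = 0.5, B3 = 0.5, B4 = 0.5, B5 = 0.5, B6 = 0, B7 = 0,
                   nr = 1, nc = 1)
  expect_equal(wetness(wh)$values[1, 1], 0.50835, tolerance = 1e-12)
})

test_that("indices match scalar oracles on random band tuples", {
  s <- random_stack(seed = 101, nr = 20, nc = 20)
  b <- s$bands
  got <- list(ndvi = ndvi(s), evi = evi(s), savi = savi(s),
              wetness = wetness(s), ndbi = ndbi(s), ndbsi = ndbsi(s),
              ui = ui(s))
  for (nm in names(oracle)) {
    expect_equal(got[[nm]]$values, oracle[[nm]](b), tolerance = 1e-12,
                 label = nm)
  }
  # CVI is the product of its three factors
  expect_equal(cvi(got$ndvi, evi(s), savi(s))$values,
               got$ndvi$values * oracle$evi(b) * oracle$savi(b),
               tolerance = 1e-12)
  # ISI from its definition
  expect_equal(isi(got$ndbi, got$ndvi)$values,
               (oracle$ndbi(b) - oracle$ndvi(b)) /
                 (oracle$ndbi(b) + oracle$ndvi(b)),
               tolerance = 1e-12)
})

test_that("zero numerators, annihilators and singular denominators behave", {
  s <- make_stack(B2 = 0.1, B3 = 0.1, B4 = 0.3, B5 = 0.3, B6 = 0.3, B7 = 0.3,
                  nr = 2, nc = 2)
  expect_equal(ndvi(s)$values, matrix(0, 2, 2))
  expect_equal(savi(s)$values, matrix(0, 2, 2))
  expect_equal(evi(s)$values, matrix(0, 2, 2))
  expect_equal(ndbsi(s)$values, matrix(0, 2, 2))
  expect_equal(ui(s)$values, matrix(0, 2, 2))

  z <- make_norm("x", matrix(0.5, 2, 2))
  expect_equal(cvi(indicator_raster("NDVI", matrix(0, 2, 2)),
                   indicator_raster("EVI", matrix(0.8, 2, 2)),
                   indicator_raster("SAVI", matrix(0.5, 2, 2)))$values,
               matrix(0, 2, 2))
  ones <- indicator_raster("x", matrix(1, 2, 2))
  expect_equal(cvi(ones, ones, ones)$values, matrix(1, 2, 2))

  # ISI: NDBI = 0.3, NDVI = 0.1 -> 0.5; NDBI = -NDVI -> nodata
  i1 <- isi(indicator_raster("NDBI", matrix(0.3, 1, 1)),
            indicator_raster("NDVI", matrix(0.1, 1, 1)))
  expect_equal(i1$values[1, 1], 0.5)
  i2 <- isi(indicator_raster("NDBI", matrix(0.2, 1, 1)),
            indicator_raster("NDVI", matrix(-0.2, 1, 1)))
  expect_true(is.na(i2$values[1, 1]))
})

test_that("normalized-difference indices are antisymmetric under band swap", {
  s <- random_stack(seed = 77, nr = 8, nc = 8)
  swapped <- s
  swapped$bands$B5 <- s$bands$B6
  swapped$bands$B6 <- s$bands$B5
  expect_equal(ndbi(swapped)$values, -ndbi(s)$values, tolerance = 1e-12)
  s2 <- s
  s2$bands$B4 <- s$bands$B5
  s2$bands$B5 <- s$bands$B4
  expect_equal(ndvi(s2)$values, -ndvi(s)$values, tolerance = 1e-12)
})

test_that("UI as printed equals NDBI bit-for-bit; SWIR2 variant differs", {
  s <- random_stack(seed = 5, nr = 6, nc = 6)
  expect_identical(ui(s)$values, ndbi(s)$values)
  expect_false(isTRUE(all.equal(ui(s, variant = "swir2")$values, ndbi(s)$values)))
  expect_equal(ui(s, variant = "swir2")$values,
               (s$bands$B7 - s$bands$B5) / (s$bands$B7 + s$bands$B5),
               tolerance = 1e-12)
})

test_that("LST retrieval matches the scalar formula and its limits", {
  # unit emissivity: LST = TB - 273.15 exactly
  s <- make_stack(B10 = 300, nr = 2, nc = 2)
  r <- lst(s, lst_constants(emissivity_mode = "fixed", emissivity = 1))
  expect_equal(r$values, matrix(300 - 273.15, 2, 2))

  r99 <- lst(s, lst_constants(emissivity_mode = "fixed", emissivity = 0.99))
  expect_equal(r99$values[1, 1], oracle_lst(300, 0.99), tolerance = 1e-12)

  # lowering emissivity at fixed TB raises LST
  r95 <- lst(s, lst_constants(emissivity_mode = "fixed", emissivity = 0.95))
  expect_gt(r95$values[1, 1], r99$values[1, 1])

  # radiance path: TB = k2 / ln(k1/L + 1)
  k1 <- 774.8853; k2 <- 1321.0789
  L <- 10.5
  sr <- make_stack(B10 = L, nr = 1, nc = 1, thermal_kind = "radiance")
  tb <- k2 / log(k1 / L + 1)
  rr <- lst(sr, lst_constants(emissivity_mode = "fixed", emissivity = 1))
  expect_equal(rr$values[1, 1], tb - 273.15, tolerance = 1e-10)

  expect_error(lst_constants(emissivity = 0), "domain error")
  expect_error(lst_constants(emissivity = 1.2), "domain error")
})

test_that("NDVI-threshold emissivity stays physical and piecewise correct", {
  nv <- matrix(c(-0.3, 0.1, 0.35, 0.7), 1, 4)
  e <- rsei:::ndvi_threshold_emissivity(nv)
  expect_equal(e[1, 1], 0.991)  # water
  expect_equal(e[1, 2], 0.966)  # bare soil
  pv <- ((0.35 - 0.2) / 0.3)^2
  expect_equal(e[1, 3], 0.986 + 0.004 * pv, tolerance = 1e-12)
  expect_equal(e[1, 4], 0.990)  # dense vegetation
  grid <- matrix(seq(-1, 1, length.out = 201), 1)
  eg <- rsei:::ndvi_threshold_emissivity(grid)
  expect_true(all(eg > 0 & eg <= 1))
})

test_that("missing bands raise configuration errors naming the band", {
  s <- make_stack(B4 = 0.2, B5 = 0.4, nr = 2, nc = 2)
  expect_error(wetness(s), "configuration error.*B2")
  expect_error(ndbsi(s), "configuration error.*B6")
  expect_error(lst(s), "configuration error.*B10")
})

test_that("index operations are elementwise: permuting pixels permutes outputs", {
  s <- random_stack(seed = 9, nr = 6, nc = 6)
  p <- withr::with_seed(1, sample(36))
  sp <- s
  for (nm in names(sp$bands)) {
    sp$bands[[nm]] <- matrix(as.vector(s$bands[[nm]])[p], 6, 6)
  }
  expect_equal(as.vector(ndvi(sp)$values), as.vector(ndvi(s)$values)[p],
               tolerance = 1e-15)
  expect_equal(as.vector(wetness(sp)$values), as.vector(wetness(s)$values)[p],
               tolerance = 1e-15)
})
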