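test_that("write/read round-trip preserves grids, georeferencing and mask", {
  s <- small_scene(seed = 11, n = 32, nodata_fraction = 0.05)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, tf)
  r1 <- read_stack(tf)

  expect_identical(names(r1$bands), names(s$bands))
  expect_identical(r1$grid_shape, s$grid_shape)
  expect_equal(r1$geotransform, s$geotransform)
  expect_identical(r1$crs, s$crs)
  expect_identical(r1$nodata_mask, s$nodata_mask)
  for (nm in names(s$bands)) {
    rng <- diff(range(s$bands[[nm]], na.rm = TRUE))
    expect_lt(max(abs(r1$bands[[nm]] - s$bands[[nm]]), na.rm = TRUE), 1e-9 * rng)
  }
  # a second write/read cycle stays within storage precision of the first
  tf2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(r1, tf2)
  r2 <- read_stack(tf2)
  expect_identical(r2$nodata_mask, r1$nodata_mask)
  for (nm in names(s$bands)) {
    rng <- diff(range(s$bands[[nm]], na.rm = TRUE))
    expect_lt(max(abs(r2$bands[[nm]] - r1$bands[[nm]]), na.rm = TRUE), 1e-9 * rng)
  }
})

test_that("read_stack validates band requests and missing files", {
  s <- small_scene(seed = 3, n = 8)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, tf)
  sub <- read_stack(tf, band_map = c("B2", "B5"))
  expect_identical(names(sub$bands), c("B2", "B5"))
  expect_error(read_stack(tf, band_map = "B99"), "configuration error.*B99")
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "I/O error")
})

test_that("surface-reflectance scaling applies gain/offset to optical bands only", {
  dn <- make_stack(B4 = 7273, B5 = 0, B10 = 300, nr = 2, nc = 2)
  s <- apply_sr_scaling(dn)
  expect_equal(s$bands$B4[1, 1], 0.0000275 * 7273 - 0.2, tolerance = 1e-12)
  expect_equal(s$bands$B5[1, 1], -0.2)
  expect_equal(s$bands$B10[1, 1], 300)  # thermal passes through

  msk <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  dn2 <- make_stack(B4 = 100, B10 = 300, nr = 2, nc = 2, nodata_mask = msk)
  s2 <- apply_sr_scaling(dn2)
  expect_true(is.na(s2$bands$B4[1, 1]))
  expect_false(anyNA(s2$bands$B4[!msk]))
})

test_that("cloud filtering retains scenes under the threshold, in order", {
  mk <- function(cf) make_stack(B4 = 0.1, nr = 2, nc = 2, cloud_fraction = cf)
  scenes <- lapply(c(0.01, 0.04, 0.10), mk)
  kept <- filter_by_cloud(scenes)
  expect_length(kept, 2)
  expect_equal(vapply(kept, `[[`, numeric(1), "cloud_fraction"), c(0.01, 0.04))
  expect_error(filter_by_cloud(lapply(c(0.05, 0.9), mk)), "no usable scenes")
  expect_length(filter_by_cloud(lapply(c(0.05, 0.9), mk), max_cloud = 1.0), 2)
})

test_that("median composite ignores per-pixel nodata and is permutation-invariant", {
  m1 <- matrix(0.1, 2, 2); m2 <- matrix(0.2, 2, 2); m3 <- matrix(0.9, 2, 2)
  s1 <- make_stack(B4 = m1, nr = 2, nc = 2)
  s2 <- make_stack(B4 = m2, nr = 2, nc = 2)
  s3 <- make_stack(B4 = m3, nr = 2, nc = 2)
  comp <- median_composite(list(s1, s2, s3))
  expect_equal(comp$bands$B4, matrix(0.2, 2, 2))
  expect_identical(median_composite(list(s1))$bands$B4, m1)

  # one scene nodata at a pixel: median over the remaining {0.3, 0.5} = 0.4
  a <- matrix(0.3, 2, 2); a[1, 1] <- NA
  sa <- make_stack(B4 = a, nr = 2, nc = 2)
  sb <- make_stack(B4 = 0.3, nr = 2, nc = 2)
  sc <- make_stack(B4 = 0.5, nr = 2, nc = 2)
  cm <- median_composite(list(sa, sb, sc))
  expect_equal(cm$bands$B4[1, 1], 0.4)
  expect_false(cm$nodata_mask[1, 1])

  # all-nodata pixel stays nodata
  b <- matrix(0.5, 2, 2); b[2, 2] <- NA
  a2 <- a; a2[2, 2] <- NA
  cm2 <- median_composite(list(make_stack(B4 = a2, nr = 2, nc = 2),
                               make_stack(B4 = b, nr = 2, nc = 2)))
  expect_true(cm2$nodata_mask[2, 2])

  perm <- median_composite(list(s3, s1, s2))
  expect_identical(perm$bands, comp$bands)
})

test_that("AOI clipping uses pixel centres, crops, and never adds valid pixels", {
  s <- make_stack(B4 = matrix(runif(100), 10, 10), nr = 10, nc = 10)
  # pixel size 30, origin (0, 0): full extent x in [0, 300], y in [-300, 0]
  full <- aoi_polygon(rbind(c(-1, 1), c(301, 1), c(301, -301), c(-1, -301), c(-1, 1)))
  cf <- clip_to_aoi(s, full)
  expect_identical(cf$bands$B4, s$bands$B4)

  # left half: x < 150 covers columns 1..5 by pixel centres
  left <- aoi_polygon(rbind(c(0, 0), c(150, 0), c(150, -300), c(0, -300), c(0, 0)))
  cl <- clip_to_aoi(s, left)
  expect_identical(dim(cl$bands$B4), c(10L, 5L))
  expect_identical(cl$bands$B4, s$bands$B4[, 1:5])

  valid_before <- sum(!s$nodata_mask)
  expect_lte(sum(!cl$nodata_mask), valid_before)

  far <- aoi_polygon(rbind(c(1000, 1000), c(1100, 1000), c(1100, 1100), c(1000, 1000)))
  expect_error(clip_to_aoi(s, far), "empty intersection")
})

test_that("GeoJSON AOI parsing handles polygons with holes", {
  gj <- list(
    type = "Feature",
    geometry = list(
      type = "Polygon",
      coordinates = list(
        list(list(0, 0), list(300, 0), list(300, -300), list(0, -300), list(0, 0)),
        list(list(100, -100), list(200, -100), list(200, -200), list(100, -200),
             list(100, -100))
      )
    )
  )
  tf <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, tf, auto_unbox = TRUE, digits = NA)
  aoi <- read_aoi(tf)
  expect_true(points_in_aoi(aoi, 50, -50))     # inside outer ring
  expect_false(points_in_aoi(aoi, 150, -150))  # inside the hole
  expect_false(points_in_aoi(aoi, 400, -50))   # outside
})
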