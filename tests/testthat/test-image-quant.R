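test_that("tile_image validates channel geometry and intensity range", {
  m <- matrix(0.5, 8, 8)
  expect_s3_class(tile_image(m, m, m), "tile_image")
  expect_error(tile_image(m, m, matrix(0.5, 8, 9)), "identical dimensions")
  expect_error(tile_image(m, m + 1, m), "outside")
  bad <- m; bad[1] <- NA
  expect_error(tile_image(bad, m, m), "non-finite")
})

test_that("auto_threshold separates a bimodal image and handles degeneracy", {
  img <- matrix(c(rep(0.1, 32), rep(0.9, 32)), 8, 8)
  th <- auto_threshold(img)
  expect_gt(th, 0.1)
  expect_lt(th, 0.9)
  # constant image: threshold equals the constant; the ROI floor rule then
  # yields an empty foreground
  const <- matrix(0.3, 8, 8)
  expect_identical(auto_threshold(const), 0.3)
  roi <- compute_roi(tile_image(const, const, const))
  expect_identical(roi$roi_area, 0L)
  expect_error(auto_threshold(numeric(0)), "empty")
  expect_error(auto_threshold(c(0.1, NA)), "non-finite")
})

test_that("auto_threshold matches exhaustive between-class-variance search", {
  set.seed(42)
  for (i in 1:25) {
    # 256-level image with a random two-component mixture
    n <- 400
    x <- c(rnorm(n / 2, runif(1, 0.2, 0.4), 0.05),
           rnorm(n / 2, runif(1, 0.6, 0.8), 0.05))
    x <- pmin(pmax(x, 0), 1)
    x <- round(x * 255) / 255
    expect_equal(auto_threshold(x), brute_otsu(x))
  }
  # independent cross-check against EBImage's histogram-based Otsu: the two
  # conventions agree up to their bin quantisation on a bimodal mixture
  xm <- c(rnorm(2048, 0.3, 0.06), rnorm(2048, 0.75, 0.06))
  img <- matrix(round(pmin(pmax(xm, 0), 1) * 255) / 255, 64, 64)
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  expect_lt(abs(auto_threshold(img) - ref), 3 / 255)
})

test_that("ROI is CK foreground minus dilated nuclei, with degenerate guards", {
  n <- 64
  epith <- matrix(FALSE, n, n); epith[10:50, 10:50] <- TRUE
  ck <- matrix(0.02, n, n); ck[epith] <- 0.5
  dapi_empty <- matrix(0.02, n, n)
  her2 <- matrix(0.3, n, n)
  # no nuclei: mask equals the CK foreground
  tl <- tile_image(dapi_empty, ck, her2)
  roi <- compute_roi(tl)
  expect_identical(unname(roi$mask), unname(epith))
  # DAPI foreground covering all CK foreground: empty mask
  dapi_full <- matrix(0.02, n, n); dapi_full[epith] <- 0.9
  roi2 <- compute_roi(tile_image(dapi_full, ck, her2))
  expect_identical(roi2$roi_area, 0L)
  # nuclei are excluded together with a 1-pixel dilated rim
  dapi_nuc <- matrix(0.02, n, n); dapi_nuc[20:24, 20:24] <- 0.9
  roi3 <- compute_roi(tile_image(dapi_nuc, ck, her2))
  expect_false(any(roi3$mask[19:25, 19:25]))
  expect_true(roi3$mask[17, 17])
  # ROI never includes sub-threshold CK pixels
  expect_true(all(ck[roi3$mask] >= roi3$ck_threshold))
})

test_that("ROI recovers the generator's epithelial ground truth", {
  ph <- case_phenotype(0.4, n_tiles = 6, epithelial_fraction = 1,
                       artifact_rate = 0, seed = 5)
  cfg <- small_config()
  for (i in 0:5) {
    tl <- generate_tile(ph, i, small_imaging())
    truth <- attr(tl, "truth")
    roi <- compute_roi(tl, cfg)
    ref <- truth$epithelium & !truth$nuclei
    jac <- sum(roi$mask & ref) / sum(roi$mask | ref)
    expect_gte(jac, 0.8)
  }
})

test_that("measure_tile averages the channels over the ROI", {
  n <- 16
  ck <- matrix(0.02, n, n)
  her2 <- matrix(0.02, n, n)
  ck[1:2, 1:2] <- 0.6
  her2[1:2, 1:2] <- c(0.2, 0.2, 0.4, 0.4)
  tl <- tile_image(matrix(0.02, n, n), ck, her2)
  roi <- compute_roi(tl, default_config(min_foreground_fraction = 0.01))
  m <- measure_tile(tl, roi, default_config(min_roi_pixels = 4))
  expect_identical(m$roi_area, 4L)
  expect_equal(m$her2_mean, 0.3)
  expect_equal(m$ck_mean, 0.6)
  expect_true(m$valid)
  # empty ROI: invalid, means undefined
  flat <- matrix(0.02, n, n)
  tl2 <- tile_image(flat, flat, flat)
  m2 <- measure_tile(tl2, compute_roi(tl2), default_config())
  expect_false(m2$valid)
  expect_true(is.na(m2$ck_mean))
  # mismatched ROI is rejected
  big <- tile_image(matrix(0.02, 32, 32), matrix(0.02, 32, 32),
                    matrix(0.02, 32, 32))
  expect_error(measure_tile(tl, compute_roi(big)), "dimensions")
})

test_that("zero-noise generator tiles measure the configured CK level exactly", {
  img <- small_imaging(noise_sd = 0, background = c(dapi = 0, ck = 0, her2 = 0))
  ph <- case_phenotype(0.3, n_tiles = 4, epithelial_fraction = 1,
                       artifact_rate = 0, stain_factor = 1, seed = 2)
  for (i in 0:3) {
    tl <- generate_tile(ph, i, img)
    m <- measure_tile(tl, compute_roi(tl, small_config()), small_config())
    expect_identical(m$ck_mean, img$ck_level)
  }
})

test_that("measure_case preserves order, flags empties, and scales with expression", {
  imgp <- small_imaging()
  ph <- case_phenotype(0.2, expression_cv = 0.02, n_tiles = 12,
                       epithelial_fraction = 1, artifact_rate = 0, seed = 9)
  ph2 <- case_phenotype(0.4, expression_cv = 0.02, n_tiles = 12,
                        epithelial_fraction = 1, artifact_rate = 0, seed = 9)
  m1 <- measure_case(generate_case_images(ph, imgp), small_config())
  m2 <- measure_case(generate_case_images(ph2, imgp), small_config())
  expect_identical(nrow(m1), 12L)
  # doubling the expression level roughly doubles the background-corrected
  # HER2 mean (tolerance from the tile-level dispersion)
  bg <- imgp$background[["her2"]]
  expect_equal(mean(m2$her2_mean - bg) / mean(m1$her2_mean - bg), 2,
               tolerance = 0.1)
  # deterministic: repeated measurement of the same tiles is identical
  m1b <- measure_case(generate_case_images(ph, imgp), small_config())
  expect_identical(m1, m1b)
  expect_error(measure_case(list()), "no tiles")
})
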