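test_that("preprocess_params validates its fields", {
  expect_error(preprocess_params(clahe_tile = 1), "clahe_tile")
  expect_error(preprocess_params(clahe_clip = 0), "clahe_clip")
  expect_error(preprocess_params(blur_sigma = -1), "blur_sigma")
  expect_error(preprocess_params(fixed_threshold = 300), "fixed_threshold")
  expect_error(preprocess_params(crop_mode = "manual"), "manual_roi")
})

test_that("contrast equalization follows the CDF transfer function", {
  # constant image: nothing to redistribute
  const <- equalize_contrast(matrix(100, 16, 16),
                             preprocess_params(clahe_tile = 8))
  expect_true(all(const == 100))
  # two equal-count levels, one tile, no clipping: CDF oracle sends the
  # levels to the range extremes: cdf(50) = n/2 = cdf_min -> 0; cdf(200) =
  # n -> 255
  img <- matrix(rep(c(50, 200), each = 32), 8, 8)
  eq <- equalize_contrast(img, preprocess_params(clahe_tile = 8,
                                                 clahe_clip = Inf))
  expect_identical(sort(unique(as.vector(eq))), c(0, 255))
  expect_true(all((eq == 0) == (img == 50)))
  # full (one-tile, unclipped) equalization is idempotent up to quantization
  ramp <- matrix(rep(0:255, length.out = 64 * 64), 64, 64)
  p <- preprocess_params(clahe_tile = 64, clahe_clip = Inf)
  e1 <- equalize_contrast(ramp, p)
  e2 <- equalize_contrast(e1, p)
  expect_lte(max(abs(e2 - e1)), 1)
  # oversized tile rejected
  expect_error(equalize_contrast(matrix(0, 32, 32),
                                 preprocess_params(clahe_tile = 64)),
               "clahe_tile")
  # clipping bounds local amplification: a flat noisy field keeps a small
  # dynamic range under the default clip limit
  noisy <- withr::with_seed(9,
    matrix(pmin(255, pmax(0, 80 + round(rnorm(64 * 64, 0, 3)))), 64, 64))
  eqc <- equalize_contrast(noisy, preprocess_params(clahe_tile = 32,
                                                    clahe_clip = 2))
  expect_lt(diff(range(eqc)), 150)
})

test_that("growth-boundary cropping finds the dominant bright region", {
  f <- matrix(10, 100, 100)
  f[31:50, 41:60] <- 240
  cr <- crop_growth_boundary(f, preprocess_params(blur_sigma = 0))
  expect_identical(dim(cr), c(20L, 20L))
  expect_identical(attr(cr, "crop_offset"), c(row = 30L, col = 40L))
  # manual full-frame ROI is the identity
  p <- preprocess_params(crop_mode = "manual", manual_roi = c(0, 0, 100, 100))
  cr2 <- crop_growth_boundary(f, p)
  expect_identical(cr2[, ], f[, ])
  expect_identical(attr(cr2, "crop_offset"), c(row = 0L, col = 0L))
  # half-open ROI semantics
  p3 <- preprocess_params(crop_mode = "manual", manual_roi = c(10, 20, 30, 25))
  cr3 <- crop_growth_boundary(f, p3)
  expect_identical(dim(cr3), c(20L, 5L))
  expect_identical(cr3[1, 1], f[11, 21])
  # all-dark frame: degenerate
  expect_error(crop_growth_boundary(matrix(5, 64, 64), preprocess_params()),
               class = "cordnet_no_growth_region")
  expect_error(crop_growth_boundary(f, preprocess_params(
    crop_mode = "manual", manual_roi = c(0, 0, 200, 200))), "bounds")
})

test_that("gaussian blur is mass-conserving, constant-preserving, identity at 0", {
  f <- matrix(runif(32 * 32) * 255, 32, 32)
  expect_identical(blur_image(f, preprocess_params(blur_sigma = 0)), f)
  cm <- matrix(120, 32, 32)
  expect_equal(blur_image(cm, preprocess_params(blur_sigma = 3)), cm,
               tolerance = 1e-9)
  imp <- matrix(0, 33, 33); imp[17, 17] <- 255
  b <- blur_image(imp, preprocess_params(blur_sigma = 2))
  expect_equal(sum(b), 255, tolerance = 1e-6 * 255)
  expect_identical(dim(b), dim(imp))
})

test_that("Otsu binarization matches the brute-force threshold scan", {
  img <- matrix(rep(c(50, 200), each = 50), 10, 10)
  bm <- binarize(img, preprocess_params(min_object_px = 0))
  th <- attr(bm, "threshold")
  expect_gte(th, 50); expect_lt(th, 200)
  expect_equal(bm, matrix(img == 200, 10, 10), ignore_attr = TRUE)
  # oracle scan agrees on the two-level image
  t_star <- otsu_oracle(img)
  expect_identical(unname(bm[, ]), unname(img > t_star))
  # fixed threshold at the intensity maximum gives empty foreground
  bf <- binarize(img, preprocess_params(threshold_method = "fixed",
                                        fixed_threshold = 255,
                                        min_object_px = 0))
  expect_false(any(bf))
  # constant image: degenerate histogram
  expect_error(binarize(matrix(7, 8, 8), preprocess_params()),
               class = "cordnet_degenerate_histogram")
})

test_that("Otsu separates a bimodal Gaussian mixture with <1% error", {
  n <- 1e5
  labels <- withr::with_seed(42, runif(n) < 0.5)
  vals <- withr::with_seed(43, ifelse(labels, rnorm(n, 180, 10), rnorm(n, 60, 10)))
  img <- matrix(pmin(255, pmax(0, vals)), 400, 250)
  bm <- binarize(img, preprocess_params(min_object_px = 0))
  mis <- mean(bm != matrix(labels, 400, 250))
  expect_lt(mis, 0.01)
})

test_that("speckle removal drops components below min_object_px", {
  img <- matrix(10, 50, 50)
  img[10:20, 10:20] <- 200   # 121 px
  img[40, 40] <- 200         # 1 px speck
  bm <- binarize(img, preprocess_params(min_object_px = 16))
  expect_identical(sum(bm), 121L)
  expect_false(bm[40, 40])
})

test_that("preprocess_frame degrades gracefully on empty frames", {
  w <- capture_warnings(m <- preprocess_frame(matrix(5, 64, 64),
                                              preprocess_params()))
  expect_match(w, "no growth region", all = FALSE)
  expect_match(w, "degenerate", all = FALSE)
  expect_false(any(m))
  expect_identical(dim(m), c(64L, 64L))
})
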