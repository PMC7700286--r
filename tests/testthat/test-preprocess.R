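test_that("breast segmentation recovers the phantom foreground", {
  # CC phantoms: the stored breast mask is the full half-ellipse foreground
  withr::with_seed(21, {
    for (i in 1:8) {
      p <- generate_phantom(phantom_spec(64, 64, target_pd = runif(1, 0.05, 0.9),
                                         view = "CC", seed = 300 + i))
      bm <- segment_breast(p$image)
      jac <- sum(bm * p$breast) / sum(pmax(bm, p$breast))
      expect_gte(jac, 0.95)
    }
  })
  expect_error(segment_breast(matrix(0, 64, 64)), "empty breast")
  expect_error(segment_breast(matrix(0.7, 64, 64)), "empty breast")
})

test_that("only the largest connected foreground component is kept", {
  img <- matrix(0, 64, 64)
  img[10:41, 10:41] <- 0.8          # ~1000 px block
  img[55:61, 55:61] <- 0.8          # ~50 px block
  bm <- segment_breast(img)
  expect_equal(sum(bm[10:41, 10:41]), 32 * 32)
  expect_equal(sum(bm[55:61, 55:61]), 0)
})

test_that("orientation detection follows the breast-mass side", {
  pL <- generate_phantom(phantom_spec(64, 64, target_pd = 0.3, side = "left",
                                      seed = 17))
  bm <- segment_breast(pL$image)
  expect_equal(detect_orientation(pL$image, bm), "left")
  flipped <- pL$image$pixels[, 64:1]
  bmf <- bm[, 64:1]
  expect_equal(detect_orientation(flipped, bmf), "right")
  right_only <- matrix(0, 10, 10); right_only[, 8:10] <- 1
  expect_equal(detect_orientation(matrix(0.5, 10, 10), right_only), "right")
  tie <- matrix(0, 10, 10); tie[5, 3] <- 1; tie[5, 8] <- 1
  expect_equal(detect_orientation(matrix(0.5, 10, 10), tie), "left")
  expect_error(detect_orientation(matrix(0.5, 4, 4), matrix(0, 4, 4)),
               "empty")
})

test_that("pectoral removal recovers the triangle and spares dense tissue", {
  withr::with_seed(22, {
    jacs <- numeric(10)
    for (i in 1:10) {
      p <- generate_phantom(phantom_spec(64, 64, target_pd = runif(1, 0.1, 0.7),
                                         view = "MLO",
                                         side = sample(c("left", "right"), 1),
                                         seed = 400 + i))
      bm <- segment_breast(p$image)
      res <- remove_pectoral(p$image, bm, detect_orientation(p$image, bm))
      jacs[i] <- sum(res$pectoral_mask * p$pectoral) /
        sum(pmax(res$pectoral_mask, p$pectoral))
      # never removes a dense pixel, never grows the breast mask
      expect_equal(sum(res$pectoral_mask * p$dense), 0)
      expect_lte(sum(res$breast_mask), sum(bm))
      expect_equal(sum(res$pectoral_mask * res$breast_mask), 0)
    }
    expect_gte(mean(jacs), 0.80)
  })
})

test_that("CC views and degenerate seeds pass through pectoral removal", {
  p <- generate_phantom(phantom_spec(64, 64, target_pd = 0.3, view = "CC",
                                     seed = 5))
  bm <- segment_breast(p$image)
  res <- remove_pectoral(p$image, bm)
  expect_equal(sum(res$pectoral_mask), 0)
  expect_identical(res$image$pixels, p$image$pixels)
  expect_false(res$warning)

  # MLO with a dark top corner: seed outside foreground -> warning flag
  img <- matrix(0, 64, 64); img[30:60, 1:40] <- 0.6
  mg <- mammogram(img, view = "MLO", side = "left")
  bm2 <- segment_breast(mg)
  res2 <- remove_pectoral(mg, bm2, "left")
  expect_true(res2$warning)
  expect_equal(sum(res2$pectoral_mask), 0)
})

test_that("standardization resizes to a square and is idempotent", {
  big <- mammogram(matrix(0.5, 3328, 4084), view = "CC")
  out <- standardize(big, 512)
  expect_equal(dim(out$pixels), c(512L, 512L))
  expect_equal(out$original_shape, c(3328L, 4084L))
  expect_true(all(abs(out$pixels - 0.5) < 1e-6))   # constant stays constant

  sm <- mammogram(matrix(runif(64 * 64), 64, 64), view = "CC")
  once <- standardize(sm, 64)
  expect_identical(once$pixels, sm$pixels)          # identity at target size
  twice <- standardize(standardize(sm, 128), 128)
  expect_identical(twice$pixels, standardize(sm, 128)$pixels)
  expect_error(standardize(sm, c(64, 128)), "square")
  expect_error(standardize(sm, 16), "at least 32")
  expect_true(all(standardize(sm, 128)$pixels >= 0 &
                  standardize(sm, 128)$pixels <= 1))
})

test_that("full preprocessing produces consistent masks at the working size", {
  p <- generate_phantom(phantom_spec(96, 96, target_pd = 0.4, view = "MLO",
                                     seed = 13))
  pp <- preprocess_mammogram(p$image, size = 64)
  expect_equal(dim(pp$image$pixels), c(64L, 64L))
  expect_equal(dim(pp$breast_mask), c(64L, 64L))
  expect_equal(sum(pp$breast_mask * pp$pectoral_mask), 0)
  expect_true(all(pp$breast_mask %in% c(0, 1)))
})
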