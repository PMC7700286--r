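test_that("phantom generation hits the target density with exact masks", {
  p0 <- generate_phantom(phantom_spec(64, 64, target_pd = 0, blob_count = 0,
                                      seed = 1))
  expect_equal(sum(p0$dense), 0)
  expect_equal(p0$birads, "I")

  p <- generate_phantom(phantom_spec(64, 64, target_pd = 0.6, seed = 2))
  frac <- sum(p$dense) / sum(p$breast)    # brute-force pixel count
  expect_gte(frac, 0.58); expect_lte(frac, 0.62)
  expect_equal(p$birads, "III")
  expect_true(all(p$dense <= p$breast))   # dense contained in breast

  # bit-identical determinism
  q1 <- generate_phantom(phantom_spec(64, 64, target_pd = 0.4, seed = 7))
  q2 <- generate_phantom(phantom_spec(64, 64, target_pd = 0.4, seed = 7))
  expect_identical(q1$image$pixels, q2$image$pixels)
  expect_identical(q1$dense, q2$dense)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(target_pd = 1.2), "target_pd")
  expect_error(phantom_spec(target_pd = -0.1), "target_pd")
  expect_error(phantom_spec(height = 16), "32x32")
  expect_error(phantom_spec(target_pd = 0.5, blob_count = 0), "blob_count")
  expect_error(phantom_spec(32, 32, blob_count = 40), "too small")
  expect_error(phantom_spec(fatty_mean = 0.8, dense_mean = 0.5), "dense_mean")
})

test_that("achieved density tracks the target over random specs", {
  withr::with_seed(2024, {
    for (i in 1:100) {
      pd <- runif(1)
      sp <- phantom_spec(48, 48, target_pd = pd,
                         view = sample(c("CC", "MLO"), 1),
                         side = sample(c("left", "right"), 1),
                         blob_count = sample(3:8, 1), seed = i)
      p <- generate_phantom(sp)
      expect_lte(abs(p$achieved_pd - pd), 0.02)
      expect_true(all(p$dense <= p$breast))
      expect_equal(sum(p$dense * p$pectoral), 0)
      expect_equal(p$birads,
                   as.character(birads_from_pd(100 * p$achieved_pd)))
    }
  })
})

test_that("augmentation ops preserve shape, binarity and their contracts", {
  p <- generate_phantom(phantom_spec(64, 64, target_pd = 0.4, seed = 3))
  img <- p$image$pixels; msk <- p$dense

  flip <- augment_op("flip")
  once <- augment_image(img, msk, flip)
  twice <- augment_image(once$image, once$mask, flip)
  expect_identical(twice$image, img)           # involution
  expect_identical(twice$mask, msk)

  idg <- augment_image(img, msk, augment_op("illumination", 1.0))
  expect_equal(idg$image, img)                 # gamma 1 is the identity
  expect_identical(idg$mask, msk)
  dark <- augment_image(img, msk, augment_op("illumination", 1.2))
  expect_identical(dark$mask, msk)             # mask never changes

  sc <- augment_image(img, msk, augment_op("scale", 1.1))
  expect_equal(dim(sc$image), dim(img))
  expect_true(all(sc$mask %in% c(0, 1)))
  n0 <- sum(msk); n1 <- sum(sc$mask)
  expect_lte(abs(n1 - n0) / n0, 0.25)          # foreground roughly preserved
  sc2 <- augment_image(img, msk, augment_op("scale", 0.9))
  expect_equal(dim(sc2$image), dim(img))

  expect_error(augment_op("rotate"), "unknown augmentation kind")
  expect_error(augment_op("illumination", -1), "positive")
})

test_that("class balancing reaches exact per-class counts deterministically", {
  man <- make_manifest(c(108, 116, 80, 22))
  bal <- balance_classes(man, 798, seed = 5)
  tr <- bal[bal$split == "train", ]
  expect_equal(unname(table(tr$birads)[c("I", "II", "III", "IV")]),
               rep(798L, 4), ignore_attr = TRUE)
  expect_equal(nrow(tr), 3192)
  expect_true(all(is.na(man$aug_kind) | man$aug_kind == ""))
  added <- bal[!is.na(bal$aug_kind), ]
  expect_true(all(added$aug_kind %in% c("illumination", "scale", "flip")))

  # no-op on an already balanced manifest
  man2 <- make_manifest(c(10, 10))
  expect_equal(nrow(balance_classes(man2, 10, seed = 1)), nrow(man2))

  # determinism
  man3 <- make_manifest(c(5, 5))
  b1 <- balance_classes(man3, 10, seed = 9)
  b2 <- balance_classes(man3, 10, seed = 9)
  expect_identical(b1, b2)

  expect_error(balance_classes(man, 100, seed = 1), "below an existing")
})

test_that("holdout split is patient-disjoint with floor training shares", {
  # one class, 798 single-record patients: the printed 638/160 arithmetic
  man <- make_manifest(798, records_per_patient = 1L)
  sp <- holdout_split(man, 0.8, seed = 1)
  expect_equal(sum(sp$split == "train"), 638)
  expect_equal(sum(sp$split == "val"), 160)

  all_train <- holdout_split(man, 1.0, seed = 1)
  expect_true(all(all_train$split == "train"))

  # 10 patients x 4 records: 8 train patients, 2 val, no overlap
  man4 <- make_manifest(40, records_per_patient = 4L)
  sp4 <- holdout_split(man4, 0.8, seed = 2)
  tr_pat <- unique(sp4$patient_id[sp4$split == "train"])
  va_pat <- unique(sp4$patient_id[sp4$split == "val"])
  expect_equal(length(tr_pat), 8)
  expect_equal(length(va_pat), 2)
  expect_equal(length(intersect(tr_pat, va_pat)), 0)

  expect_warning(holdout_split(make_manifest(4, 4), 0.8, seed = 3),
                 "single patient")
})

test_that("no patient ever lands in two splits over random manifests", {
  withr::with_seed(31, {
    for (i in 1:50) {
      counts <- sample(8:40, sample(2:4, 1), replace = TRUE)
      rpp <- sample(c(1L, 2L, 4L), 1)
      man <- make_manifest(counts, records_per_patient = rpp)
      sp <- suppressWarnings(holdout_split(man, runif(1, 0.5, 0.9), seed = i))
      per_pat <- tapply(sp$split, sp$patient_id,
                        function(s) length(unique(s)))
      expect_true(all(per_pat == 1))
    }
  })
})

test_that("phantom datasets round-trip through disk with a valid manifest", {
  dir <- withr::local_tempdir()
  man <- write_phantom_dataset(dir, n_per_class = 4, size = 48, seed = 11)
  expect_equal(nrow(man), 16)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man2$image_path, man$image_path)
  validate_manifest(man2, check_files = TRUE)
  r <- load_record(man2[1, , drop = FALSE])
  expect_equal(dim(r$image), c(48, 48))
  expect_true(all(r$mask %in% c(0, 1)))
  # labels recorded in the manifest match recomputation from the masks
  pd <- 100 * sum(r$mask) / sum(r$breast_mask)
  expect_equal(man2$birads[1], as.character(birads_from_pd(pd)))
})
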