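test_that("softmax probabilities are normalized for arbitrary masks", {
  cfg <- cnn_config(input_size = 64, channels = c(4, 8, 16), seed = 2)
  net <- mammodense:::with_seed(2, mammodense:::build_cnn(cfg))
  clf <- structure(list(net = net, cfg = cfg, class_weights = rep(0.75, 4)),
                   class = "cnn_classifier")
  withr::with_seed(10, {
    for (i in 1:20) {
      m <- matrix(rbinom(64 * 64, 1, runif(1)), 64, 64)
      r <- classify_mask(clf, m)
      expect_equal(sum(r$probabilities), 1, tolerance = 1e-6)
      expect_true(all(r$probabilities >= 0))
      expect_true(as.character(r$class) %in% c("I", "II", "III", "IV"))
    }
  })
  # evaluation mode is deterministic (dropout disabled)
  m <- matrix(rbinom(64 * 64, 1, 0.5), 64, 64)
  expect_identical(classify_mask(clf, m)$probabilities,
                   classify_mask(clf, m)$probabilities)
})

test_that("a single epoch on one batch trains without error and moves weights", {
  s <- make_mask_set(4, 5000)
  cfg <- cnn_config(input_size = 64, channels = c(4, 8, 16), epochs = 1,
                    batch_size = 16, seed = 6)
  clf <- train_classifier(s$masks, s$labels, cfg)
  expect_true(is.finite(clf$log$train_loss[1]))
  fresh <- mammodense:::with_seed(mammodense:::stage_seed(6, "cnn-init"),
                                  mammodense:::build_cnn(cfg))
  expect_false(isTRUE(all.equal(mammodense:::get_params(clf$net),
                                mammodense:::get_params(fresh))))
  expect_error(train_classifier(list(matrix(0.5, 8, 8)), "I", cfg),
               "binary")
  expect_error(train_classifier(s$masks, rep("V", length(s$masks)), cfg),
               "BI-RADS")
})

test_that("the CNN separates phantom density classes at small scale", {
  s <- make_mask_set(30, 6000)    # 120 masks, margins inside each class
  idx <- withr::with_seed(3, sample(length(s$masks)))
  tr <- idx[1:96]; te <- idx[97:120]
  cfg <- cnn_config(input_size = 64, channels = c(8, 16, 32), epochs = 12,
                    batch_size = 16, patience = 12, seed = 3)
  clf <- train_classifier(s$masks[tr], s$labels[tr], cfg,
                          val_masks = s$masks[te], val_labels = s$labels[te])
  pred <- vapply(te, function(i)
    as.character(classify_mask(clf, s$masks[[i]])$class), "")
  expect_gte(mean(pred == s$labels[te]), 0.7)
  # the densest possible input lands in the highest class
  all_ones <- matrix(1, 64, 64)
  r <- classify_mask(clf, all_ones)
  expect_equal(as.character(r$class), "IV")
  expect_gt(r$probabilities[["IV"]], 0.5)
})

test_that("class weighting raises sensitivity on rare classes", {
  # imbalanced 10:1 dominant-class set; paired comparison over 3 seeds
  sens_w <- sens_u <- numeric(3)
  for (seed in 1:3) {
    lo <- c(0.03, 0.28, 0.53, 0.78); hi <- c(0.22, 0.47, 0.72, 0.95)
    n_cls <- c(60, 6, 6, 6)
    msks <- list(); labels <- character(0); k <- 0
    for (cls in 1:4) {
      pds <- withr::with_seed(7000 + 100 * seed + cls,
                              runif(n_cls[cls], lo[cls], hi[cls]))
      for (i in seq_along(pds)) {
        k <- k + 1
        p <- generate_phantom(phantom_spec(64, 64, target_pd = pds[i],
                                           seed = 7000 + 997 * cls + i))
        msks[[k]] <- p$dense; labels[k] <- p$birads
      }
    }
    te <- make_mask_set(12, 8000 + seed)
    base <- cnn_config(input_size = 64, channels = c(8, 16, 32), epochs = 15,
                       batch_size = 16, seed = seed)
    unw <- base; unw$class_weights <- rep(0.75, 4)
    macro_sens <- function(cfg) {
      clf <- train_classifier(msks, labels, cfg)
      pred <- vapply(te$masks, function(m)
        as.character(classify_mask(clf, m)$class), "")
      rep <- evaluate_classification(te$labels, pred,
                                     c("I", "II", "III", "IV"))
      mean(rep$per_class$sensitivity, na.rm = TRUE)
    }
    sens_w[seed] <- macro_sens(base)
    sens_u[seed] <- macro_sens(unw)
  }
  # weighting helps (or at worst matches) on average across seeds
  expect_gte(mean(sens_w), mean(sens_u))
})

test_that("classifier checkpoints round-trip through disk", {
  s <- make_mask_set(4, 9000)
  cfg <- cnn_config(input_size = 64, channels = c(4, 8, 16), epochs = 1,
                    seed = 4)
  clf <- train_classifier(s$masks, s$labels, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  m <- s$masks[[1]]
  expect_equal(classify_mask(clf, m)$probabilities,
               classify_mask(clf2, m)$probabilities, tolerance = 1e-12)
})
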