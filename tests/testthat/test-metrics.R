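test_that("binary_counts tallies pixels exactly", {
  p <- c(1, 1, 0, 0); g <- c(1, 0, 1, 0)
  cts <- binary_counts(p, g)
  expect_equal(unclass(cts)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  ident <- binary_counts(m, m)
  expect_equal(ident$FP + ident$FN, 0)
  comp <- binary_counts(1 - m, m)
  expect_equal(comp$TP + comp$TN, 0)
  expect_error(binary_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               "shape mismatch")
})

test_that("binary_metrics reproduces the rate formulas and flags NaN", {
  m <- binary_metrics(list(TP = 8, TN = 90, FP = 2, FN = 0))
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 90 / 92, tolerance = 1e-12)
  perfect <- binary_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                   "specificity", "dsc", "jaccard")]) == 1))
  m2 <- binary_metrics(list(TP = 1, FP = 1, FN = 1, TN = 0))
  expect_equal(m2$dsc, 0.5)
  expect_equal(m2$jaccard, 1 / 3)
  nop <- binary_metrics(list(TP = 0, FP = 0, FN = 0, TN = 4))
  expect_true(is.nan(nop$precision))
  expect_true("precision" %in% nop$undefined)
})

test_that("DSC and Jaccard satisfy DSC = 2J/(1+J) for random counts", {
  withr::with_seed(42, {
    for (i in 1:50) {
      cts <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
                  FN = sample(0:50, 1), TN = sample(0:50, 1))
      if (cts$TP + cts$FP + cts$FN == 0) next
      m <- binary_metrics(cts)
      expect_equal(m$dsc, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-9)
      if (cts$TP + cts$FN > 0) {
        fnr <- cts$FN / (cts$TP + cts$FN)
        expect_equal(m$sensitivity + fnr, 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("multiclass_counts agrees with exhaustive enumeration", {
  # cm[i,j]: gold i predicted j, with rows c(5,1,0), c(2,3,1), c(0,0,4)
  cm <- matrix(c(5, 1, 0, 2, 3, 1, 0, 0, 4), 3, 3, byrow = TRUE)
  c1 <- multiclass_counts(cm, 1)
  expect_equal(unclass(c1)[c("TP", "FN", "FP", "TN")],
               list(TP = 5, FN = 1, FP = 2, TN = 8))

  enumerate <- function(cm, k) {
    tp <- fn <- fp <- tn <- 0
    for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
      n <- cm[i, j]
      if (i == k && j == k) tp <- tp + n
      else if (i == k) fn <- fn + n
      else if (j == k) fp <- fp + n
      else tn <- tn + n
    }
    list(TP = tp, FN = fn, FP = fp, TN = tn)
  }
  withr::with_seed(7, {
    for (r in 1:20) {
      cm4 <- matrix(sample(0:9, 16, replace = TRUE), 4, 4)
      tps <- 0
      for (k in 1:4) {
        got <- multiclass_counts(cm4, k)
        want <- enumerate(cm4, k)
        expect_equal(unclass(got)[names(want)], want)
        expect_equal(got$TP + got$FP, sum(cm4[, k]))
        tps <- tps + got$TP + got$FN
      }
      expect_equal(tps, sum(cm4))       # sum over classes of TP+FN
      expect_equal(sum(diag(cm4)),
                   sum(vapply(1:4, function(k) multiclass_counts(cm4, k)$TP, 0)))
    }
  })
  diagm <- diag(c(3, 4, 5, 6))
  for (k in 1:4) {
    dk <- multiclass_counts(diagm, k)
    expect_equal(dk$FP + dk$FN, 0)
  }
})

test_that("weighted overall accuracy combines per-class rates by support", {
  expect_equal(weighted_overall_accuracy(c(1, 1, 1), c(5, 2, 9)), 100)
  expect_equal(weighted_overall_accuracy(0.73, 17), 73)
  expect_error(weighted_overall_accuracy(c(0.5, 0.5), 3), "equal length")
  # matches plain accuracy computed from the raw confusion matrix
  withr::with_seed(11, {
    cm <- matrix(sample(5:60, 16, replace = TRUE), 4, 4)
    sizes <- rowSums(cm)
    rates <- diag(cm) / sizes
    expect_equal(weighted_overall_accuracy(rates, sizes),
                 100 * sum(diag(cm)) / sum(cm), tolerance = 1e-9)
  })
})

test_that("AND-consensus mask keeps only jointly annotated pixels", {
  a <- matrix(c(1, 1, 0, 0), 2, 2); b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(consensus_mask(a, a), a)
  expect_equal(sum(consensus_mask(a, 1 - a)), 0)
  withr::with_seed(3, {
    for (i in 1:50) {
      a <- matrix(rbinom(36, 1, runif(1)), 6, 6)
      b <- matrix(rbinom(36, 1, runif(1)), 6, 6)
      cm <- consensus_mask(a, b)
      expect_lte(sum(cm), min(sum(a), sum(b)))
      expect_true(all(cm <= a) && all(cm <= b))
    }
  })
})

test_that("segmentation report averages per class and overall consistently", {
  withr::with_seed(5, {
    gold <- lapply(1:6, function(i) matrix(rbinom(64, 1, 0.4), 8, 8))
    pred <- gold
    cls <- c("I", "I", "II", "II", "III", "IV")
    rep <- evaluate_segmentation(pred, gold, cls)
    expect_true(all(rep$all[c("accuracy", "dsc", "jaccard")] == 1))
    half <- gold
    half[[1]][] <- 0   # empty prediction for one image
    rep2 <- evaluate_segmentation(half, gold, cls)
    expect_lt(rep2$all[["dsc"]], 1)
    # class-size-weighted per-class means reproduce the overall row
    tab <- rep2$per_image
    sizes <- table(tab$class)
    per_cls <- tapply(tab$dsc, tab$class, mean)
    expect_equal(sum(per_cls * sizes[names(per_cls)]) / sum(sizes),
                 unname(rep2$all[["dsc"]]), tolerance = 1e-12)
  })
})

test_that("a single half-overlapping prediction scores DSC one half", {
  gold <- matrix(0, 8, 8); gold[1:2, 1] <- 1
  pred <- matrix(0, 8, 8); pred[2:3, 1] <- 1     # one shared, one extra pixel
  rep <- evaluate_segmentation(list(pred), list(gold), "II")
  expect_equal(unname(rep$all[["dsc"]]), 0.5)
  expect_equal(unname(rep$all[["jaccard"]]), 1 / 3, tolerance = 1e-12)
})
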