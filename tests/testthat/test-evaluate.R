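test_that("confusion matrix counts, percentages and degenerate cases", {
  truth <- matrix(c(1L, 1L, 2L, 3L), 2, 2)
  # perfect prediction: diagonal percent 100
  cm <- confusion_matrix(truth, truth)
  expect_equal(diag(cm$counts), c(non_epithelium = 2L, dysplastic = 1L,
                                  non_dysplastic = 1L))
  expect_equal(unname(diag(cm$percent)), c(100, 100, 100))

  # 4-pixel hand tally: truth (1,1,2,3), pred (1,2,2,3)
  pred <- matrix(c(1L, 2L, 2L, 3L), 2, 2)
  cm <- confusion_matrix(pred, truth)
  expect_equal(unname(cm$counts),
               matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), 3, 3))
  expect_equal(unname(cm$percent),
               matrix(c(50, 0, 0, 50, 100, 0, 0, 0, 100), 3, 3))
  expect_equal(cm$n_pixels, 4L)

  # every non-empty row sums to 100 within 1e-6
  set.seed(10)
  t2 <- matrix(sample(0:3, 400, TRUE), 20, 20)
  p2 <- matrix(sample(1:3, 400, TRUE), 20, 20)
  cm2 <- confusion_matrix(p2, t2)
  expect_lt(max(abs(rowSums(cm2$percent) - 100)), 1e-6)

  # all-false mask is degenerate
  expect_error(confusion_matrix(pred, truth, mask = matrix(FALSE, 2, 2)),
               "degenerate")
  # background and out-of-mask pixels never enter the counts
  msk <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  cm3 <- confusion_matrix(pred, truth, mask = msk)
  expect_equal(cm3$n_pixels, 3L)
})

test_that("metrics match the independent formula oracle", {
  cm <- matrix(c(8, 2, 0, 1, 7, 1, 1, 1, 9), 3, 3)  # rows = truth
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 100 * 24 / 30, tolerance = 1e-9)
  # independent hand computation, class by class
  prec <- c(8 / 10, 7 / 9, 9 / 11)
  rec <- c(8 / 10, 7 / 10, 9 / 10)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(m$macro_f1, mean(f1), tolerance = 1e-9)
  expect_equal(m$per_class$precision, prec, tolerance = 1e-9)
  expect_equal(m$per_class$recall, rec, tolerance = 1e-9)

  # perfect matrix
  mp <- metrics_from_confusion(diag(c(5, 5, 5)))
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$macro_f1, 1.0)

  # a class absent from truth is excluded from the macro mean and flagged
  cm0 <- matrix(c(8, 0, 0, 1, 0, 1, 1, 0, 9), 3, 3)
  dimnames(cm0) <- dimnames(confusion_matrix(matrix(1L), matrix(1L))$counts)
  m0 <- metrics_from_confusion(cm0)
  expect_equal(m0$excluded_classes, "dysplastic")
  expect_true(is.na(m0$per_class$recall[2]))
  expect_false(is.na(m0$macro_f1))
})

test_that("metrics are invariant to a simultaneous class permutation", {
  set.seed(17)
  truth <- matrix(sample(1:3, 900, TRUE), 30, 30)
  pred <- matrix(sample(1:3, 900, TRUE), 30, 30)
  m0 <- metrics_from_confusion(confusion_matrix(pred, truth))
  perm <- c(3L, 1L, 2L)
  m1 <- metrics_from_confusion(confusion_matrix(matrix(perm[pred], 30, 30),
                                                matrix(perm[truth], 30, 30)))
  expect_equal(m1$accuracy, m0$accuracy, tolerance = 1e-12)
  expect_equal(m1$macro_f1, m0$macro_f1, tolerance = 1e-12)
})

test_that("accuracy equals a direct pixel-agreement count", {
  set.seed(18)
  truth <- matrix(sample(0:3, 2500, TRUE), 50, 50)
  pred <- matrix(sample(1:3, 2500, TRUE), 50, 50)
  mask <- matrix(runif(2500) > 0.3, 50, 50)
  m <- metrics_from_confusion(confusion_matrix(pred, truth, mask))
  sel <- mask & truth %in% 1:3
  expect_equal(m$accuracy, 100 * mean(pred[sel] == truth[sel]),
               tolerance = 1e-12)
})

test_that("replicate aggregation uses the population SD", {
  mk <- function(acc, f1, rec, modality = "COMBINED") {
    list(accuracy = acc, macro_f1 = f1,
         per_class = data.frame(recall = c(0.9, rec, 0.9)),
         modality = modality)
  }
  # three identical replicates: SD 0
  agg <- aggregate_replicates(list(mk(90, 0.8, 0.7), mk(90, 0.8, 0.7),
                                   mk(90, 0.8, 0.7)))
  expect_true(all(agg$sd == 0))
  # hand arithmetic: (0.80, 0.82, 0.84) -> mean 0.82, population SD 0.016330
  agg <- aggregate_replicates(list(mk(80, 0.80, 0.7), mk(82, 0.82, 0.7),
                                   mk(84, 0.84, 0.7)))
  f1row <- agg[agg$metric == "macro_f1", ]
  expect_equal(f1row$mean, 0.82, tolerance = 1e-12)
  expect_equal(f1row$sd, sqrt(2 * 0.02^2 / 3), tolerance = 1e-9)
  expect_true(all(agg$mean >= c(80, 0.80, 0.7) & agg$n == 3))
  # single replicate: SD 0, n = 1
  agg1 <- aggregate_replicates(list(mk(90, 0.8, 0.7)))
  expect_true(all(agg1$sd == 0) && all(agg1$n == 1))
  # mixed modalities refuse to aggregate
  expect_error(aggregate_replicates(list(mk(90, 0.8, 0.7),
                                         mk(90, 0.8, 0.7, modality = "IR"))),
               "mix")
})

test_that("projection panels are deterministic and use distinct class colors", {
  set.seed(20)
  truth <- matrix(sample(0:3, 64 * 64, TRUE), 64, 64)
  chan <- matrix(runif(64 * 64), 64, 64)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "p1.png"); f2 <- file.path(d, "p2.png")
  render_projection(truth, truth, chan, f1)
  render_projection(truth, truth, chan, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  img <- png::readPNG(f1)
  # identical pred/truth: the two label panels are pixel-identical
  expect_identical(img[1:64, 64 + 4 + (1:64), ], img[1:64, 2 * 68 + (1:64), ])
  # panel width tracks the section grid: 3 panels plus 2 gaps
  expect_equal(dim(img)[2], 3 * 64 + 2 * 4)
  # 4 distinct class colors in the prediction panel
  panel <- img[1:64, 64 + 4 + (1:64), ]
  cols <- unique(apply(matrix(panel, ncol = 3), 1, paste, collapse = "/"))
  expect_equal(length(cols), 4L)
})

test_that("model evaluation pools patches and aggregates replicates", {
  ds <- make_tiny_dataset(n_sections = 3L, h = 256L, patch_size = 128L)
  cfg <- train_config(backbone = "reduced", max_epochs = 3L, n_replicates = 2L,
                      batch_size = 4L, seed = 21L)
  fit <- train_segmenter(ds, "IR", cfg)
  rep <- evaluate_model(fit, ds, split = "test")
  expect_s3_class(rep, "eval_report")
  expect_length(rep$replicates, 2L)
  expect_equal(attr(rep$aggregate, "modality"), "IR")
  expect_true(all(rep$aggregate$sd >= 0))
  a <- vapply(rep$replicates, `[[`, 0, "accuracy")
  expect_true(all(rep$aggregate$mean[1] >= min(a) &
                    rep$aggregate$mean[1] <= max(a)))
  # accuracy recomputed from the pooled confusion matrix
  for (r in rep$replicates)
    expect_equal(r$accuracy,
                 100 * sum(diag(r$cm$counts)) / sum(r$cm$counts))
})
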