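test_that("network shape contract holds for every modality", {
  for (m in c("DF", "IR", "COMBINED")) {
    mod <- modality_config(m)
    fcn <- build_fcn(mod, backbone = "reduced")
    expect_equal(fcn$in_channels, length(mod$channels))
    params <- init_fcn_params(fcn, seed = 1)
    x <- array(rnorm(64 * 64 * fcn$in_channels), c(64, 64, fcn$in_channels, 1))
    s <- fcn_forward(fcn, params, x)
    expect_equal(dim(s), c(64L, 64L, 3L, 1L))
  }
  # channel mismatch is a shape error
  fcn <- build_fcn(modality_config("DF"), backbone = "reduced")
  params <- init_fcn_params(fcn, seed = 1)
  expect_error(fcn_forward(fcn, params, array(0, c(64, 64, 2, 1))), "channels")
  # input must be divisible by the stride product
  expect_error(fcn_forward(fcn, params, array(0, c(62, 62, 1, 1))), "divisible")
})

test_that("the resnet50 backbone maps inputs to full-resolution score maps", {
  fcn <- build_fcn(modality_config("COMBINED"), backbone = "resnet50")
  expect_equal(fcn$stride_product, 32L)
  params <- init_fcn_params(fcn, seed = 1)
  n_par <- sum(vapply(params, length, 0L))
  expect_gt(n_par, 2e7)  # bottleneck stages 3-4-6-3 at standard widths
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  pr <- fcn_forward(fcn, params, x, probs = TRUE)
  expect_equal(dim(pr), c(64L, 64L, 3L, 1L))
  expect_lt(max(abs(apply(pr, c(1, 2, 4), sum) - 1)), 1e-6)
})

test_that("softmax scores are normalized per pixel", {
  fcn <- build_fcn(2, backbone = "reduced")
  params <- init_fcn_params(fcn, seed = 3)
  x <- array(rnorm(2 * 32 * 32 * 2), c(32, 32, 2, 2))
  pr <- fcn_forward(fcn, params, x, probs = TRUE)
  expect_lt(max(abs(apply(pr, c(1, 2, 4), sum) - 1)), 1e-6)
  expect_true(all(pr >= 0))
})

test_that("affine augmentation: identity draw, right-angle rotation, label set", {
  set.seed(14)
  patch <- list(channels = array(rnorm(32 * 32 * 2), c(32, 32, 2)),
                labels = matrix(sample(0:3, 32 * 32, TRUE), 32, 32))
  idp <- list(rot = 0, shear = 0, scale = 1, tr = 0, tc = 0)
  out <- augment_affine(patch, params = idp)
  expect_equal(out$channels, patch$channels, tolerance = 1e-7)
  expect_identical(out$labels, patch$labels)

  # 90 degrees: an exact index permutation, class-2 count preserved
  patch$labels[] <- 1L
  patch$labels[1:16, 1:16] <- 2L                       # top-left quadrant
  r90 <- augment_affine(patch, params = list(rot = 90, shear = 0, scale = 1,
                                             tr = 0, tc = 0))
  expect_equal(sum(r90$labels == 2L), sum(patch$labels == 2L))
  expect_true(all(r90$labels[17:32, 1:16] == 2L))      # moved to bottom-left
  expect_true(all(r90$labels[1:16, ] == 1L))

  # labels are never interpolated; out-of-frame fill is background 0
  big <- augment_affine(patch, params = list(rot = 45, shear = 3, scale = 0.8,
                                             tr = 2, tc = -2))
  expect_true(all(big$labels %in% 0:3))
  expect_true(any(big$labels == 0L))
})

test_that("learning rate follows the stepped schedule exactly", {
  cfg <- train_config()
  expect_identical(lr_schedule(cfg, 15),
                   rep(c(2e-4, 1e-4, 5e-5), each = 5))
})

test_that("cross-entropy ignores background pixels", {
  set.seed(5)
  scores <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  labels <- array(sample(0:3, 256, TRUE, prob = c(0.4, 0.2, 0.2, 0.2)),
                  c(16, 16, 1))
  base <- dfirseg:::ce_loss_cpp(scores, labels)
  # scrambling scores at background pixels leaves the loss untouched
  scores2 <- scores
  bg <- which(labels[, , 1] == 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(bg))) scores2[bg[i, 1], bg[i, 2], , 1] <- rnorm(3) * 10
  expect_identical(dfirseg:::ce_loss_cpp(scores2, labels), base)
  # matches an independent R softmax cross-entropy oracle
  oracle <- local({
    tot <- 0; n <- 0
    for (r in 1:16) for (c in 1:16) {
      t <- labels[r, c, 1]
      if (t >= 1) {
        z <- scores[r, c, , 1]
        p <- exp(z - max(z)); p <- p / sum(p)
        tot <- tot + -log(p[t]); n <- n + 1
      }
    }
    tot / n
  })
  expect_equal(base, oracle, tolerance = 1e-6)
})

test_that("training is replicable, schedules its LR, and honors max_epochs = 0", {
  ds <- make_tiny_dataset(n_sections = 3L, h = 256L, patch_size = 64L)
  cfg <- train_config(backbone = "reduced", max_epochs = 0L, n_replicates = 2L,
                      seed = 3L)
  fit0 <- train_segmenter(ds, "IR", cfg)
  expect_length(fit0$replicates, 2L)
  expect_equal(nrow(fit0$replicates[[1]]$history), 0L)  # no-op training
  # initialized models still satisfy the forward contract
  pr <- fcn_forward(fit0$fcn, fit0$replicates[[1]]$params,
                    array(0, c(64, 64, 2, 1)), probs = TRUE)
  expect_equal(dim(pr), c(64L, 64L, 3L, 1L))

  cfg <- train_config(backbone = "reduced", max_epochs = 7L, n_replicates = 2L,
                      batch_size = 4L, seed = 3L, early_stopping_patience = 50L)
  fit1 <- train_segmenter(ds, "IR", cfg)
  fit2 <- train_segmenter(ds, "IR", cfg)
  h1 <- fit1$replicates[[1]]$history
  expect_identical(h1, fit2$replicates[[1]]$history)    # same seed, same history
  expect_false(identical(h1$train_loss,
                         fit1$replicates[[2]]$history$train_loss))
  expect_equal(h1$lr, lr_schedule(cfg, 7))              # scheduler law in situ
  expect_true(all(diff(h1$epoch) == 1))
})

test_that("whole-section prediction stitches tiles consistently", {
  sec <- generate_phantom(tiny_phantom_params(seed = 31))
  st <- preprocess_section(sec)

  # stub with constant scores: stitching must be invariant to tiling
  stub <- function(x) {
    d <- dim(x)
    pr <- array(0, c(d[1], d[2], 3, d[4]))
    pr[, , 1, ] <- 0.2; pr[, , 2, ] <- 0.5; pr[, , 3, ] <- 0.3
    pr
  }
  preds <- list()
  for (tile in c(128L, 256L)) for (ov in c(0L, 32L)) {
    preds[[length(preds) + 1]] <- predict_section(NULL, st, tile = tile,
                                                  overlap = ov,
                                                  model_fun = stub)
  }
  for (p in preds[-1]) expect_identical(p, preds[[1]])
  expect_true(all(preds[[1]][st$tissue_mask] == 2L))
  expect_true(all(preds[[1]][!st$tissue_mask] == 0L))

  # mask supremacy: all-background mask forces an all-zero label map
  st0 <- st
  st0$tissue_mask <- matrix(FALSE, st$grid_shape[1], st$grid_shape[2])
  expect_true(all(predict_section(NULL, st0, tile = 128L, overlap = 0L,
                                  model_fun = stub) == 0L))

  # single-tile equivalence for a real fitted network
  ds <- make_tiny_dataset(n_sections = 3L, h = 256L, patch_size = 128L)
  cfg <- train_config(backbone = "reduced", max_epochs = 2L, n_replicates = 1L,
                      batch_size = 4L, seed = 8L)
  fit <- train_segmenter(ds, "COMBINED", cfg)
  small <- generate_phantom(tiny_phantom_params(h = 128L, w = 128L, seed = 32))
  sst <- preprocess_section(small)
  tiled <- predict_section(fit, sst, tile = 128L, overlap = 0L)
  x <- dfirseg:::standardize_channels(sst$channels, sst$tissue_mask, fit$stats,
                                      select = fit$modality$channels)
  pr <- fcn_forward(fit$fcn, fit$replicates[[1]]$params,
                    array(x, c(128, 128, 3, 1)), probs = TRUE)
  direct <- matrix(max.col(matrix(pr, 128 * 128, 3), ties.method = "first"),
                   128, 128)
  direct[!sst$tissue_mask] <- 0L
  storage.mode(direct) <- "integer"
  expect_identical(tiled, direct)
})

test_that("a single easy patch is memorized within 200 steps", {
  sec <- generate_phantom(noise_free_params(h = 128L, w = 128L, seed = 33))
  st <- preprocess_section(sec)
  ps <- extract_patches(st, patch_size = 128L)
  splits <- data.frame(section_id = st$section_id, split = "train")
  ds <- patch_dataset(list(ps[1]), splits, channel_stats(st))
  cfg <- train_config(backbone = "reduced", max_epochs = 200L,
                      n_replicates = 1L, batch_size = 1L, seed = 2L,
                      scheduler_step_epochs = 200L,  # 1 epoch = 1 step here
                      early_stopping_patience = 1000L, augment = FALSE)
  fit <- train_segmenter(ds, "COMBINED", cfg)
  h <- fit$replicates[[1]]$history
  expect_lt(min(h$train_loss), 0.1)
})
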