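test_that("resampling preserves extent, identities and constants", {
  m <- matrix(runif(64), 8, 8)
  expect_equal(resample_raster(m, 2, 2), m)                 # ratio 1: identity
  up <- resample_raster(m, 2, 1)
  expect_equal(dim(up), c(16L, 16L))                        # 2 um -> 1 um
  const <- matrix(0.7, 8, 8)
  expect_equal(resample_raster(const, 2, 1), matrix(0.7, 16, 16),
               tolerance = 1e-12)                           # constant stays
  expect_error(resample_raster(m, -1, 1), "positive")
  expect_error(resample_raster(m, 2, 0), "positive")
})

test_that("label resampling is nearest-neighbor and creates no new values", {
  set.seed(42)
  lab <- matrix(sample(c(0L, 1L, 3L), 12 * 12, replace = TRUE), 12, 12)
  down <- resample_raster(lab, 1, 2, mode = "label")
  expect_true(all(down %in% c(0L, 1L, 3L)))
  # brute-force nearest-neighbor index-map oracle (pixel-centre convention)
  nn_index <- function(i, n_out, n_in) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    pmin(pmax(floor(src + 0.5), 0), n_in - 1) + 1
  }
  oracle <- lab[nn_index(seq_len(nrow(down)), nrow(down), nrow(lab)),
                nn_index(seq_len(ncol(down)), ncol(down), ncol(lab))]
  expect_identical(down, oracle)
  expect_error(resample_raster(matrix(runif(9), 3, 3), 1, 2, mode = "label"),
               "integer")
})

test_that("translation registration recovers injected shifts exactly", {
  set.seed(7)
  fixed <- matrix(rnorm(96 * 96), 96, 96)
  expect_equal(register_translation(fixed, fixed)$shift, c(dy = 0, dx = 0))
  # moving = fixed rolled by (+3, -5): recovered shift (-3, +5)
  roll <- function(m, dy, dx) {
    m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
  }
  moving <- roll(fixed, 3, -5)
  r <- register_translation(moving, fixed)
  expect_equal(r$shift, c(dy = -3, dx = 5))
  # registered image matches except at the zero-filled border
  inner <- 10:90
  expect_equal(r$registered[inner, inner], fixed[inner, inner])
  expect_error(register_translation(matrix(1, 8, 8), fixed[1:8, 1:8]),
               "degenerate")
  # property: random integer shifts up to a quarter frame, recovered exactly
  for (i in 1:10) {
    dy <- sample(-24:24, 1); dx <- sample(-24:24, 1)
    expect_equal(register_translation(roll(fixed, dy, dx), fixed)$shift,
                 c(dy = -dy, dx = -dx))
  }
})

test_that("Otsu tissue mask recovers the phantom's tissue region", {
  sec <- generate_phantom(tiny_phantom_params(seed = 21))
  a1658 <- resample_raster(sec$raw_band_images[[3]]$pixels, 2, 1)
  mask <- tissue_mask(a1658)
  truth <- sec$labels != 0
  expect_lt(abs(mean(mask) - mean(truth)), 0.01)
  expect_gt(mean(mask == truth), 0.98)
  # saturated fixed-threshold case and degenerate Otsu input
  expect_true(all(tissue_mask(matrix(0.5, 8, 8), method = "fixed",
                              threshold = 0.1)))
  expect_error(tissue_mask(matrix(0, 16, 16)), "degenerate")
})

test_that("small holes are filled, large ones kept", {
  m <- matrix(0.8, 64, 64)
  m[10:12, 10:12] <- 0.01            # 9-px hole: filled
  m[30:45, 30:45] <- 0.01            # 256-px hole: kept
  mask <- tissue_mask(m, method = "fixed", threshold = 0.1, min_hole_area = 64)
  expect_true(all(mask[10:12, 10:12]))
  expect_false(any(mask[30:45, 30:45]))
})

test_that("Amide I normalization: identity, worked case, floor and clipping", {
  # identity ratio
  a <- matrix(runif(64, 0.2, 0.8), 8, 8)
  full <- matrix(TRUE, 8, 8)
  n <- normalize_to_amide1(a, a, a, full)
  expect_true(all(n$r1238 == 1) && all(n$r1546 == 1))
  # hand-computed 2x2 worked case
  a1238 <- matrix(c(0.2, 0.1, 0.4, 0.0), 2, 2)
  a1658 <- matrix(0.4, 2, 2)
  n <- normalize_to_amide1(a1238, a1238, a1658, matrix(TRUE, 2, 2))
  expect_equal(n$r1238, matrix(c(0.5, 0.25, 1.0, 0.0), 2, 2))
  # pixels under the Amide I floor leave the mask and are reported
  a1658f <- a1658; a1658f[1, 1] <- 1e-5
  n <- normalize_to_amide1(a1238, a1238, a1658f, matrix(TRUE, 2, 2))
  expect_false(n$mask[1, 1])
  expect_equal(n$n_floor_removed, 1)
  expect_equal(n$r1238[1, 1], 0)
  # clipping bounds outlier leverage
  n <- normalize_to_amide1(a1658 * 10, a1658, a1658, matrix(TRUE, 2, 2),
                           clip_max = 3)
  expect_true(all(n$r1238 == 3))
  expect_error(normalize_to_amide1(a1238[, 1, drop = FALSE], a1238, a1658, full),
               "grid")
})

test_that("ratios are invariant to a positive multiplicative field", {
  set.seed(3)
  h <- 32
  a1238 <- matrix(runif(h * h, 0.1, 0.5), h, h)
  a1546 <- matrix(runif(h * h, 0.1, 0.5), h, h)
  a1658 <- matrix(runif(h * h, 0.3, 0.8), h, h)
  mask <- matrix(TRUE, h, h)
  t_field <- matrix(exp(rnorm(h * h, sd = 0.3)), h, h)
  n0 <- normalize_to_amide1(a1238, a1546, a1658, mask)
  n1 <- normalize_to_amide1(a1238 * t_field, a1546 * t_field, a1658 * t_field,
                            mask)
  expect_lt(max(abs(n1$r1238 - n0$r1238)), 1e-12)
  expect_lt(max(abs(n1$r1546 - n0$r1546)), 1e-12)
})

test_that("stack assembly standardizes with stored training statistics", {
  h <- 32
  mask <- matrix(TRUE, h, h)
  # constant channels: standardized values are 0 inside the mask
  st <- make_stack(h, h, value = 0.4)
  z <- dfirseg:::standardize_channels(st$channels, st$tissue_mask, st$stats)
  expect_true(all(z == 0))
  # training stats applied to a shifted test section: mean becomes +1/sd
  set.seed(1)
  ch <- matrix(rnorm(h * h, 1, 0.5), h, h)
  train <- assemble_stack(ch, ch, ch, mask, section_id = "train")
  test <- assemble_stack(ch + 1, ch + 1, ch + 1, mask, section_id = "test",
                         stats = train$stats)
  z <- dfirseg:::standardize_channels(test$channels, mask, train$stats)
  expect_equal(mean(z[, , 1]), 1 / train$stats$sd[1], tolerance = 1e-8)
  expect_error(assemble_stack(ch, ch[1:4, ], ch, mask), "grid")
  expect_error(assemble_stack(ch, ch, ch, mask,
                              labels = matrix(7L, h, h)), "labels")
})

test_that("stacks round-trip through disk", {
  sec <- generate_phantom(tiny_phantom_params(h = 64L, w = 64L, seed = 22))
  st <- preprocess_section(sec)
  d <- withr::local_tempdir()
  write_stack(st, d)
  back <- read_stack(d, st$section_id)
  expect_identical(back$tissue_mask, st$tissue_mask)
  expect_identical(back$labels, st$labels)
  expect_equal(back$channels, st$channels, tolerance = 1e-6)
  expect_equal(back$stats$mean, st$stats$mean, tolerance = 1e-12)
})

test_that("preprocessing a phantom yields ratio channels centred on the class targets", {
  p <- tiny_phantom_params(seed = 23)
  sec <- generate_phantom(p)
  st <- preprocess_section(sec)
  expect_equal(st$grid_shape, dim(sec$labels))
  expect_true(all(st$channels[, , 1][!st$tissue_mask] == 0))
  for (k in 1:3) {
    sel <- st$labels == k & st$tissue_mask
    expect_lt(abs(stats::median(st$channels[, , 1][sel]) - p$mu_ratio_1238[k]),
              0.03)
  }
})
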