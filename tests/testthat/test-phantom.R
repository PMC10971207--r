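test_that("parameter invariants are enforced", {
  expect_error(phantom_params(mu_ratio_1238 = c(0.5, 0.6, 0.45)),
               "non-epithelium > dysplastic")
  expect_error(phantom_params(mu_ratio_1546 = c(0.6, 0.62, 0.6)),
               "largest for non-epithelium")
  expect_error(phantom_params(sigma_ratio_1238 = c(0.04, 0.05, 0.05)),
               "strictly largest")
  expect_error(phantom_params(sigma_ratio_1546 = c(0.12, 0.07, 0.04)),
               "non-dysplastic")
  expect_error(phantom_params(nuclear_density_per_class = c(0.001, 0.005, 0.006)),
               "nuclear density")
  expect_error(phantom_params(tissue_fraction = 0), "tissue_fraction")
  expect_error(phantom_params(tissue_fraction = 1.2), "tissue_fraction")
  expect_error(phantom_params(mu_A1658 = c(0.4, -0.1, 0.3)), "positive")
})

test_that("infeasible geometry is a parameter error", {
  expect_error(generate_phantom(tiny_phantom_params(epithelium_depth_frac = 1.2)),
               "epithelium_depth_frac")
  expect_error(
    generate_phantom(tiny_phantom_params(epithelium_depth_frac = 0.6,
                                         rete_peg_amplitude_px = 60,
                                         tissue_fraction = 0.65)),
    "does not fit")
})

test_that("labels use only the four legal values and geometry is as designed", {
  sec <- generate_phantom(tiny_phantom_params(seed = 3))
  expect_true(all(sec$labels %in% 0:3))
  expect_true(all(vapply(sec$raw_band_images,
                         function(b) all(b$pixels >= 0) && b$pixel_size == 2,
                         TRUE)))
  # IR and darkfield cover the same physical extent
  expect_equal(dim(sec$raw_band_images[[1]]$pixels) * 2, dim(sec$labels))
  expect_equal(dim(sec$darkfield) / 2, dim(sec$labels))
  # stroma lies below the epithelium: mean row index of class 1 exceeds 2 and 3
  rows <- row(sec$labels)
  expect_gt(mean(rows[sec$labels == 1]), mean(rows[sec$labels %in% 2:3]))
  # one contiguous dysplastic focus: its columns form one run
  dys_cols <- which(apply(sec$labels == 2, 2, any))
  expect_equal(dys_cols, seq(min(dys_cols), max(dys_cols)))
})

test_that("label accounting matches the tissue fraction", {
  for (tf in c(0.5, 0.7, 0.9)) {
    sec <- generate_phantom(tiny_phantom_params(seed = 4, tissue_fraction = tf))
    expect_lt(abs(mean(sec$labels != 0) - tf), 0.02)
  }
})

test_that("noise-free phantoms have piecewise-constant IR bands per class", {
  sec <- generate_phantom(noise_free_params(seed = 5))
  lab2 <- sec$labels[seq(1, 256, 2), seq(1, 256, 2)]  # 2 um measurement grid
  for (b in sec$raw_band_images) {
    for (k in 0:3) {
      v <- b$pixels[lab2 == k]
      expect_lt(diff(range(v)), 1e-12)
    }
  }
})

test_that("thickness cancels exactly in the band ratios (noise-free, CoV 0.3)", {
  sec <- generate_phantom(noise_free_params(seed = 6, thickness_cov = 0.3))
  lab2 <- sec$labels[seq(1, 256, 2), seq(1, 256, 2)]
  a1238 <- sec$raw_band_images[[1]]$pixels
  a1658 <- sec$raw_band_images[[3]]$pixels
  # thickness varies strongly ...
  expect_gt(stats::sd(a1658[lab2 == 1]) / mean(a1658[lab2 == 1]), 0.2)
  # ... yet the ratio is constant within each class
  for (k in 1:3) {
    r <- a1238[lab2 == k] / a1658[lab2 == k]
    expect_lt(stats::sd(r) / mean(r), 1e-6)
  }
})

test_that("class-conditional ratio medians reproduce their targets and ordering", {
  p <- phantom_params(seed = 0)  # default frame: >= 1e4 px per class
  sec <- generate_phantom(p)
  lab2 <- sec$labels[seq(1, p$image_height_px, 2), seq(1, p$image_width_px, 2)]
  r1238 <- sec$raw_band_images[[1]]$pixels / pmax(sec$raw_band_images[[3]]$pixels, 1e-9)
  r1546 <- sec$raw_band_images[[2]]$pixels / pmax(sec$raw_band_images[[3]]$pixels, 1e-9)
  med_1238 <- med_1546 <- numeric(3)
  for (k in 1:3) {
    expect_gt(sum(lab2 == k), 1e4)
    med_1238[k] <- stats::median(r1238[lab2 == k])
    med_1546[k] <- stats::median(r1546[lab2 == k])
    expect_lt(abs(med_1238[k] / p$mu_ratio_1238[k] - 1), 0.02)
    expect_lt(abs(med_1546[k] / p$mu_ratio_1546[k] - 1), 0.02)
  }
  expect_true(med_1238[1] > med_1238[2] && med_1238[2] > med_1238[3])
  expect_true(med_1546[1] > med_1546[2] && med_1546[1] > med_1546[3])
  # spread structure: non-epithelium widest at both bands; 1546 IQR wider for
  # non-dysplastic than dysplastic epithelium
  iqr <- function(r, k) stats::IQR(r[lab2 == k])
  expect_gt(iqr(r1238, 1), max(iqr(r1238, 2), iqr(r1238, 3)))
  expect_gt(iqr(r1546, 1), max(iqr(r1546, 2), iqr(r1546, 3)))
  expect_gt(iqr(r1546, 3), iqr(r1546, 2))
})

test_that("darkfield speckle is denser in dysplastic than non-dysplastic epithelium", {
  sec <- generate_phantom(tiny_phantom_params(h = 512L, w = 512L, seed = 8))
  labdf <- resample_raster(sec$labels, 1, 0.5, mode = "label")
  # speckle shows as local intensity variance over the class region
  v2 <- stats::sd(sec$darkfield[labdf == 2])
  v3 <- stats::sd(sec$darkfield[labdf == 3])
  expect_gt(v2, v3)
})

test_that("a fixed seed reproduces the section bit for bit", {
  a <- generate_phantom(tiny_phantom_params(seed = 9))
  b <- generate_phantom(tiny_phantom_params(seed = 9))
  expect_identical(a$labels, b$labels)
  expect_identical(a$raw_band_images[[1]]$pixels, b$raw_band_images[[1]]$pixels)
  expect_identical(a$darkfield, b$darkfield)
  # different seeds: different noise, same geometry statistics
  c <- generate_phantom(tiny_phantom_params(seed = 10))
  expect_false(identical(a$raw_band_images[[1]]$pixels,
                         c$raw_band_images[[1]]$pixels))
  expect_lt(abs(mean(a$labels != 0) - mean(c$labels != 0)), 0.02)
})

test_that("phantom sections round-trip through disk", {
  sec <- generate_phantom(tiny_phantom_params(h = 64L, w = 64L, seed = 12))
  d <- withr::local_tempdir()
  write_phantom(sec, d)
  back <- read_phantom(d, sec$section_id)
  expect_identical(back$labels, sec$labels)
  expect_equal(back$raw_band_images[[2]]$pixels,
               sec$raw_band_images[[2]]$pixels, tolerance = 1e-6)
  expect_equal(back$params$mu_ratio_1238, sec$params$mu_ratio_1238)
})
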