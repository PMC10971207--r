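#' Parameters for the synthetic tissue phantom
#'
#' Builds and validates the parameter set for [generate_phantom()]. The phantom
#' emulates an unstained oral mucosa section imaged at three discrete IR
#' wavenumbers (1238, 1546, 1658 cm^-1) plus a darkfield visible image, with a
#' per-pixel ground-truth label map. Class-conditional band-ratio medians
#' follow the orderings observed in real tissue: Amide I-normalized absorbance
#' at both 1238 and 1546 cm^-1 is largest for non-epithelium (connective
#' tissue, a heterogeneous mix of subtypes, hence also the widest spread);
#' 1238 cm^-1 is higher for dysplastic than non-dysplastic epithelium
#' (increased nuclear/DNA content); the 1546 cm^-1 spread is wider for
#' non-dysplastic than dysplastic epithelium. Darkfield carries morphology:
#' a nuclear speckle texture denser in dysplastic epithelium.
#'
#' All three-element vectors are ordered (non-epithelium, dysplastic
#' epithelium, non-dysplastic epithelium), i.e. label values 1, 2, 3.
#'
#' @param image_height_px,image_width_px frame size on the 1 um analysis grid.
#' @param epithelium_depth_frac fraction of the frame height occupied by the
#'   epithelial band (measured from the top of the tissue).
#' @param rete_peg_amplitude_px,rete_peg_period_px amplitude and period (px) of
#'   the undulating epithelium-stroma boundary (rete pegs).
#' @param dysplasia_extent_frac fraction of the section width forming one
#'   contiguous dysplastic focus within the epithelium.
#' @param mu_ratio_1238,mu_ratio_1546 per-class target medians of the
#'   A1238/A1658 and A1546/A1658 ratio channels.
#' @param sigma_ratio_1238,sigma_ratio_1546 per-class relative spread of the
#'   two ratio channels (multiplicative band noise sd).
#' @param mu_A1658 per-class baseline Amide I absorbance (AU).
#' @param thickness_mean,thickness_corr_len_um,thickness_cov mean, spatial
#'   correlation length (um) and coefficient of variation of the smooth
#'   multiplicative section thickness/density field.
#' @param df_base_intensity per-class darkfield mean intensity; background
#'   scatters at `df_background`.
#' @param df_background darkfield background intensity.
#' @param nuclear_density_per_class nuclear speckle events per square um
#'   (dysplastic must exceed non-dysplastic).
#' @param noise_sd additive detector noise sd (AU, applied to every modality).
#' @param tissue_fraction fraction of the frame covered by tissue, in (0, 1].
#' @param seed integer seed; a fixed seed makes the phantom bit-reproducible.
#' @return An object of class `phantom_params` (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_params <- function(image_height_px = 1024L,
                           image_width_px = 1024L,
                           epithelium_depth_frac = 0.30,
                           rete_peg_amplitude_px = 20,
                           rete_peg_period_px = 150,
                           dysplasia_extent_frac = 0.40,
                           mu_ratio_1238 = c(0.78, 0.60, 0.45),
                           mu_ratio_1546 = c(0.95, 0.62, 0.60),
                           sigma_ratio_1238 = c(0.10, 0.05, 0.05),
                           sigma_ratio_1546 = c(0.12, 0.04, 0.07),
                           mu_A1658 = c(0.45, 0.40, 0.38),
                           thickness_mean = 1.0,
                           thickness_corr_len_um = 100,
                           thickness_cov = 0.15,
                           df_base_intensity = c(0.25, 0.35, 0.33),
                           df_background = 0.02,
                           nuclear_density_per_class = c(0.0005, 0.012, 0.006),
                           noise_sd = 0.01,
                           tissue_fraction = 0.70,
                           seed = 0L) {
  p <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    epithelium_depth_frac = epithelium_depth_frac,
    rete_peg_amplitude_px = rete_peg_amplitude_px,
    rete_peg_period_px = rete_peg_period_px,
    dysplasia_extent_frac = dysplasia_extent_frac,
    mu_ratio_1238 = mu_ratio_1238,
    mu_ratio_1546 = mu_ratio_1546,
    sigma_ratio_1238 = sigma_ratio_1238,
    sigma_ratio_1546 = sigma_ratio_1546,
    mu_A1658 = mu_A1658,
    thickness_mean = thickness_mean,
    thickness_corr_len_um = thickness_corr_len_um,
    thickness_cov = thickness_cov,
    df_base_intensity = df_base_intensity,
    df_background = df_background,
    nuclear_density_per_class = nuclear_density_per_class,
    noise_sd = noise_sd,
    tissue_fraction = tissue_fraction,
    seed = as.integer(seed)
  )
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  for (f in c("mu_ratio_1238", "mu_ratio_1546", "sigma_ratio_1238",
              "sigma_ratio_1546", "mu_A1658", "df_base_intensity",
              "nuclear_density_per_class")) {
    if (length(p[[f]]) != 3L || !is.numeric(p[[f]]))
      stop_param("%s must be a numeric vector of length 3 (classes 1..3)", f)
  }
  m <- p$mu_ratio_1238
  if (!(m[1] > m[2] && m[2] > m[3]))
    stop_param("mu_ratio_1238 must satisfy non-epithelium > dysplastic > non-dysplastic")
  m <- p$mu_ratio_1546
  if (!(m[1] > m[2] && m[1] > m[3]))
    stop_param("mu_ratio_1546 must be largest for non-epithelium")
  s <- cbind(p$sigma_ratio_1238, p$sigma_ratio_1546)
  if (any(s > 0)) {  # all-zero spreads = deliberately noise-free phantom
    if (!all(s[1, ] > s[2, ] & s[1, ] > s[3, ]))
      stop_param("ratio spread must be strictly largest for non-epithelium")
    if (!(p$sigma_ratio_1546[3] > p$sigma_ratio_1546[2]))
      stop_param("1546 cm-1 spread must be larger for non-dysplastic than dysplastic epithelium")
  }
  d <- p$nuclear_density_per_class
  if (!(d[2] > d[3]))
    stop_param("nuclear density must be larger for dysplastic than non-dysplastic epithelium")
  if (any(p$mu_A1658 <= 0) || any(p$df_base_intensity <= 0) ||
      any(p$mu_ratio_1238 <= 0) || any(p$mu_ratio_1546 <= 0))
    stop_param("all intensities must be strictly positive")
  if (!(p$tissue_fraction > 0 && p$tissue_fraction <= 1))
    stop_param("tissue_fraction must be in (0, 1]")
  if (p$image_height_px < 16 || p$image_width_px < 16)
    stop_param("frame must be at least 16 x 16 px")
  if (p$thickness_cov < 0 || p$noise_sd < 0 || any(s < 0))
    stop_param("spread and noise parameters must be non-negative")
  invisible(p)
}

#' Single-wavenumber IR absorbance image
#'
#' Light-weight container for one discrete-frequency IR raster with its
#' wavenumber and pixel size.
#'
#' @param pixels numeric matrix of absorbance (AU), non-negative and finite.
#' @param wavenumber band position, cm^-1.
#' @param pixel_size pixel pitch, um.
#' @return An object of class `band_image`.
#' @export
band_image <- function(pixels, wavenumber, pixel_size) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_param("pixels must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop_param("band image must contain only finite values")
  if (any(pixels < 0))
    stop_param("absorbance must be non-negative")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop_param("pixel_size must be positive")
  structure(list(pixels = pixels, wavenumber = wavenumber,
                 pixel_size = pixel_size),
            class = "band_image")
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("<band_image> %d cm-1, %d x %d px @ %.2g um/px, range [%.3g, %.3g] AU\n",
              as.integer(x$wavenumber), nrow(x$pixels), ncol(x$pixels),
              x$pixel_size, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Generate one synthetic multimodal tissue section
#'
#' Simulates a paired DFIR/darkfield section with ground-truth labels. The
#' tissue is a full-width horizontal band covering `tissue_fraction` of the
#' frame; its upper part is epithelium whose lower boundary undulates as a
#' sinusoid (random phase) plus low-frequency jitter, producing rete-peg-like
#' protrusions into the stroma. One contiguous column range of the epithelium
#' is dysplastic (class 2); the rest is non-dysplastic (class 3); everything
#' below the boundary inside the tissue band is non-epithelium (class 1).
#'
#' Raw absorbance at band b: `A_b(x) = t(x) * mu[class(x), b] * (1 + eps_b(x))`
#' where `t` is a smooth multiplicative thickness/density field (lognormal,
#' correlation length `thickness_corr_len_um`) and `eps_b` is multiplicative
#' band noise with per-class sd `sigma_ratio_*` (zero for the Amide I band, so
#' the per-class ratio medians equal `mu_ratio_*`). The three IR bands are
#' sampled at 2 um pixel centers from the underlying 1 um field; additive
#' detector noise (`noise_sd`) is applied at the measurement grid. The
#' darkfield image is rendered at 0.5 um/px as a per-class base intensity plus
#' Poisson nuclear speckle (events per um^2 from `nuclear_density_per_class`)
#' blurred to a plausible point-spread width.
#'
#' @param params a [phantom_params()] object.
#' @param section_id identifier stored with the section.
#' @return An object of class `phantom_section`: list with `raw_band_images`
#'   (three [band_image()] at 2 um/px), `darkfield` (matrix at 0.5 um/px, plus
#'   attribute `pixel_size`), `labels` (integer matrix on the 1 um grid with
#'   values 0 background, 1 non-epithelium, 2 dysplastic, 3 non-dysplastic),
#'   `params`, and `section_id`.
#' @examples
#' p <- phantom_params(image_height_px = 128, image_width_px = 128, seed = 1)
#' sec <- generate_phantom(p)
#' table(sec$labels)
#' @export
generate_phantom <- function(params,
                             section_id = sprintf("phantom-%06d", params$seed)) {
  if (!inherits(params, "phantom_params"))
    stop_param("params must be a phantom_params object")
  H <- params$image_height_px
  W <- params$image_width_px
  Ht <- round(params$tissue_fraction * H)
  De <- round(params$epithelium_depth_frac * H)
  A <- params$rete_peg_amplitude_px
  if (params$epithelium_depth_frac >= 1)
    stop_param("epithelium_depth_frac must be < 1")
  if (De + A >= Ht)
    stop_param("epithelium depth plus rete peg amplitude (%d px) does not fit the tissue band (%d px)",
               De + A, Ht)

  with_seed(params$seed, {
    ## ---- label geometry (1 um grid) ----
    r0 <- floor((H - Ht) / 2)             # rows r0+1 .. r0+Ht are tissue
    phase <- stats::runif(1, 0, 2 * pi)
    jit <- smooth_noise_1d(W, sigma = params$rete_peg_period_px / 2) * (A / 3)
    depth <- De + A * sin(2 * pi * seq_len(W) / params$rete_peg_period_px + phase) + jit
    depth <- pmin(pmax(round(depth), 1), Ht - 1)

    wd <- max(1L, round(params$dysplasia_extent_frac * W))
    c0 <- sample.int(W - wd + 1L, 1L)
    dys_col <- logical(W)
    dys_col[c0:(c0 + wd - 1L)] <- TRUE

    rowidx <- matrix(seq_len(H), H, W)
    bnd <- matrix(r0 + depth, H, W, byrow = TRUE)
    tissue <- rowidx > r0 & rowidx <= r0 + Ht
    epi <- tissue & rowidx <= bnd
    labels <- matrix(0L, H, W)
    labels[tissue] <- 1L
    labels[epi & matrix(dys_col, H, W, byrow = TRUE)] <- 2L
    labels[epi & !matrix(dys_col, H, W, byrow = TRUE)] <- 3L

    ## ---- underlying 1 um absorbance fields ----
    if (params$thickness_cov > 0) {
      z <- smooth_noise_2d(H, W, params$thickness_corr_len_um)
      sln <- sqrt(log(1 + params$thickness_cov^2))
      thick <- params$thickness_mean * exp(sln * z - sln^2 / 2)
    } else {
      thick <- matrix(params$thickness_mean, H, W)
    }

    class_map <- function(v, background = 0) {
      m <- matrix(background, H, W)
      for (k in 1:3) m[labels == k] <- v[k]
      m
    }
    muI <- class_map(params$mu_A1658)
    mu1238 <- muI * class_map(params$mu_ratio_1238)
    mu1546 <- muI * class_map(params$mu_ratio_1546)

    band_field <- function(mu, sigma_by_class) {
      if (is.null(sigma_by_class)) return(thick * mu)
      sig <- class_map(sigma_by_class)
      eps <- matrix(stats::rnorm(H * W), H, W) * sig
      thick * mu * (1 + eps)
    }
    f1238 <- band_field(mu1238, params$sigma_ratio_1238)
    f1546 <- band_field(mu1546, params$sigma_ratio_1546)
    f1658 <- band_field(muI, NULL)

    ## ---- 2 um measurement grid (sampled at pixel centers) ----
    ri <- seq(1L, H, by = 2L)
    ci <- seq(1L, W, by = 2L)
    measure <- function(f) {
      m <- f[ri, ci, drop = FALSE]
      if (params$noise_sd > 0)
        m <- m + matrix(stats::rnorm(length(m), sd = params$noise_sd),
                        nrow(m), ncol(m))
      pmax(m, 0)
    }
    bands <- list(
      band_image(measure(f1238), 1238, 2),
      band_image(measure(f1546), 1546, 2),
      band_image(measure(f1658), 1658, 2)
    )

    ## ---- darkfield at 0.5 um/px ----
    Hd <- 2L * H
    Wd <- 2L * W
    lab_df <- resample_cpp(labels + 0.0, Hd, Wd, "nearest")
    df <- matrix(params$df_background, Hd, Wd)
    for (k in 1:3) df[lab_df == k] <- params$df_base_intensity[k]
    speckle <- matrix(0, Hd, Wd)
    for (k in 1:3) {
      area_um2 <- sum(labels == k)            # 1 um^2 per label pixel
      n <- stats::rpois(1, params$nuclear_density_per_class[k] * area_um2)
      if (n > 0) {
        pos <- sample(which(lab_df == k), n, replace = TRUE)
        tab <- tabulate(pos, nbins = Hd * Wd)
        speckle <- speckle + matrix(tab, Hd, Wd)
      }
    }
    if (any(speckle > 0))
      speckle <- as.matrix(EBImage::gblur(speckle * 0.8, sigma = 1.5, radius = 7))
    df <- df + speckle
    if (params$noise_sd > 0)
      df <- df + matrix(stats::rnorm(Hd * Wd, sd = params$noise_sd), Hd, Wd)
    df <- pmax(df, 0)
    attr(df, "pixel_size") <- 0.5

    structure(list(raw_band_images = bands, darkfield = df, labels = labels,
                   params = params, section_id = section_id),
              class = "phantom_section")
  })
}

#' @export
print.phantom_section <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf("<phantom_section> %s: %d x %d um frame\n", x$section_id,
              nrow(x$labels), ncol(x$labels)))
  cat(sprintf("  labels: background %d | non-epithelium %d | dysplastic %d | non-dysplastic %d px\n",
              tab[1], tab[2], tab[3], tab[4]))
  cat(sprintf("  IR bands: %s cm-1 @ 2 um/px; darkfield %d x %d @ 0.5 um/px\n",
              paste(vapply(x$raw_band_images, function(b) as.character(b$wavenumber), ""),
                    collapse = ", "),
              nrow(x$darkfield), ncol(x$darkfield)))
  invisible(x)
}

#' @export
plot.phantom_section <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  pal <- class_palette()
  graphics::image(t(x$labels)[, nrow(x$labels):1], col = pal, axes = FALSE,
                  main = "labels", useRaster = TRUE)
  b <- x$raw_band_images[[3]]$pixels
  graphics::image(t(b)[, nrow(b):1], col = grDevices::gray.colors(64),
                  axes = FALSE, main = "A1658", useRaster = TRUE)
  invisible(x)
}

#' Write a phantom section to disk
#'
#' Raw bands and the darkfield image are written as 32-bit float TIFF (values
#' scaled into `[0, 1]` by a factor recorded in the JSON sidecar), the label
#' map as an 8-bit PNG, and the parameters plus seed as JSON.
#'
#' @param section a `phantom_section`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(section, dir) {
  if (!inherits(section, "phantom_section"))
    stop_param("section must be a phantom_section")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- section$section_id
  files <- character()
  scales <- list()
  for (b in section$raw_band_images) {
    f <- file.path(dir, sprintf("%s_A%d.tif", id, as.integer(b$wavenumber)))
    sc <- max(1, max(b$pixels))
    tiff::writeTIFF(b$pixels / sc, f, bits.per.sample = 32L)
    scales[[sprintf("A%d", as.integer(b$wavenumber))]] <- sc
    files <- c(files, f)
  }
  f <- file.path(dir, sprintf("%s_darkfield.tif", id))
  sc <- max(1, max(section$darkfield))
  tiff::writeTIFF(section$darkfield / sc, f, bits.per.sample = 32L)
  scales[["darkfield"]] <- sc
  files <- c(files, f)
  f <- file.path(dir, sprintf("%s_labels.png", id))
  png::writePNG(section$labels / 255, f)
  files <- c(files, f)
  side <- list(section_id = id,
               pixel_size_um = list(ir = 2, darkfield = 0.5, labels = 1),
               intensity_scale = scales,
               params = unclass(section$params))
  f <- file.path(dir, sprintf("%s.json", id))
  write_json_file(side, f)
  files <- c(files, f)
  invisible(files)
}

#' Read a phantom section written by [write_phantom()]
#' @param dir directory containing the files.
#' @param section_id the section identifier.
#' @return A `phantom_section`.
#' @export
read_phantom <- function(dir, section_id) {
  side <- read_json_file(file.path(dir, sprintf("%s.json", section_id)))
  sc <- side$intensity_scale
  bands <- lapply(c(1238L, 1546L, 1658L), function(wn) {
    m <- tiff::readTIFF(file.path(dir, sprintf("%s_A%d.tif", section_id, wn)))
    band_image(m * sc[[sprintf("A%d", wn)]], wn, 2)
  })
  df <- tiff::readTIFF(file.path(dir, sprintf("%s_darkfield.tif", section_id))) *
    sc$darkfield
  attr(df, "pixel_size") <- 0.5
  labels <- round(png::readPNG(file.path(dir, sprintf("%s_labels.png",
                                                      section_id))) * 255)
  storage.mode(labels) <- "integer"
  pars <- side$params
  pars <- do.call(phantom_params, pars[names(pars) %in% names(formals(phantom_params))])
  structure(list(raw_band_images = bands, darkfield = df, labels = labels,
                 params = pars, section_id = section_id),
            class = "phantom_section")
}

# fixed class colormap: background, non-epithelium, dysplastic, non-dysplastic
class_palette <- function() {
  c("#000000", "#4575B4", "#D73027", "#1A9850")
}
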