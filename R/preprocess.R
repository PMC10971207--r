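#' Resample a raster to a new pixel size
#'
#' Extent-preserving resampling on a pixel-center grid: the output covers the
#' same physical field of view, with `round(n * pixel_size / target)` pixels
#' per axis. Intensity rasters are interpolated bilinearly; label/mask rasters
#' use nearest-neighbor sampling so no new values are created.
#'
#' @param pixels numeric (or integer, for `mode = "label"`) matrix.
#' @param pixel_size source pixel pitch, um.
#' @param target_pixel_size output pixel pitch, um.
#' @param mode `"intensity"` (bilinear) or `"label"` (nearest neighbor).
#' @return The resampled matrix (integer for label mode).
#' @export
resample_raster <- function(pixels, pixel_size, target_pixel_size,
                            mode = c("intensity", "label")) {
  mode <- match.arg(mode)
  if (!is.matrix(pixels)) stop_param("pixels must be a matrix")
  if (!is.numeric(pixel_size) || pixel_size <= 0 ||
      !is.numeric(target_pixel_size) || target_pixel_size <= 0)
    stop_param("pixel sizes must be positive")
  if (mode == "label" && any(pixels != round(pixels)))
    stop_param("label mode requires an integer-valued raster")
  out_h <- max(1L, as.integer(round(nrow(pixels) * pixel_size / target_pixel_size)))
  out_w <- max(1L, as.integer(round(ncol(pixels) * pixel_size / target_pixel_size)))
  out <- resample_cpp(pixels + 0.0, out_h, out_w,
                      if (mode == "label") "nearest" else "bilinear")
  if (mode == "label") storage.mode(out) <- "integer"
  out
}

#' Rigid integer-pixel registration by cross-correlation
#'
#' Estimates the integer translation that best aligns `moving` onto `fixed` by
#' maximizing the circular cross-correlation of the mean-subtracted,
#' unit-variance images (computed via FFT), then applies the shift with
#' zero-filled edges.
#'
#' @param moving,fixed numeric matrices on the same pixel grid.
#' @return A list with `shift` (named vector `dy`, `dx`: `registered[r, c] =
#'   moving[r - dy, c - dx]`) and `registered`, the shifted moving image.
#' @export
register_translation <- function(moving, fixed) {
  if (!is.matrix(moving) || !is.matrix(fixed) ||
      !all(dim(moving) == dim(fixed)))
    stop_param("moving and fixed must be matrices on the same grid")
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0)
    stop_param("degenerate input: correlation of a constant image is undefined")
  H <- nrow(fixed); W <- ncol(fixed)
  a <- (fixed - mean(fixed)) / stats::sd(fixed)
  b <- (moving - mean(moving)) / stats::sd(moving)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  k <- which.max(cc)
  dy <- (k - 1) %% H
  dx <- (k - 1) %/% H
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  list(shift = c(dy = dy, dx = dx),
       registered = shift_raster(moving, dy, dx))
}

# integer shift with zero fill: out[r, c] = x[r - dy, c - dx]
shift_raster <- function(x, dy, dx) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  rs <- max(1, 1 + dy):min(H, H + dy)
  cs <- max(1, 1 + dx):min(W, W + dx)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- x[rs - dy, cs - dx]
  out
}

#' Tissue mask from the Amide I image
#'
#' Thresholds the 1658 cm^-1 absorbance image (the strongest and most uniform
#' tissue band) either by Otsu's method or at a fixed absorbance, then fills
#' enclosed holes smaller than `min_hole_area` pixels.
#'
#' @param a1658 numeric matrix of Amide I absorbance on the analysis grid.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold absorbance threshold (AU), required for `method = "fixed"`.
#' @param min_hole_area holes (enclosed background components) smaller than
#'   this area are filled.
#' @return A logical matrix, `TRUE` on tissue.
#' @export
tissue_mask <- function(a1658, method = c("otsu", "fixed"), threshold = NULL,
                        min_hole_area = 64) {
  method <- match.arg(method)
  if (!is.matrix(a1658)) stop_param("a1658 must be a matrix")
  if (method == "otsu") {
    rng <- range(a1658)
    if (rng[1] == rng[2])
      stop_param("degenerate input: Otsu threshold of a constant image is undefined")
    scaled <- (a1658 - rng[1]) / (rng[2] - rng[1])
    thr_scaled <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    threshold <- rng[1] + thr_scaled * (rng[2] - rng[1])
  } else if (is.null(threshold)) {
    stop_param("method = \"fixed\" requires a threshold")
  }
  mask <- a1658 > threshold
  if (min_hole_area > 0 && any(mask) && any(!mask)) {
    holes <- EBImage::bwlabel(EBImage::Image(!mask))
    hd <- EBImage::imageData(holes)
    border_ids <- unique(c(hd[1, ], hd[nrow(hd), ], hd[, 1], hd[, ncol(hd)]))
    sizes <- tabulate(hd[hd > 0])
    fill_ids <- setdiff(which(sizes < min_hole_area), border_ids)
    if (length(fill_ids)) mask[hd %in% fill_ids] <- TRUE
  }
  mask
}

#' Amide I band-ratio normalization
#'
#' Divides the 1238 and 1546 cm^-1 absorbance images by the 1658 cm^-1 (Amide
#' I) image to cancel section thickness and density variation: any positive
#' multiplicative field applied to all three bands leaves the ratios
#' unchanged. Pixels whose Amide I absorbance falls below `floor` are removed
#' from the mask (division there would amplify detector noise); inside the
#' mask, ratios are clipped to `[0, clip_max]`; outside they are exactly 0.
#'
#' @param a1238,a1546,a1658 co-registered numeric matrices on the 1 um grid.
#' @param mask logical tissue mask.
#' @param clip_max upper clip for the ratio channels.
#' @param floor minimum Amide I absorbance (AU) for a valid ratio.
#' @return List with `r1238`, `r1546`, the pruned `mask`, and
#'   `n_floor_removed`, the number of pixels dropped by the Amide I floor.
#' @export
normalize_to_amide1 <- function(a1238, a1546, a1658, mask, clip_max = 3,
                                floor = 1e-3) {
  dims <- dim(a1658)
  if (!all(dim(a1238) == dims) || !all(dim(a1546) == dims) ||
      !all(dim(mask) == dims))
    stop_param("all bands and the mask must share the same grid")
  ok <- mask & (a1658 >= floor)
  n_removed <- sum(mask & !ok)
  ratio <- function(num) {
    r <- matrix(0, dims[1], dims[2])
    r[ok] <- pmin(pmax(num[ok] / a1658[ok], 0), clip_max)
    r
  }
  list(r1238 = ratio(a1238), r1546 = ratio(a1546), mask = ok,
       n_floor_removed = n_removed)
}

#' Assemble the multimodal analysis stack
#'
#' Combines the two IR ratio channels and the darkfield channel into one
#' co-registered stack on the 1 um grid, in the fixed channel order
#' (`r1238`, `r1546`, `df`). Per-channel standardization statistics (mean/sd
#' over masked pixels) are computed here on training sections and stored for
#' reuse at inference; pass `stats` to reuse statistics from another stack.
#'
#' @param r1238,r1546,df numeric matrices on the shared 1 um grid.
#' @param mask logical tissue mask.
#' @param labels optional integer label matrix (values 0..3) on the same grid.
#' @param section_id provenance string.
#' @param stats optional standardization statistics (`list(mean, sd)`, each of
#'   length 3) computed on training data; if `NULL`, computed from this stack.
#' @return An object of class `multimodal_stack`.
#' @export
assemble_stack <- function(r1238, r1546, df, mask, labels = NULL,
                           section_id = "section", stats = NULL) {
  dims <- dim(r1238)
  for (m in list(r1546, df, mask))
    if (!all(dim(m) == dims)) stop_param("all channels and the mask must share the same grid")
  if (!is.null(labels)) {
    if (!all(dim(labels) == dims)) stop_param("labels must share the stack grid")
    if (!all(labels %in% 0:3)) stop_param("labels must be in {0, 1, 2, 3}")
    storage.mode(labels) <- "integer"
  }
  channels <- array(c(r1238, r1546, df), dim = c(dims, 3L),
                    dimnames = list(NULL, NULL, c("r1238", "r1546", "df")))
  if (is.null(stats)) stats <- channel_stats_one(channels, mask)
  structure(list(channels = channels, tissue_mask = mask, labels = labels,
                 grid_shape = dims, section_id = section_id, stats = stats),
            class = "multimodal_stack")
}

channel_stats_one <- function(channels, mask) {
  mu <- sdv <- numeric(dim(channels)[3])
  for (k in seq_along(mu)) {
    v <- channels[, , k][mask]
    mu[k] <- mean(v)
    sdv[k] <- stats::sd(v)
    if (!is.finite(sdv[k]) || sdv[k] == 0) sdv[k] <- 1
  }
  list(mean = mu, sd = sdv, channel = dimnames(channels)[[3]])
}

#' Pooled standardization statistics over training stacks
#'
#' @param stacks list of `multimodal_stack` objects (the training sections).
#' @return `list(mean, sd)` per channel, pooled over all masked pixels.
#' @export
channel_stats <- function(stacks) {
  if (inherits(stacks, "multimodal_stack")) stacks <- list(stacks)
  nch <- dim(stacks[[1]]$channels)[3]
  n <- 0; s <- s2 <- numeric(nch)
  for (st in stacks) {
    for (k in seq_len(nch)) {
      v <- st$channels[, , k][st$tissue_mask]
      s[k] <- s[k] + sum(v)
      s2[k] <- s2[k] + sum(v^2)
    }
    n <- n + sum(st$tissue_mask)
  }
  mu <- s / n
  sdv <- sqrt(pmax(s2 / n - mu^2, 0))
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv, channel = dimnames(stacks[[1]]$channels)[[3]])
}

# standardized channel array: (x - mean) / sd inside the mask, 0 outside
standardize_channels <- function(channels, mask, stats, select = NULL) {
  if (is.null(select)) select <- seq_len(dim(channels)[3])
  out <- array(0, dim = c(dim(channels)[1:2], length(select)))
  for (i in seq_along(select)) {
    k <- select[i]
    ch <- (channels[, , k] - stats$mean[k]) / stats$sd[k]
    ch[!mask] <- 0
    out[, , i] <- ch
  }
  out
}

#' @export
print.multimodal_stack <- function(x, ...) {
  cat(sprintf("<multimodal_stack> %s: %d x %d um grid, channels %s\n",
              x$section_id, x$grid_shape[1], x$grid_shape[2],
              paste(dimnames(x$channels)[[3]], collapse = ", ")))
  cat(sprintf("  tissue: %.1f%% of frame%s\n", 100 * mean(x$tissue_mask),
              if (is.null(x$labels)) "" else "; ground-truth labels attached"))
  invisible(x)
}

#' Preprocess a phantom (or equivalently acquired) section
#'
#' Runs the full preprocessing chain: bilinear up-sampling of the 2 um IR
#' bands and down-sampling of the 0.5 um darkfield image to the shared 1 um
#' grid, optional translation registration of the darkfield channel onto the
#' Amide I image, Otsu tissue masking on Amide I, Amide I band-ratio
#' normalization, and stack assembly.
#'
#' @param section a `phantom_section` (or any list with the same fields).
#' @param clip_max ratio clip passed to [normalize_to_amide1()].
#' @param mask_method,threshold passed to [tissue_mask()].
#' @param register if `TRUE`, register the darkfield channel to Amide I.
#' @param stats optional standardization statistics to reuse.
#' @return A `multimodal_stack` (with `labels` if the section carried them).
#' @export
preprocess_section <- function(section, clip_max = 3,
                               mask_method = "otsu", threshold = NULL,
                               register = TRUE, stats = NULL) {
  bands <- section$raw_band_images
  wn <- vapply(bands, function(b) as.integer(b$wavenumber), 0L)
  need <- c(1238L, 1546L, 1658L)
  if (!all(need %in% wn)) stop_param("section must carry the 1238/1546/1658 cm-1 bands")
  up <- lapply(need, function(w) {
    b <- bands[[match(w, wn)]]
    resample_raster(b$pixels, b$pixel_size, 1, mode = "intensity")
  })
  dfp <- attr(section$darkfield, "pixel_size")
  if (is.null(dfp)) dfp <- 0.5
  df <- resample_raster(section$darkfield, dfp, 1, mode = "intensity")
  target <- dim(up[[3]])
  if (!all(dim(df) == target))
    df <- resample_cpp(df, target[1], target[2], "bilinear")
  if (register) {
    reg <- register_translation(df, up[[3]])
    df <- reg$registered
  }
  mask <- tissue_mask(up[[3]], method = mask_method, threshold = threshold)
  nrm <- normalize_to_amide1(up[[1]], up[[2]], up[[3]], mask,
                             clip_max = clip_max)
  labels <- section$labels
  if (!is.null(labels) && !all(dim(labels) == target))
    labels <- resample_raster(labels, 1, 1, mode = "label")
  assemble_stack(nrm$r1238, nrm$r1546, df, nrm$mask, labels = labels,
                 section_id = section$section_id, stats = stats)
}

#' Write / read a multimodal stack
#'
#' Channels are written as one 32-bit float TIFF per channel (scaled into
#' `[0, 1]` by a factor recorded in the JSON sidecar), the mask and labels as
#' 8-bit PNG, and the standardization statistics in the sidecar JSON.
#'
#' @param stack a `multimodal_stack`.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- stack$section_id
  files <- character(); scales <- list()
  chn <- dimnames(stack$channels)[[3]]
  for (k in seq_along(chn)) {
    f <- file.path(dir, sprintf("%s_%s.tif", id, chn[k]))
    sc <- max(1, max(stack$channels[, , k]))
    tiff::writeTIFF(stack$channels[, , k] / sc, f, bits.per.sample = 32L)
    scales[[chn[k]]] <- sc
    files <- c(files, f)
  }
  f <- file.path(dir, sprintf("%s_mask.png", id))
  png::writePNG(stack$tissue_mask * 1.0, f)
  files <- c(files, f)
  if (!is.null(stack$labels)) {
    f <- file.path(dir, sprintf("%s_labels.png", id))
    png::writePNG(stack$labels / 255, f)
    files <- c(files, f)
  }
  side <- list(section_id = id, grid_shape = stack$grid_shape,
               channels = chn, intensity_scale = scales,
               stats = stack$stats[c("mean", "sd")],
               has_labels = !is.null(stack$labels))
  f <- file.path(dir, sprintf("%s_stack.json", id))
  write_json_file(side, f)
  invisible(c(files, f))
}

#' @rdname write_stack
#' @param section_id identifier of the stack to read.
#' @export
read_stack <- function(dir, section_id) {
  side <- read_json_file(file.path(dir, sprintf("%s_stack.json", section_id)))
  chn <- side$channels
  dims <- as.integer(side$grid_shape)
  channels <- array(0, dim = c(dims, length(chn)),
                    dimnames = list(NULL, NULL, chn))
  for (k in seq_along(chn)) {
    m <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", section_id, chn[k])))
    channels[, , k] <- m * side$intensity_scale[[chn[k]]]
  }
  mask <- png::readPNG(file.path(dir, sprintf("%s_mask.png", section_id))) > 0.5
  labels <- NULL
  if (isTRUE(side$has_labels)) {
    labels <- round(png::readPNG(file.path(dir, sprintf("%s_labels.png",
                                                        section_id))) * 255)
    storage.mode(labels) <- "integer"
  }
  stats <- list(mean = as.numeric(side$stats$mean),
                sd = as.numeric(side$stats$sd), channel = chn)
  structure(list(channels = channels, tissue_mask = mask, labels = labels,
                 grid_shape = dims, section_id = section_id, stats = stats),
            class = "multimodal_stack")
}
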