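# Shared fixtures, built in code at test time.

# small phantom parameter set scaled for unit tests
tiny_phantom_params <- function(h = 256L, w = 256L, seed = 1L,
                                rete_peg_amplitude_px = 10,
                                rete_peg_period_px = 60, ...) {
  phantom_params(image_height_px = h, image_width_px = w,
                 rete_peg_amplitude_px = rete_peg_amplitude_px,
                 rete_peg_period_px = rete_peg_period_px,
                 seed = seed, ...)
}

# all stochastic intensity terms off: thickness CoV 0 unless overridden
noise_free_params <- function(h = 256L, w = 256L, seed = 1L,
                              thickness_cov = 0, ...) {
  tiny_phantom_params(h, w, seed = seed, noise_sd = 0,
                      sigma_ratio_1238 = c(0, 0, 0),
                      sigma_ratio_1546 = c(0, 0, 0),
                      thickness_cov = thickness_cov, ...)
}

# a hand-built multimodal stack with full control over mask and channels
make_stack <- function(h = 128L, w = 128L, mask = NULL, labels = NULL,
                       section_id = "test", value = 0.5) {
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  ch <- matrix(value, h, w)
  assemble_stack(ch, ch, ch, mask, labels = labels, section_id = section_id)
}

# brute-force enumerate-and-filter tiling oracle (independent of
# extract_patches internals): all non-overlapping patch origins, retained if
# the mask fraction meets the threshold
tile_oracle <- function(mask, patch_size, min_tissue_frac = 0.5) {
  H <- nrow(mask); W <- ncol(mask)
  kept <- list()
  r0 <- 0L
  while (r0 + patch_size <= H) {
    c0 <- 0L
    while (c0 + patch_size <= W) {
      frac <- mean(mask[(r0 + 1):(r0 + patch_size), (c0 + 1):(c0 + patch_size)])
      if (frac >= min_tissue_frac)
        kept[[length(kept) + 1L]] <- c(row = r0, col = c0, frac = frac)
      c0 <- c0 + patch_size
    }
    r0 <- r0 + patch_size
  }
  kept
}

origin_key <- function(origins) {
  sort(vapply(origins, function(o) paste(o[["row"]], o[["col"]], sep = ","), ""))
}

# a dataset small enough for fast training tests: sections drawn from the
# phantom generator, preprocessed and patched
make_tiny_dataset <- function(n_sections = 3L, h = 256L, patch_size = 128L,
                              counts = c(train = 1L, val = 1L, test = 1L),
                              seed = 11L) {
  ids <- sprintf("sec%02d", seq_len(n_sections))
  stacks <- lapply(seq_len(n_sections), function(i) {
    sec <- generate_phantom(tiny_phantom_params(h, h, seed = seed + i),
                            section_id = ids[i])
    preprocess_section(sec)
  })
  splits <- split_sections(ids, counts = counts, seed = seed)
  tr <- splits$section_id[splits$split == "train"]
  stats <- channel_stats(stacks[ids %in% tr])
  psets <- lapply(stacks, extract_patches, patch_size = patch_size)
  patch_dataset(psets, splits, stats)
}
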