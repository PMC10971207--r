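#' Extract non-overlapping training patches from a section
#'
#' Tiles the section on a non-overlapping grid anchored at the top-left
#' corner, in row-major order, and keeps tiles whose tissue-mask fraction is
#' at least `min_tissue_frac`. Partial tiles at the right/bottom edges are
#' discarded. "Tissue" is defined by the stack's tissue mask (what exists
#' before any annotation), not by the label map.
#'
#' @param stack a `multimodal_stack`.
#' @param labels optional label matrix; defaults to the stack's own labels.
#' @param patch_size tile side, px (the acquisition-scale protocol uses 256).
#' @param min_tissue_frac minimum fraction of mask-positive pixels.
#' @return An object of class `patch_set`: a list of patches, each a list with
#'   `channels` (`patch_size x patch_size x C`, raw, unstandardized), `labels`
#'   (or `NULL`), `mask`, `section_id`, `origin` (0-based `(row, col)` offset,
#'   a multiple of `patch_size`), and `tissue_frac`.
#' @export
extract_patches <- function(stack, labels = stack$labels, patch_size = 256L,
                            min_tissue_frac = 0.5) {
  if (!inherits(stack, "multimodal_stack"))
    stop_param("stack must be a multimodal_stack")
  patch_size <- as.integer(patch_size)
  H <- stack$grid_shape[1]; W <- stack$grid_shape[2]
  if (!is.null(labels) && !all(dim(labels) == c(H, W)))
    stop_param("labels must share the stack grid")
  out <- list()
  if (patch_size > H || patch_size > W) {
    warning("patch_size exceeds the section; returning an empty patch set")
    return(structure(out, class = "patch_set"))
  }
  for (r0 in seq(0L, H - patch_size, by = patch_size)) {
    for (c0 in seq(0L, W - patch_size, by = patch_size)) {
      rs <- (r0 + 1L):(r0 + patch_size)
      cs <- (c0 + 1L):(c0 + patch_size)
      m <- stack$tissue_mask[rs, cs]
      tf <- mean(m)
      if (tf >= min_tissue_frac) {
        out[[length(out) + 1L]] <- list(
          channels = stack$channels[rs, cs, , drop = FALSE],
          labels = if (is.null(labels)) NULL else labels[rs, cs],
          mask = m,
          section_id = stack$section_id,
          origin = c(row = r0, col = c0),
          tissue_frac = tf
        )
      }
    }
  }
  structure(out, class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches", length(x)))
  if (length(x))
    cat(sprintf(" of %d px from section %s", nrow(x[[1]]$labels %||% x[[1]]$mask),
                paste(unique(vapply(x, `[[`, "", "section_id")), collapse = ", ")))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Section-level dataset split
#'
#' Assigns whole sections to train/validation/test splits (no section
#' contributes patches to two splits), reproducibly for a fixed seed. Counts
#' are honored exactly; with `val = 0` the split reproduces the two-way
#' train / held-out design used at acquisition scale (20 training and 3
#' validation-and-blind-testing sections out of 23).
#'
#' @param section_ids character vector of section identifiers (>= 3).
#' @param counts named integer vector `c(train =, val =, test =)`; any
#'   remainder is unassigned. Alternatively fractions summing to <= 1.
#' @param seed integer seed for the assignment.
#' @return A data.frame with columns `section_id` and `split`.
#' @export
split_sections <- function(section_ids, counts = c(train = 20, val = 0, test = 3),
                           seed = 0L) {
  n <- length(section_ids)
  if (n < 3) stop_param("at least 3 sections are required")
  if (anyDuplicated(section_ids)) stop_param("section_ids must be unique")
  if (is.null(names(counts)))
    names(counts) <- c("train", "val", "test")[seq_along(counts)]
  if (all(counts <= 1) && sum(counts) <= 1 && any(counts != round(counts)))
    counts <- round(counts * n)
  counts <- counts[counts > 0]
  if (sum(counts) > n)
    stop_param("requested %d sections but only %d are available", sum(counts), n)
  ord <- with_seed(seed, sample(section_ids))
  split <- rep(NA_character_, n)
  i <- 0L
  for (s in names(counts)) {
    split[(i + 1L):(i + counts[[s]])] <- s
    i <- i + counts[[s]]
  }
  out <- data.frame(section_id = ord, split = split,
                    stringsAsFactors = FALSE)[!is.na(split), ]
  rownames(out) <- NULL
  out[order(match(out$section_id, section_ids)), , drop = FALSE]
}

#' Patch dataset with section-level splits
#'
#' Bundles the per-section patch sets with a section-level split assignment
#' and pooled training-set standardization statistics.
#'
#' @param patch_sets named list of `patch_set` objects (names = section ids),
#'   or a single list of patches from multiple sections.
#' @param splits data.frame from [split_sections()].
#' @param stats standardization statistics computed on the training sections
#'   (see [channel_stats()]); required for training.
#' @return An object of class `patch_dataset`.
#' @export
patch_dataset <- function(patch_sets, splits, stats) {
  patches <- do.call(c, lapply(unname(patch_sets), unclass))
  ids <- vapply(patches, `[[`, "", "section_id")
  if (!all(ids %in% splits$section_id))
    stop_param("patches reference sections absent from the split table")
  structure(list(patches = patches, splits = splits, stats = stats),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  ids <- vapply(x$patches, `[[`, "", "section_id")
  sp <- x$splits$split[match(ids, x$splits$section_id)]
  cat("<patch_dataset>\n")
  for (s in unique(x$splits$split))
    cat(sprintf("  %s: %d sections, %d patches\n", s,
                sum(x$splits$split == s), sum(sp == s)))
  invisible(x)
}

#' Dataset manifest
#'
#' One row per retained patch with its split, provenance and tissue fraction.
#'
#' @param dataset a `patch_dataset`.
#' @return A data.frame with columns `section_id`, `split`, `origin_row`,
#'   `origin_col`, `tissue_frac`.
#' @export
dataset_manifest <- function(dataset) {
  ids <- vapply(dataset$patches, `[[`, "", "section_id")
  data.frame(
    section_id = ids,
    split = dataset$splits$split[match(ids, dataset$splits$section_id)],
    origin_row = vapply(dataset$patches, function(p) p$origin[["row"]], 0),
    origin_col = vapply(dataset$patches, function(p) p$origin[["col"]], 0),
    tissue_frac = vapply(dataset$patches, `[[`, 0, "tissue_frac"),
    stringsAsFactors = FALSE
  )
}

#' Per-class pixel counts for a split
#'
#' Sums the pixels of the three annotated tissue classes (background excluded)
#' over the retained patches of one split.
#'
#' @param dataset a `patch_dataset`.
#' @param split split name (`"train"`, `"val"`, `"test"`).
#' @return Named integer vector of pixel counts for classes 1..3.
#' @export
class_pixel_summary <- function(dataset, split = "train") {
  ids <- vapply(dataset$patches, `[[`, "", "section_id")
  sp <- dataset$splits$split[match(ids, dataset$splits$section_id)]
  sel <- which(sp == split)
  counts <- c(non_epithelium = 0L, dysplastic = 0L, non_dysplastic = 0L)
  if (!length(sel)) {
    warning(sprintf("split '%s' contains no patches", split))
    return(counts)
  }
  for (i in sel) {
    lab <- dataset$patches[[i]]$labels
    if (is.null(lab)) stop_param("patches carry no labels")
    t <- tabulate(lab, nbins = 3L)
    counts <- counts + t
  }
  counts
}

# Assemble [H, W, C, N] channel and [H, W, N] label arrays for one split,
# standardized with the dataset's (training) statistics and restricted to the
# modality's channels. Background label 0 is kept and ignored by the loss;
# pixels outside the tissue mask are also forced to label 0 so they never
# contribute.
patch_arrays <- function(dataset, split, modality) {
  ids <- vapply(dataset$patches, `[[`, "", "section_id")
  sp <- dataset$splits$split[match(ids, dataset$splits$section_id)]
  sel <- which(sp == split)
  if (!length(sel)) return(NULL)
  p1 <- dataset$patches[[sel[1]]]
  ps <- dim(p1$channels)[1]
  chans <- modality$channels
  X <- array(0, dim = c(ps, ps, length(chans), length(sel)))
  Y <- array(0L, dim = c(ps, ps, length(sel)))
  for (j in seq_along(sel)) {
    p <- dataset$patches[[sel[j]]]
    X[, , , j] <- standardize_channels(p$channels, p$mask, dataset$stats,
                                       select = chans)
    lab <- p$labels
    lab[!p$mask] <- 0L
    Y[, , j] <- lab
  }
  list(X = X, Y = Y)
}
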