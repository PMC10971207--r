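#' Pixel-level confusion matrix
#'
#' Counts pixels by (true class, predicted class) over the evaluation set:
#' pixels inside the mask whose true label is one of the three tissue classes.
#' Background never enters the metrics. The percent matrix is row-normalized
#' (each true-class row sums to 100); rows with no truth pixels are flagged,
#' not divided.
#'
#' @param pred,truth integer label matrices (values 0..3) on a shared grid.
#' @param mask logical evaluation mask (e.g. the tissue mask).
#' @return An object of class `confusion_matrix` with `counts` (3x3 integer,
#'   rows = truth 1..3, cols = predicted 1..3), `percent`, `n_pixels`, and
#'   `empty_rows` (flagged truth classes without pixels).
#' @export
confusion_matrix <- function(pred, truth, mask = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop_param("pred and truth must share a grid")
  if (is.null(mask)) mask <- array(TRUE, dim(truth))
  if (!all(dim(mask) == dim(truth)))
    stop_param("mask must share the grid")
  sel <- mask & truth %in% 1:3
  if (!any(sel))
    stop_param("degenerate input: no annotated tissue pixels to evaluate")
  t <- truth[sel]
  p <- pred[sel]
  if (any(p < 1 | p > 3)) {
    warning(sprintf("%d evaluated pixels predicted outside classes 1..3 were dropped",
                    sum(p < 1 | p > 3)))
    keep <- p >= 1 & p <= 3
    t <- t[keep]; p <- p[keep]
  }
  counts <- matrix(tabulate((t - 1L) * 3L + p, nbins = 9L), 3, 3, byrow = TRUE)
  cls <- c("non_epithelium", "dysplastic", "non_dysplastic")
  dimnames(counts) <- list(truth = cls, predicted = cls)
  rs <- rowSums(counts)
  percent <- counts * NA_real_
  nz <- rs > 0
  percent[nz, ] <- 100 * counts[nz, , drop = FALSE] / rs[nz]
  structure(list(counts = counts, percent = percent, n_pixels = sum(counts),
                 empty_rows = cls[!nz]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("<confusion_matrix> %s pixels (row-normalized %%)\n",
              format(x$n_pixels, big.mark = ",")))
  print(round(x$percent, digits))
  if (length(x$empty_rows))
    cat("rows without truth pixels:", paste(x$empty_rows, collapse = ", "), "\n")
  invisible(x)
}

#' Segmentation metrics from a confusion matrix
#'
#' Overall accuracy is `100 * trace / sum`. Per-class F1 is `2PR / (P + R)`
#' with the 0 convention when `P + R = 0`; macro F1 is the unweighted mean
#' over the tissue classes. A class absent from the truth has undefined
#' recall and is excluded from the macro mean (and flagged).
#'
#' @param cm a [confusion_matrix()] (or a plain counts matrix).
#' @return List with `accuracy` (percent), `macro_f1`, `per_class`
#'   (data.frame of precision/recall/F1), and `excluded_classes`.
#' @export
metrics_from_confusion <- function(cm) {
  counts <- if (inherits(cm, "confusion_matrix")) cm$counts else as.matrix(cm)
  if (sum(counts) <= 0) stop_param("confusion matrix has no evaluated pixels")
  k <- nrow(counts)
  accuracy <- 100 * sum(diag(counts)) / sum(counts)
  rs <- rowSums(counts); cs <- colSums(counts); d <- diag(counts)
  precision <- ifelse(cs > 0, d / cs, NA_real_)
  recall <- ifelse(rs > 0, d / rs, NA_real_)
  f1 <- numeric(k)
  for (i in seq_len(k)) {
    p <- precision[i]; r <- recall[i]
    f1[i] <- if (is.na(r)) NA_real_
    else if (is.na(p) || p + r == 0) 0
    else 2 * p * r / (p + r)
  }
  present <- rs > 0
  cls <- rownames(counts) %||% paste0("class", seq_len(k))
  list(accuracy = accuracy,
       macro_f1 = mean(f1[present]),
       per_class = data.frame(class = cls, precision = precision,
                              recall = recall, f1 = f1, row.names = NULL),
       excluded_classes = cls[!present])
}

#' Aggregate metrics over training replicates
#'
#' Mean and population standard deviation (divisor `n`) of each metric across
#' the replicate trainings of one modality.
#'
#' @param reports list of per-replicate metric lists (each as returned by
#'   [metrics_from_confusion()], optionally carrying a `modality` field).
#' @return A data.frame with one row per metric: `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(reports) {
  if (!length(reports)) stop_param("at least one replicate report is required")
  mods <- unique(unlist(lapply(reports, function(r) r$modality)))
  if (length(mods) > 1)
    stop_param("replicate reports mix modalities: %s", paste(mods, collapse = ", "))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  vals <- list(
    accuracy = vapply(reports, `[[`, 0, "accuracy"),
    macro_f1 = vapply(reports, `[[`, 0, "macro_f1"),
    dysplastic_recall = vapply(reports, function(r) r$per_class$recall[2], 0)
  )
  out <- data.frame(
    metric = names(vals),
    mean = vapply(vals, mean, 0),
    sd = vapply(vals, pop_sd, 0),
    n = length(reports), row.names = NULL
  )
  if (length(mods)) attr(out, "modality") <- mods
  out
}

# Evaluate one replicate on the test split of a dataset: per-patch forward
# pass (eval mode), pooled confusion matrix over all annotated masked pixels.
evaluate_replicate <- function(model, dataset, split = "test", replicate = 1L,
                               batch = 8L) {
  arr <- patch_arrays(dataset, split, model$modality)
  if (is.null(arr)) stop_param("split '%s' contains no patches", split)
  params <- model$replicates[[replicate]]$params
  n <- dim(arr$X)[4]
  pred <- array(0L, dim = dim(arr$Y))
  for (off in seq(1L, n, by = batch)) {
    idx <- off:min(off + batch - 1L, n)
    pr <- nn_forward(model$fcn$spec, params,
                     arr$X[, , , idx, drop = FALSE], FALSE, TRUE)
    d <- dim(pr)
    for (j in seq_along(idx)) {
      pj <- matrix(pr[, , , j], d[1] * d[2], d[3])
      pred[, , idx[j]] <- matrix(max.col(pj, ties.method = "first"), d[1], d[2])
    }
  }
  cm <- confusion_matrix(pred, arr$Y, mask = array(TRUE, dim(arr$Y)))
  m <- metrics_from_confusion(cm)
  m$cm <- cm
  m$modality <- model$modality$name
  m$replicate <- replicate
  m
}

#' Evaluate a fitted model on a dataset split
#'
#' Runs every replicate of the fitted ensemble on the given split and
#' aggregates accuracy, macro F1 and dysplastic-class recall across
#' replicates (mean and population SD).
#'
#' @param model a fitted `dfir_fcn`.
#' @param dataset the `patch_dataset` carrying the split.
#' @param split split name (default `"test"`).
#' @return An object of class `eval_report`: `modality`, `replicates`
#'   (per-replicate metrics + confusion matrix), and `aggregate`.
#' @export
evaluate_model <- function(model, dataset, split = "test") {
  reps <- lapply(seq_along(model$replicates), function(r)
    evaluate_replicate(model, dataset, split = split, replicate = r))
  structure(list(modality = model$modality$name, replicates = reps,
                 aggregate = aggregate_replicates(reps), split = split),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> modality %s, %d replicate(s) on split '%s'\n",
              x$modality, length(x$replicates), x$split))
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-18s %.3f (SD %.4f)\n", a$metric[i], a$mean[i], a$sd[i]))
  invisible(x)
}

#' Modality ablation
#'
#' Trains `config$n_replicates` models per modality on identical splits and
#' seeds, evaluates each on the test split, and returns the per-modality
#' reports plus a comparison table — the darkfield-only / IR-only / combined
#' ablation.
#'
#' @param dataset a `patch_dataset` with train/val/test splits.
#' @param config a [train_config()].
#' @param modalities modalities to ablate.
#' @return An object of class `ablation_result`: named list of `eval_report`s
#'   (`reports`), the fitted models (`models`), and a long-format `table` with
#'   one row per modality x replicate x metric.
#' @export
ablation_run <- function(dataset, config = train_config(),
                         modalities = c("DF", "IR", "COMBINED")) {
  reports <- list(); models <- list(); rows <- list()
  for (m in modalities) {
    fit <- train_segmenter(dataset, modality = m, config = config)
    rep <- evaluate_model(fit, dataset, split = "test")
    models[[m]] <- fit
    reports[[m]] <- rep
    for (r in rep$replicates) {
      rows[[length(rows) + 1L]] <- data.frame(
        modality = m, replicate = r$replicate,
        accuracy = r$accuracy, macro_f1 = r$macro_f1,
        dysplastic_recall = r$per_class$recall[2],
        stringsAsFactors = FALSE)
    }
  }
  structure(list(reports = reports, models = models,
                 table = do.call(rbind, rows)),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result>\n")
  for (m in names(x$reports)) {
    a <- x$reports[[m]]$aggregate
    cat(sprintf("  %-9s accuracy %.1f%% (SD %.2f), macro F1 %.3f (SD %.3f), dysplastic recall %.3f\n",
                m, a$mean[a$metric == "accuracy"], a$sd[a$metric == "accuracy"],
                a$mean[a$metric == "macro_f1"], a$sd[a$metric == "macro_f1"],
                a$mean[a$metric == "dysplastic_recall"]))
  }
  invisible(x)
}

#' Render a whole-section projection panel
#'
#' Writes a deterministic PNG panel showing an input channel, the model
#' prediction and the ground truth side by side, using the fixed class
#' colormap (background black, non-epithelium blue, dysplastic red,
#' non-dysplastic green) with a legend strip along the bottom.
#'
#' @param pred,truth integer label matrices on a shared grid.
#' @param channel numeric matrix shown as the input panel (e.g. Amide I or
#'   darkfield), normalized to its own range.
#' @param path output PNG path.
#' @return Invisibly, `path`.
#' @export
render_projection <- function(pred, truth, channel, path) {
  if (!all(dim(pred) == dim(truth)) || !all(dim(pred) == dim(channel)))
    stop_param("pred, truth and channel must share a grid")
  H <- nrow(pred); W <- ncol(pred)
  pal <- grDevices::col2rgb(class_palette()) / 255
  colorize <- function(lab) {
    rgb <- array(0, dim = c(H, W, 3))
    for (k in 0:3) {
      sel <- lab == k
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[sel] <- pal[ch, k + 1]
        rgb[, , ch] <- plane
      }
    }
    rgb
  }
  rng <- range(channel)
  g <- if (rng[1] == rng[2]) matrix(0, H, W) else
    (channel - rng[1]) / (rng[2] - rng[1])
  gap <- 4L
  panel <- array(1, dim = c(H, 3L * W + 2L * gap, 3))
  for (ch in 1:3) panel[, 1:W, ch] <- g
  panel[, W + gap + (1:W), ] <- colorize(pred)
  panel[, 2L * (W + gap) + (1:W), ] <- colorize(truth)
  # legend strip: one colored block per class along the bottom
  strip_h <- max(4L, H %/% 32L)
  legend <- array(1, dim = c(strip_h, dim(panel)[2], 3))
  bw <- dim(panel)[2] %/% 8L
  for (k in 0:3) {
    cols <- (k * 2L * bw + 1L):(k * 2L * bw + bw)
    for (ch in 1:3) legend[, cols, ch] <- pal[ch, k + 1]
  }
  out <- array(1, dim = c(H + strip_h + gap, dim(panel)[2], 3))
  out[1:H, , ] <- panel
  out[H + gap + (1:strip_h), , ] <- legend
  png::writePNG(out, path)
  invisible(path)
}
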