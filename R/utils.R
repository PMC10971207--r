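# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# smooth 1-D noise: circularly filtered white noise scaled to unit sd
smooth_noise_1d <- function(n, sigma) {
  half <- max(1L, min(ceiling(3 * sigma), (n - 1L) %/% 2L))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  x <- as.numeric(stats::filter(stats::rnorm(n), k, circular = TRUE))
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else x / s
}

# smooth 2-D Gaussian random field on an H x W grid with approximate
# correlation length `corr_len` (pixels), unit variance; generated at reduced
# resolution for speed and upsampled bilinearly
smooth_noise_2d <- function(h, w, corr_len) {
  down <- max(1L, min(4L, floor(corr_len / 8)))
  hc <- max(8L, ceiling(h / down))
  wc <- max(8L, ceiling(w / down))
  z <- matrix(stats::rnorm(hc * wc), hc, wc)
  sigma <- max(corr_len / (2 * down), 0.5)
  radius <- min(2 * ceiling(sigma) + 1, 2 * ((min(hc, wc) - 1) %/% 2) + 1)
  z <- as.matrix(EBImage::gblur(z, sigma = sigma, radius = radius))
  z <- resample_cpp(z, as.integer(h), as.integer(w), "bilinear")
  s <- stats::sd(z)
  if (s == 0) matrix(0, h, w) else (z - mean(z)) / s
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
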