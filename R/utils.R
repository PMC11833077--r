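#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif var sd median
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this helper: no function leaves
# a footprint on the global stream, and equal seeds give bit-identical output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive n child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ITU-R BT.601 luma of an H x W x 3 array (0..255), returning H x W.
luminance <- function(pixels) {
  0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] + 0.114 * pixels[, , 3L]
}

# Round half away from zero (so 0.5 -> 1), used when mapping scores to 0..255.
round_half_up <- function(x) floor(x + 0.5)

# Area-weighted (box filter) resampling of a matrix to out_h x out_w.
# Each output pixel averages the exactly-overlapping source region, so thin
# dark traces attenuate smoothly instead of aliasing away as point sampling
# would. Implemented as two dense weight-matrix products.
area_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov
    }
  }
  w / rowSums(w)
}

resize_matrix_area <- function(m, out_h, out_w) {
  a <- area_weights(nrow(m), out_h)
  b <- t(area_weights(ncol(m), out_w))
  a %*% m %*% b
}

resize_pixels_area <- function(pixels, out_h, out_w) {
  out <- array(0, c(out_h, out_w, dim(pixels)[3L]))
  for (c in seq_len(dim(pixels)[3L])) {
    out[, , c] <- resize_matrix_area(pixels[, , c], out_h, out_w)
  }
  out
}

# Resample a logical mask: an output pixel is "signal" when signal covers more
# than `min_fraction` of its source footprint.
resize_mask_area <- function(mask, out_h, out_w, min_fraction = 0.2) {
  resize_matrix_area(mask * 1, out_h, out_w) > min_fraction
}

# Separable Gaussian blur of a matrix, sigma in pixels; sigma <= 0 is identity.
# Borders are handled by renormalising the kernel over the valid support.
gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(x) {
    n <- length(k)
    pad <- matrix(0, nrow(x) + 2 * r, ncol(x))
    pad[(r + 1):(r + nrow(x)), ] <- x
    wsum <- matrix(0, nrow(x) + 2 * r, ncol(x))
    wsum[(r + 1):(r + nrow(x)), ] <- 1
    num <- matrix(0, nrow(x), ncol(x))
    den <- matrix(0, nrow(x), ncol(x))
    for (i in seq_len(n)) {
      rows <- i:(i + nrow(x) - 1)
      num <- num + k[i] * pad[rows, , drop = FALSE]
      den <- den + k[i] * wsum[rows, , drop = FALSE]
    }
    num / den
  }
  t(blur_1d(t(blur_1d(m))))
}

stop_if_not_image <- function(image, arg = "image") {
  if (!inherits(image, "ecg_image")) {
    abort(sprintf("`%s` must be an <ecg_image> (see render_ecg_image()).", arg))
  }
}
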