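#' Blur gate: variance-of-Laplacian focus measure
#'
#' Computes the discrete Laplacian (4-neighbour 3 x 3 kernel) of the
#' image's ITU-R BT.601 luminance and reports its population variance over
#' all interior pixels. Images whose variance falls below the cutoff are
#' flagged as too blurry to analyze; a variance exactly at the cutoff is
#' accepted.
#'
#' @param image An `ecg_image`.
#' @param cutoff Acceptance cutoff on the Laplacian variance (default 10).
#' @return A one-row tibble (`laplacian_variance`, `accepted`, `cutoff`).
#' @export
blur_gate <- function(image, cutoff = 10) {
  stop_if_not_image(image)
  lum <- matrix(luminance(image$pixels), dim(image$pixels)[1],
                dim(image$pixels)[2])
  h <- nrow(lum)
  w <- ncol(lum)
  if (h < 3 || w < 3) {
    return(tibble(laplacian_variance = 0, accepted = FALSE, cutoff = cutoff))
  }
  core <- lum[2:(h - 1), 2:(w - 1)]
  lap <- lum[1:(h - 2), 2:(w - 1)] + lum[3:h, 2:(w - 1)] +
    lum[2:(h - 1), 1:(w - 2)] + lum[2:(h - 1), 3:w] - 4 * core
  v <- mean((lap - mean(lap))^2)
  tibble(laplacian_variance = v, accepted = v >= cutoff, cutoff = cutoff)
}

#' Threshold segmentation of the ECG trace
#'
#' Marks every pixel whose luminance is strictly below `threshold` (of 256
#' 8-bit levels) as signal. With the renderer's near-black ink this recovers
#' the trace pixels; the grid and paper stay above threshold.
#'
#' @param image An `ecg_image`.
#' @param threshold 8-bit luminance threshold (default 10; a pixel of
#'   luminance 9 is signal, 10 is not).
#' @return A logical H x W matrix of class `binary_mask`.
#' @export
segment_signal <- function(image, threshold = 10) {
  stop_if_not_image(image)
  m <- luminance(image$pixels) < threshold
  class(m) <- c("binary_mask", class(m))
  m
}

#' Standardize an image for forward propagation
#'
#' Maps each channel to zero mean and unit variance over the image, keeping
#' the inverse transform as attributes so saliency maps computed on the
#' normalized raster can be expressed in original pixel units. A constant
#' channel is shifted to zero and its scale left at 1.
#'
#' @param image An `ecg_image`, or a bare H x W x 3 array of 0-255 values.
#' @return A numeric H x W x 3 array with attributes `norm_mean` and
#'   `norm_sd` (per channel), class `normalized_raster`.
#' @export
normalize_image <- function(image) {
  px <- if (inherits(image, "ecg_image")) image$pixels else image
  if (length(dim(px)) != 3L) abort("expected an H x W x 3 raster")
  mu <- apply(px, 3, mean)
  sdv <- sqrt(pmax(apply(px, 3, function(ch) mean((ch - mean(ch))^2)), 0))
  sdv[sdv < 1e-12] <- 1
  out <- px
  for (c in seq_len(dim(px)[3])) out[, , c] <- (px[, , c] - mu[c]) / sdv[c]
  attr(out, "norm_mean") <- mu
  attr(out, "norm_sd") <- sdv
  class(out) <- c("normalized_raster", class(out))
  out
}
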