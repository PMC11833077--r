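#' Per-pixel Jacobian saliency map
#'
#' Differentiates the label-predictor output with respect to every input
#' pixel and colour channel in a single backward pass through the network
#' (in eval mode; no weights change). For `target = "presence"` the map is
#' the gradient of the predicted probability of the condition; for
#' `"absence"` it is the gradient of `1 - p`, i.e. the element-wise negation
#' — the magnitude is the same, the meaning (what would make the model more
#' confident the condition is absent) differs.
#'
#' The map is taken with respect to the normalized input and, when the
#' raster carries normalization metadata, rescaled to original 0-255 pixel
#' units so its geometry aligns with the displayed image.
#'
#' @param model An `ecg_net` (used in eval mode).
#' @param x A `normalized_raster` (H x W x 3) matching the model input size.
#' @param target `"presence"` or `"absence"`.
#' @param condition_id Optional condition label stored in the map.
#' @return An object of class `saliency_map` with fields `raw`
#'   (H x W x 3 signed partials), `label_prob`, `target`, `condition_id`;
#'   `magnitude` and `scaled` are filled by [aggregate_and_scale()].
#' @export
jacobian_map <- function(model, x, target = c("presence", "absence"),
                         condition_id = NULL) {
  target <- match.arg(target)
  d <- dim(x)
  if (length(d) != 3L) abort("`x` must be a single H x W x 3 raster.")
  xb <- array(as.numeric(x), c(d, 1L))
  out <- model_forward(model, xb, train = FALSE, heads = "label")
  # differentiate the predicted probability: d p / d logit = p (1 - p);
  # the absence map differentiates 1 - p, the exact negation
  sign <- if (target == "presence") 1 else -1
  seed_grad <- sign * out$label_prob * (1 - out$label_prob)
  dx <- model_backward(model, out, d_label = seed_grad)
  raw <- array(dx, d)
  sdv <- attr(x, "norm_sd")
  if (!is.null(sdv)) {
    # chain rule through x_norm = (x - mean) / sd back to pixel units
    for (c in seq_len(d[3])) raw[, , c] <- raw[, , c] / sdv[c]
  }
  structure(
    list(raw = raw, magnitude = NULL, scaled = NULL,
         label_prob = out$label_prob, target = target,
         condition_id = condition_id),
    class = "saliency_map"
  )
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(
    "<saliency_map> %s%s: p = %.4f, %s\n",
    x$target,
    if (is.null(x$condition_id)) "" else paste0(" of ", x$condition_id),
    x$label_prob,
    if (is.null(x$scaled)) "raw only" else "scaled 0-255"
  ))
  invisible(x)
}

#' Aggregate channels and scale a saliency map to 0-255
#'
#' Per pixel, the channel partials collapse to a nonnegative magnitude
#' (maximum absolute value over the three channels by default, or the
#' Euclidean norm), which is then min-max mapped onto integers 0-255
#' (round half up). An all-constant map scales to all zeros.
#'
#' @param map A `saliency_map` with `raw` present.
#' @param channel_agg `"max_abs"` (default) or `"l2"`.
#' @return The map with `magnitude` and `scaled` filled.
#' @export
aggregate_and_scale <- function(map, channel_agg = c("max_abs", "l2")) {
  channel_agg <- match.arg(channel_agg)
  if (is.null(map$raw)) abort("`map$raw` is missing.")
  a <- abs(map$raw)
  mag <- switch(channel_agg,
    max_abs = pmax(a[, , 1], a[, , 2], a[, , 3]),
    l2 = sqrt(a[, , 1]^2 + a[, , 2]^2 + a[, , 3]^2)
  )
  rng <- range(mag)
  scaled <- if (diff(rng) < .Machine$double.eps) {
    matrix(0L, nrow(mag), ncol(mag))
  } else {
    matrix(as.integer(round_half_up(255 * (mag - rng[1]) / diff(rng))),
           nrow(mag), ncol(mag))
  }
  map$magnitude <- mag
  map$scaled <- scaled
  map
}

#' Binarize a scaled saliency map
#'
#' Marks scaled values strictly above the cutoff (default 20) as `TRUE`.
#'
#' @param map A `saliency_map` after [aggregate_and_scale()].
#' @param cutoff Threshold on the 0-255 scale.
#' @return A logical matrix of class `binary_mask`.
#' @export
binarize_saliency <- function(map, cutoff = 20) {
  if (is.null(map$scaled)) abort("Run aggregate_and_scale() first.")
  m <- map$scaled > cutoff
  class(m) <- c("binary_mask", class(m))
  m
}

#' Overlay a binary mask on an ECG image
#'
#' Alpha-blends masked pixels toward the marker colour (purple by default,
#' as saliency is conventionally displayed over the trace); unmasked pixels
#' are untouched.
#'
#' @param image An `ecg_image`.
#' @param mask Logical matrix of the same H x W.
#' @param color Marker RGB, 0-255.
#' @param alpha Blend weight in `[0, 1]` (1 = solid marker).
#' @return The blended `ecg_image`.
#' @export
overlay_mask <- function(image, mask, color = c(128, 0, 128), alpha = 0.6) {
  stop_if_not_image(image)
  d <- dim(image$pixels)
  if (!identical(dim(mask), d[1:2])) {
    abort(sprintf("Mask %s does not match image %s.",
                  paste(dim(mask), collapse = "x"),
                  paste(d[1:2], collapse = "x")))
  }
  px <- image$pixels
  for (c in 1:3) {
    ch <- px[, , c]
    ch[mask] <- (1 - alpha) * ch[mask] + alpha * color[c]
    px[, , c] <- ch
  }
  new_ecg_image_like(image, px)
}

#' Explain one ECG image
#'
#' The full interpretability pipeline: blur gate, resample to the network
#' input size, normalize, Jacobian map, channel aggregation and 0-255
#' scaling, binarization, and overlay. Images failing the blur gate are
#' skipped with a report rather than an error.
#'
#' @param model A trained `ecg_net`.
#' @param image An `ecg_image`.
#' @param target `"presence"` or `"absence"`.
#' @param condition_id Label recorded in the outputs.
#' @param cutoff Binarization cutoff (default 20).
#' @param blur_cutoff Blur-gate cutoff (default 10).
#' @return A list: `skipped` (logical), `blur` (the gate report), and when
#'   not skipped `map` (`saliency_map`), `mask` (`binary_mask` at input
#'   resolution), `overlay` (`ecg_image` at input resolution), `label_prob`,
#'   and `elapsed_s`.
#' @export
explain_image <- function(model, image, target = "presence",
                          condition_id = NULL, cutoff = 20,
                          blur_cutoff = 10) {
  stop_if_not_image(image)
  gate <- blur_gate(image, blur_cutoff)
  if (!gate$accepted) {
    return(list(skipped = TRUE, reason = "too blurry to analyze",
                blur = gate))
  }
  t0 <- proc.time()[["elapsed"]]
  size <- model$config$input_size
  small <- resize_pixels_area(image$pixels, size[1], size[2])
  xn <- normalize_image(small)
  map <- jacobian_map(model, xn, target, condition_id) |>
    aggregate_and_scale()
  mask <- binarize_saliency(map, cutoff)
  small_img <- new_ecg_image_like(
    image, small,
    signal_mask = if (!is.null(image$signal_mask)) {
      resize_mask_area(image$signal_mask, size[1], size[2])
    } else {
      NULL
    }
  )
  ov <- overlay_mask(small_img, mask)
  list(skipped = FALSE, blur = gate, map = map, mask = mask, overlay = ov,
       label_prob = map$label_prob,
       elapsed_s = proc.time()[["elapsed"]] - t0)
}
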