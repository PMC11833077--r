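#' Configuration for mobile-photo artifact simulation
#'
#' Defaults encode the augmentation recipe used to build the photo-like
#' training domain: four shadows per image with attenuations drawn uniformly
#' from 0.3-0.7 of full intensity, shadow shapes sampled with replacement
#' from polygons, ellipses and single-source (half-plane) shadows, a blur
#' whose Gaussian width grows linearly with shadow attenuation (0 to 3 px),
#' moderate perspective tilt, and optional flash saturation.
#'
#' @param n_shadows Number of shadows composited per image (default 4).
#' @param intensity_range Attenuation interval, a fraction of maximum
#'   intensity (default `c(0.3, 0.7)`).
#' @param shape_set Subset of `c("polygon", "ellipse", "point_source")`.
#' @param perspective_max_tilt Maximum capture tilt in degrees (< 45).
#' @param flash_probability Probability a flash highlight is added.
#' @param blur_coupling Monotone function mapping attenuation (0-1) to a
#'   Gaussian sigma in pixels; default `function(a) 3 * a`.
#' @param seed Integer seed for the augmentation stream.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(n_shadows = 4,
                           intensity_range = c(0.3, 0.7),
                           shape_set = c("polygon", "ellipse", "point_source"),
                           perspective_max_tilt = 12,
                           flash_probability = 0.5,
                           blur_coupling = function(a) 3 * a,
                           seed = 1L) {
  if (n_shadows < 0) abort("`n_shadows` must be >= 0.")
  if (length(intensity_range) != 2L || any(intensity_range < 0) ||
      any(intensity_range > 1) || diff(intensity_range) < 0) {
    abort("`intensity_range` must be an increasing interval inside [0, 1].")
  }
  shape_set <- match.arg(shape_set, several.ok = TRUE)
  if (n_shadows > 0 && length(shape_set) == 0) {
    abort("`shape_set` must be nonempty when `n_shadows` > 0.")
  }
  if (perspective_max_tilt >= 45) abort("`perspective_max_tilt` must be < 45 degrees.")
  if (flash_probability < 0 || flash_probability > 1) {
    abort("`flash_probability` must lie in [0, 1].")
  }
  structure(
    list(n_shadows = n_shadows, intensity_range = intensity_range,
         shape_set = shape_set, perspective_max_tilt = perspective_max_tilt,
         flash_probability = flash_probability, blur_coupling = blur_coupling,
         seed = as.integer(seed)),
    class = "augment_config"
  )
}

# Draw the per-shadow specification (shape, attenuation, blur sigma,
# placement). Shapes are sampled uniformly with replacement from the shape
# set; attenuations from the configured uniform law.
draw_shadow_specs <- function(n, config, H, W) {
  if (n == 0L) return(tibble())
  tibble(
    shape = sample(config$shape_set, n, replace = TRUE),
    attenuation = runif(n, config$intensity_range[1], config$intensity_range[2]),
    cx = runif(n, 1, W),
    cy = runif(n, 1, H),
    size = runif(n, 0.18, 0.45) * sqrt(H * W),
    angle = runif(n, 0, 2 * pi)
  ) |>
    dplyr::mutate(sigma = purrr::map_dbl(.data$attenuation, config$blur_coupling))
}

# Soft coverage field (H x W in [0,1]) of one shadow shape.
shadow_alpha <- function(spec, H, W) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  alpha <- switch(spec$shape,
    ellipse = {
      dx <- (xs - spec$cx) / (0.7 * spec$size)
      dy <- (ys - spec$cy) / (0.45 * spec$size)
      u <- dx * cos(spec$angle) + dy * sin(spec$angle)
      v <- -dx * sin(spec$angle) + dy * cos(spec$angle)
      (u^2 + v^2 <= 1) * 1
    },
    polygon = {
      # convex 5-7-gon around the centre; point-in-polygon by half-plane
      # intersection, orientation fixed by the sign at the centroid
      k <- 5 + (round(spec$cx + spec$cy) %% 3)
      ang <- spec$angle + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
      rad <- spec$size * 0.6
      vx <- spec$cx + rad * cos(ang)
      vy <- spec$cy + rad * sin(ang)
      inside <- matrix(TRUE, H, W)
      for (i in seq_len(k)) {
        j <- if (i == k) 1L else i + 1L
        cr <- (vx[j] - vx[i]) * (ys - vy[i]) - (vy[j] - vy[i]) * (xs - vx[i])
        s <- sign((vx[j] - vx[i]) * (spec$cy - vy[i]) -
                    (vy[j] - vy[i]) * (spec$cx - vx[i]))
        inside <- inside & (s * cr >= 0)
      }
      inside * 1
    },
    point_source = {
      # "single source" shadow: a soft half-plane gradient, as cast by an
      # off-frame occluder under one light source
      nx <- cos(spec$angle)
      ny <- sin(spec$angle)
      d <- (xs - spec$cx) * nx + (ys - spec$cy) * ny
      clamp(0.5 + d / (0.8 * spec$size), 0, 1)
    }
  )
  alpha
}

#' Composite synthetic shadows onto an ECG image
#'
#' Each shadow darkens the raster multiplicatively: `pixel * (1 - a * alpha)`
#' where `a` is the shadow's attenuation (uniform on the configured range)
#' and `alpha` its soft coverage field, blurred with a Gaussian whose width
#' is coupled to the attenuation. Dimensions, layout and `signal_mask` are
#' unchanged; `n_shadows = 0` is the identity.
#'
#' @param image An `ecg_image`.
#' @param config An [augment_config()].
#' @param seed Seed for this call (defaults to `config$seed`).
#' @return The shadowed `ecg_image`, with the drawn shadow parameters
#'   attached as attribute `"shadow_params"`.
#' @export
add_shadows <- function(image, config = augment_config(), seed = config$seed) {
  stop_if_not_image(image)
  if (config$n_shadows == 0L) return(image)
  d <- dim(image$pixels)
  with_seed(seed, {
    specs <- draw_shadow_specs(config$n_shadows, config, d[1], d[2])
    px <- image$pixels
    for (i in seq_len(nrow(specs))) {
      alpha <- shadow_alpha(as.list(specs[i, ]), d[1], d[2])
      alpha <- gaussian_blur_matrix(alpha, specs$sigma[i])
      factor <- 1 - specs$attenuation[i] * alpha
      for (c in 1:3) px[, , c] <- px[, , c] * factor
    }
    out <- new_ecg_image_like(image, px, provenance = "augmented")
    attr(out, "shadow_params") <- specs
    out
  })
}

# Homography mapping the unit corners of an H x W image to perturbed corners.
# Solved from 4 point pairs by the direct linear transform.
homography_from_corners <- function(src, dst) {
  a <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    a[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    a[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(a, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# Inverse-map warp with bilinear sampling; `fill` for out-of-canvas pixels.
warp_matrix <- function(m, hom, fill) {
  H <- nrow(m); W <- ncol(m)
  hinv <- solve(hom)
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  den <- hinv[3, 1] * xs + hinv[3, 2] * ys + hinv[3, 3]
  sx <- (hinv[1, 1] * xs + hinv[1, 2] * ys + hinv[1, 3]) / den
  sy <- (hinv[2, 1] * xs + hinv[2, 2] * ys + hinv[2, 3]) / den
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    out <- matrix(fill, H, W)
    out[ok] <- m[cbind(yy[ok], xx[ok])]
    out
  }
  (1 - fx) * (1 - fy) * pick(y0, x0) + fx * (1 - fy) * pick(y0, x0 + 1) +
    (1 - fx) * fy * pick(y0 + 1, x0) + fx * fy * pick(y0 + 1, x0 + 1)
}

#' Apply a random perspective change
#'
#' Simulates an off-axis mobile capture: the four image corners are displaced
#' by a random fraction of the canvas governed by `perspective_max_tilt`, the
#' raster is warped with the resulting homography (bilinear sampling, paper-
#' white padding), and the signal mask is warped with the same homography so
#' it stays registered to the trace. Degenerate corner draws are resampled.
#'
#' @inheritParams add_shadows
#' @return The warped `ecg_image`; the homography is attached as attribute
#'   `"homography"`.
#' @export
apply_perspective <- function(image, config = augment_config(),
                              seed = config$seed) {
  stop_if_not_image(image)
  d <- dim(image$pixels)
  H <- d[1]; W <- d[2]
  with_seed(seed, {
    # tilt as max corner displacement: tan(tilt) of the half-extent
    frac <- tan(config$perspective_max_tilt * pi / 180) / 2
    src <- cbind(c(1, W, W, 1), c(1, 1, H, H))
    repeat {
      dst <- src + cbind(runif(4, -frac * W, frac * W),
                         runif(4, -frac * H, frac * H))
      area <- abs(
        (dst[2, 1] - dst[1, 1]) * (dst[3, 2] - dst[1, 2]) -
          (dst[3, 1] - dst[1, 1]) * (dst[2, 2] - dst[1, 2])
      )
      if (area > 0.2 * H * W) break # reject near-collinear corner sets
    }
    hom <- homography_from_corners(src, dst)
    out <- warp_ecg_image(image, hom)
    attr(out, "homography") <- hom
    out
  })
}

# Deterministic warp of an image (and its mask) by a given homography.
warp_ecg_image <- function(image, hom) {
  px <- image$pixels
  out_px <- px
  for (c in 1:3) out_px[, , c] <- clamp(warp_matrix(px[, , c], hom, fill = 255), 0, 255)
  mask <- image$signal_mask
  out_mask <- if (!is.null(mask)) warp_matrix(mask * 1, hom, fill = 0) >= 0.5 else NULL
  new_ecg_image_like(image, out_px, signal_mask = out_mask,
                     provenance = "augmented")
}

#' Add flash saturation
#'
#' With probability `flash_probability`, adds a radial Gaussian brightness
#' field centred at a random location and clips at 255; the field's peak is
#' at least 255, so the flash centre always saturates. Never darkens a pixel.
#'
#' @inheritParams add_shadows
#' @return The `ecg_image`, with attribute `"flash_params"` (`NULL` when no
#'   flash fired).
#' @export
add_flash_saturation <- function(image, config = augment_config(),
                                 seed = config$seed) {
  stop_if_not_image(image)
  d <- dim(image$pixels)
  with_seed(seed, {
    if (runif(1) >= config$flash_probability) return(image)
    H <- d[1]; W <- d[2]
    cx <- runif(1, 0.2 * W, 0.8 * W)
    cy <- runif(1, 0.2 * H, 0.8 * H)
    amp <- runif(1, 255, 340)
    radius <- runif(1, 0.15, 0.35) * min(H, W)
    xs <- matrix(rep(seq_len(W), each = H), H, W)
    ys <- matrix(rep(seq_len(H), W), H, W)
    field <- amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * radius^2))
    px <- image$pixels
    for (c in 1:3) px[, , c] <- clamp(px[, , c] + field, 0, 255)
    out <- new_ecg_image_like(image, px, provenance = "augmented")
    attr(out, "flash_params") <- list(cx = cx, cy = cy, amp = amp,
                                      radius = radius)
    out
  })
}

#' Full photo-artifact pipeline
#'
#' Shadows, then perspective, then flash, each with a child seed derived from
#' `seed`; the output is tagged as target-domain.
#'
#' @inheritParams add_shadows
#' @return The augmented `ecg_image`.
#' @export
augment_photo <- function(image, config = augment_config(),
                          seed = config$seed) {
  seeds <- derive_seeds(seed, 3)
  out <- add_shadows(image, config, seeds[1])
  sp <- attr(out, "shadow_params")
  out <- apply_perspective(out, config, seeds[2])
  hom <- attr(out, "homography")
  out <- add_flash_saturation(out, config, seeds[3])
  attr(out, "shadow_params") <- sp
  attr(out, "homography") <- hom
  out$domain_tag <- "target"
  out
}
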