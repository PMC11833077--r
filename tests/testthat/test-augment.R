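white_image <- function(h = 60, w = 90) {
  structure(list(pixels = array(255, c(h, w, 3L)),
                 signal_mask = matrix(FALSE, h, w), mm_per_pixel = 1,
                 layout = NULL, domain_tag = "source",
                 provenance = "synthetic", record_meta = NULL),
            class = "ecg_image")
}

test_that("defaults drop four shadows, each attenuation inside [0.3, 0.7]", {
  out <- add_shadows(white_image(), augment_config(), seed = 5)
  sp <- attr(out, "shadow_params")
  expect_equal(nrow(sp), 4L)
  expect_true(all(sp$attenuation >= 0.3 & sp$attenuation <= 0.7))
  expect_lt(min(out$pixels), 255) # something actually darkened
  expect_identical(dim(out$pixels), dim(white_image()$pixels))
})

test_that("shadow attenuations follow U(0.3, 0.7): Monte-Carlo moments", {
  cfg <- augment_config()
  draws <- ecgsaliency:::with_seed(99, {
    ecgsaliency:::draw_shadow_specs(10000, cfg, 100, 100)$attenuation
  })
  expect_gte(min(draws), 0.3)
  expect_lte(max(draws), 0.7)
  expect_lt(abs(mean(draws) - 0.5), 0.01)
})

test_that("shadows never brighten; flash never darkens", {
  img <- fx_image()
  sh <- add_shadows(img, augment_config(), seed = 3)
  expect_true(all(sh$pixels <= img$pixels + 1e-9))
  fl <- add_flash_saturation(img, augment_config(flash_probability = 1),
                             seed = 3)
  expect_true(all(fl$pixels >= img$pixels - 1e-9))
})

test_that("n_shadows = 0 and flash_probability = 0 are identities", {
  img <- fx_image()
  expect_identical(add_shadows(img, augment_config(n_shadows = 0), 1)$pixels,
                   img$pixels)
  expect_identical(
    add_flash_saturation(img, augment_config(flash_probability = 0), 1)$pixels,
    img$pixels
  )
})

test_that("flash fires on every seed at probability 1 and saturates its centre", {
  img <- white_image(40, 40)
  img$pixels[] <- 120
  cfg <- augment_config(flash_probability = 1)
  altered <- vapply(1:25, function(s) {
    out <- add_flash_saturation(img, cfg, seed = s)
    p <- attr(out, "flash_params")
    centre <- out$pixels[round(p$cy), round(p$cx), ]
    expect_equal(unname(centre), rep(255, 3))
    !identical(out$pixels, img$pixels)
  }, logical(1))
  expect_true(all(altered))
})

test_that("augmentations are deterministic in (image, config, seed)", {
  img <- fx_image()
  cfg <- augment_config()
  expect_identical(add_shadows(img, cfg, 11)$pixels,
                   add_shadows(img, cfg, 11)$pixels)
  expect_identical(apply_perspective(img, cfg, 11)$pixels,
                   apply_perspective(img, cfg, 11)$pixels)
  expect_identical(augment_photo(img, cfg, 11)$pixels,
                   augment_photo(img, cfg, 11)$pixels)
  expect_false(identical(add_shadows(img, cfg, 11)$pixels,
                         add_shadows(img, cfg, 12)$pixels))
})

test_that("all augmentations preserve shape and 8-bit range", {
  img <- fx_image()
  out <- augment_photo(img, augment_config(), seed = 2)
  expect_identical(dim(out$pixels), dim(img$pixels))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  expect_identical(dim(out$signal_mask), dim(img$signal_mask))
  expect_identical(out$domain_tag, "target")
})

test_that("zero tilt yields an identity warp", {
  img <- fx_image()
  out <- apply_perspective(img, augment_config(perspective_max_tilt = 0), 4)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-9)
  expect_identical(out$signal_mask, img$signal_mask)
})

test_that("warp composed with its inverse is near-identity on the interior", {
  # smooth test pattern: resampling error is then dominated by the
  # homography round trip, not by bilinear smoothing of sharp edges
  h <- 80; w <- 120
  px <- array(0, c(h, w, 3))
  px[, , 1] <- outer(seq(0, 255, length.out = h), rep(1, w))
  px[, , 2] <- outer(rep(1, h), seq(0, 255, length.out = w))
  px[, , 3] <- 128 + 100 * outer(sin(seq(0, 6, length.out = h)),
                                 cos(seq(0, 6, length.out = w)))
  img <- structure(list(pixels = px, signal_mask = matrix(FALSE, h, w),
                        mm_per_pixel = 1, layout = NULL,
                        domain_tag = "source", provenance = "synthetic",
                        record_meta = NULL), class = "ecg_image")
  out <- apply_perspective(img, augment_config(perspective_max_tilt = 10), 8)
  hom <- attr(out, "homography")
  back <- ecgsaliency:::warp_ecg_image(out, solve(hom))
  interior_r <- 15:(h - 15)
  interior_c <- 15:(w - 15)
  mad <- mean(abs(back$pixels[interior_r, interior_c, ] -
                    img$pixels[interior_r, interior_c, ]))
  expect_lt(mad, 2)
})

test_that("the warped mask stays registered with the warped trace", {
  img <- fx_image("sinus_bradycardia", 5)
  out <- apply_perspective(img, augment_config(perspective_max_tilt = 10), 9)
  lum <- 0.299 * out$pixels[, , 1] + 0.587 * out$pixels[, , 2] +
    0.114 * out$pixels[, , 3]
  # bilinear resampling bleeds ink into neighbours: demand that nearly all
  # warped-mask pixels stay well below paper luminance
  frac_dark <- mean(lum[out$signal_mask] < 128)
  expect_gte(frac_dark, 0.95)
})
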