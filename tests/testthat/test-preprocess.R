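as_image <- function(px) {
  structure(list(pixels = px, signal_mask = NULL, mm_per_pixel = 1,
                 layout = NULL, domain_tag = "source",
                 provenance = "synthetic", record_meta = NULL),
            class = "ecg_image")
}

gray_image <- function(m) as_image(array(rep(m, 3), c(dim(m), 3L)))

# independent convolution oracle for the 4-neighbour Laplacian
laplacian_oracle <- function(lum) {
  h <- nrow(lum); w <- ncol(lum)
  out <- matrix(NA_real_, h - 2, w - 2)
  for (i in 2:(h - 1)) {
    for (j in 2:(w - 1)) {
      out[i - 1, j - 1] <- lum[i - 1, j] + lum[i + 1, j] +
        lum[i, j - 1] + lum[i, j + 1] - 4 * lum[i, j]
    }
  }
  out
}

test_that("blur gate: constant image has zero variance and is rejected", {
  rep <- blur_gate(gray_image(matrix(128, 20, 20)))
  expect_equal(rep$laplacian_variance, 0)
  expect_false(rep$accepted)
})

test_that("blur gate matches an independent convolution oracle", {
  set.seed(42)
  lum <- matrix(sample(0:255, 30 * 24, replace = TRUE), 30, 24)
  rep <- blur_gate(gray_image(lum))
  lap <- laplacian_oracle(lum)
  expect_equal(rep$laplacian_variance, mean((lap - mean(lap))^2),
               tolerance = 1e-12)
  # checkerboard: sharply in focus, far above any reasonable cutoff
  cb <- 255 * outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_true(blur_gate(gray_image(cb))$accepted)
})

test_that("blur gate boundary: variance exactly at the cutoff is accepted", {
  set.seed(7)
  lum <- matrix(runif(400, 0, 255), 20, 20)
  v <- blur_gate(gray_image(lum))$laplacian_variance
  expect_true(blur_gate(gray_image(lum), cutoff = v)$accepted)
  expect_false(blur_gate(gray_image(lum), cutoff = v + 1e-9)$accepted)
})

test_that("blur gate is invariant to channel permutation only through luminance", {
  img <- fx_image()
  rep1 <- blur_gate(img)
  gray <- gray_image(0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
                       0.114 * img$pixels[, , 3])
  expect_equal(blur_gate(gray)$laplacian_variance, rep1$laplacian_variance,
               tolerance = 1e-9)
})

test_that("degenerate single-pixel image reports zero and is rejected", {
  rep <- blur_gate(as_image(array(100, c(1, 1, 3))))
  expect_equal(rep$laplacian_variance, 0)
  expect_false(rep$accepted)
})

test_that("segmentation thresholds strictly below 10 of 256", {
  px <- array(255, c(2, 2, 3))
  px[1, 1, ] <- 9
  px[1, 2, ] <- 10
  m <- segment_signal(as_image(px))
  expect_true(m[1, 1])
  expect_false(m[1, 2])
  expect_equal(sum(segment_signal(as_image(array(255, c(4, 4, 3))))), 0)
})

test_that("segmentation recovers the renderer mask on clean images", {
  img <- fx_image("atrial_flutter", 3)
  seg <- segment_signal(img)
  recall <- sum(seg & img$signal_mask) / sum(img$signal_mask)
  expect_gte(recall, 0.99)
})

test_that("normalization standardizes channels and keeps inverse metadata", {
  img <- fx_image()
  n <- normalize_image(img)
  for (c in 1:3) {
    expect_lt(abs(mean(n[, , c])), 1e-6)
    expect_lt(abs(sd(as.vector(n[, , c])) - 1), 1e-3)
  }
  mu <- attr(n, "norm_mean")
  sdv <- attr(n, "norm_sd")
  rec <- n
  for (c in 1:3) rec[, , c] <- n[, , c] * sdv[c] + mu[c]
  expect_equal(as.vector(rec), as.vector(img$pixels), tolerance = 1e-9)
})

test_that("a constant channel normalizes to all zeros", {
  px <- array(77, c(5, 5, 3))
  n <- normalize_image(px)
  expect_true(all(n == 0))
  expect_equal(attr(n, "norm_sd"), rep(1, 3))
})
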