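test_that("a purely linear map's Jacobian equals its weight field", {
  # flatten + single dense unit: f(x) = sum(w * x), so d f / d x = w exactly
  fl <- ecgsaliency:::new_flatten()
  de <- ecgsaliency:::new_dense(4 * 4 * 3, 1)
  x <- rand_tensor(c(4, 4, 3, 1), seed = 1)
  ecgsaliency:::stack_forward(list(fl, de), x, train = FALSE)
  g <- ecgsaliency:::stack_backward(list(fl, de), matrix(1))
  expect_equal(as.vector(g), as.vector(de$W))
})

test_that("Jacobian maps match central finite differences on seeded tiny nets", {
  for (s in 1:5) {
    m <- build_model(model_config(input_size = c(16, 16),
                                  encoder_channels = c(4, 8), fc_widths = 8,
                                  dropout_rate = 0), seed = 100 + s)
    x <- rand_tensor(c(16, 16, 3), seed = 200 + s)
    map <- jacobian_map(m, x, "presence")
    f <- function(xx) model_forward(m, array(xx, c(16, 16, 3, 1)),
                                    train = FALSE, heads = "label")$label_prob
    set.seed(300 + s)
    idx <- sample(length(x), 30)
    num <- fd_gradient(f, x, idx)
    ana <- as.vector(map$raw)[idx]
    # central differences are only a valid oracle where the (piecewise
    # linear) activations are locally smooth: exclude elements whose
    # one-sided differences disagree, i.e. that straddle a Leaky ReLU kink
    os <- fd_one_sided(f, x, idx)
    smooth <- abs(os["fwd", ] - os["bwd", ]) <=
      1e-3 * pmax(abs(num), max(abs(ana)))
    expect_gt(mean(smooth), 0.9)
    rel <- abs(num - ana) / pmax(abs(num), 1e-6)
    expect_lt(max(rel[smooth]), 1e-3)
  }
})

test_that("absence maps are the exact negation of presence maps", {
  m <- fx_tiny_model(seed = 21)
  x <- rand_tensor(c(16, 16, 3), seed = 22)
  pres <- jacobian_map(m, x, "presence")
  abs_ <- jacobian_map(m, x, "absence")
  expect_identical(abs_$raw, -pres$raw)
  expect_identical(abs_$label_prob, pres$label_prob)
})

test_that("saliency respects normalization metadata (pixel-unit chain rule)", {
  m <- fx_tiny_model(seed = 23)
  px <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  xn <- normalize_image(px)
  map_n <- jacobian_map(m, array(as.numeric(xn), dim(xn)))  # no metadata
  map_px <- jacobian_map(m, xn)                             # with metadata
  sdv <- attr(xn, "norm_sd")
  for (c in 1:3) {
    expect_equal(map_px$raw[, , c], map_n$raw[, , c] / sdv[c],
                 tolerance = 1e-12)
  }
})

test_that("channel aggregation and 0-255 scaling follow their contracts", {
  raw <- array(0, c(3, 3, 3))
  raw[2, 2, ] <- c(-4, 2, 1)
  map <- structure(list(raw = raw, target = "presence", label_prob = 0.5),
                   class = "saliency_map")
  agg <- aggregate_and_scale(map)
  expect_equal(agg$magnitude[2, 2], 4) # max-abs over the channel triplet
  expect_equal(agg$scaled[2, 2], 255L) # single nonzero -> 255, rest 0
  expect_equal(sum(agg$scaled), 255L)
  # min-max scaling is invariant to a global factor
  map10 <- map
  map10$raw <- raw * 10
  expect_identical(aggregate_and_scale(map10)$scaled, agg$scaled)
  # all-zero raw scales to all zeros
  map0 <- map
  map0$raw <- raw * 0
  expect_true(all(aggregate_and_scale(map0)$scaled == 0L))
  # l2 aggregation exposed as an alternative
  expect_equal(aggregate_and_scale(map, "l2")$magnitude[2, 2], sqrt(21))
})

test_that("binarization is strict at the cutoff and counts a full ramp", {
  mk <- function(scaled) {
    structure(list(raw = array(0, c(dim(scaled), 3)), scaled = scaled,
                   target = "presence", label_prob = 0.5),
              class = "saliency_map")
  }
  b <- binarize_saliency(mk(matrix(c(20L, 21L), 1, 2)))
  expect_false(b[1, 1])
  expect_true(b[1, 2])
  ramp <- matrix(0:255, 16, 16)
  expect_equal(sum(binarize_saliency(mk(ramp))), 235L)
  expect_equal(sum(binarize_saliency(mk(matrix(0L, 4, 4)))), 0L)
})

test_that("overlay blends only masked pixels and honours alpha = 1", {
  img <- fx_image()
  d <- dim(img$pixels)
  empty <- matrix(FALSE, d[1], d[2])
  expect_identical(overlay_mask(img, empty)$pixels, img$pixels)
  full <- matrix(TRUE, d[1], d[2])
  solid <- overlay_mask(img, full, color = c(128, 0, 128), alpha = 1)
  expect_true(all(solid$pixels[, , 1] == 128))
  expect_true(all(solid$pixels[, , 2] == 0))
  some <- rand_mask(d[1], d[2], seed = 1)
  out <- overlay_mask(img, some, alpha = 0.5)
  for (c in 1:3) {
    expect_identical(out$pixels[, , c][!some], img$pixels[, , c][!some])
  }
  expect_error(overlay_mask(img, matrix(TRUE, 2, 2)), "match")
})

test_that("explain_image skips blurred inputs with the gate report", {
  m <- build_model(model_config(input_size = c(48, 128)), seed = 1)
  flat <- structure(list(pixels = array(200, c(48, 128, 3)),
                         signal_mask = NULL, mm_per_pixel = 1, layout = NULL,
                         domain_tag = "source", provenance = "synthetic",
                         record_meta = NULL),
                    class = "ecg_image")
  res <- explain_image(m, flat)
  expect_true(res$skipped)
  expect_match(res$reason, "too blurry")
  sharp <- fx_image()
  res2 <- explain_image(m, sharp, condition_id = "normal")
  expect_false(res2$skipped)
  expect_identical(dim(res2$mask), c(48L, 128L))
  expect_s3_class(res2$map, "saliency_map")
  expect_true(res2$elapsed_s < 10) # single backward pass, CPU-friendly
})
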