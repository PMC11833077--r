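test_that("binary cross-entropy matches hand-computed values", {
  expect_lt(bce_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(bce_loss(0, 0.5), -log(0.5), tolerance = 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.1)), -log(0.9), tolerance = 1e-6)
  expect_equal(round(bce_loss(c(1, 0), c(0.9, 0.1)), 5), 0.10536)
  expect_error(bce_loss(c(1, 0), 0.5), "mismatch")
})

test_that("MSE loss matches hand-computed values and rejects shape mismatch", {
  m <- matrix(runif(12), 3, 4)
  expect_equal(mse_loss(m, m), 0)
  expect_equal(mse_loss(matrix(0, 1, 1), matrix(1, 1, 1)), 1)
  expect_equal(mse_loss(matrix(0, 2, 2), matrix(2, 2, 2)), 4)
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "mismatch")
})

test_that("composite loss applies the 60 / 2 / 0.2 weights", {
  expect_equal(total_loss(1, 0, 0), 60)
  expect_equal(total_loss(0, 1, 0), 2)
  expect_equal(total_loss(0, 0, 1), 0.2)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(1, 1, 1), 62.2)
})

test_that("lambda schedule starts at 0.85 and grows exponentially to ~208", {
  expect_equal(lambda_schedule(0, 0, 10, 10), 0.85)
  expect_equal(lambda_schedule(0, 10, 10, 10), 0.85 * exp(5.5),
               tolerance = 1e-12) # ~ 208 at p = 1
  lams <- vapply(0:9, function(b) lambda_schedule(b, 3, 10, 10), numeric(1))
  expect_true(all(diff(lams) > 0))
  expect_error(lambda_schedule(0, 0, 0, 10), "positive")
})

test_that("dataset splitting reproduces the published 85/15 counts", {
  spl <- split_dataset(seq_len(11316), 0.85, seed = 1)
  expect_equal(sum(spl$subset != "holdout"), 9619)
  expect_equal(sum(spl$subset == "holdout"), 1697)
})

test_that("splits partition the ids for any size", {
  for (n in c(10, 100, 997)) {
    spl <- split_dataset(seq_len(n), seed = 3)
    expect_equal(nrow(spl), n)
    expect_equal(sort(spl$id), seq_len(n))
    expect_equal(sum(spl$subset != "holdout"), round(n * 0.85))
  }
  expect_error(split_dataset(1:10, dev_fraction = 1.2), "between 0 and 1")
  expect_error(split_dataset(integer(0)), "nonempty")
})

test_that("checkpoint rule requires all three conditions", {
  h <- tibble::tibble(label_metric = c(0.8, 0.9),
                      decoder_loss = c(0.5, 0.4),
                      dc_accuracy = c(0.9, 0.5))
  expect_equal(checkpoint_rule(h), "save")
  h$dc_accuracy[2] <- 0.9
  expect_equal(checkpoint_rule(h), "skip")
  h$dc_accuracy[2] <- 0.5
  h$decoder_loss[2] <- 0.6 # decoder worse than best
  expect_equal(checkpoint_rule(h), "skip")
  h$decoder_loss[2] <- 0.4
  h$label_metric[2] <- 0.7 # label worse than best
  expect_equal(checkpoint_rule(h), "skip")
})

test_that("early stopping halts after 5 overfitting epochs and resets on improvement", {
  overfit <- tibble::tibble(train_loss = seq(1, 0.4, by = -0.1),
                            test_metric = c(0.9, rep(0.85, 6)))
  expect_equal(early_stop(overfit), "halt")
  # 4 non-improving then 1 improving -> continue
  reset <- tibble::tibble(train_loss = seq(1, 0.5, by = -0.1),
                          test_metric = c(0.8, 0.7, 0.7, 0.7, 0.7, 0.95))
  expect_equal(early_stop(reset), "continue")
  improving <- tibble::tibble(train_loss = seq(1, 0.3, by = -0.1),
                              test_metric = seq(0.5, 0.85, by = 0.05))
  expect_equal(early_stop(improving), "continue")
})

test_that("an epoch of batch size 25 over 100 records has 4 batches", {
  batches <- ecgsaliency:::with_seed(1, {
    ecgsaliency:::epoch_batches(100, 0, 25, mixed = FALSE)
  })
  expect_length(batches, 4)
  expect_equal(sort(unname(unlist(batches))), 1:100)
})

test_that("target-domain samples contribute zero gradient to the label head", {
  m <- fx_tiny_model(seed = 11)
  x <- rand_tensor(c(16, 16, 3, 4), seed = 12)
  out <- model_forward(m, x, train = FALSE)
  # only the first two (source) rows carry label gradient
  d_label <- c(0.3, -0.2, 0, 0)
  model_backward(m, out, d_label = d_label)
  dense <- Filter(function(l) l$type == "dense", m$label_head)[[1]]
  dW_full <- dense$dW
  out2 <- model_forward(m, x[, , , 1:2, drop = FALSE], train = FALSE)
  model_backward(m, out2, d_label = d_label[1:2])
  expect_equal(dW_full, dense$dW, tolerance = 1e-12)
})

test_that("phase-1 training reduces reconstruction loss on a tiny corpus", {
  src <- make_image_dataset(c("sinus_bradycardia", "sinus_tachycardia"), 12,
                            "sinus_tachycardia", input_size = c(24, 64),
                            seed = 301)
  m <- build_model(model_config(input_size = c(24, 64),
                                encoder_channels = c(6, 12),
                                fc_widths = 16), seed = 1)
  cfg <- training_config(learning_rate = 1e-3, batch_size = 6, seed = 1)
  h <- run_phase(m, 1, src, config = cfg, epochs = 4)
  expect_lt(h$recon_loss[4], h$recon_loss[1])
})

test_that("phase 3 rejects an empty target-domain dataset", {
  src <- make_image_dataset("normal", 2, "normal", input_size = c(24, 64),
                            seed = 5)
  m <- build_model(model_config(input_size = c(24, 64),
                                encoder_channels = c(6, 12),
                                fc_widths = 16), seed = 1)
  expect_error(run_phase(m, 3, src, target = NULL), "target-domain")
})
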