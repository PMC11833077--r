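test_that("agreement coefficient: identity, complement, and a hand count", {
  m <- rand_mask(8, 8, seed = 1)
  expect_equal(agreement_coefficient(m, m), 1)
  expect_equal(agreement_coefficient(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2)),
               0)
  a <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2, byrow = TRUE)
  b <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2, byrow = TRUE)
  expect_equal(agreement_coefficient(a, b), 0.75) # one disagreeing pixel of 4
  expect_error(agreement_coefficient(a, matrix(TRUE, 3, 3)), "mismatch")
})

test_that("agreement coefficient obeys symmetry, complement law and bounds", {
  for (k in 1:100) {
    a <- rand_mask(6, 7, seed = k, p = runif(1))
    b <- rand_mask(6, 7, seed = 1000 + k, p = runif(1))
    ab <- agreement_coefficient(a, b)
    expect_identical(ab, agreement_coefficient(b, a))
    expect_equal(ab + agreement_coefficient(a, !b), 1)
    expect_gte(ab, 0)
    expect_lte(ab, 1)
  }
})

test_that("colocalization calls follow the 90% rule strictly", {
  base <- matrix(FALSE, 10, 10)
  sal <- base; sal[1, 1:10] <- TRUE
  rel_all <- base; rel_all[1, ] <- TRUE
  # saliency entirely inside the clinical features -> TP
  r <- colocalization_confusion(sal, rel_all)
  expect_true(r$tp); expect_false(r$fp)
  # overlap 0.89 < 0.90 -> FP (strict application)
  sal100 <- matrix(FALSE, 10, 10); sal100[] <- TRUE
  rel89 <- matrix(FALSE, 10, 10); rel89[seq_len(89)] <- TRUE
  r2 <- colocalization_confusion(sal100, rel89)
  expect_equal(r2$relevant_fraction, 0.89)
  expect_false(r2$tp); expect_true(r2$fp)
  # overlap exactly 0.90 -> TP
  rel90 <- matrix(FALSE, 10, 10); rel90[seq_len(90)] <- TRUE
  expect_true(colocalization_confusion(sal100, rel90)$tp)
  # saliency entirely on irrelevant features -> FN (fraction 1 >= 0.10)
  irr <- rel_all
  r3 <- colocalization_confusion(sal, base, irrelevant_mask = irr)
  expect_true(r3$fn); expect_false(r3$tn)
  # saliency avoiding irrelevant features -> TN
  r4 <- colocalization_confusion(sal, rel_all, irrelevant_mask = !rel_all)
  expect_true(r4$tn); expect_false(r4$fn)
  # empty saliency -> abstention
  r5 <- colocalization_confusion(base, rel_all)
  expect_true(r5$abstained)
  expect_true(is.na(r5$tp))
})

test_that("the prospective protocol scores images and summarizes by condition", {
  m <- build_model(model_config(input_size = c(48, 128)), seed = 2)
  imgs <- list(fx_image("sinus_bradycardia", 31),
               fx_image("sinus_bradycardia", 32),
               fx_image("sinus_tachycardia", 33))
  size <- m$config$input_size
  anns <- lapply(imgs, function(im) {
    ecgsaliency:::resize_mask_area(im$signal_mask, size[1], size[2])
  })
  rep <- prospective_protocol(imgs, anns, m)
  expect_s3_class(rep, "agreement_report")
  expect_equal(nrow(rep$per_image), 3)
  expect_true(all(rep$per_image$coefficient >= 0 &
                    rep$per_image$coefficient <= 1))
  # the condition mean lies within the per-image range
  for (cond in unique(rep$per_image$condition)) {
    ci <- rep$per_image$coefficient[rep$per_image$condition == cond]
    mc <- rep$per_condition$mean_c[rep$per_condition$condition == cond]
    expect_gte(mc, min(ci)); expect_lte(mc, max(ci))
  }
  # a missing annotation is skipped with a warning, not an error
  expect_warning(
    rep2 <- prospective_protocol(imgs[1:2], list(anns[[1]], NULL), m),
    "no annotation"
  )
  expect_equal(nrow(rep2$per_image), 1)
  # tidy/glance accessors
  expect_identical(tidy(rep), rep$per_image)
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("annotation identical to the algorithm mask gives C = 1; all-false gives 1 - f", {
  m <- build_model(model_config(input_size = c(48, 128)), seed = 3)
  img <- fx_image("pvc", 41)
  ex <- explain_image(m, img)
  expect_equal(agreement_coefficient(ex$mask, ex$mask), 1)
  f <- mean(ex$mask)
  allf <- matrix(FALSE, nrow(ex$mask), ncol(ex$mask))
  expect_equal(agreement_coefficient(allf, ex$mask), 1 - f)
})
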