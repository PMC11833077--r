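# End-to-end smoke run shared by the acceptance tests: the desk-scale
# bradycardia-vs-tachycardia transfer task (200 source records, 100
# photo-augmented target records, 48 x 128 input, phases 1-2; phase 3 on
# request). Returns the trained model, the held-out source set, the mixed
# test set, and per-phase histories. Configuration is fixed; `seed` drives
# data, weights, and batching.
smoke_run <- function(seed, phase3 = FALSE, n_source = 200, n_target = 100,
                      epochs1 = 16, epochs2 = 16, epochs3 = 12) {
  conds <- c("sinus_bradycardia", "sinus_tachycardia")
  input_size <- c(48L, 128L)
  src <- make_image_dataset(conds, n_source, "sinus_tachycardia",
                            input_size = input_size, seed = 1000 + seed)
  tgt <- make_image_dataset(conds, n_target, "sinus_tachycardia",
                            input_size = input_size, domain = "target",
                            seed = 2000 + seed)
  spl <- split_dataset(seq_len(nrow(src)), seed = seed)
  train <- src[spl$subset != "holdout", ]
  holdout <- src[spl$subset == "holdout", ]
  mixed <- rbind(holdout, tgt[seq_len(nrow(holdout)), ])
  model <- build_model(model_config(input_size = input_size,
                                    dropout_rate = 0), seed = seed)
  config <- training_config(learning_rate = 1e-3, seed = seed)
  total <- epochs2 + epochs3
  h1 <- run_phase(model, 1, train, config = config, epochs = epochs1)
  h2 <- run_phase(model, 2, train, tgt, config = config, epochs = epochs2,
                  epoch_offset = 0, total_epochs = total,
                  early_stopping = FALSE)
  h3 <- NULL
  if (phase3) {
    # restart the domain head so the adversarial game resumes unsaturated
    ecgsaliency:::with_seed(seed + 300L, {
      model$domain_head <- ecgsaliency:::build_head(
        model$feat_dim, model$config$fc_widths, model$config$leaky_slope
      )
    })
    h3 <- run_phase(model, 3, train, tgt, config = config, epochs = epochs3,
                    test_source = holdout, test_mixed = mixed,
                    epoch_offset = epochs2, total_epochs = total,
                    early_stopping = FALSE)
  }
  list(model = model, train = train, target = tgt, holdout = holdout,
       mixed = mixed, h1 = h1, h2 = h2, h3 = h3, config = config)
}

holdout_accuracy <- function(run) {
  ecgsaliency:::eval_label_accuracy(run$model, run$holdout)
}

# lift of binarized saliency on renderer signal pixels over the base rate
saliency_enrichment <- function(run, cutoff = 20) {
  vapply(seq_len(nrow(run$holdout)), function(i) {
    map <- aggregate_and_scale(jacobian_map(run$model, run$holdout$x[[i]]))
    bm <- binarize_saliency(map, cutoff)
    msk <- run$holdout$mask[[i]]
    if (sum(bm) == 0) return(NA_real_)
    (sum(bm & msk) / sum(bm)) / mean(msk)
  }, numeric(1))
}

smoke_cache <- new.env()

cached_smoke <- function(seed, phase3 = FALSE, epochs3 = 12) {
  key <- paste0("s", seed)
  if (is.null(smoke_cache[[key]])) {
    smoke_cache[[key]] <- smoke_run(seed)
  }
  base <- smoke_cache[[key]]
  if (!phase3) return(base)
  p3key <- paste0(key, "_p3")
  if (is.null(smoke_cache[[p3key]])) {
    # continue phase 3 on a cloned model so the cached phase-2 state stays
    # untouched for the other tests
    model <- build_model(base$model$config, seed = seed)
    restore_model_state(model, model_state(base$model))
    ecgsaliency:::with_seed(seed + 300L, {
      model$domain_head <- ecgsaliency:::build_head(
        model$feat_dim, model$config$fc_widths, model$config$leaky_slope
      )
    })
    train <- base$train
    h3 <- run_phase(model, 3, base$train, base$target, config = base$config,
                    epochs = epochs3, test_source = base$holdout,
                    test_mixed = base$mixed, epoch_offset = 16,
                    total_epochs = 16 + epochs3, early_stopping = FALSE)
    out <- base
    out$model <- model
    out$h3 <- h3
    smoke_cache[[p3key]] <- out
  }
  smoke_cache[[p3key]]
}
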