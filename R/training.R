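#' Binary cross-entropy loss
#'
#' Standard BCE, `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with
#' predictions clamped to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param y True labels in `{0, 1}` (values in `[0,1]` are accepted).
#' @param p Predicted probabilities, same length as `y`.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(y, p) {
  if (length(y) != length(p)) {
    abort(sprintf("Length mismatch: %d labels vs %d predictions.",
                  length(y), length(p)))
  }
  p <- clamp(p, 1e-7, 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Mean squared error between two rasters
#'
#' `(1 / (H * W)) * sum((I - Ihat)^2)` over all pixel positions.
#'
#' @param original,reconstruction Numeric arrays of identical shape.
#' @return Nonnegative scalar loss.
#' @export
mse_loss <- function(original, reconstruction) {
  if (!identical(dim(original), dim(reconstruction)) &&
      !(is.null(dim(original)) && is.null(dim(reconstruction)) &&
          length(original) == length(reconstruction))) {
    abort(sprintf(
      "Shape mismatch: %s vs %s.",
      paste(dim(original), collapse = "x"),
      paste(dim(reconstruction), collapse = "x")
    ))
  }
  mean((original - reconstruction)^2)
}

#' Composite training loss
#'
#' Fixed-weight sum `60 * reconstruction + 2 * label + 0.2 * domain`.
#'
#' @param recon_loss,label_loss,domain_loss Component losses (>= 0).
#' @param weights Named or positional weights (reconstruction, label,
#'   domain); defaults are the published 60 / 2 / 0.2.
#' @return Scalar total loss.
#' @export
total_loss <- function(recon_loss, label_loss, domain_loss,
                       weights = c(recon = 60, label = 2, domain = 0.2)) {
  weights[[1]] * recon_loss + weights[[2]] * label_loss +
    weights[[3]] * domain_loss
}

#' Dynamic gradient-reversal weight
#'
#' `lambda = base * exp(rate * p)` with training progress
#' `p = (b + E * N_batches) / (N_batches * N_epochs)`, so `lambda` sweeps
#' from `base` (0.85) on the first batch towards `base * exp(rate)` (about
#' 208) at the end of the run: domain adaptation is easy relative to the
#' diagnostic task, and the reversal pressure ramps up as training advances.
#'
#' @param batch_index Batch index within the epoch, 0-based.
#' @param epoch_index Epoch index, 0-based.
#' @param n_batches Batches per epoch (> 0).
#' @param n_epochs Total planned epochs (> 0).
#' @param base,rate Schedule constants (defaults 0.85 and 5.5).
#' @return Scalar `lambda`.
#' @export
lambda_schedule <- function(batch_index, epoch_index, n_batches, n_epochs,
                            base = 0.85, rate = 5.5) {
  if (n_batches <= 0 || n_epochs <= 0) {
    abort("`n_batches` and `n_epochs` must be positive.")
  }
  p <- (batch_index + epoch_index * n_batches) / (n_batches * n_epochs)
  base * exp(rate * p)
}

#' Split record ids into development / holdout and train / validation
#'
#' Ids are shuffled under `seed`; the development set takes
#' `round(n * dev_fraction)` ids and the holdout the complement. Within
#' development, `round(n_dev * train_fraction)` ids become training and the
#' rest internal validation. Round-to-nearest reproduces an 11,316-record
#' corpus splitting into 9,619 development and 1,697 holdout at 85%.
#'
#' @param ids Vector of record identifiers.
#' @param dev_fraction Development fraction (default 0.85).
#' @param train_fraction Training fraction of the development set (0.94).
#' @param seed Shuffle seed.
#' @return A tibble with `id` and `subset`
#'   (`"train"`, `"validation"`, `"holdout"`).
#' @export
split_dataset <- function(ids, dev_fraction = 0.85, train_fraction = 0.94,
                          seed = 1L) {
  if (!length(ids)) abort("`ids` must be nonempty.")
  if (dev_fraction <= 0 || dev_fraction >= 1) {
    abort("`dev_fraction` must lie strictly between 0 and 1.")
  }
  n <- length(ids)
  n_dev <- round(n * dev_fraction)
  with_seed(seed, {
    shuffled <- sample(ids, n)
    dev <- shuffled[seq_len(n_dev)]
    hold <- shuffled[setdiff(seq_len(n), seq_len(n_dev))]
    n_train <- round(length(dev) * train_fraction)
    tibble(
      id = c(dev, hold),
      subset = c(rep("train", n_train),
                 rep("validation", length(dev) - n_train),
                 rep("holdout", length(hold)))
    )
  })
}

#' Training configuration
#'
#' Defaults encode the published recipe: Adam with learning rate 4e-5 and
#' betas 0.9 / 0.999, batch size 25, composite-loss weights 60 / 2 / 0.2,
#' gradient-reversal schedule 0.85 * exp(5.5 p), early-stopping patience 5,
#' a domain-classifier checkpoint window of 40-60% accuracy, and a maximum
#' of 50 epochs.
#'
#' @param learning_rate,adam_beta1,adam_beta2 Adam parameters.
#' @param batch_size Records per mini-batch.
#' @param loss_weights Composite-loss weights (reconstruction, label, domain).
#' @param lambda_base,lambda_rate Gradient-reversal schedule constants.
#' @param early_stop_patience Consecutive non-improving epochs before halting.
#' @param max_epochs Cap on epochs per phase.
#' @param dc_accuracy_window Domain-classifier accuracy band required for a
#'   checkpoint.
#' @param adversarial_floor Floor on the magnitude of the domain
#'   classifier's logit-level gradient (default 0.02): a saturated domain
#'   classifier would otherwise emit a vanishing gradient and stall the
#'   gradient-reversal game.
#' @param input_noise_sd Standard deviation of Gaussian noise added to the
#'   (standardized) training inputs each batch (default 0, i.e. off);
#'   emulates sensor noise when modelling noisy capture chains.
#' @param seed Seed controlling shuffling, dropout, and weight init.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 4e-5,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            batch_size = 25L,
                            loss_weights = c(recon = 60, label = 2,
                                             domain = 0.2),
                            lambda_base = 0.85, lambda_rate = 5.5,
                            early_stop_patience = 5L,
                            max_epochs = 50L,
                            dc_accuracy_window = c(0.40, 0.60),
                            adversarial_floor = 0.02,
                            input_noise_sd = 0,
                            seed = 1L) {
  stopifnot(learning_rate > 0, batch_size > 0,
            all(dc_accuracy_window >= 0), all(dc_accuracy_window <= 1))
  structure(
    list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
         adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
         loss_weights = loss_weights, lambda_base = lambda_base,
         lambda_rate = lambda_rate,
         early_stop_patience = as.integer(early_stop_patience),
         max_epochs = as.integer(max_epochs),
         dc_accuracy_window = dc_accuracy_window,
         adversarial_floor = adversarial_floor,
         input_noise_sd = input_noise_sd, seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Checkpoint decision rule
#'
#' A checkpoint is saved after an epoch only when all three conditions hold:
#' the label metric is the best seen so far, the decoder loss is the lowest
#' seen so far, and the domain-classifier accuracy lies inside the
#' configured window (40-60% by default — near random guessing, evidence the
#' features are domain-agnostic).
#'
#' @param history Tibble with one row per completed epoch, columns
#'   `label_metric` (larger is better), `decoder_loss` (smaller is better),
#'   and `dc_accuracy`; the decision applies to the last row.
#' @param dc_window Accuracy band, default `c(0.40, 0.60)`.
#' @return `"save"` or `"skip"`.
#' @export
checkpoint_rule <- function(history, dc_window = c(0.40, 0.60)) {
  if (!nrow(history)) abort("`history` must contain the current epoch.")
  i <- nrow(history)
  best_label <- history$label_metric[i] >= max(history$label_metric[1:i])
  best_decoder <- history$decoder_loss[i] <= min(history$decoder_loss[1:i])
  dc_ok <- history$dc_accuracy[i] >= dc_window[1] &&
    history$dc_accuracy[i] <= dc_window[2]
  if (best_label && best_decoder && dc_ok) "save" else "skip"
}

#' Early-stopping rule
#'
#' Training halts when, for `patience` consecutive epochs, the training loss
#' kept decreasing while the test metric failed to improve on its best —
#' the signature of overfitting rather than noise.
#'
#' @param history Tibble with per-epoch `train_loss` and `test_metric`
#'   (larger is better).
#' @param patience Number of consecutive such epochs (default 5).
#' @return `"halt"` or `"continue"`.
#' @export
early_stop <- function(history, patience = 5L) {
  n <- nrow(history)
  if (n < patience + 1L) return("continue")
  for (i in (n - patience + 1L):n) {
    train_decreased <- history$train_loss[i] < history$train_loss[i - 1L]
    best_before <- max(history$test_metric[1:(i - 1L)])
    improved <- history$test_metric[i] > best_before
    if (!train_decreased || improved) return("continue")
  }
  "halt"
}

# -- data plumbing -----------------------------------------------------------

as_batch <- function(tensors) {
  d <- dim(tensors[[1]])
  array(unlist(tensors, use.names = FALSE), c(d, length(tensors)))
}

#' Build a ready-to-train synthetic dataset
#'
#' Synthesizes records, renders them on ECG paper, optionally pushes them
#' through the photo-artifact pipeline (target domain), resamples image and
#' masks to the network input size (area-weighted box filter), and
#' normalizes. The decoder target is the segmented signal of the *clean*
#' rendering, so the network learns to recover the trace from the corrupted
#' view.
#'
#' @param conditions Condition of each record (recycled against `n`).
#' @param n Number of records.
#' @param positive_condition Condition mapped to label 1.
#' @param input_size `c(H, W)` network input size.
#' @param domain `"source"` (clean scans) or `"target"` (photo-augmented).
#' @param seed Corpus seed; each record gets a derived child seed.
#' @param render `"direct"` (default) draws the record straight at the
#'   network input scale — the trace stays one crisp sub-threshold-dark
#'   pixel wide and the signal mask is exact; `"pooled"` renders at
#'   `mm_per_pixel` and resamples down with an area-weighted box filter,
#'   emulating a high-resolution scan shrunk to the network input (traces
#'   soften to gray, as they would for a downscaled photo).
#' @param mm_per_pixel Rendering scale for `render = "pooled"`.
#' @param augment_cfg [augment_config()] used when `domain = "target"`.
#' @return A tibble with columns `id`, `condition`, `label`, `domain`,
#'   `x` (normalized `H x W x 3` arrays), `recon` (`H x W x 1` decoder
#'   targets), `mask` (logical signal masks at input resolution).
#' @export
make_image_dataset <- function(conditions, n,
                               positive_condition,
                               input_size = c(48L, 128L),
                               domain = c("source", "target"),
                               seed = 1L, render = c("direct", "pooled"),
                               mm_per_pixel = 0.5,
                               augment_cfg = augment_config()) {
  domain <- match.arg(domain)
  render <- match.arg(render)
  conditions <- rep_len(conditions, n)
  seeds <- derive_seeds(seed, n)
  layout <- ecg_layout()
  rows_total <- layout$rows + 1L # + rhythm strip
  rows <- purrr::map(seq_len(n), function(i) {
    rec <- synthesize_record(conditions[i], duration_s = 10, seed = seeds[i])
    if (render == "direct") {
      mpp <- rows_total * layout$panel_height_mm / input_size[1]
      img <- render_ecg_image(rec, layout = layout, mm_per_pixel = mpp,
                              domain_tag = domain)
      clean_mask <- img$signal_mask
      if (domain == "target") img <- augment_photo(img, augment_cfg, seeds[i])
      img <- pad_image_to(img, input_size)
      clean_mask <- pad_matrix_to(clean_mask, input_size, FALSE)
      small <- img$pixels
      recon_t <- clean_mask * 1
      mask_small <- img$signal_mask
    } else {
      img <- render_ecg_image(rec, layout = layout,
                              mm_per_pixel = mm_per_pixel,
                              domain_tag = domain)
      clean_mask <- img$signal_mask
      if (domain == "target") img <- augment_photo(img, augment_cfg, seeds[i])
      small <- resize_pixels_area(img$pixels, input_size[1], input_size[2])
      recon_t <- pmin(
        2 * resize_matrix_area(clean_mask * 1, input_size[1], input_size[2]),
        1
      )
      mask_small <- resize_mask_area(img$signal_mask, input_size[1],
                                     input_size[2])
    }
    tibble(
      id = sprintf("%s_%s_%04d", domain, conditions[i], i),
      condition = conditions[i],
      label = as.numeric(conditions[i] == positive_condition),
      domain = ifelse(domain == "source", 0, 1),
      x = list(normalize_image(small)),
      recon = list(array(recon_t, c(input_size, 1L))),
      mask = list(mask_small)
    )
  })
  dplyr::bind_rows(rows)
}

# Pad (paper-white) or crop an image to the requested H x W.
pad_image_to <- function(image, size) {
  d <- dim(image$pixels)
  if (identical(as.integer(d[1:2]), as.integer(size))) return(image)
  px <- array(255, c(size, 3L))
  h <- min(d[1], size[1])
  w <- min(d[2], size[2])
  px[seq_len(h), seq_len(w), ] <- image$pixels[seq_len(h), seq_len(w), ]
  mask <- pad_matrix_to(image$signal_mask, size, FALSE)
  new_ecg_image_like(image, px, signal_mask = mask)
}

pad_matrix_to <- function(m, size, fill) {
  if (is.null(m)) return(NULL)
  out <- matrix(fill, size[1], size[2])
  h <- min(nrow(m), size[1])
  w <- min(ncol(m), size[2])
  out[seq_len(h), seq_len(w)] <- m[seq_len(h), seq_len(w)]
  out
}

# -- the three-phase loop ----------------------------------------------------

epoch_batches <- function(n_source, n_target, batch_size, mixed) {
  if (!mixed) {
    idx <- sample(n_source)
    split(idx, ceiling(seq_along(idx) / batch_size))
  } else {
    half <- max(1L, batch_size %/% 2L)
    s_idx <- sample(n_source)
    n_b <- ceiling(n_source / half)
    t_idx <- sample(rep_len(sample(n_target), n_b * half))
    lapply(seq_len(n_b), function(b) {
      s <- s_idx[((b - 1L) * half + 1L):min(b * half, n_source)]
      t <- t_idx[((b - 1L) * half + 1L):(b * half)]
      list(source = s, target = t)
    })
  }
}

eval_label_accuracy <- function(model, data, batch_size = 50L) {
  if (is.null(data) || !nrow(data)) return(NA_real_)
  probs <- predict_heads(model, data$x, "label", batch_size)$label
  mean((probs > 0.5) == (data$label > 0.5))
}

eval_decoder_loss <- function(model, data, batch_size = 50L) {
  if (is.null(data) || !nrow(data)) return(NA_real_)
  losses <- numeric(0)
  for (chunk in split(seq_len(nrow(data)),
                      ceiling(seq_len(nrow(data)) / batch_size))) {
    out <- model_forward(model, as_batch(data$x[chunk]), train = FALSE,
                         heads = "decoder")
    for (k in seq_along(chunk)) {
      losses <- c(losses, mse_loss(data$recon[[chunk[k]]],
                                   out$reconstruction[, , , k, drop = FALSE] |>
                                     array(dim(data$recon[[chunk[k]]]))))
    }
  }
  mean(losses)
}

eval_domain_accuracy <- function(model, data, batch_size = 50L) {
  if (is.null(data) || !nrow(data)) return(NA_real_)
  probs <- predict_heads(model, data$x, "domain", batch_size)$domain
  mean((probs > 0.5) == (data$domain > 0.5))
}

predict_heads <- function(model, xs, heads, batch_size = 50L) {
  out <- list(label = numeric(0), domain = numeric(0))
  for (chunk in split(seq_along(xs), ceiling(seq_along(xs) / batch_size))) {
    res <- model_forward(model, as_batch(xs[chunk]), train = FALSE,
                         heads = heads)
    if ("label" %in% heads) out$label <- c(out$label, res$label_prob)
    if ("domain" %in% heads) out$domain <- c(out$domain, res$domain_prob)
  }
  out
}

#' Run one phase of the three-phase training procedure
#'
#' Phase 1 trains the feature extractor and signal decoder alone on
#' source-domain images against their segmented-signal targets
#' (reconstruction loss only). Phases 2 and 3 jointly minimize the composite
#' loss on mixed half-source / half-target batches: source images propagate
#' through decoder, label predictor and domain classifier, target images
#' through the domain classifier only, with the gradient reversal weight
#' following [lambda_schedule()] each batch. Phase 3 additionally applies
#' the three-condition [checkpoint_rule()] after each epoch and keeps the
#' best passing weights.
#'
#' @param model An `ecg_net` (modified in place).
#' @param phase 1, 2 or 3.
#' @param source Source-domain dataset tibble from [make_image_dataset()].
#' @param target Target-domain tibble (required for phases 2-3).
#' @param config A [training_config()].
#' @param epochs Number of epochs for this phase (defaults: 6 for phase 1,
#'   otherwise `config$max_epochs` capped by early stopping).
#' @param test_source Source-only test set (label / decoder metrics).
#' @param test_mixed Mixed-domain test set (domain metric).
#' @param epoch_offset,total_epochs Position of this phase inside the whole
#'   adversarial run: the progress variable p of the gradient-reversal
#'   schedule is `(b + (E + epoch_offset) * N_batches) / (N_batches *
#'   total_epochs)`, so lambda keeps ramping across phases 2 and 3 instead
#'   of resetting (defaults: this phase alone spans the run).
#' @param early_stopping Apply the early-stopping rule (default TRUE).
#' @param verbose Print per-epoch metrics.
#' @return A tibble history, one row per epoch: losses per head, total loss,
#'   label / domain accuracy, the epoch-end lambda, and the checkpoint
#'   decision. The best checkpoint state (phase 3) is attached as attribute
#'   `"best_state"`.
#' @export
run_phase <- function(model, phase, source, target = NULL,
                      config = training_config(), epochs = NULL,
                      test_source = NULL, test_mixed = NULL,
                      epoch_offset = 0L, total_epochs = NULL,
                      early_stopping = TRUE, verbose = FALSE) {
  stopifnot(phase %in% 1:3)
  mixed <- phase >= 2
  if (mixed && (is.null(target) || !nrow(target))) {
    abort(sprintf("Phase %d requires a nonempty target-domain dataset.", phase))
  }
  if (is.null(epochs)) epochs <- if (phase == 1) 6L else config$max_epochs
  if (is.null(total_epochs)) total_epochs <- epoch_offset + epochs
  w <- config$loss_weights
  hist <- list()
  best_state <- NULL
  with_seed(config$seed + phase, {
    for (E in seq_len(epochs) - 1L) {
      batches <- epoch_batches(nrow(source),
                               if (mixed) nrow(target) else 0L,
                               config$batch_size, mixed)
      n_batches <- length(batches)
      ep_losses <- c(recon = 0, label = 0, domain = 0, total = 0)
      lam <- 0
      for (b in seq_len(n_batches) - 1L) {
        bt <- batches[[b + 1L]]
        nz <- config$input_noise_sd
        if (!mixed) {
          idx_s <- bt
          x <- as_batch(source$x[idx_s])
          if (nz > 0) x <- x + rnorm(length(x), 0, nz)
          n_s <- length(idx_s)
          n_all <- n_s
          out <- model_forward(model, x, train = TRUE, heads = "decoder")
          recon_t <- as_batch(source$recon[idx_s])
          diff <- out$reconstruction - recon_t
          recon_l <- mean(apply(diff^2, 4, mean))
          d_recon <- w[[1]] * 2 * diff / (prod(dim(diff)[1:2]) * n_s)
          model_backward(model, out, d_recon = d_recon)
          adam_step(c(model$encoder, model$decoder), config$learning_rate,
                    config$adam_beta1, config$adam_beta2)
          ep_losses <- ep_losses +
            c(recon_l, 0, 0, w[[1]] * recon_l) / n_batches
        } else {
          idx_s <- bt$source
          idx_t <- bt$target
          n_s <- length(idx_s)
          n_t <- length(idx_t)
          n_all <- n_s + n_t
          x <- as_batch(c(source$x[idx_s], target$x[idx_t]))
          if (nz > 0) x <- x + rnorm(length(x), 0, nz)
          y_lab <- source$label[idx_s]
          y_dom <- c(rep(0, n_s), rep(1, n_t))
          lam <- lambda_schedule(b, E + epoch_offset, n_batches, total_epochs,
                                 config$lambda_base, config$lambda_rate)
          out <- model_forward(model, x, train = TRUE)
          p_lab <- clamp(out$label_prob[seq_len(n_s)], 1e-7, 1 - 1e-7)
          p_dom <- clamp(out$domain_prob, 1e-7, 1 - 1e-7)
          recon_t <- as_batch(source$recon[idx_s])
          diff <- out$reconstruction[, , , seq_len(n_s), drop = FALSE] -
            recon_t
          recon_l <- mean(apply(diff^2, 4, mean))
          label_l <- bce_loss(y_lab, p_lab)
          domain_l <- bce_loss(y_dom, p_dom)
          # logit-level BCE gradients (p - y)/N; target rows contribute
          # nothing to the label head or decoder
          d_label <- numeric(n_all)
          d_label[seq_len(n_s)] <- w[[2]] * (p_lab - y_lab) / n_s
          # the domain gradient is floored away from zero: once the domain
          # classifier saturates its gradient would vanish and the
          # adversarial game die, so the reversal keeps a live signal
          fl <- config$adversarial_floor
          p_dom_fl <- clamp(out$domain_prob, fl, 1 - fl)
          d_domain <- w[[3]] * (p_dom_fl - y_dom) / n_all
          d_recon <- array(0, dim(out$reconstruction))
          d_recon[, , , seq_len(n_s)] <- w[[1]] * 2 * diff /
            (prod(dim(diff)[1:2]) * n_s)
          # the reversal only makes sense while the domain classifier beats
          # chance on the batch; once it is at or below chance, reversing
          # further would push it to be anti-correct (a runaway that wrecks
          # the shared features), so the encoder-side multiplier is gated.
          # The classifier's own (un-reversed) update always proceeds.
          batch_dc <- mean((out$domain_prob > 0.5) == (y_dom > 0.5))
          lam_eff <- if (batch_dc > 0.5) lam else 0
          model_backward(model, out, d_label = d_label, d_domain = d_domain,
                         d_recon = d_recon, lambda = lam_eff)
          adam_step(all_layers(model), config$learning_rate,
                    config$adam_beta1, config$adam_beta2)
          ep_losses <- ep_losses + c(
            recon_l, label_l, domain_l,
            total_loss(recon_l, label_l, domain_l, w)
          ) / n_batches
        }
      }
      row <- tibble(
        phase = phase, epoch = E + 1L,
        recon_loss = ep_losses[[1]], label_loss = ep_losses[[2]],
        domain_loss = ep_losses[[3]], train_loss = ep_losses[[4]],
        label_metric = eval_label_accuracy(model, test_source),
        decoder_loss = eval_decoder_loss(model, test_source),
        dc_accuracy = eval_domain_accuracy(model, test_mixed),
        lambda_end = lam,
        checkpoint = "skip"
      )
      hist[[length(hist) + 1L]] <- row
      hdf <- dplyr::bind_rows(hist)
      if (phase == 3 && !is.na(row$label_metric) && !is.na(row$dc_accuracy)) {
        if (checkpoint_rule(hdf, config$dc_accuracy_window) == "save") {
          best_state <- model_state(model)
          hdf$checkpoint[nrow(hdf)] <- "save"
          hist[[length(hist)]]$checkpoint <- "save"
        }
      }
      if (verbose) {
        message(sprintf(
          "phase %d epoch %d: total %.4f label_acc %.3f dc_acc %.3f",
          phase, E + 1L, row$train_loss, row$label_metric, row$dc_accuracy
        ))
      }
      if (early_stopping && !is.na(row$label_metric) &&
          nrow(hdf) > config$early_stop_patience) {
        es <- early_stop(
          dplyr::transmute(hdf, train_loss = .data$train_loss,
                           test_metric = .data$label_metric),
          config$early_stop_patience
        )
        if (es == "halt") break
      }
    }
  })
  out <- dplyr::bind_rows(hist)
  attr(out, "best_state") <- best_state
  out
}

#' Train the full pipeline on synthetic data
#'
#' Convenience wrapper running phase 1 (decoder on clean source images),
#' phase 2 (condition fine-tuning on mixed batches) and optionally phase 3
#' (domain-classifier consolidation), returning an `ecg_fit`.
#'
#' @param model An `ecg_net`.
#' @param source,target Dataset tibbles from [make_image_dataset()].
#' @param config A [training_config()].
#' @param epochs Named vector of per-phase epochs,
#'   e.g. `c(phase1 = 6, phase2 = 10, phase3 = 4)`.
#' @param test_source,test_mixed Held-out evaluation tibbles.
#' @param phases Which phases to run (default 1:3).
#' @param fresh_domain_head Re-initialize the domain classifier at the start
#'   of phase 3, so the adversarial game restarts from an unsaturated
#'   classifier while the reversal weight is already high (default TRUE).
#' @param early_stopping Apply the early-stopping rule within phases.
#' @param verbose Print progress.
#' @return An object of class `ecg_fit`: the trained model, the concatenated
#'   per-epoch history, and the configuration. Supports [generics::tidy()],
#'   [generics::glance()] and `ggplot2::autoplot()`.
#' @export
train_pipeline <- function(model, source, target, config = training_config(),
                           epochs = c(phase1 = 6L, phase2 = 10L, phase3 = 4L),
                           test_source = NULL, test_mixed = NULL,
                           phases = 1:3, fresh_domain_head = TRUE,
                           early_stopping = TRUE, verbose = FALSE) {
  history <- list()
  # lambda progress spans the adversarial phases (2 and 3) as one run
  adv_total <- sum(vapply(intersect(phases, 2:3), function(p) {
    e <- unname(epochs[paste0("phase", p)])
    if (length(e) != 1L || is.na(e)) as.numeric(config$max_epochs) else as.numeric(e)
  }, numeric(1)))
  adv_done <- 0L
  for (ph in phases) {
    ep <- unname(epochs[paste0("phase", ph)])
    if (length(ep) != 1L || is.na(ep)) ep <- NULL
    if (ph == 3 && fresh_domain_head) {
      with_seed(config$seed + 300L, {
        model$domain_head <- build_head(model$feat_dim, model$config$fc_widths,
                                        model$config$leaky_slope)
      })
    }
    h <- run_phase(model, ph, source, target, config,
                   epochs = ep,
                   test_source = test_source, test_mixed = test_mixed,
                   epoch_offset = if (ph >= 2) adv_done else 0L,
                   total_epochs = if (ph >= 2) max(adv_total, 1L) else NULL,
                   early_stopping = early_stopping, verbose = verbose)
    if (ph >= 2) adv_done <- adv_done + nrow(h)
    history[[length(history) + 1L]] <- h
    if (ph == 3 && !is.null(attr(h, "best_state"))) {
      restore_model_state(model, attr(h, "best_state"))
    }
  }
  structure(
    list(model = model, history = dplyr::bind_rows(history), config = config),
    class = "ecg_fit"
  )
}

#' @export
print.ecg_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<ecg_fit> %d epochs over phases %s; final label acc %.3f, dc acc %.3f\n",
    nrow(x$history), paste(unique(x$history$phase), collapse = ","),
    last$label_metric, last$dc_accuracy
  ))
  invisible(x)
}
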