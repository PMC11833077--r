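#' Network architecture configuration
#'
#' Describes the four-component domain-adversarial network: a convolutional
#' feature extractor (stacked convolution + batch-normalization + dropout
#' blocks with Leaky ReLU), a transposed-convolution signal decoder that
#' mirrors the extractor, and fully connected label-predictor and
#' domain-classifier heads on the flattened features, the domain head sitting
#' behind a gradient reversal layer. Layer counts and widths are tunable;
#' the defaults are sized so a single CPU can train the network on the
#' bundled synthetic task.
#'
#' @param input_size `c(H, W)` of the network input; each dimension must be
#'   divisible by `2 ^ length(encoder_channels)`.
#' @param in_channels Number of input channels (3 for RGB rasters).
#' @param encoder_channels Output channels of successive encoder blocks.
#' @param kernel_size Kernel size per encoder block (recycled; even sizes
#'   only, so each stride-2 block halves the grid exactly). A larger first
#'   kernel smooths per-pixel gradients — neighbouring pixels then share
#'   most of their gradient paths — which de-speckles saliency maps.
#' @param stride Stride shared by all blocks (the decoder inverts the
#'   geometry exactly).
#' @param dilation Dilation factor of the encoder convolutions.
#' @param dropout_rate Dropout probability inside each encoder block.
#' @param batch_norm Apply batch normalization in each block.
#' @param fc_widths Hidden widths of the label/domain heads.
#' @param leaky_slope Negative-side slope of the Leaky ReLU (default 0.01).
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_size = c(48L, 128L),
                         in_channels = 3L,
                         encoder_channels = c(12L, 24L, 48L),
                         kernel_size = c(8L, 4L, 4L), stride = 2L,
                         dilation = 1L,
                         dropout_rate = 0.1,
                         batch_norm = TRUE,
                         fc_widths = 64L,
                         leaky_slope = 0.01) {
  n_blocks <- length(encoder_channels)
  if (any(input_size %% (2^n_blocks) != 0)) {
    abort(sprintf(
      "input_size (%s) must be divisible by 2^%d for %d stride-2 blocks.",
      paste(input_size, collapse = "x"), n_blocks, n_blocks
    ))
  }
  kernel_size <- rep_len(as.integer(kernel_size), n_blocks)
  if (any(kernel_size %% 2L != 0L)) {
    abort("`kernel_size` values must be even so stride-2 blocks halve exactly.")
  }
  structure(
    list(input_size = as.integer(input_size), in_channels = as.integer(in_channels),
         encoder_channels = as.integer(encoder_channels),
         kernel_size = kernel_size, stride = as.integer(stride),
         pad = (kernel_size - 2L) %/% 2L, dilation = as.integer(dilation),
         dropout_rate = dropout_rate, batch_norm = batch_norm,
         fc_widths = as.integer(fc_widths), leaky_slope = leaky_slope),
    class = "model_config"
  )
}

build_encoder <- function(config) {
  layers <- list()
  c_in <- config$in_channels
  for (i in seq_along(config$encoder_channels)) {
    c_out <- config$encoder_channels[i]
    layers <- c(layers, list(new_conv(c_in, c_out, config$kernel_size[i],
                                      config$stride, config$pad[i],
                                      config$dilation)))
    if (config$batch_norm) layers <- c(layers, list(new_bn(c_out)))
    layers <- c(layers, list(new_lrelu(config$leaky_slope)))
    if (config$dropout_rate > 0) {
      layers <- c(layers, list(new_dropout(config$dropout_rate)))
    }
    c_in <- c_out
  }
  layers
}

build_decoder <- function(config) {
  chans <- rev(config$encoder_channels)
  ks <- rev(config$kernel_size)
  ps <- rev(config$pad)
  layers <- list()
  for (i in seq_along(chans)) {
    c_in <- chans[i]
    c_out <- if (i < length(chans)) chans[i + 1] else 1L
    layers <- c(layers, list(new_tconv(c_in, c_out, ks[i],
                                       config$stride, ps[i])))
    if (i < length(chans)) {
      if (config$batch_norm) layers <- c(layers, list(new_bn(c_out)))
      layers <- c(layers, list(new_lrelu(config$leaky_slope)))
    } else {
      layers <- c(layers, list(new_sigmoid()))
    }
  }
  layers
}

# Heads emit a logit; the sigmoid is applied functionally in model_forward
# and its derivative folded into the backward seed (numerically stable
# BCE-with-logits form).
build_head <- function(feat_dim, fc_widths, leaky_slope) {
  layers <- list(new_flatten())
  d_in <- feat_dim
  for (w in fc_widths) {
    layers <- c(layers, list(new_dense(d_in, w), new_lrelu(leaky_slope)))
    d_in <- w
  }
  c(layers, list(new_dense(d_in, 1L)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Build the domain-adversarial ECG image network
#'
#' Instantiates the feature extractor, mirrored decoder, and the two
#' fully connected heads with He-initialized weights drawn under `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ecg_net` (an environment holding the layer
#'   stacks, configuration, and feature geometry).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  n_blocks <- length(config$encoder_channels)
  feat_hw <- config$input_size %/% (2L^n_blocks)
  feat_ch <- config$encoder_channels[n_blocks]
  feat_dim <- prod(feat_hw) * feat_ch
  with_seed(seed, {
    m <- new.env(parent = emptyenv())
    m$config <- config
    m$feat_hw <- feat_hw
    m$feat_ch <- feat_ch
    m$feat_dim <- feat_dim
    m$encoder <- build_encoder(config)
    m$decoder <- build_decoder(config)
    m$label_head <- build_head(feat_dim, config$fc_widths, config$leaky_slope)
    m$domain_head <- build_head(feat_dim, config$fc_widths, config$leaky_slope)
    class(m) <- "ecg_net"
    m
  })
}

#' @export
print.ecg_net <- function(x, ...) {
  cat(sprintf(
    "<ecg_net> input %s, %d encoder blocks (%s ch), feature dim %d\n",
    paste(x$config$input_size, collapse = "x"),
    length(x$config$encoder_channels),
    paste(x$config$encoder_channels, collapse = "/"), x$feat_dim
  ))
  invisible(x)
}

check_input_size <- function(model, x) {
  d <- dim(x)
  exp <- c(model$config$input_size, model$config$in_channels)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), as.integer(exp))) {
    abort(sprintf(
      "Input spatial shape mismatch: expected %s x C=%d, received %s.",
      paste(exp[1:2], collapse = "x"), exp[3],
      paste(d, collapse = "x")
    ))
  }
}

#' Forward propagation
#'
#' Runs a batch through the feature extractor and the requested heads. In
#' eval mode (`train = FALSE`) dropout is disabled and batch normalization
#' uses its running statistics, so the forward pass is a deterministic pure
#' function of the input.
#'
#' @param model An `ecg_net`.
#' @param x Input tensor, `H x W x C x N` array of normalized rasters (a
#'   single `normalized_raster` is promoted to a batch of one).
#' @param train Training mode flag.
#' @param heads Which heads to evaluate, subset of
#'   `c("label", "domain", "decoder")`.
#' @return A list with `label_prob` and `domain_prob` (length-N vectors in
#'   `[0, 1]`), `reconstruction` (`H x W x 1 x N` array), and `features`;
#'   heads not requested are `NULL`.
#' @export
model_forward <- function(model, x, train = FALSE,
                          heads = c("label", "domain", "decoder")) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  check_input_size(model, x)
  feat <- stack_forward(model$encoder, x, train)
  out <- list(features = feat, label_prob = NULL, domain_prob = NULL,
              label_logit = NULL, domain_logit = NULL,
              reconstruction = NULL)
  if ("label" %in% heads) {
    out$label_logit <- as.vector(stack_forward(model$label_head, feat, train))
    out$label_prob <- sigmoid(out$label_logit)
  }
  if ("domain" %in% heads) {
    # gradient reversal layer: identity here, sign flip during backprop
    out$domain_logit <- as.vector(
      stack_forward(model$domain_head, grl_forward(feat), train)
    )
    out$domain_prob <- sigmoid(out$domain_logit)
  }
  if ("decoder" %in% heads) {
    out$reconstruction <- stack_forward(model$decoder, feat, train)
  }
  out
}

# Reverse pass. d_label / d_domain are dLoss/dLOGIT (length N, zero entries
# for samples excluded from a head; for BCE this is (p - y)/N up to a
# weight); d_recon matches the reconstruction shape. lambda scales the
# reversed domain gradient at the GRL. Returns the gradient with respect to
# the input tensor; parameter gradients are stored in the layers.
model_backward <- function(model, out, d_label = NULL, d_domain = NULL,
                           d_recon = NULL, lambda = 1) {
  d_feat <- out$features * 0
  if (!is.null(d_label)) {
    d_feat <- d_feat + stack_backward(model$label_head,
                                      matrix(d_label, ncol = 1L))
  }
  if (!is.null(d_domain)) {
    g <- stack_backward(model$domain_head, matrix(d_domain, ncol = 1L))
    d_feat <- d_feat + grl_backward(g, lambda)
  }
  if (!is.null(d_recon)) {
    d_feat <- d_feat + stack_backward(model$decoder, d_recon)
  }
  stack_backward(model$encoder, d_feat)
}

all_layers <- function(model, heads = c("encoder", "decoder", "label_head",
                                        "domain_head")) {
  unlist(lapply(heads, function(h) model[[h]]), recursive = FALSE)
}

#' Snapshot and restore model weights
#'
#' `model_state()` deep-copies all parameters and batch-normalization
#' running statistics; `restore_model_state()` writes them back. Used by the
#' checkpoint rule and by [save_checkpoint()].
#'
#' @param model An `ecg_net`.
#' @return A nested list of numeric arrays.
#' @export
model_state <- function(model) {
  list(encoder = stack_state(model$encoder),
       decoder = stack_state(model$decoder),
       label_head = stack_state(model$label_head),
       domain_head = stack_state(model$domain_head))
}

#' @rdname model_state
#' @param state A state list from `model_state()`.
#' @export
restore_model_state <- function(model, state) {
  restore_stack_state(model$encoder, state$encoder)
  restore_stack_state(model$decoder, state$decoder)
  restore_stack_state(model$label_head, state$label_head)
  restore_stack_state(model$domain_head, state$domain_head)
  invisible(model)
}

#' Save / load a training checkpoint
#'
#' A checkpoint is a self-describing archive: weights, the `model_config`, a
#' hash of the config, and an optional training manifest (epoch, metric
#' history). Loading validates the config hash before restoring weights.
#'
#' @param model An `ecg_net`.
#' @param path File path (`.rds`).
#' @param manifest Optional list stored alongside the weights.
#' @export
save_checkpoint <- function(model, path, manifest = NULL) {
  obj <- list(config = model$config,
              config_hash = config_hash(model$config),
              state = model_state(model),
              manifest = manifest)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a rebuilt `ecg_net` with attribute
#'   `"manifest"`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(config_hash(obj$config), obj$config_hash)) {
    abort("Checkpoint config hash mismatch: file is corrupt or was edited.")
  }
  model <- build_model(obj$config, seed = 1L)
  restore_model_state(model, obj$state)
  attr(model, "manifest") <- obj$manifest
  model
}

config_hash <- function(config) {
  sum(utf8ToInt(paste(deparse(config), collapse = "")) *
        (seq_along(utf8ToInt(paste(deparse(config), collapse = ""))) %% 97 + 1))
}

#' Replace the feature extractor with another backbone
#'
#' The decoder and both heads are kept; the new encoder must produce a
#' flattened feature vector of the same width, otherwise the swap is
#' rejected naming both widths. The saliency machinery works on the swapped
#' model unmodified.
#'
#' @param model An `ecg_net`.
#' @param encoder_config A [model_config()] describing the replacement
#'   encoder (its `input_size`/`encoder_channels` determine the feature
#'   width).
#' @param seed Seed for the new encoder's weights.
#' @return The model, with its encoder replaced in place.
#' @export
swap_encoder <- function(model, encoder_config, seed = 1L) {
  n_blocks <- length(encoder_config$encoder_channels)
  feat_hw <- encoder_config$input_size %/% (2L^n_blocks)
  feat_dim <- prod(feat_hw) * encoder_config$encoder_channels[n_blocks]
  if (feat_dim != model$feat_dim) {
    abort(sprintf(
      "Feature-width mismatch: the heads expect %d features but the new encoder emits %d.",
      model$feat_dim, feat_dim
    ))
  }
  with_seed(seed, {
    model$encoder <- build_encoder(encoder_config)
  })
  model$config$input_size <- encoder_config$input_size
  model$config$encoder_channels <- encoder_config$encoder_channels
  model$feat_hw <- feat_hw
  model$feat_ch <- encoder_config$encoder_channels[n_blocks]
  invisible(model)
}
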