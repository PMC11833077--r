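# Minimal reverse-mode CNN engine on base R arrays.
#
# Tensors are H x W x C x N arrays (batch last). Convolutions are im2col /
# col2im around BLAS matrix products; every layer caches what its backward
# pass needs, and backward returns the gradient with respect to the layer
# input, so gradients propagate all the way to the image — which is exactly
# the quantity the Jacobian saliency map reads out. Correctness of the whole
# chain is pinned to central finite differences in the test suite.
#
# Layers are environments: forward/backward mutate caches and gradient slots
# in place; adam_step() updates parameters.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

he_init <- function(n_row, n_col, fan_in) {
  matrix(rnorm(n_row * n_col, 0, sqrt(2 / fan_in)), n_row, n_col)
}

# -- im2col geometry ---------------------------------------------------------

conv_out_dim <- function(n, k, stride, pad, dilation) {
  (n + 2L * pad - ((k - 1L) * dilation + 1L)) %/% stride + 1L
}

# Linear indices into the flattened padded image (Hp x Wp x C) for each
# (output position, kernel element) pair. Column order: ki fastest, then kj,
# then channel — matching the weight-matrix row layout.
build_im2col_idx <- function(H, W, C, k, stride, pad, dilation) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  out_h <- conv_out_dim(H, k, stride, pad, dilation)
  out_w <- conv_out_dim(W, k, stride, pad, dilation)
  oh <- rep(seq_len(out_h), times = out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  p_spatial <- ((oh - 1L) * stride + 1L) + ((ow - 1L) * stride) * Hp
  ki <- rep(seq_len(k), times = k * C)
  kj <- rep(rep(seq_len(k), each = k), times = C)
  ch <- rep(seq_len(C), each = k * k)
  offs <- (ki - 1L) * dilation + (kj - 1L) * dilation * Hp + (ch - 1L) * Hp * Wp
  idx <- outer(p_spatial, offs, `+`)
  storage.mode(idx) <- "integer"
  list(idx = idx, out_h = out_h, out_w = out_w, Hp = Hp, Wp = Wp)
}

pad_tensor <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# x: H x W x C x N  ->  (out_h*out_w*N) x (k*k*C), image blocks stacked with
# spatial index fastest, batch index next. The gather/scatter kernels live
# in src/conv_ops.cpp.
im2col <- function(x, geom, pad) {
  d <- dim(x)
  xp <- pad_tensor(x, pad)
  gather_patches(matrix(xp, ncol = d[4]), geom$idx)
}

# Adjoint of im2col: scatter-add columns back into the padded canvas.
col2im <- function(cols, geom, H, W, C, N, pad) {
  xp <- scatter_add_patches(cols, geom$idx, geom$Hp * geom$Wp * C)
  dim(xp) <- c(geom$Hp, geom$Wp, C, N)
  if (pad > 0L) xp <- xp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
  xp
}

mat_to_tensor <- function(m, out_h, out_w, n_ch, N) {
  mat_to_tensor_cpp(m, out_h, out_w, n_ch, N)
}

tensor_to_mat <- function(x) {
  d <- dim(x)
  tensor_to_mat_cpp(x, d[1], d[2], d[3], d[4])
}

# -- layers ------------------------------------------------------------------

new_conv <- function(c_in, c_out, k = 4L, stride = 2L, pad = 1L,
                     dilation = 1L) {
  new_layer("conv",
            c_in = c_in, c_out = c_out, k = k, stride = stride, pad = pad,
            dilation = dilation,
            W = he_init(k * k * c_in, c_out, k * k * c_in),
            b = numeric(c_out), geom = NULL, in_dim = NULL)
}

conv_forward <- function(l, x) {
  d <- dim(x)
  if (is.null(l$geom) || !identical(l$in_dim, d[1:2])) {
    l$geom <- build_im2col_idx(d[1], d[2], l$c_in, l$k, l$stride, l$pad,
                               l$dilation)
    l$in_dim <- d[1:2]
  }
  xcol <- im2col(x, l$geom, l$pad)
  y <- xcol %*% l$W
  y <- y + rep(l$b, each = nrow(y))
  l$cache <- list(xcol = xcol, N = d[4])
  mat_to_tensor(y, l$geom$out_h, l$geom$out_w, l$c_out, d[4])
}

conv_backward <- function(l, dy) {
  dym <- tensor_to_mat(dy)
  l$dW <- crossprod(l$cache$xcol, dym)
  l$db <- colSums(dym)
  dxcol <- tcrossprod(dym, l$W)
  dxp <- col2im(dxcol, l$geom, l$in_dim[1], l$in_dim[2], l$c_in,
                l$cache$N, l$pad)
  dxp
}

new_tconv <- function(c_in, c_out, k = 4L, stride = 2L, pad = 1L) {
  new_layer("tconv",
            c_in = c_in, c_out = c_out, k = k, stride = stride, pad = pad,
            W = he_init(k * k * c_out, c_in, k * k * c_in),
            b = numeric(c_out), geom = NULL, in_dim = NULL)
}

tconv_out_dim <- function(n, k, stride, pad) (n - 1L) * stride - 2L * pad + k

tconv_forward <- function(l, x) {
  d <- dim(x)
  H_out <- tconv_out_dim(d[1], l$k, l$stride, l$pad)
  W_out <- tconv_out_dim(d[2], l$k, l$stride, l$pad)
  if (is.null(l$geom) || !identical(l$in_dim, d[1:2])) {
    l$geom <- build_im2col_idx(H_out, W_out, l$c_out, l$k, l$stride, l$pad, 1L)
    stopifnot(nrow(l$geom$idx) == d[1] * d[2])
    l$in_dim <- d[1:2]
    l$out_dim <- c(H_out, W_out)
  }
  xm <- tensor_to_mat(x)
  zcol <- tcrossprod(xm, l$W)
  y <- col2im(zcol, l$geom, H_out, W_out, l$c_out, d[4], l$pad)
  for (c in seq_len(l$c_out)) y[, , c, ] <- y[, , c, ] + l$b[c]
  l$cache <- list(xm = xm, N = d[4])
  y
}

tconv_backward <- function(l, dy) {
  dycol <- im2col(dy, l$geom, l$pad)
  l$dW <- crossprod(dycol, l$cache$xm)
  l$db <- apply(dy, 3, sum)
  dxm <- dycol %*% l$W
  mat_to_tensor(dxm, l$in_dim[1], l$in_dim[2], l$c_in, l$cache$N)
}

new_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", C = C, momentum = momentum, eps = eps,
            gamma = rep(1, C), beta = rep(0, C),
            run_mean = rep(0, C), run_var = rep(1, C))
}

bn_forward <- function(l, x, train) {
  d <- dim(x)
  xm <- tensor_to_mat(x)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
  } else {
    mu <- l$run_mean
    v <- l$run_var
  }
  invstd <- 1 / sqrt(v + l$eps)
  M <- nrow(xm)
  xhat <- (xm - rep(mu, each = M)) * rep(invstd, each = M)
  y <- xhat * rep(l$gamma, each = M) + rep(l$beta, each = M)
  l$cache <- list(xhat = xhat, invstd = invstd, train = train, d = d)
  mat_to_tensor(y, d[1], d[2], d[3], d[4])
}

bn_backward <- function(l, dy) {
  d <- l$cache$d
  dym <- tensor_to_mat(dy)
  xhat <- l$cache$xhat
  l$dgamma <- colSums(dym * xhat)
  l$dbeta <- colSums(dym)
  M <- nrow(dym)
  scale <- rep(l$gamma * l$cache$invstd, each = M)
  if (l$cache$train) {
    t1 <- dym - rep(colMeans(dym), each = M)
    t2 <- xhat * rep(colMeans(dym * xhat), each = M)
    dxm <- (t1 - t2) * scale
  } else {
    dxm <- dym * scale
  }
  mat_to_tensor(dxm, d[1], d[2], d[3], d[4])
}

new_lrelu <- function(slope = 0.01) new_layer("lrelu", slope = slope)

lrelu_forward <- function(l, x) {
  neg <- x < 0
  l$cache <- neg
  x[neg] <- x[neg] * l$slope
  x
}

lrelu_backward <- function(l, dy) {
  dy[l$cache] <- dy[l$cache] * l$slope
  dy
}

new_dropout <- function(rate) new_layer("dropout", rate = rate)

dropout_forward <- function(l, x, train) {
  if (!train || l$rate <= 0) {
    l$cache <- NULL
    return(x)
  }
  keep <- 1 - l$rate
  m <- (array(runif(length(x)), dim(x)) < keep) / keep
  l$cache <- m
  x * m
}

dropout_backward <- function(l, dy) {
  if (is.null(l$cache)) dy else dy * l$cache
}

new_dense <- function(d_in, d_out) {
  new_layer("dense", d_in = d_in, d_out = d_out,
            W = he_init(d_in, d_out, d_in), b = numeric(d_out))
}

dense_forward <- function(l, x) {
  l$cache <- x
  y <- x %*% l$W
  y + rep(l$b, each = nrow(y))
}

dense_backward <- function(l, dy) {
  l$dW <- crossprod(l$cache, dy)
  l$db <- colSums(dy)
  tcrossprod(dy, l$W)
}

new_sigmoid <- function() new_layer("sigmoid")

sigmoid_forward <- function(l, x) {
  y <- 1 / (1 + exp(-x))
  l$cache <- y
  y
}

sigmoid_backward <- function(l, dy) dy * l$cache * (1 - l$cache)

new_flatten <- function() new_layer("flatten")

flatten_forward <- function(l, x) {
  d <- dim(x)
  l$cache <- d
  t(matrix(x, prod(d[1:3]), d[4]))
}

flatten_backward <- function(l, dy) {
  d <- l$cache
  array(t(dy), d)
}

layer_forward <- function(l, x, train) {
  switch(l$type,
    conv = conv_forward(l, x),
    tconv = tconv_forward(l, x),
    bn = bn_forward(l, x, train),
    lrelu = lrelu_forward(l, x),
    dropout = dropout_forward(l, x, train),
    dense = dense_forward(l, x),
    sigmoid = sigmoid_forward(l, x),
    flatten = flatten_forward(l, x)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = conv_backward(l, dy),
    tconv = tconv_backward(l, dy),
    bn = bn_backward(l, dy),
    lrelu = lrelu_backward(l, dy),
    dropout = dropout_backward(l, dy),
    dense = dense_backward(l, dy),
    sigmoid = sigmoid_backward(l, dy),
    flatten = flatten_backward(l, dy)
  )
}

stack_forward <- function(layers, x, train) {
  for (l in layers) x <- layer_forward(l, x, train)
  x
}

stack_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

#' Gradient reversal
#'
#' The gradient reversal layer is the identity on the forward pass; during
#' backpropagation it multiplies the upstream gradient by `-lambda`, so the
#' feature extractor is trained to *hurt* the domain classifier, driving the
#' features domain-agnostic.
#'
#' @param x Forward input (returned unchanged).
#' @param lambda Nonnegative reversal strength.
#' @return `grl_forward()`: `x`. `grl_backward()`: `-lambda * grad`.
#' @export
grl_forward <- function(x, lambda = 1) {
  if (lambda < 0) abort("`lambda` must be >= 0.")
  x
}

#' @rdname grl_forward
#' @param grad Upstream gradient arriving at the layer during backprop.
#' @export
grl_backward <- function(grad, lambda = 1) {
  if (lambda < 0) abort("`lambda` must be >= 0.")
  -lambda * grad
}

# -- Adam --------------------------------------------------------------------

layer_params <- function(l) {
  switch(l$type,
    conv = ,
    tconv = ,
    dense = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0)
  )
}

param_grad_name <- function(p) {
  c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")[[p]]
}

adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    ps <- layer_params(l)
    if (!length(ps)) next
    l$t <- (if (is.null(l$t)) 0L else l$t) + 1L
    for (p in ps) {
      g <- get(param_grad_name(p), envir = l)
      mkey <- paste0("m_", p)
      vkey <- paste0("v_", p)
      m <- if (is.null(l[[mkey]])) g * 0 else l[[mkey]]
      v <- if (is.null(l[[vkey]])) g * 0 else l[[vkey]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      assign(mkey, m, envir = l)
      assign(vkey, v, envir = l)
      mhat <- m / (1 - beta1^l$t)
      vhat <- v / (1 - beta2^l$t)
      assign(p, get(p, envir = l) - lr * mhat / (sqrt(vhat) + eps), envir = l)
    }
  }
}

# Deep-copy parameters and normalisation state out of / into a layer stack.
stack_state <- function(layers) {
  lapply(layers, function(l) {
    keep <- c(layer_params(l), if (l$type == "bn") c("run_mean", "run_var"))
    stats::setNames(lapply(keep, function(p) get(p, envir = l)), keep)
  })
}

restore_stack_state <- function(layers, state) {
  for (i in seq_along(layers)) {
    for (p in names(state[[i]])) assign(p, state[[i]][[p]], envir = layers[[i]])
  }
  invisible(layers)
}
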