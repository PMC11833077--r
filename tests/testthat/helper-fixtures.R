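# Shared fixtures, built once per test run.

fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fx_record <- function(condition = "normal", seed = 1) {
  fixture(paste0("rec_", condition, "_", seed),
          function() synthesize_record(condition, 10, seed = seed))
}

fx_image <- function(condition = "normal", seed = 1) {
  fixture(paste0("img_", condition, "_", seed),
          function() render_ecg_image(fx_record(condition, seed)))
}

# tiny network for gradient tests: no dropout so eval == train determinism
fx_tiny_model <- function(seed = 1) {
  fixture(paste0("tiny_", seed), function() {
    build_model(model_config(input_size = c(16L, 16L),
                             encoder_channels = c(4L, 8L),
                             fc_widths = 8L, dropout_rate = 0),
                seed = seed)
  })
}

rand_tensor <- function(dim, seed) {
  set.seed(seed)
  array(rnorm(prod(dim)), dim)
}

rand_mask <- function(h, w, seed, p = 0.3) {
  set.seed(seed)
  matrix(runif(h * w) < p, h, w)
}

# numeric central-difference gradient of f at x (restricted to idx)
fd_gradient <- function(f, x, idx, eps = 1e-3) {
  vapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# one-sided differences: used to detect activation-kink straddles, where the
# central-difference oracle is invalid (the function is piecewise linear)
fd_one_sided <- function(f, x, idx, eps = 1e-3) {
  f0 <- f(x)
  vapply(idx, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    c(fwd = (f(xp) - f0) / eps, bwd = (f0 - f(xm)) / eps)
  }, numeric(2))
}
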