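# Minimal 1-D convolutional network plumbing shared by the translation GAN
# and the AF classifier. Convolutions run through the compiled kernels in
# src/conv1d.cpp; everything else (activations, upsampling, Adam) is plain
# vectorized R. Parameters live in flat named lists of numeric vectors so a
# single Adam implementation serves every network.

# ---- layer constructors -----------------------------------------------------

# A conv layer descriptor; weights are stored separately in the param list.
conv_spec <- function(name, k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(name = name, k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride), pad = as.integer(pad))
}

# Initialize weights for one conv layer. "he" scales with fan-in (used by
# the GAN); "trunc_normal" is a truncated normal with fixed SD (used by the
# classifier, whose published recipe states SD 0.05 with zero biases).
conv_init <- function(spec, init = c("he", "trunc_normal"), sd = 0.05) {
  init <- match.arg(init)
  n <- spec$k * spec$cin * spec$cout
  w <- if (init == "he") {
    rnorm(n, 0, sqrt(2 / (spec$k * spec$cin)))
  } else {
    x <- rnorm(n, 0, sd)
    while (any(bad <- abs(x) > 2 * sd)) x[bad] <- rnorm(sum(bad), 0, sd)
    x
  }
  list(w = w, b = numeric(spec$cout))
}

conv_fwd <- function(x, par, spec) {
  conv1d_fwd(x, par$w, par$b, spec$k, spec$stride, spec$pad)
}

conv_bwd <- function(x, gy, par, spec, input_grad = TRUE) {
  g <- conv1d_bwd_params(x, gy, spec$k, spec$stride, spec$pad)
  gx <- if (input_grad)
    conv1d_bwd_input(gy, par$w, spec$k, spec$stride, spec$pad, nrow(x), spec$cin)
  else NULL
  list(gw = g$gw, gb = g$gb, gx = gx)
}

# ---- activations ------------------------------------------------------------

leaky <- function(x, alpha) {
  m <- (x > 0) * (1 - alpha) + alpha
  x * m
}
leaky_grad <- function(x, g, alpha) {
  m <- (x > 0) * (1 - alpha) + alpha
  g * m
}

# ---- resampling along time --------------------------------------------------

upsample2 <- function(x) x[rep(seq_len(nrow(x)), each = 2L), , drop = FALSE]

upsample2_grad <- function(gy) {
  n <- nrow(gy) %/% 2L
  gy[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    gy[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}

# Reflect-pad a vector to `target` samples (appended at the end), recording
# how to crop back.
pad_reflect <- function(x, target) {
  n <- length(x)
  if (n == target) return(x)
  if (n > target) stop("signal longer than the padded target length")
  extra <- target - n
  if (extra > n - 1) stop("padding longer than the signal itself")
  c(x, x[seq(n - 1, by = -1, length.out = extra)])
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  zero <- lapply(params, function(p) lapply(p, function(v) v * 0))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (ly in names(params)) {
    for (pn in names(params[[ly]])) {
      g <- grads[[ly]][[pn]]
      state$m[[ly]][[pn]] <- beta1 * state$m[[ly]][[pn]] + (1 - beta1) * g
      state$v[[ly]][[pn]] <- beta2 * state$v[[ly]][[pn]] + (1 - beta2) * g^2
      params[[ly]][[pn]] <- params[[ly]][[pn]] -
        lr * (state$m[[ly]][[pn]] / bc1) / (sqrt(state$v[[ly]][[pn]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# Elementwise sum of two gradient trees with the same shape.
grads_add <- function(a, b) {
  for (ly in names(b)) for (pn in names(b[[ly]]))
    a[[ly]][[pn]] <- a[[ly]][[pn]] + b[[ly]][[pn]]
  a
}

grads_scale <- function(a, s) {
  for (ly in names(a)) for (pn in names(a[[ly]]))
    a[[ly]][[pn]] <- a[[ly]][[pn]] * s
  a
}

# ---- adversarial losses -----------------------------------------------------

# Binary cross-entropy with logits; returns loss and d(loss)/d(logits),
# averaged over patch scores.
bce_logits <- function(z, target) {
  n <- length(z)
  p <- 1 / (1 + exp(-z))
  loss <- mean(ifelse(z >= 0, z - target * z + log1p(exp(-z)),
                      -target * z + log1p(exp(z))))
  list(loss = loss, dz = (p - target) / n)
}

# Least-squares adversarial loss (LSGAN variant).
ls_loss <- function(z, target) {
  n <- length(z)
  list(loss = mean((z - target)^2), dz = 2 * (z - target) / n)
}
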