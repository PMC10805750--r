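#' Generator architecture specification
#'
#' A 1-D U-Net: `depth` strided-convolution encoder levels that halve the
#' signal length while doubling the channel count, a bottleneck convolution,
#' and a mirrored decoder of nearest-neighbour upsampling plus convolution.
#' Skip connections concatenate each encoder level's features onto the
#' matching decoder level so positional detail lost in the bottleneck is
#' recovered. The output head is a convolution to one channel with a tanh
#' activation, matching the `[-1, 1]` amplitude normalization of the data.
#'
#' @param depth number of encoder levels.
#' @param base_filters channel count of the first level; level `i` has
#'   `base_filters * 2^(i-1)` channels.
#' @param kernel convolution kernel taps (odd).
#' @param skip use skip connections (default `TRUE`).
#' @param input_len training segment length in samples; must be divisible by
#'   `2^depth`.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 5, base_filters = 16, kernel = 9,
                           skip = TRUE, input_len = 3072) {
  if (kernel %% 2 != 1) stop("kernel must be odd")
  if (input_len %% 2^depth != 0)
    stop("input_len must be divisible by 2^depth")
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel), skip = isTRUE(skip),
                 input_len = as.integer(input_len)),
            class = "generator_spec")
}

#' Markovian (patch) discriminator specification
#'
#' A stack of strided convolutions over the channel-wise concatenation of
#' the ECG and (real or generated) PPG, ending in a one-channel score map:
#' each output score sees only a local receptive field of the input pair,
#' so the critic judges local waveform realism rather than a whole segment.
#'
#' @param n_layers number of stride-2 convolution layers.
#' @param base_filters channel count of the first layer.
#' @param kernel convolution kernel taps (odd).
#' @param patch_output emit the full patch score map (`TRUE`, default)
#'   rather than its mean.
#' @return object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(n_layers = 3, base_filters = 16, kernel = 9,
                               patch_output = TRUE) {
  if (kernel %% 2 != 1) stop("kernel must be odd")
  structure(list(n_layers = as.integer(n_layers),
                 base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel), patch_output = isTRUE(patch_output)),
            class = "discriminator_spec")
}

#' Adversarial training configuration
#'
#' The generator loss is the adversarial term plus `lambda_rec` times the
#' mean absolute reconstruction error against the reference PPG, the
#' conditional-translation convention; `lambda_rec = 0` disables the
#' reconstruction term. One discriminator step is taken per generator step.
#'
#' @param epochs training epochs.
#' @param batch_size examples per parameter update (default 1).
#' @param lr_g,lr_d Adam learning rates (default 2e-4 each, beta1 = 0.5).
#' @param adv_loss `"bce"` (sigmoid cross-entropy, default) or `"lsgan"`
#'   (least-squares).
#' @param lambda_rec weight of the L1 reconstruction term (default 100).
#' @param seed integer seed covering shuffling and initialization noise.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 20, batch_size = 1, lr_g = 2e-4, lr_d = 2e-4,
                         adv_loss = c("bce", "lsgan"), lambda_rec = 100,
                         seed = 1L) {
  adv_loss <- match.arg(adv_loss)
  if (lambda_rec < 0) stop("lambda_rec must be non-negative")
  if (lr_g <= 0 || lr_d <= 0) stop("learning rates must be positive")
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_g = lr_g, lr_d = lr_d, adv_loss = adv_loss,
                 lambda_rec = lambda_rec, seed = as.integer(seed)),
            class = "train_config")
}

# Channel count at encoder level i (level 0 = the single input channel).
gen_channels <- function(spec, i) if (i == 0) 1L else spec$base_filters * 2L^(i - 1L)

#' Build an untrained U-Net generator
#'
#' @param spec a [generator_spec()].
#' @param seed seed for weight initialization (He-scaled normals).
#' @return a `generator` list holding the spec, layer table and parameters.
#' @export
build_generator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  D <- spec$depth; k <- spec$kernel
  layers <- list()
  for (i in seq_len(D))
    layers[[paste0("enc", i)]] <- conv_spec(paste0("enc", i), k,
                                            gen_channels(spec, i - 1),
                                            gen_channels(spec, i), stride = 2L)
  layers[["mid"]] <- conv_spec("mid", k, gen_channels(spec, D), gen_channels(spec, D))
  for (j in seq(D - 1, 0)) {
    cin <- gen_channels(spec, j + 1) + if (spec$skip && j >= 1) gen_channels(spec, j) else 0L
    cout <- if (j >= 1) gen_channels(spec, j) else spec$base_filters
    layers[[paste0("dec", j)]] <- conv_spec(paste0("dec", j), k, cin, cout)
  }
  layers[["out"]] <- conv_spec("out", k, spec$base_filters, 1L)
  params <- with_seed(seed, lapply(layers, conv_init, init = "he"))
  structure(list(spec = spec, layers = layers, params = params), class = "generator")
}

# Forward pass through the generator. `x` is a length-L vector with L
# divisible by 2^depth. Returns the output vector and (optionally) the
# caches needed for backprop.
gen_forward <- function(gen, x, keep_cache = FALSE) {
  spec <- gen$spec; D <- spec$depth
  L <- length(x)
  if (L %% 2^D != 0) stop("input length must be divisible by 2^depth")
  h <- matrix(x, ncol = 1)
  enc_in <- list(); enc_pre <- list(); e <- list()
  for (i in seq_len(D)) {
    nm <- paste0("enc", i)
    enc_in[[i]] <- h
    z <- conv_fwd(h, gen$params[[nm]], gen$layers[[nm]])
    enc_pre[[i]] <- z
    h <- leaky(z, 0.2)
    e[[i]] <- h
  }
  mid_in <- h
  mid_pre <- conv_fwd(h, gen$params$mid, gen$layers$mid)
  d <- leaky(mid_pre, 0.2)
  dec_in <- list(); dec_pre <- list()
  for (j in seq(D - 1, 0)) {
    nm <- paste0("dec", j)
    u <- upsample2(d)
    if (spec$skip && j >= 1) u <- cbind(u, e[[j]])
    dec_in[[nm]] <- u
    z <- conv_fwd(u, gen$params[[nm]], gen$layers[[nm]])
    dec_pre[[nm]] <- z
    d <- leaky(z, 0.2)
  }
  out_in <- d
  z_out <- conv_fwd(d, gen$params$out, gen$layers$out)
  y <- tanh(z_out)
  cache <- if (keep_cache)
    list(enc_in = enc_in, enc_pre = enc_pre, e = e, mid_in = mid_in,
         mid_pre = mid_pre, dec_in = dec_in, dec_pre = dec_pre,
         out_in = out_in, y = y, L = L)
  else NULL
  list(y = as.numeric(y), cache = cache)
}

# Backprop through the generator given d(loss)/d(output). Returns the
# gradient tree matching gen$params.
gen_backward <- function(gen, cache, dy) {
  spec <- gen$spec; D <- spec$depth
  grads <- list()
  dz <- matrix(dy, ncol = 1) * (1 - cache$y^2)
  g <- conv_bwd(cache$out_in, dz, gen$params$out, gen$layers$out)
  grads$out <- list(w = g$gw, b = g$gb)
  dd <- g$gx
  de <- vector("list", D)   # gradients flowing into each encoder activation
  for (j in seq(0, D - 1)) {
    nm <- paste0("dec", j)
    dz <- leaky_grad(cache$dec_pre[[nm]], dd, 0.2)
    g <- conv_bwd(cache$dec_in[[nm]], dz, gen$params[[nm]], gen$layers[[nm]])
    grads[[nm]] <- list(w = g$gw, b = g$gb)
    du <- g$gx
    ch_up <- gen_channels(spec, j + 1)
    if (spec$skip && j >= 1) {
      de[[j]] <- du[, (ch_up + 1):ncol(du), drop = FALSE]
      du <- du[, seq_len(ch_up), drop = FALSE]
    }
    dd <- upsample2_grad(du)
  }
  dz <- leaky_grad(cache$mid_pre, dd, 0.2)
  g <- conv_bwd(cache$mid_in, dz, gen$params$mid, gen$layers$mid)
  grads$mid <- list(w = g$gw, b = g$gb)
  dh <- g$gx
  for (i in seq(D, 1)) {
    nm <- paste0("enc", i)
    if (!is.null(de[[i]])) dh <- dh + de[[i]]
    dz <- leaky_grad(cache$enc_pre[[i]], dh, 0.2)
    g <- conv_bwd(cache$enc_in[[i]], dz, gen$params[[nm]], gen$layers[[nm]],
                  input_grad = i > 1)
    grads[[nm]] <- list(w = g$gw, b = g$gb)
    if (i > 1) dh <- g$gx
  }
  grads
}

#' Build an untrained patch discriminator
#'
#' @param spec a [discriminator_spec()].
#' @param seed seed for weight initialization.
#' @return a `discriminator` list.
#' @export
build_discriminator <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  N <- spec$n_layers; k <- spec$kernel
  layers <- list()
  cin <- 2L
  for (i in seq_len(N)) {
    cout <- spec$base_filters * 2L^(i - 1L)
    layers[[paste0("conv", i)]] <- conv_spec(paste0("conv", i), k, cin, cout, stride = 2L)
    cin <- cout
  }
  layers[["score"]] <- conv_spec("score", k, cin, 1L)
  params <- with_seed(seed, lapply(layers, conv_init, init = "he"))
  structure(list(spec = spec, layers = layers, params = params), class = "discriminator")
}

# Forward pass: xy is an L x 2 matrix (ECG, PPG). Returns patch logits.
disc_forward <- function(disc, xy, keep_cache = FALSE) {
  if (ncol(xy) != 2) stop("discriminator input must have 2 channels")
  if (any(!is.finite(xy))) stop("non-finite discriminator input")
  N <- disc$spec$n_layers
  h <- xy
  ins <- list(); pres <- list()
  for (i in seq_len(N)) {
    nm <- paste0("conv", i)
    ins[[i]] <- h
    z <- conv_fwd(h, disc$params[[nm]], disc$layers[[nm]])
    pres[[i]] <- z
    h <- leaky(z, 0.2)
  }
  score_in <- h
  z <- conv_fwd(h, disc$params$score, disc$layers$score)
  scores <- if (disc$spec$patch_output) as.numeric(z) else mean(z)
  list(scores = scores, z = z,
       cache = if (keep_cache) list(ins = ins, pres = pres, score_in = score_in,
                                    L = nrow(xy)) else NULL)
}

# Backprop through the discriminator. dz matches the patch logit map.
# Returns parameter grads and (optionally) the gradient w.r.t. the input
# pair, needed for the generator's adversarial update.
disc_backward <- function(disc, cache, dz, input_grad = FALSE) {
  N <- disc$spec$n_layers
  grads <- list()
  g <- conv_bwd(cache$score_in, matrix(dz, ncol = 1), disc$params$score,
                disc$layers$score)
  grads$score <- list(w = g$gw, b = g$gb)
  dh <- g$gx
  for (i in seq(N, 1)) {
    nm <- paste0("conv", i)
    dzc <- leaky_grad(cache$pres[[i]], dh, 0.2)
    g <- conv_bwd(cache$ins[[i]], dzc, disc$params[[nm]], disc$layers[[nm]],
                  input_grad = input_grad || i > 1)
    grads[[nm]] <- list(w = g$gw, b = g$gb)
    dh <- g$gx
  }
  list(grads = grads, dx = dh)
}

# Pad a segment to the nearest multiple of 2^depth by end reflection.
pad_for_depth <- function(x, depth) {
  mult <- 2L^depth
  target <- as.integer(ceiling(length(x) / mult) * mult)
  pad_reflect(x, target)
}

#' Train the ECG-to-PPG translation GAN
#'
#' Alternating updates: for each training pair the discriminator is stepped
#' on one real and one generated (ECG, PPG) pair, then the generator is
#' stepped on its adversarial score plus `lambda_rec` times the L1 error
#' against the reference PPG. Segments whose length is not divisible by
#' `2^depth` are reflect-padded for the forward pass. Per-epoch mean losses
#' are recorded; a non-finite loss aborts with a diagnostic.
#'
#' @param pairs a [segment_store()] carrying PPG segments with the paired
#'   ECG matrix attached; both channels in `[-1, 1]`.
#' @param cfg a [train_config()].
#' @param gen_spec a [generator_spec()]; `input_len` is taken from the data.
#' @param disc_spec a [discriminator_spec()].
#' @return a `translator_model`: generator, discriminator, per-epoch
#'   history, and the configuration snapshot.
#' @export
gan_train <- function(pairs, cfg = train_config(),
                      gen_spec = generator_spec(),
                      disc_spec = discriminator_spec()) {
  stopifnot(inherits(pairs, "segment_store"), inherits(cfg, "train_config"))
  if (is.null(pairs$ecg)) stop("training store must carry the paired ECG matrix")
  n <- nrow(pairs$segments)
  if (n == 0) stop("empty training store")
  L <- ncol(pairs$segments)
  mult <- 2L^gen_spec$depth
  Lp <- as.integer(ceiling(L / mult) * mult)
  gen_spec$input_len <- Lp
  gen <- build_generator(gen_spec, seed = derive_seed(cfg$seed, "generator-init"))
  disc <- build_discriminator(disc_spec, seed = derive_seed(cfg$seed, "discriminator-init"))
  ad_g <- adam_new(gen$params)
  ad_d <- adam_new(disc$params)
  adv <- if (cfg$adv_loss == "bce") bce_logits else ls_loss
  hist <- data.frame(epoch = integer(0), d_loss = numeric(0),
                     g_adv = numeric(0), g_rec = numeric(0))
  with_seed(derive_seed(cfg$seed, "gan-train"), {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      dl <- ga <- gr <- 0
      bcount <- 0L
      gacc <- dacc <- NULL
      for (ii in seq_along(idx)) {
        i <- idx[ii]
        x <- pad_reflect(pairs$ecg[i, ], Lp)
        y <- pad_reflect(pairs$segments[i, ], Lp)
        fw <- gen_forward(gen, x, keep_cache = TRUE)
        fake <- fw$y
        # --- discriminator ---
        fr <- disc_forward(disc, cbind(x, y), keep_cache = TRUE)
        lr_ <- adv(fr$scores, 1)
        gr_r <- disc_backward(disc, fr$cache, lr_$dz)$grads
        ff <- disc_forward(disc, cbind(x, fake), keep_cache = TRUE)
        lf_ <- adv(ff$scores, 0)
        gr_f <- disc_backward(disc, ff$cache, lf_$dz)$grads
        d_grads <- grads_scale(grads_add(gr_r, gr_f), 0.5)
        # --- generator ---
        fg <- disc_forward(disc, cbind(x, fake), keep_cache = TRUE)
        la_ <- adv(fg$scores, 1)
        db <- disc_backward(disc, fg$cache, la_$dz, input_grad = TRUE)
        dfake <- db$dx[, 2]
        rec_err <- fake - y
        rec_mae <- mean(abs(rec_err))
        dfake <- dfake + cfg$lambda_rec * sign(rec_err) / Lp
        g_grads <- gen_backward(gen, fw$cache, dfake)
        # --- accumulate / step ---
        dacc <- if (is.null(dacc)) d_grads else grads_add(dacc, d_grads)
        gacc <- if (is.null(gacc)) g_grads else grads_add(gacc, g_grads)
        bcount <- bcount + 1L
        if (bcount == cfg$batch_size || ii == length(idx)) {
          sd_ <- adam_step(disc$params, grads_scale(dacc, 1 / bcount), ad_d,
                           cfg$lr_d, beta1 = 0.5)
          disc$params <- sd_$params; ad_d <- sd_$state
          sg_ <- adam_step(gen$params, grads_scale(gacc, 1 / bcount), ad_g,
                           cfg$lr_g, beta1 = 0.5)
          gen$params <- sg_$params; ad_g <- sg_$state
          dacc <- gacc <- NULL; bcount <- 0L
        }
        dloss <- 0.5 * (lr_$loss + lf_$loss)
        if (!is.finite(dloss) || !is.finite(la_$loss) || !is.finite(rec_mae))
          stop(sprintf("training diverged (non-finite loss) at epoch %d, step %d", ep, ii))
        dl <- dl + dloss; ga <- ga + la_$loss; gr <- gr + rec_mae
      }
      hist <- rbind(hist, data.frame(epoch = ep, d_loss = dl / n,
                                     g_adv = ga / n, g_rec = gr / n))
    }
  })
  structure(list(generator = gen, discriminator = disc, history = hist,
                 config = cfg), class = "translator_model")
}

#' @export
print.translator_model <- function(x, ...) {
  h <- tail(x$history, 1)
  cat(sprintf("<translator_model> U-Net depth %d, %d epochs; final d_loss=%.4f g_adv=%.4f g_rec=%.4f\n",
              x$generator$spec$depth, nrow(x$history), h$d_loss, h$g_adv, h$g_rec))
  invisible(x)
}

#' Translate ECG segments into PPG with a trained model
#'
#' Inputs are expected in `[-1, 1]`. Each segment is reflect-padded to the
#' nearest multiple of `2^depth`, passed through the generator, and cropped
#' back to its original length; outputs are bounded by the tanh head.
#'
#' @param model a `translator_model` from [gan_train()].
#' @param ecg numeric vector, or matrix with one segment per row.
#' @return same shape as the input, values in `[-1, 1]`.
#' @export
generate_ppg <- function(model, ecg) {
  stopifnot(inherits(model, "translator_model"))
  one <- function(x) {
    if (any(!is.finite(x))) stop("non-finite input to generate_ppg")
    xp <- pad_for_depth(x, model$generator$spec$depth)
    gen_forward(model$generator, xp)$y[seq_along(x)]
  }
  if (is.matrix(ecg)) t(apply(ecg, 1, one)) else one(ecg)
}

#' Save or load a translator checkpoint
#'
#' The checkpoint is a single file holding parameters, architecture specs,
#' history and the training configuration; a round-trip reproduces forward
#' passes bit-identically.
#'
#' @param model a `translator_model`.
#' @param path file path.
#' @return `load_translator` returns the model; `save_translator` its path,
#'   invisibly.
#' @export
save_translator <- function(model, path) {
  stopifnot(inherits(model, "translator_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_translator
#' @export
load_translator <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "translator_model"))
  model
}
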