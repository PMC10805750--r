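#' AF classifier architecture specification
#'
#' A compact 1-D CNN for AF-vs-SR classification of 15-s PPG slices:
#' six convolution layers with 4, 8, 16, 32, 64 and 128 filters, kernel 3,
#' leaky-ReLU activations (alpha 0.15), truncated-normal weight
#' initialization (SD 0.05) with zero biases, global average pooling and a
#' softmax output over two classes (class 1 = AF), trained with
#' cross-entropy and Adam at learning rate 0.001. Stride-2 convolutions
#' shrink the 1500-sample input to a short feature map before pooling.
#'
#' @param input_len input length in samples (default 1500 = 15 s at 100 Hz).
#' @param filters per-layer filter counts; must be 6 strictly increasing
#'   values.
#' @param kernel kernel taps (default 3).
#' @param leaky_alpha leaky-ReLU slope (default 0.15).
#' @param init_sd truncated-normal initialization SD (default 0.05).
#' @param lr Adam learning rate (default 0.001).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(input_len = 1500, filters = c(4, 8, 16, 32, 64, 128),
                            kernel = 3, leaky_alpha = 0.15, init_sd = 0.05,
                            lr = 0.001) {
  if (length(filters) != 6 || any(diff(filters) <= 0))
    stop("filters must be 6 strictly increasing counts")
  structure(list(input_len = as.integer(input_len), filters = as.integer(filters),
                 kernel = as.integer(kernel), leaky_alpha = leaky_alpha,
                 init_sd = init_sd, lr = lr),
            class = "classifier_spec")
}

#' Build an untrained AF classifier
#'
#' @param spec a [classifier_spec()].
#' @param seed seed for the truncated-normal initialization.
#' @return an `af_classifier` list (spec, conv layer table, parameters).
#' @export
build_classifier <- function(spec = classifier_spec(), seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  layers <- list()
  cin <- 1L
  for (i in seq_along(spec$filters)) {
    layers[[paste0("conv", i)]] <- conv_spec(paste0("conv", i), spec$kernel,
                                             cin, spec$filters[i], stride = 2L)
    cin <- spec$filters[i]
  }
  params <- with_seed(seed, {
    p <- lapply(layers, conv_init, init = "trunc_normal", sd = spec$init_sd)
    nf <- spec$filters[length(spec$filters)]
    w <- rnorm(nf * 2L, 0, spec$init_sd)
    while (any(bad <- abs(w) > 2 * spec$init_sd))
      w[bad] <- rnorm(sum(bad), 0, spec$init_sd)
    p$dense <- list(w = matrix(w, nf, 2L), b = numeric(2L))
    p
  })
  structure(list(spec = spec, layers = layers, params = params,
                 history = NULL), class = "af_classifier")
}

# Forward pass for a single segment. Returns class probabilities, the
# pooled feature vector, and optional caches for backprop.
clf_forward <- function(clf, x, keep_cache = FALSE) {
  if (length(x) != clf$spec$input_len)
    stop(sprintf("classifier expects input length %d, got %d",
                 clf$spec$input_len, length(x)))
  a <- clf$spec$leaky_alpha
  h <- matrix(x, ncol = 1)
  ins <- list(); pres <- list()
  for (i in seq_along(clf$spec$filters)) {
    nm <- paste0("conv", i)
    ins[[i]] <- h
    z <- conv_fwd(h, clf$params[[nm]], clf$layers[[nm]])
    pres[[i]] <- z
    h <- leaky(z, a)
  }
  g <- colMeans(h)
  logits <- as.numeric(g %*% clf$params$dense$w + clf$params$dense$b)
  m <- max(logits)
  p <- exp(logits - m)
  p <- p / sum(p)
  list(probs = p, features = g,
       cache = if (keep_cache) list(ins = ins, pres = pres, h_last = h, g = g) else NULL)
}

# Backprop from d(loss)/d(logits) for one segment.
clf_backward <- function(clf, cache, dlogits) {
  a <- clf$spec$leaky_alpha
  grads <- list(dense = list(w = outer(cache$g, dlogits), b = dlogits))
  dg <- as.numeric(clf$params$dense$w %*% dlogits)
  Lh <- nrow(cache$h_last)
  dh <- matrix(dg / Lh, Lh, length(dg), byrow = TRUE)
  for (i in seq(length(clf$spec$filters), 1)) {
    nm <- paste0("conv", i)
    dz <- leaky_grad(cache$pres[[i]], dh, a)
    g <- conv_bwd(cache$ins[[i]], dz, clf$params[[nm]], clf$layers[[nm]],
                  input_grad = i > 1)
    grads[[nm]] <- list(w = g$gw, b = g$gb)
    if (i > 1) dh <- g$gx
  }
  grads
}

store_class_labels <- function(store) as.integer(store$labels == "AF")

#' Train the AF classifier
#'
#' Cross-entropy minimized with Adam; gradients are averaged over
#' mini-batches drawn in seeded shuffled order. The per-epoch mean loss and
#' training accuracy are recorded on the returned model.
#'
#' @param data a [segment_store()] containing both classes.
#' @param spec a [classifier_spec()].
#' @param epochs training epochs (default 10); 0 returns the freshly
#'   initialized model without any updates.
#' @param batch mini-batch size (default 32).
#' @param seed seed covering initialization and shuffling.
#' @return a trained `af_classifier` with a `history` data frame.
#' @export
train_classifier <- function(data, spec = classifier_spec(), epochs = 10,
                             batch = 32, seed = 1L) {
  stopifnot(inherits(data, "segment_store"))
  lab <- store_class_labels(data)
  if (length(unique(lab)) < 2) stop("training data must contain both classes")
  if (ncol(data$segments) != spec$input_len)
    stop("segment length does not match classifier input_len")
  clf <- build_classifier(spec, seed = derive_seed(seed, "clf-init"))
  if (epochs == 0) {   # untrained baseline: the initialized model as-is
    clf$history <- data.frame(epoch = integer(0), loss = numeric(0),
                              accuracy = numeric(0))
    return(clf)
  }
  ad <- adam_new(clf$params)
  n <- nrow(data$segments)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  with_seed(derive_seed(seed, "clf-train"), {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      tot_loss <- 0; correct <- 0L
      acc_g <- NULL; bcount <- 0L
      for (ii in seq_along(idx)) {
        i <- idx[ii]
        fw <- clf_forward(clf, data$segments[i, ], keep_cache = TRUE)
        y <- lab[i]
        pr <- max(fw$probs[y + 1L], 1e-12)
        tot_loss <- tot_loss + (-log(pr))
        correct <- correct + as.integer(which.max(fw$probs) - 1L == y)
        dlogits <- fw$probs
        dlogits[y + 1L] <- dlogits[y + 1L] - 1
        g <- clf_backward(clf, fw$cache, dlogits)
        acc_g <- if (is.null(acc_g)) g else grads_add(acc_g, g)
        bcount <- bcount + 1L
        if (bcount == batch || ii == length(idx)) {
          st <- adam_step(clf$params, grads_scale(acc_g, 1 / bcount), ad, spec$lr)
          clf$params <- st$params; ad <- st$state
          acc_g <- NULL; bcount <- 0L
        }
      }
      if (!is.finite(tot_loss)) stop(sprintf("training diverged at epoch %d", ep))
      hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / n,
                                     accuracy = correct / n))
    }
  })
  clf$history <- hist
  clf
}

#' Class probabilities and pooled features for a segment store
#'
#' @param clf an `af_classifier`.
#' @param store a [segment_store()].
#' @return list with `probs` (n x 2 matrix, columns SR/AF) and `features`
#'   (n x 128 global-average-pooled feature map, the input of the softmax
#'   head — the representation used for feature-space embedding).
#' @export
predict_classifier <- function(clf, store) {
  stopifnot(inherits(clf, "af_classifier"), inherits(store, "segment_store"))
  n <- nrow(store$segments)
  probs <- matrix(0, n, 2)
  feats <- matrix(0, n, clf$spec$filters[length(clf$spec$filters)])
  for (i in seq_len(n)) {
    fw <- clf_forward(clf, store$segments[i, ])
    probs[i, ] <- fw$probs
    feats[i, ] <- fw$features
  }
  colnames(probs) <- c("SR", "AF")
  list(probs = probs, features = feats)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling; equals the
#' probability that a random positive outscores a random negative, counting
#' ties as one half.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 class labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUROC undefined: test set has a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# Stratified bootstrap CI for the AUROC.
auroc_ci <- function(scores, labels, n_boot = 2000, seed = 1L, level = 0.95) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  with_seed(seed, {
    stats_ <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
      auroc(scores[i], labels[i])
    }, numeric(1))
    unname(quantile(stats_, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Evaluate a trained classifier on a test store
#'
#' Threshold-free AUROC (with a seeded stratified-bootstrap 95% CI) from
#' the AF-class probabilities, plus accuracy, precision, recall, F1 and the
#' 2x2 confusion counts at the argmax decision, with AF as the positive
#' class. A single-class test set raises an error for the AUROC pathway.
#'
#' @param clf a trained `af_classifier`.
#' @param test a [segment_store()].
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param seed bootstrap seed.
#' @return an `eval_report` list: `accuracy`, `auroc`, `auroc_ci_low/high`,
#'   `precision`, `recall`, `f1`, `confusion` (TN, FP, FN, TP), `n`.
#' @export
evaluate_classifier <- function(clf, test, n_boot = 2000, seed = 1L) {
  stopifnot(inherits(test, "segment_store"))
  if (nrow(test$segments) == 0) stop("empty test store")
  lab <- store_class_labels(test)
  scores <- predict_classifier(clf, test)$probs[, "AF"]
  evaluate_scores(scores, lab, n_boot = n_boot, seed = seed)
}

#' Evaluation metrics from scores and labels
#'
#' The metric core of [evaluate_classifier()], usable on any probability
#' scores: AUROC with a stratified-bootstrap CI, plus thresholded metrics
#' and the confusion counts at `scores > 0.5`.
#'
#' @param scores AF-class probabilities (or any monotone scores in `[0,1]`).
#' @param lab 0/1 labels (1 = AF).
#' @param n_boot,seed bootstrap settings.
#' @return an `eval_report`; see [evaluate_classifier()].
#' @export
evaluate_scores <- function(scores, lab, n_boot = 2000, seed = 1L) {
  pred <- as.integer(scores > 0.5)
  tp <- sum(pred == 1 & lab == 1); tn <- sum(pred == 0 & lab == 0)
  fp <- sum(pred == 1 & lab == 0); fn <- sum(pred == 0 & lab == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  au <- auroc(scores, lab)   # errors on one-class input, by contract
  ci <- auroc_ci(scores, lab, n_boot = n_boot, seed = seed)
  structure(list(accuracy = (tp + tn) / length(lab), auroc = au,
                 auroc_ci_low = ci[1], auroc_ci_high = ci[2],
                 precision = precision, recall = recall, f1 = f1,
                 confusion = c(TN = tn, FP = fp, FN = fn, TP = tp),
                 n = length(lab)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d acc=%.3f AUROC=%.3f [%.3f-%.3f] P=%.3f R=%.3f F1=%.3f\n",
              x$n, x$accuracy, x$auroc, x$auroc_ci_low, x$auroc_ci_high,
              x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

# Split a store into parent-level halves: all slices of a parent stay
# together, preventing leakage between overlapping slices.
half_by_parents <- function(store, seed) {
  parents <- unique(store$parent_id)
  if (length(parents) < 2) stop("need at least 2 parent segments to halve")
  sel <- with_seed(seed, sample(parents, floor(length(parents) / 2)))
  subset_store(store, store$parent_id %in% sel)
}

# Trim `store` to (about) `target` segments by dropping whole parents.
trim_to_count <- function(store, target, seed) {
  if (n_segments(store) <= target) return(store)
  parents <- with_seed(seed, sample(unique(store$parent_id)))
  counts <- table(store$parent_id)[parents]
  keep <- parents[cumsum(counts) <= target]
  if (length(keep) == 0) keep <- parents[1]
  subset_store(store, store$parent_id %in% keep)
}

#' Compose a training dataset from segment pools
#'
#' The composition schemes used to probe the value of generated AF data:
#' * `D1` — all generated AF + sinus rhythm (no real AF);
#' * `D2` — half the generated AF + half the real AF + sinus rhythm;
#' * `D3` — all real AF + sinus rhythm;
#' * `D4` — half the real AF + half the sinus rhythm (no generated data);
#' * `TEST` — all real AF + all sinus rhythm.
#'
#' Halves are selected by seeded sampling of whole parent segments, so
#' overlapping slices of one parent never straddle a selection boundary.
#' For D1-D3 the sinus-rhythm side is trimmed (by whole parents) to the AF
#' count so classes stay balanced.
#'
#' @param pools named list with [segment_store()] entries `generated_af`,
#'   `real_af`, `real_sr` (only those a scheme needs must be present).
#' @param scheme one of `"D1"`, `"D2"`, `"D3"`, `"D4"`, `"TEST"`.
#' @param seed selection seed.
#' @return list with `store` (the composed [segment_store()]) and `scheme`
#'   (id plus the realized `af_generated`, `af_real`, `sr_real` counts).
#' @export
compose_dataset <- function(pools, scheme = c("D1", "D2", "D3", "D4", "TEST"),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  need <- switch(scheme,
                 D1 = c("generated_af", "real_sr"),
                 D2 = c("generated_af", "real_af", "real_sr"),
                 D3 = c("real_af", "real_sr"),
                 D4 = c("real_af", "real_sr"),
                 TEST = c("real_af", "real_sr"))
  for (nm in need) {
    if (is.null(pools[[nm]]) || n_segments(pools[[nm]]) == 0)
      stop(sprintf("scheme %s needs a nonempty '%s' pool", scheme, nm))
  }
  af <- switch(scheme,
    D1 = pools$generated_af,
    D2 = bind_stores(half_by_parents(pools$generated_af, derive_seed(seed, "half-gen")),
                     half_by_parents(pools$real_af, derive_seed(seed, "half-real"))),
    D3 = pools$real_af,
    D4 = half_by_parents(pools$real_af, derive_seed(seed, "half-real")),
    TEST = pools$real_af)
  sr <- switch(scheme,
    D4 = half_by_parents(pools$real_sr, derive_seed(seed, "half-sr")),
    TEST = pools$real_sr,
    trim_to_count(pools$real_sr, n_segments(af), derive_seed(seed, "trim-sr")))
  store <- bind_stores(af, sr)
  list(store = store,
       scheme = list(scheme_id = scheme,
                     af_generated = sum(af$origin == "generated"),
                     af_real = sum(af$origin == "real" & af$labels == "AF"),
                     sr_real = n_segments(sr)))
}

#' Run the dataset-composition validation experiment
#'
#' Trains one identically configured classifier per composition scheme and
#' evaluates each on the same held-out test store, guarding against parent
#' segments shared between any training pool and the test set.
#'
#' @param pools named pool list as in [compose_dataset()].
#' @param test a [segment_store()] disjoint from the pools at parent level.
#' @param schemes character vector of scheme ids (default D1-D4).
#' @param spec a [classifier_spec()].
#' @param epochs,batch,seed training settings shared by every scheme.
#' @param n_boot bootstrap resamples for each AUROC CI.
#' @return list with `table` (one row per scheme: accuracy, AUROC + CI,
#'   precision, recall, F1) and `reports` (the full `eval_report`s).
#' @export
run_validation_experiment <- function(pools, test,
                                      schemes = c("D1", "D2", "D3", "D4"),
                                      spec = classifier_spec(), epochs = 10,
                                      batch = 32, seed = 1L, n_boot = 2000) {
  pool_parents <- unlist(lapply(pools, function(p) unique(p$parent_id)))
  if (length(intersect(pool_parents, unique(test$parent_id))) > 0)
    stop("leakage: parent segments shared between training pools and test set")
  reports <- list()
  rows <- list()
  for (sc in schemes) {
    comp <- compose_dataset(pools, sc, seed = derive_seed(seed, paste0("compose-", sc)))
    clf <- train_classifier(comp$store, spec, epochs = epochs, batch = batch,
                            seed = derive_seed(seed, paste0("train-", sc)))
    rep_ <- evaluate_classifier(clf, test, n_boot = n_boot,
                                seed = derive_seed(seed, paste0("eval-", sc)))
    reports[[sc]] <- rep_
    rows[[sc]] <- data.frame(dataset = sc, accuracy = rep_$accuracy,
                             auroc = rep_$auroc, ci_low = rep_$auroc_ci_low,
                             ci_high = rep_$auroc_ci_high,
                             precision = rep_$precision, recall = rep_$recall,
                             f1 = rep_$f1,
                             n_train = n_segments(comp$store))
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}
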