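test_that("generator specs enforce divisibility and preserve shape at any depth", {
  expect_error(generator_spec(depth = 5, input_len = 3000), "divisible")
  for (depth in c(2, 3)) {
    g <- build_generator(generator_spec(depth = depth, base_filters = 4,
                                        kernel = 5, input_len = 256), seed = 1)
    x <- rnorm(256)
    out <- ecg2ppg:::gen_forward(g, x)$y
    expect_length(out, 256)
    expect_true(all(abs(out) <= 1))
  }
})

test_that("skip connections add parameters and forward passes are deterministic", {
  sk <- build_generator(generator_spec(depth = 3, base_filters = 4, kernel = 5,
                                       input_len = 256, skip = TRUE), seed = 1)
  no <- build_generator(generator_spec(depth = 3, base_filters = 4, kernel = 5,
                                       input_len = 256, skip = FALSE), seed = 1)
  n_par <- function(g) sum(vapply(g$params, function(p) length(p$w) + length(p$b),
                                  numeric(1)))
  expect_gt(n_par(sk), n_par(no))

  x <- rnorm(256)
  expect_identical(ecg2ppg:::gen_forward(sk, x)$y, ecg2ppg:::gen_forward(sk, x)$y)
  sk2 <- build_generator(generator_spec(depth = 3, base_filters = 4, kernel = 5,
                                        input_len = 256, skip = TRUE), seed = 1)
  expect_identical(sk$params, sk2$params)
})

test_that("the patch discriminator emits a local score map sensitive to the PPG channel", {
  d <- build_discriminator(discriminator_spec(n_layers = 4, base_filters = 4,
                                              kernel = 5), seed = 2)
  x <- rnorm(3072); y <- rnorm(3072)
  s1 <- ecg2ppg:::disc_forward(d, cbind(x, y))$scores
  expect_gt(length(s1), 1)          # a map of patch scores, not one scalar
  expect_lt(length(s1), 3072)       # each score sees a local receptive field
  s2 <- ecg2ppg:::disc_forward(d, cbind(x, rnorm(3072)))$scores
  expect_false(isTRUE(all.equal(s1, s2)))
  expect_identical(s1, ecg2ppg:::disc_forward(d, cbind(x, y))$scores)
  expect_error(ecg2ppg:::disc_forward(d, matrix(rnorm(30), 10, 3)), "2 channels")
})

test_that("adversarial training learns the identity task to low reconstruction error", {
  set.seed(3)
  n <- 100; L <- 512
  smooth_rows <- function(m) t(apply(m, 1, function(r)
    minmax_scale(stats::filter(r, rep(1 / 8, 8), circular = TRUE))))
  X <- smooth_rows(matrix(rnorm(n * L), n, L))
  st <- segment_store(X, rep("AF", n), "real", fs = 100,
                      segment_seconds = L / 100, ecg = X)
  m <- gan_train(st, train_config(epochs = 25, lambda_rec = 100, seed = 2),
                 generator_spec(depth = 3, base_filters = 8, kernel = 9,
                                input_len = 512),
                 discriminator_spec(3, 8, 9))
  expect_equal(nrow(m$history), 25)
  expect_true(all(is.finite(as.matrix(m$history[-1]))))
  Xh <- smooth_rows(matrix(rnorm(20 * L), 20, L))
  out <- generate_ppg(m, Xh)
  expect_lt(mean(abs(out - Xh)), 0.05)
})

test_that("training without the reconstruction term stays finite, and seeds fix the history", {
  st <- cohort_pairs(6, seed = 41)
  short <- segment_store(st$segments[, 1:512], st$labels, st$origin,
                         st$parent_id, fs = st$fs, segment_seconds = 5.12,
                         ecg = st$ecg[, 1:512])
  gs <- generator_spec(depth = 2, base_filters = 4, kernel = 5, input_len = 512)
  ds <- discriminator_spec(2, 4, 5)
  m0 <- gan_train(short, train_config(epochs = 2, lambda_rec = 0, seed = 7), gs, ds)
  expect_true(all(is.finite(as.matrix(m0$history[-1]))))
  m1 <- gan_train(short, train_config(epochs = 2, seed = 7), gs, ds)
  m2 <- gan_train(short, train_config(epochs = 2, seed = 7), gs, ds)
  expect_identical(m1$history, m2$history)
  empty <- segment_store(matrix(0, 0, 512), character(0), character(0),
                         character(0), fs = 100, segment_seconds = 5.12,
                         ecg = matrix(0, 0, 512))
  expect_error(gan_train(empty, train_config(epochs = 1)), "empty")
})

test_that("generation preserves length, bounds output, and round-trips checkpoints bit-identically", {
  ecg <- clean_record("AF", seed = 51)$ecg
  out <- generate_ppg(shared_gan, ecg)
  expect_length(out, length(ecg))
  expect_true(all(abs(out) <= 1))
  z <- generate_ppg(shared_gan, rep(0, 3000))
  expect_true(all(is.finite(z)) && all(abs(z) <= 1))
  expect_error(generate_ppg(shared_gan, c(rep(0, 2999), NA)), "non-finite")

  path <- withr::local_tempfile(fileext = ".rds")
  save_translator(shared_gan, path)
  back <- load_translator(path)
  expect_identical(generate_ppg(back, ecg), out)
})

test_that("rhythm variability of held-out AF records transfers to the generated pulse train", {
  cors <- vapply(shared_heldout_af, function(r) {
    g <- generate_ppg(shared_gan, r$ecg)
    interval_correlation(detect_r_peaks(r$ecg, 100), detect_ppg_peaks(g, 100))
  }, numeric(1))
  expect_gt(mean(cors), 0.8)
  expect_gt(min(cors), 0.8)
})
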