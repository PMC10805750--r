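ns <- asNamespace("ecg2ppg")

test_that("input affinities are normalized, symmetric, and match the formula transcription", {
  set.seed(2)
  x <- matrix(rnorm(10 * 4), 10, 4)
  aff <- compute_affinities(x, perplexity = 5)
  expect_lt(abs(sum(aff$p) - 1), 1e-10)
  expect_equal(aff$p, t(aff$p))
  expect_true(all(diag(aff$p) == 0))

  # brute-force evaluation of the conditional Gaussian at the calibrated
  # bandwidths, then the symmetrizing average
  n <- 10
  Pc <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) if (j != i)
      Pc[i, j] <- exp(-sum((x[i, ] - x[j, ])^2) / (2 * aff$sigma[i]^2))
    Pc[i, ] <- Pc[i, ] / sum(Pc[i, ])
  }
  expect_lt(max(abs((Pc + t(Pc)) / (2 * n) - aff$p)), 1e-12)

  # each conditional hits the target perplexity
  H <- apply(Pc, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  expect_lt(max(abs(exp(H) - 5)), 1e-3)

  # three equidistant points: all off-diagonal affinities equal
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  a3 <- suppressWarnings(compute_affinities(rbind(tri, tri + 100), perplexity = 2))
  off <- a3$p[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
  expect_lt(diff(range(off)), 1e-8)

  expect_error(compute_affinities(x, perplexity = 10), "perplexity")
  expect_error(compute_affinities(x[1:3, ]), "at least 5")
})

test_that("the analytic embedding gradient matches numerical differentiation of the KL cost", {
  set.seed(5)
  x <- matrix(rnorm(8 * 3), 8, 3)
  p <- compute_affinities(x, perplexity = 3)$p
  y <- matrix(rnorm(16) * 0.1, 8, 2)
  g <- ns$tsne_gradient(p, y)
  eps <- 1e-6
  for (i in 1:8) for (d in 1:2) {
    yp <- y; yp[i, d] <- yp[i, d] + eps
    ym <- y; ym[i, d] <- ym[i, d] - eps
    num <- (ns$tsne_cost(p, ns$lowdim_affinities(yp)$q) -
            ns$tsne_cost(p, ns$lowdim_affinities(ym)$q)) / (2 * eps)
    expect_lt(abs(g[i, d] - num), 1e-5)
  }
})

test_that("t-SNE keeps the KL cost finite and non-negative and separates distant clusters", {
  set.seed(6)
  X <- rbind(matrix(rnorm(50 * 50), 50, 50),
             matrix(rnorm(50 * 50, mean = 20), 50, 50))
  emb <- tsne_embed(X, perplexity = 15, iters = 300, seed = 4)
  expect_true(all(is.finite(emb$kl_history)))
  expect_true(all(emb$kl_history >= 0))
  # cost settles: non-increasing over the last 50 iterations (small numeric
  # slack for the momentum steps)
  expect_lt(max(diff(tail(emb$kl_history, 50))), 1e-6)
  expect_true(all(is.finite(emb$y)))

  lab <- rep(1:2, each = 50)
  mid <- (colMeans(emb$y[lab == 1, ]) + colMeans(emb$y[lab == 2, ])) / 2
  dirv <- colMeans(emb$y[lab == 2, ]) - colMeans(emb$y[lab == 1, ])
  proj <- as.numeric((emb$y - matrix(mid, 100, 2, byrow = TRUE)) %*% dirv)
  expect_true(all(proj[lab == 1] < 0) && all(proj[lab == 2] > 0))

  # seeded determinism
  emb2 <- tsne_embed(X, perplexity = 15, iters = 300, seed = 4)
  expect_identical(emb$y, emb2$y)
})

test_that("kernel density masses normalize and match the analytic normal integral", {
  set.seed(9)
  Y <- matrix(rnorm(20000), 10000, 2)
  kg <- kde2d_masses(Y, grid_n = 50)
  expect_lt(abs(sum(kg$mass) - 1), 1e-9)
  dx <- diff(kg$xs[1:2]); dy <- diff(kg$ys[1:2])
  ana <- outer(dnorm(kg$xs), dnorm(kg$ys)) * dx * dy
  expect_lt(max(abs(kg$mass - ana / sum(ana))), 0.005)
  # a tight cluster puts its mode at the centroid cell
  tight <- matrix(rnorm(200, sd = 0.01), 100, 2) +
    matrix(c(2, -1), 100, 2, byrow = TRUE)
  kt <- kde2d_masses(tight, grid_n = 40)
  peak <- which(kt$mass == max(kt$mass), arr.ind = TRUE)
  expect_lt(abs(kt$xs[peak[1]] - 2), 0.1)
  expect_lt(abs(kt$ys[peak[2]] + 1), 0.1)
  expect_warning(kde2d_masses(matrix(1, 50, 2), grid_n = 20), "degenerate")
})

test_that("Degree of Overlap: identity, disjoint supports, symmetry, and the half-overlap case", {
  set.seed(10)
  kg <- kde2d_masses(matrix(rnorm(400), 200, 2), grid_n = 40)
  expect_equal(degree_of_overlap(kg, kg), 1.0)

  lims <- c(-60, 60, -60, 60)
  ka <- kde2d_masses(matrix(rnorm(400, 0), 200, 2), 60, c(0.3, 0.3), lims)
  kb <- kde2d_masses(matrix(rnorm(400, 50), 200, 2), 60, c(0.3, 0.3), lims)
  expect_lt(degree_of_overlap(ka, kb), 1e-9)
  expect_equal(degree_of_overlap(ka, kb), degree_of_overlap(kb, ka))

  # uniform on A union B vs uniform on B, |A| = |B|: sqrt(1/2) by hand
  p1 <- matrix(0, 4, 4); p1[1:2, ] <- 1 / 16; p1[3:4, ] <- 1 / 16
  p2 <- matrix(0, 4, 4); p2[3:4, ] <- 1 / 8
  expect_equal(degree_of_overlap(p1, p2), sqrt(1 / 2), tolerance = 1e-12)
  # pure sum over cells: invariant under a common relabeling of cells
  perm <- sample(16)
  expect_equal(degree_of_overlap(matrix(p1[perm], 4, 4), matrix(p2[perm], 4, 4)),
               degree_of_overlap(p1, p2))
  expect_error(degree_of_overlap(p1, matrix(1 / 9, 3, 3)), "mismatch")
})

test_that("population overlap is near 1 for identical populations and lower for rhythm mismatch", {
  st_af <- slice_segments(cohort_pairs(6, af_frac = 1, seed = 81, id_prefix = "A"))
  st_af2 <- slice_segments(cohort_pairs(6, af_frac = 1, seed = 82, id_prefix = "B"))
  st_sr <- slice_segments(cohort_pairs(6, af_frac = 0, seed = 83, id_prefix = "C"))

  same <- population_overlap(st_af, st_af, perplexity = 10, iters = 120,
                             seed = 2, grid_n = 40, max_per_pop = 90)
  expect_gt(same$do, 0.99)

  afaf <- population_overlap(st_af, st_af2, perplexity = 10, iters = 120,
                             seed = 2, grid_n = 40, max_per_pop = 60)
  afsr <- population_overlap(st_af, st_sr, perplexity = 10, iters = 120,
                             seed = 2, grid_n = 40, max_per_pop = 60)
  expect_lt(afsr$do, afaf$do)

  rerun <- population_overlap(st_af, st_af2, perplexity = 10, iters = 120,
                              seed = 2, grid_n = 40, max_per_pop = 60)
  expect_identical(afaf$do, rerun$do)
})
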