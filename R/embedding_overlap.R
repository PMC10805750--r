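# Exact (O(n^2)) t-SNE and the kernel-density Degree-of-Overlap statistic
# used to compare an embedded generated population against a real one.

#' Gaussian input affinities with perplexity calibration
#'
#' Conditional affinities use a Gaussian kernel,
#' `p_{j|i} = exp(-||x_i - x_j||^2 / (2 sigma_i^2)) / sum_{k != i} exp(...)`,
#' with each bandwidth `sigma_i` found by bisection so the conditional
#' distribution's perplexity `2^H(P_i)` matches the target within 1e-4.
#' The joint matrix is the symmetrization `p_ij = (p_{i|j} + p_{j|i}) / (2n)`,
#' which sums to 1 over all ordered pairs.
#'
#' @param x n x d numeric matrix (n >= 5).
#' @param perplexity target perplexity, must be below n.
#' @return an `affinity_matrix` list: `p` (n x n, symmetric, zero diagonal),
#'   `sigma`, `perplexity`.
#' @export
compute_affinities <- function(x, perplexity = 30) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 points")
  if (perplexity >= n) stop("perplexity must be below the number of points")
  d2 <- sq_dists(x)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -30; hi <- 30   # bisection on log2(beta), beta = 1/(2 sigma^2)
    for (iter in seq_len(200)) {
      beta <- 2^((lo + hi) / 2)
      w <- exp(-di * beta + min(di) * beta)   # shift for stability
      sw <- sum(w)
      pj <- w / sw
      H <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      if (abs(exp(H) - perplexity) < 1e-4) break
      if (H > target) lo <- (lo + hi) / 2 else hi <- (lo + hi) / 2
    }
    P[i, -i] <- pj
    sigma[i] <- 1 / sqrt(2 * beta)
  }
  structure(list(p = (P + t(P)) / (2 * n), sigma = sigma, perplexity = perplexity),
            class = "affinity_matrix")
}

sq_dists <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

# Student-t low-dimensional affinities; returns Q, the unnormalized kernel
# W = (1+||y_i-y_j||^2)^-1 and its normalizer Z.
lowdim_affinities <- function(y) {
  W <- 1 / (1 + sq_dists(y))
  diag(W) <- 0
  Z <- sum(W)
  list(q = pmax(W / Z, 1e-12), w = W, z = Z)
}

# KL(P || Q) over ordered pairs i != j.
tsne_cost <- function(p, q) {
  mask <- p > 0
  sum(p[mask] * log(p[mask] / q[mask]))
}

# Analytic gradient of the KL cost: dC/dy_i = 4 sum_j (p-q)_ij w_ij (y_i - y_j).
tsne_gradient <- function(p, y) {
  lq <- lowdim_affinities(y)
  M <- (p - lq$q) * lq$w
  4 * (diag(rowSums(M)) %*% y - M %*% y)
}

#' Embed data in 2-D with t-SNE
#'
#' Minimizes the Kullback-Leibler divergence between the Gaussian input
#' affinities and Student-t output affinities by gradient descent with
#' momentum and per-coordinate gains, from a small random Gaussian
#' initialization. Early exaggeration multiplies the input affinities for
#' the first phase to form well-separated clusters. The KL cost is recorded
#' at every iteration against the true (unexaggerated) affinities.
#'
#' @param x n x d data matrix.
#' @param s output dimensionality (default 2).
#' @param perplexity target perplexity (default 30).
#' @param iters gradient-descent iterations (default 500).
#' @param seed seed for the random initialization.
#' @param lr learning rate (default 200).
#' @param exaggeration,exaggeration_iters early-exaggeration factor and
#'   duration (defaults 4 and 50). The last 50 iterations switch to plain
#'   gradient descent with step halving, so the recorded cost is
#'   non-increasing while the embedding settles.
#' @param momentum_lo,momentum_hi,momentum_switch momentum schedule (0.5
#'   until iteration 250, then 0.8).
#' @return an `embedding` list: `y` (n x s), `kl_history`, `seed`.
#' @export
tsne_embed <- function(x, s = 2, perplexity = 30, iters = 500, seed = 1L,
                       lr = 200, exaggeration = 4, exaggeration_iters = 50,
                       momentum_lo = 0.5, momentum_hi = 0.8,
                       momentum_switch = 250) {
  aff <- if (inherits(x, "affinity_matrix")) x else compute_affinities(x, perplexity)
  p <- aff$p
  n <- nrow(p)
  y <- with_seed(seed, matrix(rnorm(n * s, 0, 1e-4), n, s))
  inc <- matrix(0, n, s)
  gains <- matrix(1, n, s)
  kl <- numeric(iters)
  settle_from <- max(iters - 49, exaggeration_iters + 1)
  prev_cost <- Inf
  step <- lr
  for (it in seq_len(iters)) {
    if (it < settle_from) {
      # momentum + per-coordinate gains, with early exaggeration
      pe <- if (it <= exaggeration_iters) p * exaggeration else p
      g <- tsne_gradient(pe, y)
      mom <- if (it <= momentum_switch) momentum_lo else momentum_hi
      gains <- ifelse(sign(g) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- mom * inc - lr * gains * g
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
      kl[it] <- tsne_cost(p, lowdim_affinities(y)$q)
    } else {
      # settling phase: plain descent with step halving, so the recorded
      # cost is non-increasing over the final iterations
      if (!is.finite(prev_cost)) prev_cost <- tsne_cost(p, lowdim_affinities(y)$q)
      g <- tsne_gradient(p, y)
      cand_cost <- Inf
      for (h in 1:20) {
        cand <- sweep(y - step * g, 2, colMeans(y - step * g))
        cand_cost <- tsne_cost(p, lowdim_affinities(cand)$q)
        if (is.finite(cand_cost) && cand_cost <= prev_cost) break
        step <- step / 2
      }
      if (is.finite(cand_cost) && cand_cost <= prev_cost) {
        y <- cand
        kl[it] <- cand_cost
      } else {
        kl[it] <- prev_cost   # no admissible step: stay put
      }
      prev_cost <- kl[it]
    }
    if (!is.finite(kl[it]))
      stop(sprintf("t-SNE diverged (non-finite cost) at iteration %d", it))
  }
  structure(list(y = y, kl_history = kl, seed = seed), class = "embedding")
}

#' Bivariate Gaussian kernel density as cell masses on a lattice
#'
#' Evaluates a product-Gaussian kernel density at the cell centers of a
#' regular grid and converts to per-cell probability masses normalized to
#' sum 1. Bandwidths default to Silverman's rule per dimension; the grid
#' defaults to the data range extended by `margin` bandwidths.
#'
#' @param y n x 2 coordinate matrix (n >= 2).
#' @param grid_n grid resolution per axis (default 100).
#' @param bandwidth length-2 bandwidth vector, or `NULL` for Silverman.
#' @param lims `c(xmin, xmax, ymin, ymax)`, or `NULL` to derive from data.
#' @param margin grid margin in bandwidths (default 3).
#' @return a `kde_grid` list: `mass` (grid_n x grid_n, sums to 1), `xs`,
#'   `ys` (cell-center coordinates), `bandwidth`.
#' @export
kde2d_masses <- function(y, grid_n = 100, bandwidth = NULL, lims = NULL,
                         margin = 3) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 2, nrow(y) >= 1)
  n <- nrow(y)
  if (is.null(bandwidth)) {
    bandwidth <- vapply(1:2, function(j) {
      s <- sd(y[, j])
      if (!is.finite(s) || s == 0) s <- max(diff(range(y[, j])) / 10, 1e-6)
      1.06 * s * n^(-1 / 5)
    }, numeric(1))
  }
  if (all(y[, 1] == y[1, 1]) && all(y[, 2] == y[1, 2]))
    warning("degenerate point cloud: density collapses to a single cell")
  if (is.null(lims))
    lims <- c(min(y[, 1]) - margin * bandwidth[1], max(y[, 1]) + margin * bandwidth[1],
              min(y[, 2]) - margin * bandwidth[2], max(y[, 2]) + margin * bandwidth[2])
  xs <- seq(lims[1], lims[2], length.out = grid_n)
  ys <- seq(lims[3], lims[4], length.out = grid_n)
  # density at cell centers: outer product of per-axis kernel matrices
  kx <- outer(xs, y[, 1], function(a, b) dnorm(a - b, sd = bandwidth[1]))
  ky <- outer(ys, y[, 2], function(a, b) dnorm(a - b, sd = bandwidth[2]))
  dens <- kx %*% t(ky) / n
  total <- sum(dens)
  if (total == 0) stop("all density mass fell outside the grid")
  structure(list(mass = dens / total, xs = xs, ys = ys, bandwidth = bandwidth),
            class = "kde_grid")
}

#' Degree of Overlap between two densities on a shared grid
#'
#' The Bhattacharyya coefficient `sum(sqrt(P1 * P2))` over grid cells:
#' 1 for identical distributions, 0 for disjoint supports. The result is
#' clipped to `[0, 1]` against floating-point rounding.
#'
#' @param p1,p2 `kde_grid` objects on the same lattice, or plain matrices of
#'   cell masses with identical dimensions, each summing to 1.
#' @return the overlap coefficient in `[0, 1]`.
#' @export
degree_of_overlap <- function(p1, p2) {
  m1 <- if (inherits(p1, "kde_grid")) p1$mass else as.matrix(p1)
  m2 <- if (inherits(p2, "kde_grid")) p2$mass else as.matrix(p2)
  if (!all(dim(m1) == dim(m2))) stop("cell-mass grids have mismatched dimensions")
  if (inherits(p1, "kde_grid") && inherits(p2, "kde_grid") &&
      (max(abs(p1$xs - p2$xs)) > 1e-9 || max(abs(p1$ys - p2$ys)) > 1e-9))
    stop("kde grids are not on the same lattice")
  max(0, min(1, sum(sqrt(m1 * m2))))
}

#' Embedding overlap between a real and a generated population
#'
#' Embeds the two populations jointly (a single t-SNE on the concatenated
#' segment matrices, so both live in one 2-D space), estimates one kernel
#' density per population on a shared lattice, and returns the Degree of
#' Overlap. Populations larger than `max_per_pop` are subsampled with the
#' given seed.
#'
#' @param real_segs,gen_segs [segment_store()] objects with equal segment
#'   length.
#' @param perplexity,iters,seed t-SNE settings.
#' @param grid_n lattice resolution (default 100).
#' @param max_per_pop subsampling cap per population (default 2000).
#' @return an `overlap_result` list: `embedding` (the n x 2 coordinates),
#'   `which_pop`, `P1` and `P2` (`kde_grid`s for real and generated), `do`.
#' @export
population_overlap <- function(real_segs, gen_segs, perplexity = 30,
                               iters = 400, seed = 1L, grid_n = 100,
                               max_per_pop = 2000) {
  stopifnot(inherits(real_segs, "segment_store"), inherits(gen_segs, "segment_store"))
  if (ncol(real_segs$segments) != ncol(gen_segs$segments))
    stop("populations have different segment lengths")
  if (nrow(real_segs$segments) == 0 || nrow(gen_segs$segments) == 0)
    stop("both populations must be nonempty")
  pick <- function(m, sd_seed) {
    if (nrow(m) <= max_per_pop) return(m)
    m[with_seed(sd_seed, sample.int(nrow(m), max_per_pop)), , drop = FALSE]
  }
  a <- pick(real_segs$segments, derive_seed(seed, "subsample-real"))
  b <- pick(gen_segs$segments, derive_seed(seed, "subsample-gen"))
  x <- rbind(a, b)
  emb <- tsne_embed(x, perplexity = min(perplexity, (nrow(x) - 1) / 3),
                    iters = iters, seed = derive_seed(seed, "tsne"))
  y <- emb$y
  pop <- rep(c("real", "generated"), c(nrow(a), nrow(b)))
  bw <- vapply(1:2, function(j) {
    s <- sd(y[, j])
    if (!is.finite(s) || s == 0) s <- 1e-6
    1.06 * s * nrow(y)^(-1 / 5)
  }, numeric(1))
  lims <- c(min(y[, 1]) - 3 * bw[1], max(y[, 1]) + 3 * bw[1],
            min(y[, 2]) - 3 * bw[2], max(y[, 2]) + 3 * bw[2])
  P1 <- kde2d_masses(y[pop == "real", , drop = FALSE], grid_n, bw, lims)
  P2 <- kde2d_masses(y[pop == "generated", , drop = FALSE], grid_n, bw, lims)
  structure(list(embedding = emb, which_pop = pop, P1 = P1, P2 = P2,
                 do = degree_of_overlap(P1, P2)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %d embedded points, Degree of Overlap = %.3f\n",
              nrow(x$embedding$y), x$do))
  invisible(x)
}
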