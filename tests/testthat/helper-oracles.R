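# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; no binary fixtures.

rand_spd <- function(k, scale = 1) {
  A <- matrix(rnorm(k * k), k, k)
  crossprod(A) / k * scale + diag(0.1 * scale, k)
}

rand_belief <- function(space, support = rep(TRUE, space$M)) {
  M <- space$M
  mean <- rnorm(M)
  cov <- matrix(0, M, M)
  k <- sum(support)
  if (k) cov[support, support] <- rand_spd(k)
  gaussian_belief(space, mean, cov, support)
}

# random linear-Gaussian problem with a nested reduced prior; returns the
# full conjugate inversion and a conjugate oracle for the reduced model
rand_linear_problem <- function(D = 20, M = 5, off = 0) {
  sp <- parameter_space(paste0("t", seq_len(M)))
  A <- matrix(rnorm(D * M), D, M)
  prior <- gaussian_belief(sp, rnorm(M, 0, 0.5), diag(runif(M, 0.3, 2)))
  nv <- runif(1, 0.05, 0.5)
  theta <- drop(rmvnorm_chol_test(1, prior$mean, prior$cov))
  y <- drop(A %*% theta) + rnorm(D, 0, sqrt(nv))
  full <- conjugate_invert(A, y, prior, diag(nv, D))

  supp <- rep(TRUE, M)
  off <- min(off, M - 1)   # keep at least one live dimension
  if (off > 0) supp[sample.int(M, off)] <- FALSE
  rmean <- prior$mean + rnorm(M, 0, 0.2)
  rcov <- prior$cov * runif(1, 0.3, 1)
  reduced <- gaussian_belief(sp, rmean, rcov, supp)

  # oracle: direct conjugate inversion under the reduced prior
  keep <- which(supp); offi <- which(!supp)
  y2 <- y - if (length(offi)) drop(A[, offi, drop = FALSE] %*% rmean[offi]) else 0
  sp2 <- parameter_space(paste0("t", keep))
  p2 <- gaussian_belief(sp2, rmean[keep], rcov[keep, keep, drop = FALSE])
  oracle <- conjugate_invert(A[, keep, drop = FALSE], y2, p2, diag(nv, D))
  list(sp = sp, A = A, y = y, nv = nv, prior = prior, full = full,
       reduced = reduced, keep = keep, oracle = oracle)
}

# local sampler so the helper does not depend on package internals
rmvnorm_chol_test <- function(n, mean, cov) {
  k <- length(mean)
  R <- chol(cov + diag(1e-12, k))
  sweep(matrix(rnorm(n * k), n, k) %*% R, 2, mean, "+")
}

# 1-D KL(q||p) by adaptive quadrature (independent of the closed form)
kl_quadrature_1d <- function(mq, vq, mp, vp) {
  f <- function(x) {
    lq <- dnorm(x, mq, sqrt(vq), log = TRUE)
    lp <- dnorm(x, mp, sqrt(vp), log = TRUE)
    exp(lq) * (lq - lp)
  }
  integrate(f, mq - 12 * sqrt(vq), mq + 12 * sqrt(vq),
            rel.tol = 1e-10)$value
}

# small, fast synthetic study for module tests
small_sim <- function(seed = 1, ...) {
  simulate_group_study(simulation_config(
    n_per_group = 4, block_sizes = c(forward = 1, backward = 1, intrinsic = 2),
    n_obs = 16, seed = seed, ...))
}
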