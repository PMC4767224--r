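test_that("second_level_model validates the design", {
  expect_error(second_level_model(matrix(c(0, 0, 1, 1), 2)), "constant")
  X <- cbind(1, c(1, 1))
  expect_error(second_level_model(X), "rank deficient")
  slm <- second_level_model(cbind(mean = 1, group = c(-1, 1)))
  expect_s3_class(slm, "second_level_model")
})

test_that("an identity empirical prior recovers F_full plus prior terms", {
  set.seed(30)
  sim <- small_sim(seed = 6)
  sub <- fit_group(sim, exact = TRUE)[[1]]
  slm <- second_level_model(matrix(1, 1, 1))
  # gamma such that Q0 + exp(-gamma) Q1 = prior precision:
  # (1/16 + 16 exp(-gamma)) = 1  =>  gamma = -log(15/256)
  g <- -log(15 / 256)
  f2 <- second_level_free_energy(list(sub), slm, beta = sim$prior$mean,
                                 gamma = g)
  expect_equal(f2, sub$evidence$F - 0.5 * g^2, tolerance = 1e-6)
})

test_that("identical subjects with a constant design pool to their mean", {
  set.seed(31)
  sp <- parameter_space(paste0("t", 1:3))
  # near-flat first-level prior, so the posterior mean is the ML estimate
  # and the pooled beta must land on it (a shrunk posterior would be
  # un-shrunk by the empirical-prior replacement)
  prior <- gaussian_belief(sp, 0, 1e4)
  m <- c(0.4, -0.2, 0.1)
  post <- gaussian_belief(sp, m, diag(0.05, 3))
  subs <- replicate(4, structure(
    list(data = NULL, model = NULL, full_prior = prior, full_posterior = post,
         hyper_posterior = NULL, evidence = evidence_record(0, 0),
         trace = 0, converged = TRUE), class = "subject_inversion"),
    simplify = FALSE)
  bspace <- parameter_space(paste0("mean:c", 1:3))
  slm <- second_level_model(matrix(1, 4, 1),
                            beta_prior = gaussian_belief(bspace, 0, 1e8))
  fit <- suppressWarnings(peb_invert(subs, slm))
  expect_lt(max(abs(fit$beta$mean - m)), 1e-3)
})

test_that("PEB equals the collapsed GLS oracle for linear first levels", {
  sim <- simulate_group_study(simulation_config(seed = 3))
  subs <- fit_group(sim, exact = TRUE)
  X <- sim$X
  fit <- peb_invert(subs, second_level_model(X), opts = list(fix_gamma = 0))
  M <- sim$space$M; B <- ncol(X)
  bv <- sim$config$prior_var / 16
  Pib <- diag(1 / rep(sim$config$prior_var, B * M))
  H <- Pib; h <- rep(0, B * M)
  for (i in seq_along(subs)) {
    Ai <- sim$A[[i]]
    nv <- (sd(drop(Ai %*% sim$theta_true[i, ])) *
             sim$config$noise_sd_ratio)^2
    Ti <- kronecker(matrix(X[i, ], 1, B), diag(M))
    Vi <- Ai %*% diag(bv, M) %*% t(Ai) + diag(nv, nrow(Ai))
    G <- Ai %*% Ti
    iVG <- solve(Vi, G)
    H <- H + crossprod(G, iVG)
    h <- h + drop(crossprod(iVG, sim$y[[i]]))
  }
  beta_gls <- solve(H, h)
  expect_lt(max(abs(fit$beta$mean - beta_gls)), 1e-3)
  # fix_gamma = 0 matches the generative between-variance exactly:
  # the posterior covariance should agree with the GLS covariance too
  expect_lt(max(abs(fit$beta$cov - solve(H))), 1e-3)
})

test_that("the objective trace is non-decreasing and the precision SPD", {
  for (s in 1:5) {
    sim <- small_sim(seed = 40 + s)
    subs <- fit_group(sim, exact = TRUE)
    fit <- suppressWarnings(peb_invert(subs, second_level_model(sim$X)))
    expect_gte(min(diff(fit$trace)), -1e-8)
    ev <- eigen(fit$joint$P, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("shrinkage pulls random effects toward the empirical prior mean", {
  set.seed(32)
  sim <- small_sim(seed = 7)
  subs <- fit_group(sim, exact = TRUE)
  fit <- suppressWarnings(peb_invert(subs, second_level_model(sim$X)))
  # identity: empirical prior = full prior leaves the posterior unchanged
  sub <- subs[[1]]
  same <- apply_shrinkage(sub, sub$full_prior)
  expect_equal(same$mean, sub$full_posterior$mean, tolerance = 1e-8)
  # limit: tiny empirical variance pins the posterior at the prior mean
  ep <- fit$empirical_priors[[1]]
  tiny <- gaussian_belief(ep$space, ep$mean, diag(1e-10, ep$space$M))
  pinned <- apply_shrinkage(sub, tiny)
  expect_lt(max(abs(pinned$mean - ep$mean)), 1e-3)
  # Mahalanobis contraction for every subject under the fitted priors
  S2inv <- belief_precision(fit$empirical_priors[[1]])
  for (i in seq_along(subs)) {
    d0 <- subs[[i]]$full_posterior$mean - fit$empirical_priors[[i]]$mean
    d1 <- fit$shrunk_posteriors[[i]]$mean - fit$empirical_priors[[i]]$mean
    expect_lte(drop(crossprod(d1, S2inv %*% d1)),
               drop(crossprod(d0, S2inv %*% d0)) + 1e-9)
  }
  # 1-D: the shrunk mean lies strictly between MAP and group mean
  sp1 <- parameter_space("t")
  pr1 <- gaussian_belief(sp1, 0, 1)
  po1 <- gaussian_belief(sp1, 1, 0.25)
  sub1 <- structure(list(full_prior = pr1, full_posterior = po1,
                         evidence = evidence_record(0, 0)),
                    class = "subject_inversion")
  ep1 <- gaussian_belief(sp1, 0.2, 0.5)
  sh <- apply_shrinkage(sub1, ep1)
  expect_true(sh$mean > 0.2 && sh$mean < 1)
})

test_that("an identity third level leaves beta unchanged", {
  # pinning between-level covariance + the shared prior as third-level
  # prior: for a single pseudo-subject this must be a no-op on beta
  sim <- small_sim(seed = 8)
  subs <- fit_group(sim, exact = TRUE)
  fit <- suppressWarnings(peb_invert(subs, second_level_model(sim$X)))
  BC <- fit$beta$space$M
  pin <- second_level_model(
    matrix(1, 1, 1),
    Q0 = diag(1e8, BC), Q = list(diag(BC)),
    beta_prior = gaussian_belief(parameter_space(paste0("b", 1:BC)),
                                 fit$ctx$beta_prior$mean,
                                 fit$ctx$beta_prior$cov))
  fit3 <- suppressWarnings(peb_recursive(fit, pin,
                                         opts = list(fix_gamma = 32)))
  expect_lt(max(abs(fit3$beta$mean - fit$beta$mean)), 1e-5)
})

test_that("a pinning third level pools two groups like BPA", {
  sim <- small_sim(seed = 9)
  subs <- fit_group(sim, exact = TRUE)
  slm1 <- second_level_model(matrix(1, 4, 1))
  fa <- suppressWarnings(peb_invert(subs[1:4], slm1))
  fb <- suppressWarnings(peb_invert(subs[5:8], slm1))
  BC <- fa$beta$space$M
  # Sigma2 -> 0 forces a common beta; with the shared beta prior as the
  # third-level prior this is exactly Bayesian parameter averaging
  pin <- second_level_model(
    matrix(1, 2, 1),
    Q0 = diag(1e8, BC), Q = list(diag(BC)),
    beta_prior = gaussian_belief(parameter_space(paste0("b", 1:BC)),
                                 fa$ctx$beta_prior$mean,
                                 fa$ctx$beta_prior$cov))
  pseudo <- lapply(list(fa, fb), as_subject_inversion)
  fit3 <- suppressWarnings(peb_invert(pseudo, pin,
                                      opts = list(fix_gamma = 32)))
  fused <- bpa(list(fa$beta, fb$beta), fa$ctx$beta_prior)
  expect_lt(max(abs(fit3$beta$mean - fused$mean)), 5e-3)
})
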