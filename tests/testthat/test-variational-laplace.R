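test_that("linear inversion is exactly conjugate", {
  set.seed(10)
  for (rep in 1:5) {
    pr <- rand_linear_problem(D = 20, M = 5)
    hp <- gaussian_belief(parameter_space("lambda1"), log(1 / pr$nv), 1e-10)
    vl <- invert_laplace(linear_model(pr$sp, pr$A), pr$y, pr$prior, hp,
                         opts = list(fix_hyper = TRUE, tol = 1e-9))
    expect_true(vl$converged)
    expect_lt(max(abs(vl$full_posterior$mean - pr$full$full_posterior$mean)),
              1e-6)
    expect_lt(max(abs(vl$full_posterior$cov - pr$full$full_posterior$cov)),
              1e-6)
    expect_equal(vl$evidence$F, pr$full$evidence$F, tolerance = 1e-6)
  }
})

test_that("free energy decomposes and is zero-complexity at the prior", {
  set.seed(11)
  sp <- parameter_space(c("a", "b"))
  A <- matrix(rnorm(12), 6, 2)
  m <- linear_model(sp, A)
  prior <- gaussian_belief(sp, c(0.2, -0.1), diag(2))
  hp <- gaussian_belief(parameter_space("lambda1"), 0, 1 / 16)
  y <- drop(A %*% prior$mean)
  ev <- free_energy(m, y, prior, prior, hp, hp)
  expect_equal(ev$complexity, 0)
  expect_equal(ev$F, ev$accuracy - ev$complexity, tolerance = 1e-10)
  # accuracy = log N(y; g, Sigma) - tr(C J' iS J)/2, computed independently
  S <- diag(exp(0), 6)
  manual <- sum(dnorm(y, drop(A %*% prior$mean), 1, log = TRUE)) -
    0.5 * sum(prior$cov * crossprod(A, A))
  expect_equal(ev$accuracy, manual, tolerance = 1e-10)
})

test_that("doubling the noise precision moves accuracy by the determinant term", {
  set.seed(12)
  sp <- parameter_space("a")
  A <- matrix(rnorm(8), 8, 1)
  m <- linear_model(sp, A)
  prior <- gaussian_belief(sp, 0, 1)
  q <- gaussian_belief(sp, 0.4, 0.2)
  hs <- parameter_space("lambda1")
  hp <- gaussian_belief(hs, 0, 1e-12)
  y <- drop(A %*% 0.5) + rnorm(8, 0, 0.5)
  a1 <- free_energy(m, y, prior, q, gaussian_belief(hs, 0, 1e-12), hp)$accuracy
  a2 <- free_energy(m, y, prior, q, gaussian_belief(hs, log(2), 1e-12), hp)$accuracy
  r <- y - drop(A %*% q$mean)
  quad_change <- -0.5 * sum(r^2) * (2 - 1) -
    0.5 * drop(q$cov) * sum(A^2) * (2 - 1)
  # D ln2 / 2 from the determinant, minus the quadratic-term change
  expect_equal(a2 - a1, 8 * log(2) / 2 + quad_change, tolerance = 1e-8)
})

test_that("nonlinear MAP matches a brute-force optimiser", {
  set.seed(13)
  x <- seq(-2, 2, length.out = 40)
  sp <- parameter_space(c("amp", "slope"))
  sig <- function(u) 1 / (1 + exp(-u))
  pred <- function(theta) theta[1] * sig(theta[2] * x)
  m <- nonlinear_model(sp, pred, noise_components = list(diag(40)))
  prior <- gaussian_belief(sp, c(1, 1), diag(c(1, 1)))
  nv <- 0.05
  y <- 1.4 * sig(0.8 * x) + rnorm(40, 0, sqrt(nv))
  hp <- gaussian_belief(parameter_space("lambda1"), log(1 / nv), 1e-10)
  vl <- invert_laplace(m, y, prior, hp, opts = list(fix_hyper = TRUE,
                                                    tol = 1e-10))
  neg_log_post <- function(theta) {
    r <- y - pred(theta)
    0.5 * sum(r^2) / nv + 0.5 * sum((theta - prior$mean)^2)
  }
  map <- optim(c(1, 1), neg_log_post, method = "BFGS",
               control = list(reltol = 1e-14))$par
  # the converged mode is the stationary point of F, which sits close to
  # (but, through the curvature terms, not exactly at) the MAP
  expect_lt(max(abs(vl$full_posterior$mean - map)), 0.02)
  # oracle for the stated fixed point: brute-force maximisation of F with
  # the covariance profiled, from an independent optimiser and start
  fstar <- function(theta) {
    S <- diag(nv, 40)
    J <- pebr:::num_jacobian(pred, theta)
    C <- solve(crossprod(J, J) / nv + diag(2))
    q <- gaussian_belief(sp, theta, C)
    -free_energy(m, y, prior, q, gaussian_belief(parameter_space("lambda1"),
                                                 log(1 / nv), 1e-10),
                 hp)$F
  }
  fmax <- optim(c(0.5, 0.5), fstar, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 2000))$par
  expect_lt(max(abs(vl$full_posterior$mean - fmax)), 1e-4)
})

test_that("the free-energy trace is non-decreasing on random problems", {
  set.seed(14)
  worst <- 0
  for (rep in 1:100) {
    D <- 8; M <- 2
    sp <- parameter_space(paste0("t", 1:M))
    A <- matrix(rnorm(D * M), D, M)
    pred <- function(theta) tanh(drop(A %*% theta))
    m <- nonlinear_model(sp, pred, noise_components = list(diag(D)),
                         jacobian = function(theta) {
                           u <- drop(A %*% theta)
                           (1 / cosh(u)^2) * A
                         })
    prior <- gaussian_belief(sp, 0, 0.5)
    y <- pred(rnorm(M, 0, 0.5)) + rnorm(D, 0, 0.2)
    vl <- suppressWarnings(
      invert_laplace(m, y, prior, gaussian_belief(parameter_space("lambda1"),
                                                  0, 1),
                     opts = list(max_iter = 32)))
    worst <- min(worst, min(diff(vl$trace)))
  }
  expect_gte(worst, -1e-9)
})

test_that("finite-difference and analytic Jacobians agree", {
  set.seed(15)
  D <- 10; M <- 3
  A <- matrix(rnorm(D * M), D, M)
  pred <- function(theta) tanh(drop(A %*% theta))
  jac <- function(theta) (1 / cosh(drop(A %*% theta))^2) * A
  theta <- rnorm(M)
  Jn <- pebr:::num_jacobian(pred, theta)
  Ja <- jac(theta)
  expect_lt(max(abs(Jn - Ja)) / max(abs(Ja)), 1e-5)
})

test_that("hyperparameters are estimated when free", {
  set.seed(16)
  pr <- rand_linear_problem(D = 60, M = 3)
  hp <- gaussian_belief(parameter_space("lambda1"), 0, 16)
  vl <- suppressWarnings(invert_laplace(linear_model(pr$sp, pr$A), pr$y,
                                        pr$prior, hp))
  # recovered log precision within a nat of the truth at D = 60
  expect_lt(abs(vl$hyper_posterior$mean - log(1 / pr$nv)), 1)
  expect_error(invert_laplace(linear_model(pr$sp, pr$A), c(pr$y[-1], NaN),
                              pr$prior, hp), "finite")
})
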