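test_that("identity and uninformative reductions return delta_F = 0", {
  set.seed(20)
  sp <- parameter_space(paste0("t", 1:4))
  prior <- rand_belief(sp)
  post <- rand_belief(sp)
  r <- bmr_reduce(prior, post, prior, F_full = 3.5)
  expect_equal(r$delta_F, 0, tolerance = 1e-10)
  expect_equal(r$F_R, 3.5, tolerance = 1e-10)
  expect_equal(r$reduced_posterior$mean, post$mean, tolerance = 1e-8)
  expect_equal(unname(r$reduced_posterior$cov), unname(post$cov),
               tolerance = 1e-8)
  # uninformative data: posterior = prior -> reduced posterior = reduced prior
  rp <- gaussian_belief(sp, prior$mean + 0.3, prior$cov * 0.5)
  r2 <- bmr_reduce(prior, prior, rp)
  expect_equal(r2$delta_F, 0, tolerance = 1e-8)
  expect_equal(r2$reduced_posterior$mean, rp$mean, tolerance = 1e-8)
  expect_equal(unname(r2$reduced_posterior$cov), unname(rp$cov),
               tolerance = 1e-8)
})

test_that("the 1-D worked example reproduces its conjugate oracle", {
  sp <- parameter_space("t")
  fp <- gaussian_belief(sp, 0, 1)
  fq <- gaussian_belief(sp, 0.5, 0.5)
  rp <- gaussian_belief(sp, 0, 0.25)
  r <- bmr_reduce(fp, fq, rp)
  expect_equal(r$reduced_posterior$mean, 0.2, tolerance = 1e-10)
  expect_equal(drop(r$reduced_posterior$cov), 0.2, tolerance = 1e-10)
  expect_equal(r$delta_F, 0.5 * log(1.6) - 0.15, tolerance = 1e-10)
  # oracle: y = 1 observed with unit noise; evidence ratio of the two priors
  expect_equal(r$delta_F,
               dnorm(1, 0, sqrt(1.25), log = TRUE) -
                 dnorm(1, 0, sqrt(2), log = TRUE), tolerance = 1e-10)
})

test_that("linear-Gaussian reductions are exact against direct inversion", {
  set.seed(21)
  for (rep in 1:20) {
    off <- sample(0:2, 1)
    pr <- rand_linear_problem(D = sample(10:25, 1), M = sample(3:7, 1),
                              off = off)
    r <- bmr_reduce(pr$full$full_prior, pr$full$full_posterior, pr$reduced,
                    pr$full$evidence$F)
    expect_lt(abs(r$F_R - pr$oracle$evidence$F), 1e-6)
    expect_lt(max(abs(r$reduced_posterior$mean[pr$keep] -
                        pr$oracle$full_posterior$mean)), 1e-6)
    expect_lt(max(abs(r$reduced_posterior$cov[pr$keep, pr$keep] -
                        pr$oracle$full_posterior$cov)), 1e-6)
  }
})

test_that("reduction is equivariant under parameter permutation", {
  set.seed(22)
  pr <- rand_linear_problem(D = 15, M = 5, off = 1)
  r <- bmr_reduce(pr$full$full_prior, pr$full$full_posterior, pr$reduced)
  perm <- sample(5)
  spp <- parameter_space(paste0("t", seq_len(5)))
  permute <- function(b) gaussian_belief(spp, b$mean[perm],
                                         b$cov[perm, perm], b$support[perm])
  rp <- bmr_reduce(permute(pr$full$full_prior),
                   permute(pr$full$full_posterior), permute(pr$reduced))
  expect_equal(rp$delta_F, r$delta_F, tolerance = 1e-8)
  expect_equal(rp$reduced_posterior$mean, r$reduced_posterior$mean[perm],
               tolerance = 1e-8)
})

test_that("delta_F differences equal conjugate log evidence ratios", {
  set.seed(23)
  pr <- rand_linear_problem(D = 20, M = 5)
  mk <- function(scale) gaussian_belief(pr$sp, pr$prior$mean,
                                        pr$prior$cov * scale)
  ra <- bmr_reduce(pr$full$full_prior, pr$full$full_posterior, mk(0.5))
  rb <- bmr_reduce(pr$full$full_prior, pr$full$full_posterior, mk(0.25))
  ora <- conjugate_invert(pr$A, pr$y, mk(0.5), diag(pr$nv, 20))
  orb <- conjugate_invert(pr$A, pr$y, mk(0.25), diag(pr$nv, 20))
  expect_equal(ra$delta_F - rb$delta_F,
               ora$evidence$F - orb$evidence$F, tolerance = 1e-6)
})

test_that("the large-precision fallback agrees with subspace restriction", {
  set.seed(24)
  pr <- rand_linear_problem(D = 20, M = 6, off = 2)
  r1 <- bmr_reduce(pr$full$full_prior, pr$full$full_posterior, pr$reduced)
  r2 <- bmr_reduce(pr$full$full_prior, pr$full$full_posterior, pr$reduced,
                   off_method = "precision")
  # the fallback's delta_F error scales with posterior precision x 2^-32,
  # so agreement in F is problem-dependent around 1e-5; means are tighter
  expect_lt(abs(r1$delta_F - r2$delta_F), 1e-4)
  expect_lt(max(abs(r1$reduced_posterior$mean - r2$reduced_posterior$mean)),
            1e-6)
})

test_that("incompatible reductions are reported with the offending direction", {
  sp <- parameter_space("t")
  prior <- gaussian_belief(sp, 0, 1)
  post <- gaussian_belief(sp, 0, 5)    # inconsistent: posterior wider
  rp <- gaussian_belief(sp, 0, 100)
  expect_error(bmr_reduce(prior, post, rp), "not positive definite")
  # nesting violation
  sp2 <- parameter_space(c("a", "b"))
  p2 <- gaussian_belief(sp2, 0, diag(c(1, 0)))
  q2 <- gaussian_belief(sp2, 0, diag(c(0.5, 0)))
  r2 <- gaussian_belief(sp2, 0, diag(c(1, 1)))
  expect_error(bmr_reduce(p2, q2, r2), "nesting violation")
})

test_that("bmr_point equals the Savage-Dickey ratio and the variance limit", {
  sp <- parameter_space("t")
  fp <- gaussian_belief(sp, 0, 1)
  fq <- gaussian_belief(sp, 0.5, 0.5)
  expect_equal(bmr_point(fp, fp, 1, 0)$delta_F, 0, tolerance = 1e-10)
  r <- bmr_point(fp, fq, 1, 0)
  expect_equal(r$delta_F, 0.5 * log(2) - 0.25, tolerance = 1e-10)
  expect_equal(r$delta_F,
               dnorm(0, 0.5, sqrt(0.5), log = TRUE) - dnorm(0, 0, 1, log = TRUE),
               tolerance = 1e-12)
  # limit agreement across shrinking variances
  set.seed(25)
  pr <- rand_linear_problem(D = 15, M = 4)
  idx <- c(2, 4); vals <- c(0.1, -0.3)
  point <- bmr_point(pr$full$full_prior, pr$full$full_posterior, idx, vals)
  errs <- vapply(c(1e-5, 1e-8, 1e-12), function(v) {
    cv <- pr$full$full_prior$cov
    cv[idx, ] <- 0; cv[, idx] <- 0; diag(cv)[idx] <- v
    mn <- pr$full$full_prior$mean; mn[idx] <- vals
    rp <- gaussian_belief(pr$sp, mn, cv)
    rr <- bmr_reduce(pr$full$full_prior, pr$full$full_posterior, rp)
    abs(rr$delta_F - point$delta_F)
  }, 0)
  expect_true(all(diff(errs) < 0))      # monotone approach to the limit
  expect_lt(errs[3], 1e-5)              # agreement at variance 1e-12
  expect_error(bmr_point(gaussian_belief(sp, 0, 0), fq, 1, 0), "off the")
})

test_that("score_model_set scores whole lattices and keeps the full model", {
  set.seed(26)
  sim <- small_sim(seed = 4)
  sub <- fit_group(sim, exact = TRUE)[[1]]
  full_only <- list(model_definition("full", sim$prior))
  s1 <- score_model_set(sub, full_only)
  expect_equal(nrow(s1$table), 1)
  expect_equal(s1$table$delta_F, 0, tolerance = 1e-8)
  ms <- make_model_space(sim$prior, sim$blocks)
  s8 <- score_model_set(sub, ms)
  expect_equal(nrow(s8$table), 8)
  expect_true(all(is.finite(s8$table$F_R)))
  # every reduced model nests: the one with no support removed is the full
  expect_equal(s8$table$delta_F[1], 0, tolerance = 1e-8)
})
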