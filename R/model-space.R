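softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Build a subjects-by-models array of reductions
#'
#' Applies [score_model_set()] to every subject, giving the `N x K` free
#' energy matrix and posterior grid that the comparison operators work on.
#' By convention the full model occupies the first column.
#'
#' @param subjects list of `subject_inversion` objects.
#' @param models list of [model_definition()] objects (first = full model).
#' @return an object of class `model_array`: `F` (`N x K` matrix),
#'   `posteriors` (list of lists of [gaussian_belief()]), `models`,
#'   `subjects`.
#' @export
model_array <- function(subjects, models) {
  scored <- lapply(subjects, score_model_set, models = models)
  Fmat <- do.call(rbind, lapply(scored, function(s) s$table$F_R))
  colnames(Fmat) <- vapply(models, `[[`, "", "name")
  if (any(!is.finite(Fmat))) stop("non-finite free energy in model array")
  posts <- lapply(scored, function(s)
    lapply(s$results, `[[`, "reduced_posterior"))
  structure(list(F = Fmat, posteriors = posts, models = models,
                 subjects = subjects),
            class = "model_array")
}

#' Fixed-effects Bayesian model comparison
#'
#' Accumulates evidence by summing free energies over subjects; posterior
#' model probabilities are a softmax of the summed free energies (flat
#' model priors).
#'
#' @param F `N x K` matrix of free energies (or a `model_array`).
#' @return list with `group_F` (column sums) and `prob`.
#' @export
ffx_bmc <- function(F) {
  if (inherits(F, "model_array")) F <- F$F
  F <- as.matrix(F)
  if (any(!is.finite(F))) stop("free energies must be finite")
  gF <- colSums(F)
  list(group_F = gF, prob = softmax(gF))
}

#' Random-effects Bayesian model comparison
#'
#' Variational Dirichlet scheme treating the model identity as a random
#' effect sampled per subject: iterates the standard updates
#' `u_{nk} = exp(F_{nk} + psi(alpha_k) - psi(sum alpha))`,
#' `alpha = alpha0 + sum_n u_n / sum_k u_{nk}` to convergence, then
#' estimates exceedance probabilities by seeded Monte-Carlo Dirichlet
#' sampling.
#'
#' @param F `N x K` free energy matrix (or `model_array`).
#' @param alpha0 prior concentration (default 1).
#' @param nsamp Monte-Carlo draws for exceedance probabilities (default 1e5).
#' @param seed RNG seed for the draws.
#' @return list with `alpha`, `expected_freq`, `exceedance`.
#' @export
rfx_bmc <- function(F, alpha0 = 1, nsamp = 1e5, seed = 1) {
  if (inherits(F, "model_array")) F <- F$F
  F <- as.matrix(F)
  stopifnot(alpha0 > 0)
  K <- ncol(F)
  alpha <- rep(alpha0, K)
  done <- FALSE
  for (it in 1:200) {
    lu <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- t(apply(lu, 1, softmax))
    if (K == 1) g <- matrix(g, ncol = 1)
    new_alpha <- alpha0 + colSums(g)
    done <- max(abs(new_alpha - alpha)) < 1e-6
    alpha <- new_alpha
    if (done) break
  }
  if (!done) warning("rfx_bmc: Dirichlet updates did not converge")
  xp <- with_seed(seed, {
    draws <- matrix(stats::rgamma(nsamp * K, shape = rep(alpha, each = nsamp)),
                    nsamp, K)
    tabulate(max.col(draws), nbins = K) / nsamp
  })
  list(alpha = alpha, expected_freq = alpha / sum(alpha), exceedance = xp)
}

#' Bayesian model averaging over one subject's models
#'
#' Averages the posteriors of one subject over models, weighting by a
#' softmax of the free energies restricted to an Occam's window (models
#' within `window` nats of the best). Returns the analytic mixture moments
#' (`mean = sum w_k mu_k`,
#' `cov = sum w_k (C_k + mu_k mu_k') - mean mean'`) together with seeded
#' samples from the mixture.
#'
#' @param posteriors list of [gaussian_belief()] over a common space.
#' @param F free energies, one per model.
#' @param window Occam's window in nats (default 8).
#' @param nsamp number of mixture samples (default 1e4).
#' @param seed RNG seed.
#' @return list with `mean`, `cov`, `weights` (zero outside the window),
#'   `samples` (`nsamp x M` matrix).
#' @export
bma <- function(posteriors, F, window = 8, nsamp = 1e4, seed = 1) {
  K <- length(posteriors)
  stopifnot(length(F) == K, K >= 1)
  keep <- F >= max(F) - window
  w <- rep(0, K)
  w[keep] <- softmax(F[keep])
  M <- posteriors[[1]]$space$M
  mu <- rep(0, M)
  S <- matrix(0, M, M)
  for (k in which(w > 0)) {
    mu <- mu + w[k] * posteriors[[k]]$mean
  }
  for (k in which(w > 0)) {
    d <- posteriors[[k]]$mean - mu
    S <- S + w[k] * (posteriors[[k]]$cov + tcrossprod(d))
  }
  samples <- with_seed(seed, {
    comp <- sample.int(K, nsamp, replace = TRUE, prob = w)
    out <- matrix(0, nsamp, M)
    for (k in unique(comp)) {
      idx <- which(comp == k)
      b <- posteriors[[k]]
      si <- which(b$support)
      draw <- matrix(rep(b$mean, length(idx)), length(idx), M, byrow = TRUE)
      if (length(si))
        draw[, si] <- rmvnorm_chol(length(idx), b$mean[si],
                                   b$cov[si, si, drop = FALSE])
      out[idx, ] <- draw
    }
    colnames(out) <- posteriors[[1]]$space$names
    out
  })
  list(mean = mu, cov = sym(S), weights = w, samples = samples)
}

#' Bayesian parameter averaging over subjects
#'
#' Fuses the posteriors of several subjects for the same model under a
#' shared prior, accumulating evidence: the fused precision is
#' `sum_i P_i - (N-1) Pi_prior` and the fused mean
#' `P^-1 (sum_i P_i mu_i - (N-1) Pi_prior eta)`.
#'
#' @param posteriors list of [gaussian_belief()] (one per subject).
#' @param prior the shared prior, a [gaussian_belief()].
#' @return the fused posterior, a [gaussian_belief()].
#' @export
bpa <- function(posteriors, prior) {
  N <- length(posteriors)
  stopifnot(N >= 1)
  s <- prior$support
  si <- which(s)
  Pi0 <- belief_precision(prior)
  P <- -(N - 1) * Pi0
  h <- -(N - 1) * drop(Pi0 %*% prior$mean[si])
  for (b in posteriors) {
    if (!same_space(b$space, prior$space) || any(b$support != s))
      stop("posteriors must share the prior's space and support")
    Pi <- psd_solve(b$cov[si, si, drop = FALSE], label = "posterior covariance")
    P <- P + Pi
    h <- h + drop(Pi %*% b$mean[si])
  }
  ev <- eigen(sym(P), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("fused precision is not positive definite")
  C <- psd_solve(sym(P))
  m <- prior$mean
  m[si] <- drop(C %*% h)
  cov <- matrix(0, prior$space$M, prior$space$M)
  cov[si, si] <- sym(C)
  gaussian_belief(prior$space, m, cov, s)
}

#' Search over second-level parameter subsets
#'
#' Scores reduced second-level models that switch off subsets of the
#' non-constant group effects (reduced prior mean 0, variance 0) by
#' applying Bayesian model reduction to the joint `(beta, gamma)` posterior
#' of a PEB inversion; the constant-column effects are always retained.
#' Exhaustive when the number of candidate effects is at most
#' `exhaustive_limit` (default 16), otherwise greedy backward elimination
#' (remove the single effect whose removal raises the free energy most,
#' ties broken by lowest index, until no removal helps). Redundant effects
#' are pruned automatically, the empirical-Bayes analogue of automatic
#' relevance determination. A Bayesian model average of `beta` over the
#' retained models (Occam's window, softmax weights) is returned.
#'
#' @param slp a `second_level_posterior`.
#' @param window Occam's window in nats for the average (default 8).
#' @param exhaustive_limit switch-over to greedy search (default 16).
#' @return list with `table` (subset membership, `delta_F`, `prob`),
#'   `best` (logical mask over candidate effects), `bma` (list as [bma()],
#'   without samples), `candidates` (names of searchable effects),
#'   `method`.
#' @export
peb_bmc_search <- function(slp, window = 8, exhaustive_limit = 16) {
  BC <- slp$beta$space$M
  C <- slp$ctx$C
  nm <- slp$joint$names
  sp <- parameter_space(nm)
  prior_cov <- psd_solve(as.matrix(slp$joint$prior_precision))
  prior_mean <- c(slp$ctx$beta_prior$mean,
                  if (length(nm) > BC) slp$ctx$gamma_prior$mean)
  prior <- gaussian_belief(sp, prior_mean, sym(prior_cov))
  post <- gaussian_belief(sp, slp$joint$mean, sym(as.matrix(slp$joint$cov)))
  cand <- (C + 1):BC            # non-constant beta dimensions
  if (BC == C) stop("no non-constant effects to search over")

  ## scoring only needs the Savage-Dickey marginal ratio over the
  ## switched-off dimensions; full reduced posteriors are computed lazily,
  ## for the models inside the Occam window only
  mu_c <- post$mean[cand];  C_c <- post$cov[cand, cand, drop = FALSE]
  eta_c <- prior$mean[cand]; S_c <- prior$cov[cand, cand, drop = FALSE]
  ldens0 <- function(m, S, off) {   # log N(0; m_off, S_off)
    k <- length(off)
    R <- chol_jitter(S[off, off, drop = FALSE])
    z <- backsolve(R, m[off], transpose = TRUE)
    -0.5 * (k * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
  }
  score_dF <- function(off) {       # off: indices into cand that are removed
    if (length(off) == 0) return(0)
    ldens0(mu_c, C_c, off) - ldens0(eta_c, S_c, off)
  }
  full_reduction <- function(off) {
    if (length(off) == 0) return(post)
    bmr_point(prior, post, cand[off], rep(0, length(off)))$reduced_posterior
  }

  k <- length(cand)
  if (k <= exhaustive_limit) {
    method <- "exhaustive"
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
    colnames(subsets) <- nm[cand]
  } else {
    method <- "greedy"
    off <- logical(k)
    path <- list(off)
    repeat {
      base <- score_dF(which(off))
      gains <- rep(-Inf, k)
      for (j in which(!off)) {
        try_off <- off; try_off[j] <- TRUE
        gains[j] <- tryCatch(score_dF(which(try_off)),
                             error = function(e) -Inf) - base
      }
      j <- which.max(gains)        # ties: lowest index (which.max semantics)
      if (gains[j] <= 0) break
      off[j] <- TRUE
      path <- c(path, list(off))
    }
    subsets <- do.call(rbind, path)
    colnames(subsets) <- nm[cand]
  }
  dF <- vapply(seq_len(nrow(subsets)), function(i)
    score_dF(which(subsets[i, ])), 0)
  prob <- rep(0, length(dF))
  keep <- dF >= max(dF) - window
  prob[keep] <- softmax(dF[keep])
  tab <- data.frame(subsets, delta_F = dF, prob = prob, check.names = FALSE)
  posts <- lapply(which(keep), function(i)
    full_reduction(which(subsets[i, ])))
  avg <- bma(posts, dF[keep], window = Inf, nsamp = 2, seed = 1)
  best <- subsets[which.max(dF), ]
  list(table = tab, best = !best,   # best = retained mask over candidates
       bma = list(mean = avg$mean, cov = avg$cov, weights = prob[keep],
                  names = nm),
       candidates = nm[cand], method = method)
}

#' Joint first- and second-level model comparison
#'
#' For every pair of a (nested) first-level model and a second-level design
#' subset, applies Bayesian model reduction to every subject under the
#' first-level model and then inverts the between-subject level under the
#' design subset. The resulting second-level free energies are directly
#' comparable (they are all functions of the same data); marginal
#' probabilities over first- and second-level models are softmax row/column
#' sums over the grid.
#'
#' @param subjects list of `subject_inversion` objects.
#' @param first_models list of [model_definition()] objects (nested in the
#'   full model).
#' @param second_models list of integer vectors of design-matrix columns;
#'   each must include column 1 (the constant).
#' @param slm a [second_level_model()] holding the full design.
#' @param opts passed to [peb_invert()].
#' @return list with `F2` (`K1 x K2` grid), `prob` (joint softmax),
#'   `first_prob`, `second_prob`, and the winning pair `best`.
#' @export
joint_bmc_peb <- function(subjects, first_models, second_models, slm,
                          opts = list()) {
  stopifnot(length(first_models) >= 1, length(second_models) >= 1)
  if (!all(vapply(second_models, function(s) 1L %in% s, TRUE)))
    stop("every second-level model must include the constant column")
  K1 <- length(first_models); K2 <- length(second_models)
  F2 <- matrix(NA_real_, K1, K2)
  rownames(F2) <- vapply(first_models, `[[`, "", "name")
  colnames(F2) <- vapply(second_models, function(s)
    paste(colnames(slm$X)[s], collapse = "+"), "")
  for (i in seq_len(K1)) {
    red <- lapply(subjects, function(sub) {
      rr <- bmr_reduce(sub$full_prior, sub$full_posterior,
                       first_models[[i]]$reduced_prior, sub$evidence$F)
      structure(list(data = sub$data, model = sub$model,
                     full_prior = first_models[[i]]$reduced_prior,
                     full_posterior = rr$reduced_posterior,
                     hyper_posterior = sub$hyper_posterior,
                     evidence = evidence_record(rr$F_R, 0),
                     trace = rr$F_R, converged = TRUE),
                class = "subject_inversion")
    })
    no_re <- !any(first_models[[i]]$reduced_prior$support &
                    first_models[[i]]$reduced_prior$space$random_effects)
    for (j in seq_len(K2)) {
      if (no_re) {
        # no random effects survive this reduction: the second level is
        # empty and the hierarchical evidence is just the summed reduced F
        F2[i, j] <- sum(vapply(red, function(s) s$evidence$F, 0))
        next
      }
      cols <- second_models[[j]]
      slm_j <- second_level_model(slm$X[, cols, drop = FALSE], W = slm$W,
                                  Q0 = slm$Q0, Q = slm$Q,
                                  gamma_prior = slm$gamma_prior)
      fit <- suppressWarnings(peb_invert(red, slm_j, opts))
      F2[i, j] <- fit$F2
    }
  }
  p <- matrix(softmax(as.vector(F2)), K1, K2, dimnames = dimnames(F2))
  ij <- which(F2 == max(F2), arr.ind = TRUE)[1, ]
  list(F2 = F2, prob = p,
       first_prob = rowSums(p), second_prob = colSums(p),
       best = list(first = rownames(F2)[ij[1]], second = colnames(F2)[ij[2]],
                   index = ij))
}
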