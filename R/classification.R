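#' Posterior-predictive estimation of design-matrix entries
#'
#' Swaps the roles of the design matrix and the group effects: given a
#' trained second-level posterior (expectations `beta~`, `gamma~`), the
#' empirical prior for a new (test) subject has mean `(x kron W) beta~` and
#' between-subject precision `Q0 + sum_j exp(-gamma~_j) Q_j`, where `x` is
#' the subject's (partly unknown) design row. The subject's reduced free
#' energy is an explicit quadratic function of `x` through the empirical
#' prior mean, so the posterior over the unknown design entries is Gaussian
#' and obtained by a single exact Newton step. Known entries (e.g. the
#' constant, which is 1 by construction) are fixed with tight priors
#' (variance 1e-8); unknown entries get a `N(0, 1)` prior by default.
#'
#' Only the trained expectations are propagated (an optional
#' `integrate_training = TRUE` adds the trained `beta` covariance to the
#' empirical-prior uncertainty through the design map).
#'
#' @param trained a `second_level_posterior` from [peb_invert()].
#' @param test a `subject_inversion` of the test subject under the same
#'   full first-level prior.
#' @param known named numeric vector / list of known design entries, names
#'   or indices matching columns of the training design (column 1 defaults
#'   to 1 if not supplied).
#' @param unknown_prior prior for each unknown entry as `c(mean, var)`
#'   (default `c(0, 1)`).
#' @param known_var tight prior variance for known entries (default 1e-8).
#' @param integrate_training propagate trained beta covariance (default
#'   FALSE).
#' @return an object of class `predictive_posterior`: `x_posterior` and
#'   `x_prior` ([gaussian_belief()] over all design columns), `unknown`
#'   (column indices), `delta_F` at the posterior mode.
#' @export
posterior_predictive <- function(trained, test, known = c(mean = 1),
                                 unknown_prior = c(0, 1), known_var = 1e-8,
                                 integrate_training = FALSE) {
  ctx <- trained$ctx
  B <- ctx$B; C <- ctx$C
  cols <- colnames(ctx$X)
  kn <- unlist(known)
  ki <- if (is.null(names(kn)) || any(names(kn) == ""))
    as.integer(seq_along(kn)) else match(names(kn), cols)
  if (anyNA(ki)) stop("unknown design column in `known`")
  if (!(1L %in% ki)) { ki <- c(1L, ki); kn <- c(1, kn) }
  unknown <- setdiff(seq_len(B), ki)
  xsp <- parameter_space(cols)
  xmean <- numeric(B); xvar <- numeric(B)
  xmean[ki] <- kn;       xvar[ki] <- known_var
  xmean[unknown] <- unknown_prior[1]
  xvar[unknown] <- unknown_prior[2]
  x_prior <- gaussian_belief(xsp, xmean, diag(xvar, B))

  if (!same_space(test$full_prior$space, ctx$space) ||
      any(test$full_prior$support != ctx$s))
    stop("test subject must share the training parameter space and support")

  beta <- trained$beta$mean
  gamma <- trained$gamma$mean
  Pi2 <- pi2_of_gamma(ctx, gamma)
  Sigma2 <- psd_solve(Pi2)
  if (integrate_training) {
    # fold E_x[(x kron W) C_beta (x kron W)'] at the prior mean of x into
    # the empirical prior covariance (first-order propagation)
    Tm <- kronecker(matrix(xmean, 1, B), ctx$W)
    Sigma2 <- sym(Sigma2 + Tm %*% trained$beta$cov %*% t(Tm))
    Pi2 <- psd_solve(Sigma2)
  }

  # empirical prior mean is A x + 0 with A[, b] = W beta_b
  Amap <- matrix(0, ctx$Mr, B)
  for (b in seq_len(B))
    Amap[, b] <- drop(ctx$W %*% beta[((b - 1) * C + 1):(b * C)])

  si <- ctx$si; n <- length(si)
  SF <- test$full_prior$cov[si, si, drop = FALSE]
  CF <- test$full_posterior$cov[si, si, drop = FALSE]
  p <- list(etaF = test$full_prior$mean[si],
            PiF = psd_solve(SF), muF = test$full_posterior$mean[si],
            PF = psd_solve(CF),
            Piff = if (length(ctx$fi))
              psd_solve(SF[ctx$fi, ctx$fi, drop = FALSE]) else matrix(0, 0, 0))
  PiR <- matrix(0, n, n)
  PiR[ctx$ri, ctx$ri] <- Pi2
  if (length(ctx$fi)) PiR[ctx$fi, ctx$fi] <- p$Piff

  eval_x <- function(x) {
    etaR <- p$etaF
    etaR[ctx$ri] <- drop(Amap %*% x)
    bmr_core(p$etaF, p$PiF, p$muF, p$PF, etaR, PiR)
  }
  Pix <- diag(1 / xvar, B)
  core0 <- eval_x(xmean)
  g0 <- drop(crossprod(Amap, Pi2 %*% (core0$muR[ctx$ri] - drop(Amap %*% xmean))))
  Hred <- Pi2 %*% core0$CR[ctx$ri, ctx$ri, drop = FALSE] %*% Pi2 - Pi2
  Hx <- crossprod(Amap, Hred %*% Amap) - Pix
  xhat <- xmean + drop(psd_solve(sym(-Hx), g0))
  Px <- sym(-Hx)
  Cx <- psd_solve(Px)
  x_post <- gaussian_belief(xsp, xhat, Cx)
  structure(list(x_posterior = x_post, x_prior = x_prior, unknown = unknown,
                 delta_F = eval_x(xhat)$dF,
                 trained = trained),
            class = "predictive_posterior")
}

#' @export
print.predictive_posterior <- function(x, ...) {
  cat("<predictive_posterior> unknown columns:",
      paste(x$x_posterior$space$names[x$unknown], collapse = ", "), "\n")
  m <- rbind(mean = x$x_posterior$mean, sd = sqrt(diag(x$x_posterior$cov)))
  colnames(m) <- x$x_posterior$space$names
  print(round(m, 4))
  invisible(x)
}

#' Categorical (Savage-Dickey) label probabilities
#'
#' Evaluates the evidence for each candidate value of an unknown design
#' entry by setting its reduced expectation to the value and its reduced
#' variance to zero: the reduced free energy for label `v` is the
#' Savage-Dickey log ratio `ln q(v) - ln p(v)` of the posterior to the
#' prior marginal density, and label probabilities are a softmax of those
#' free energies. Generalises to any finite label set, yielding a posterior
#' predictive distribution over the explanatory variable.
#'
#' @param pp a `predictive_posterior` from [posterior_predictive()].
#' @param labels numeric vector of candidate values (e.g. `c(-1, 1)`).
#' @param column design column (index or name); default the first unknown.
#' @return named probability vector over labels.
#' @export
categorical_probability <- function(pp, labels, column = NULL) {
  if (is.null(column)) column <- pp$unknown[1]
  if (is.character(column))
    column <- match(column, pp$x_posterior$space$names)
  dF <- vapply(labels, function(v) {
    bmr_point(pp$x_prior, pp$x_posterior, column, v)$delta_F
  }, 0)
  p <- softmax(dF)
  names(p) <- as.character(labels)
  p
}

#' Leave-one-out predictive classification
#'
#' For each subject: trains the second level on the remaining subjects via
#' [peb_invert()], then predicts the held-out subject's unknown design
#' entry with [posterior_predictive()] and [categorical_probability()].
#'
#' @param subjects list of `subject_inversion` objects.
#' @param slm a [second_level_model()] with the full design (the row of
#'   each held-out subject supplies its known covariate values).
#' @param unknown_column design column (index or name) to predict.
#' @param labels candidate categorical values (default `c(-1, 1)`).
#' @param opts passed to [peb_invert()].
#' @param null_permute permutation control: when `TRUE`, the
#'   `unknown_column` entries of each fold's *training* design rows are
#'   randomly permuted (seeded by `null_seed + fold`), so the trained
#'   second level carries no information about the predicted variable and
#'   `p_correct` is at chance by construction. The held-out subject keeps
#'   its true value for scoring.
#' @param null_seed base seed for the per-fold permutations (default 1).
#' @return a data.frame with one row per subject: posterior mean and sd of
#'   the unknown entry, one probability column per label, the true value
#'   and `p_correct` (probability assigned to the nearest label to the true
#'   value), plus a `converged` flag per fold.
#' @export
loo_cross_validation <- function(subjects, slm, unknown_column = 2,
                                 labels = c(-1, 1), opts = list(),
                                 null_permute = FALSE, null_seed = 1) {
  N <- length(subjects)
  if (N < 3) stop("leave-one-out needs at least 3 subjects")
  X <- slm$X
  if (is.character(unknown_column))
    unknown_column <- match(unknown_column, colnames(X))
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    Xtrain <- X[-i, , drop = FALSE]
    if (null_permute)
      Xtrain[, unknown_column] <- with_seed(
        null_seed + i, sample(Xtrain[, unknown_column]))
    slm_i <- second_level_model(Xtrain, W = slm$W,
                                Q0 = slm$Q0, Q = slm$Q,
                                beta_prior = slm$beta_prior,
                                gamma_prior = slm$gamma_prior)
    fit <- suppressWarnings(peb_invert(subjects[-i], slm_i, opts))
    kn <- X[i, -unknown_column]
    names(kn) <- colnames(X)[-unknown_column]
    pp <- posterior_predictive(fit, subjects[[i]], known = kn)
    pr <- categorical_probability(pp, labels, unknown_column)
    truth <- X[i, unknown_column]
    rows[[i]] <- data.frame(
      subject = i,
      post_mean = pp$x_posterior$mean[unknown_column],
      post_sd = sqrt(pp$x_posterior$cov[unknown_column, unknown_column]),
      t(pr), truth = truth,
      p_correct = unname(pr[which.min(abs(labels - truth))]),
      converged = fit$converged, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
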