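#' Second-level (between-subject) model specification
#'
#' Specifies the linear between-subject model
#' `theta_i = (x_i kron W) beta + epsilon_i`,
#' `epsilon_i ~ N(0, Sigma2(gamma))`, with between-subject precision
#' `Pi2(gamma) = Q0 + sum_j exp(-gamma_j) Q_j` over the random-effect
#' parameters. `X` is the `N x B` between-subject design (first column a
#' constant), `W` the `M_r x C` within-subject design over random-effect
#' parameters (default identity: every random-effect parameter may express
#' every group effect). Components left `NULL` are filled with defaults at
#' inversion time from the subjects' first-level priors:
#' `Q0 = diag(prior precision)/16` (precision floor),
#' a single component `Q1 = 16 * diag(prior precision)` (so `gamma = 0`
#' corresponds to a between-subject variance of a sixteenth of the prior
#' variance), a `N(0, 1)` prior per log-precision, and a `beta` prior with
#' the first-level prior variances tiled over the effect columns.
#'
#' @param X between-subject design matrix (`N x B`), first column constant.
#' @param W within-subject design (`M_r x C` matrix) or `"identity"`.
#' @param Q0 precision floor matrix (`M_r x M_r`), or `NULL` for default.
#' @param Q list of PSD precision components, or `NULL` for the default
#'   single component.
#' @param beta_prior [gaussian_belief()] over the `B*C` group effects, or
#'   `NULL`.
#' @param gamma_prior [gaussian_belief()] over the log-precisions, or `NULL`.
#' @return an object of class `second_level_model`.
#' @export
second_level_model <- function(X, W = "identity", Q0 = NULL, Q = NULL,
                               beta_prior = NULL, gamma_prior = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("mean", paste0("effect", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  if (any(abs(X[, 1] - 1) > 1e-12))
    stop("the first column of the design matrix must be a constant term (all ones)")
  if (qr(X)$rank < ncol(X)) stop("design matrix X is rank deficient")
  if (!is.null(Q) && length(Q) == 0) stop("at least one precision component is required")
  structure(list(X = X, W = W, Q0 = Q0, Q = Q,
                 beta_prior = beta_prior, gamma_prior = gamma_prior),
            class = "second_level_model")
}

# Fill slm defaults from the subjects' shared first-level prior.
# Returns the expanded context used by the PEB engine.
peb_context <- function(subjects, slm) {
  prior <- subjects[[1]]$full_prior
  space <- prior$space
  s <- prior$support
  for (sub in subjects) {
    if (!same_space(sub$full_prior$space, space) ||
        any(sub$full_prior$support != s))
      stop("all subjects must share the first-level parameter space and support")
  }
  r <- which(space$random_effects & s)
  if (length(r) == 0L) stop("no random-effect parameters on support")
  si <- which(s)
  ri <- match(r, si)
  fi <- setdiff(seq_along(si), ri)
  Mr <- length(r)
  W <- slm$W
  if (is.character(W) && identical(W, "identity")) W <- diag(Mr)
  W <- as.matrix(W)
  if (nrow(W) != Mr) stop("W must have one row per random-effect parameter")
  C <- ncol(W)
  X <- slm$X
  N <- nrow(X); B <- ncol(X)
  if (N != length(subjects)) stop("X must have one row per subject")

  Srr <- prior$cov[r, r, drop = FALSE]
  pv <- diag(Srr)
  Q0 <- if (is.null(slm$Q0)) diag(1 / pv, Mr) / 16 else as.matrix(slm$Q0)
  Q <- if (is.null(slm$Q)) list(16 * diag(1 / pv, Mr)) else lapply(slm$Q, as.matrix)
  J <- length(Q)

  bnames <- as.vector(t(outer(colnames(X), paste0("c", seq_len(C)),
                              paste, sep = ":")))
  # within-subject index fast, effect (column of X) slow
  bspace <- parameter_space(bnames)
  if (is.null(slm$beta_prior)) {
    bmean <- rep(0, B * C)
    if (C == Mr && all(abs(W - diag(Mr)) < 1e-12))
      bmean[seq_len(C)] <- prior$mean[r]
    bv <- rep(pmax(diag(crossprod(W, Srr %*% W)), 1e-12), B)
    beta_prior <- gaussian_belief(bspace, bmean, diag(bv, B * C))
  } else {
    beta_prior <- slm$beta_prior
    if (beta_prior$space$M != B * C) stop("beta prior dimension mismatch")
  }
  gspace <- parameter_space(paste0("gamma", seq_len(J)))
  gamma_prior <- if (is.null(slm$gamma_prior))
    gaussian_belief(gspace, 0, diag(1, J)) else slm$gamma_prior
  if (gamma_prior$space$M != J) stop("gamma prior dimension mismatch")

  # per-subject sufficient statistics on the support subspace
  pre <- lapply(subjects, function(sub) {
    SF <- sub$full_prior$cov[si, si, drop = FALSE]
    CF <- sub$full_posterior$cov[si, si, drop = FALSE]
    list(etaF = sub$full_prior$mean[si],
         PiF = psd_solve(SF, label = "full prior covariance"),
         muF = sub$full_posterior$mean[si],
         PF = psd_solve(CF, label = "full posterior covariance"),
         Piff = if (length(fi))
           psd_solve(SF[fi, fi, drop = FALSE], label = "fixed-effect prior")
         else matrix(0, 0, 0),
         F = sub$evidence$F)
  })
  Ti <- lapply(seq_len(N), function(i)
    kronecker(matrix(X[i, ], 1, B), W))   # Mr x (B*C)

  list(space = space, s = s, si = si, r = r, ri = ri, fi = fi, Mr = Mr,
       W = W, C = C, X = X, N = N, B = B, Q0 = Q0, Q = Q, J = J,
       beta_prior = beta_prior, gamma_prior = gamma_prior,
       pre = pre, Ti = Ti, prior = prior)
}

pi2_of_gamma <- function(ctx, gamma) {
  gamma <- pmin(pmax(gamma, -32), 32)
  P <- ctx$Q0
  for (j in seq_len(ctx$J)) P <- P + exp(-gamma[j]) * ctx$Q[[j]]
  sym(P)
}

# Evaluate the reduction of every subject under the empirical priors at
# (beta, gamma). Returns per-subject bmr_core results plus Pi2.
peb_eval <- function(ctx, beta, gamma) {
  Pi2 <- pi2_of_gamma(ctx, gamma)
  n <- length(ctx$si)
  cores <- vector("list", ctx$N)
  for (i in seq_len(ctx$N)) {
    p <- ctx$pre[[i]]
    PiR <- matrix(0, n, n)
    PiR[ctx$ri, ctx$ri] <- Pi2
    if (length(ctx$fi)) PiR[ctx$fi, ctx$fi] <- p$Piff
    etaR <- p$etaF
    etaR[ctx$ri] <- drop(ctx$Ti[[i]] %*% beta)
    cores[[i]] <- bmr_core(p$etaF, p$PiF, p$muF, p$PF, etaR, PiR)
  }
  list(cores = cores, Pi2 = Pi2,
       sum_dF = sum(vapply(cores, `[[`, 0, "dF")))
}

# G(mu2): the mu2-dependent part of the second-level free energy
peb_objective <- function(ctx, ev, beta, gamma, fix_gamma = FALSE) {
  db <- beta - ctx$beta_prior$mean
  Pib <- belief_precision(ctx$beta_prior)
  g <- ev$sum_dF - 0.5 * drop(crossprod(db, Pib %*% db))
  dg <- gamma - ctx$gamma_prior$mean
  Pig <- belief_precision(ctx$gamma_prior)
  g - 0.5 * drop(crossprod(dg, Pig %*% dg))
}

# analytic gradient/Hessian of sum_i dF_i with respect to beta
peb_beta_derivs <- function(ctx, ev, beta) {
  BC <- ctx$B * ctx$C
  g <- numeric(BC)
  H <- matrix(0, BC, BC)
  Pi2 <- ev$Pi2
  for (i in seq_len(ctx$N)) {
    core <- ev$cores[[i]]
    Tmat <- ctx$Ti[[i]]
    resid <- core$muR[ctx$ri] - drop(Tmat %*% beta)
    g <- g + drop(crossprod(Tmat, Pi2 %*% resid))
    Hred <- Pi2 %*% core$CR[ctx$ri, ctx$ri, drop = FALSE] %*% Pi2 - Pi2
    H <- H + crossprod(Tmat, Hred %*% Tmat)
  }
  list(g = g, H = sym(H))
}

#' Second-level free energy at given expectations
#'
#' Evaluates the `mu2 = (beta, gamma)`-dependent part of the second-level
#' free energy: the sum over subjects of the reduced free energies
#' `F_i + dF_i` under the empirical priors at `mu2`, minus the quadratic
#' prior penalties on `beta` and `gamma`. The posterior-entropy and
#' curvature terms, which depend on the converged posterior covariance, are
#' added by [peb_invert()].
#'
#' @param subjects list of `subject_inversion` objects.
#' @param slm a [second_level_model()].
#' @param beta,gamma second-level expectations.
#' @return a number in nats.
#' @export
second_level_free_energy <- function(subjects, slm, beta, gamma) {
  ctx <- peb_context(subjects, slm)
  ev <- peb_eval(ctx, beta, gamma)
  sum(vapply(ctx$pre, `[[`, 0, "F")) + peb_objective(ctx, ev, beta, gamma)
}

#' Parametric empirical Bayes over first-level posteriors
#'
#' Inverts the second (between-subject) level from the subjects'
#' first-level posteriors alone, by maximising the second-level free energy
#' over group effects `beta` and between-subject log-precisions `gamma`.
#' Each evaluation reduces every subject under the empirical prior
#' `N((x_i kron W) beta, Sigma2(gamma))` via Bayesian model reduction; the
#' `beta` step is an exact Newton step (the reduced free energy is quadratic
#' in the empirical prior mean), the `gamma` step a damped Newton step on
#' central finite differences (step 1e-3). At convergence the posterior
#' precision over `(beta, gamma)` is the second-level prior precision minus
#' the curvature of the summed reduced free energies (`hessian =
#' "consistent"`), or minus the curvature alone (`hessian = "paper"`).
#'
#' @param subjects list of `subject_inversion` objects sharing a parameter
#'   space; random effects are taken from the space's `random_effects` mask,
#'   fixed-effect parameters keep their full priors.
#' @param slm a [second_level_model()].
#' @param opts list: `max_iter` (64), `tol` (1e-4 on `|dF2|`, 4 consecutive),
#'   `hessian` ("consistent" or "paper"), `fix_gamma` (optional numeric:
#'   pin the log-precisions, e.g. for profiling).
#' @return an object of class `second_level_posterior`: beliefs `beta` and
#'   `gamma`, joint covariance `C2`, free energy `F2`, per-subject
#'   `empirical_priors` and `shrunk_posteriors`, the objective `trace`, and
#'   the filled-in design context.
#' @export
peb_invert <- function(subjects, slm, opts = list()) {
  o <- utils::modifyList(list(max_iter = 64L, tol = 1e-4,
                              hessian = "consistent", fix_gamma = NULL), opts)
  ctx <- peb_context(subjects, slm)
  if (ctx$N < ctx$B)
    stop("need at least as many subjects as design columns")
  Pib <- belief_precision(ctx$beta_prior)
  Pig <- belief_precision(ctx$gamma_prior)

  ## beta initialised by OLS of subject posterior means on X
  XtX <- kronecker(crossprod(ctx$X), crossprod(ctx$W))
  rhs <- numeric(ctx$B * ctx$C)
  for (i in seq_len(ctx$N)) {
    th <- ctx$pre[[i]]$muF[ctx$ri]
    rhs <- rhs + drop(crossprod(ctx$Ti[[i]], th))
  }
  beta <- drop(psd_solve(XtX + diag(1e-8, length(rhs)), rhs))
  fixg <- !is.null(o$fix_gamma)
  gamma <- if (fixg) rep_len(as.numeric(o$fix_gamma), ctx$J) else
    ctx$gamma_prior$mean

  ev <- peb_eval(ctx, beta, gamma)
  G <- peb_objective(ctx, ev, beta, gamma)
  trace <- G
  n_small <- 0L
  converged <- FALSE
  fd <- 1e-3

  for (iter in seq_len(o$max_iter)) {
    Gprev <- G
    ## exact Newton on beta
    d <- peb_beta_derivs(ctx, ev, beta)
    gb <- d$g - Pib %*% (beta - ctx$beta_prior$mean)
    Hb <- d$H - Pib
    beta <- beta + drop(psd_solve(-Hb, gb))
    ev <- peb_eval(ctx, beta, gamma)
    G <- peb_objective(ctx, ev, beta, gamma)
    ## damped Newton on gamma (finite differences)
    if (!fixg) {
      gg <- numeric(ctx$J); Hg <- matrix(0, ctx$J, ctx$J)
      f0 <- ev$sum_dF
      fp <- numeric(ctx$J); fm <- numeric(ctx$J)
      for (j in seq_len(ctx$J)) {
        gp <- gamma; gp[j] <- gp[j] + fd
        gm <- gamma; gm[j] <- gm[j] - fd
        fp[j] <- peb_eval(ctx, beta, gp)$sum_dF
        fm[j] <- peb_eval(ctx, beta, gm)$sum_dF
        gg[j] <- (fp[j] - fm[j]) / (2 * fd)
        Hg[j, j] <- (fp[j] - 2 * f0 + fm[j]) / fd^2
      }
      if (ctx$J > 1) {
        for (j in seq_len(ctx$J - 1)) for (k in (j + 1):ctx$J) {
          gpp <- gamma; gpp[c(j, k)] <- gpp[c(j, k)] + fd
          gmm <- gamma; gmm[c(j, k)] <- gmm[c(j, k)] - fd
          Hg[j, k] <- Hg[k, j] <-
            (peb_eval(ctx, beta, gpp)$sum_dF - fp[j] - fp[k] + 2 * f0 -
               fm[j] - fm[k] + peb_eval(ctx, beta, gmm)$sum_dF) / (2 * fd^2)
        }
      }
      gg <- gg - Pig %*% (gamma - ctx$gamma_prior$mean)
      Hg <- Hg - Pig
      ## ascend: solve with negative-definite guard
      step <- tryCatch(drop(psd_solve(-Hg, gg)),
                       error = function(e) drop(gg) * 0.1)
      for (try in 1:8) {
        cand <- pmin(pmax(gamma + step, -32), 32)
        evc <- peb_eval(ctx, beta, cand)
        Gc <- peb_objective(ctx, evc, beta, cand)
        if (is.finite(Gc) && Gc >= G - 1e-12) {
          gamma <- cand; ev <- evc; G <- Gc
          break
        }
        step <- step / 2
      }
    }
    trace <- c(trace, G)
    if (abs(G - Gprev) < o$tol) n_small <- n_small + 1L else n_small <- 0L
    if (n_small >= 4L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("peb_invert: no convergence after ", o$max_iter,
            " iterations; returning best-so-far")

  ## posterior precision over (beta[, gamma])
  BC <- ctx$B * ctx$C
  d <- peb_beta_derivs(ctx, ev, beta)
  if (fixg) {
    Hd <- d$H
    Pip2 <- Pib
  } else {
    nb <- BC + ctx$J
    Hd <- matrix(0, nb, nb)
    Hd[1:BC, 1:BC] <- d$H
    f0 <- ev$sum_dF
    for (j in seq_len(ctx$J)) {
      gp <- gamma; gp[j] <- gp[j] + fd
      gm <- gamma; gm[j] <- gm[j] - fd
      evp <- peb_eval(ctx, beta, gp)
      evm <- peb_eval(ctx, beta, gm)
      Hd[BC + j, BC + j] <- (evp$sum_dF - 2 * f0 + evm$sum_dF) / fd^2
      cross <- (peb_beta_derivs(ctx, evp, beta)$g -
                  peb_beta_derivs(ctx, evm, beta)$g) / (2 * fd)
      Hd[1:BC, BC + j] <- Hd[BC + j, 1:BC] <- cross
    }
    if (ctx$J > 1) {
      for (j in seq_len(ctx$J - 1)) for (k in (j + 1):ctx$J) {
        gpp <- gamma; gpp[c(j, k)] <- gpp[c(j, k)] + fd
        gmm <- gamma; gmm[c(j, k)] <- gmm[c(j, k)] - fd
        gpj <- gamma; gpj[j] <- gpj[j] + fd
        gpk <- gamma; gpk[k] <- gpk[k] + fd
        gmj <- gamma; gmj[j] <- gmj[j] - fd
        gmk <- gamma; gmk[k] <- gmk[k] - fd
        Hd[BC + j, BC + k] <- Hd[BC + k, BC + j] <-
          (peb_eval(ctx, beta, gpp)$sum_dF -
             peb_eval(ctx, beta, gpj)$sum_dF -
             peb_eval(ctx, beta, gpk)$sum_dF + 2 * f0 -
             peb_eval(ctx, beta, gmj)$sum_dF -
             peb_eval(ctx, beta, gmk)$sum_dF +
             peb_eval(ctx, beta, gmm)$sum_dF) / (2 * fd^2)
      }
    }
    Pip2 <- matrix(0, nb, nb)
    Pip2[1:BC, 1:BC] <- Pib
    Pip2[BC + seq_len(ctx$J), BC + seq_len(ctx$J)] <- Pig
  }
  Hd <- sym(Hd)
  P2 <- if (identical(o$hessian, "paper")) sym(-Hd) else sym(Pip2 - Hd)
  C2 <- psd_solve(P2, label = "second-level posterior precision")

  ## Laplace normalisation terms of F2 (Eq.-14 form)
  sumF <- sum(vapply(ctx$pre, `[[`, 0, "F"))
  F2 <- sumF + G + 0.5 * sum(C2 * Hd) +
    0.5 * (logdet_psd(Pip2) - logdet_psd(P2))

  bnames <- ctx$beta_prior$space$names
  beta_belief <- gaussian_belief(ctx$beta_prior$space, beta,
                                 sym(C2[1:BC, 1:BC, drop = FALSE]))
  gspace <- ctx$gamma_prior$space
  gamma_belief <- if (fixg)
    gaussian_belief(gspace, gamma, diag(0, ctx$J), rep(FALSE, ctx$J))
  else gaussian_belief(gspace, gamma,
                       sym(C2[BC + seq_len(ctx$J), BC + seq_len(ctx$J),
                              drop = FALSE]))

  ## empirical priors and shrunk posteriors at the optimum
  Sigma2 <- psd_solve(ev$Pi2, label = "between-subject precision")
  M <- ctx$space$M
  emp <- vector("list", ctx$N)
  shr <- vector("list", ctx$N)
  for (i in seq_len(ctx$N)) {
    m <- ctx$prior$mean
    m[ctx$si] <- ctx$pre[[i]]$etaF
    m[ctx$r] <- drop(ctx$Ti[[i]] %*% beta)
    cv <- matrix(0, M, M)
    cv[ctx$si, ctx$si] <- subjects[[i]]$full_prior$cov[ctx$si, ctx$si]
    cv[ctx$r, ] <- 0; cv[, ctx$r] <- 0
    cv[ctx$r, ctx$r] <- Sigma2
    emp[[i]] <- gaussian_belief(ctx$space, m, sym(cv), ctx$s)
    core <- ev$cores[[i]]
    pm <- ctx$prior$mean; pm[ctx$si] <- core$muR
    pc <- matrix(0, M, M); pc[ctx$si, ctx$si] <- core$CR
    shr[[i]] <- gaussian_belief(ctx$space, pm, sym(pc), ctx$s)
  }

  structure(list(beta = beta_belief, gamma = gamma_belief,
                 joint = list(mean = c(beta, if (!fixg) gamma),
                              cov = C2, P = P2, prior_precision = Pip2,
                              Hd = Hd,
                              names = c(bnames,
                                        if (!fixg) gspace$names)),
                 F2 = F2, empirical_priors = emp, shrunk_posteriors = shr,
                 ctx = ctx, trace = trace, converged = converged,
                 hessian = o$hessian, fix_gamma = o$fix_gamma,
                 subject_F = vapply(ctx$pre, `[[`, 0, "F")),
            class = "second_level_posterior")
}

#' @export
print.second_level_posterior <- function(x, ...) {
  cat(sprintf("<second_level_posterior> N = %d, B = %d, C = %d, F2 = %.3f (%s)\n",
              x$ctx$N, x$ctx$B, x$ctx$C, x$F2,
              if (x$converged) "converged" else "NOT converged"))
  m <- rbind(mean = x$beta$mean, sd = sqrt(diag(x$beta$cov)))
  colnames(m) <- x$beta$space$names
  print(round(m, 4))
  invisible(x)
}

#' Shrink a subject's posterior under an empirical prior
#'
#' Replaces the subject's full prior with the supplied empirical prior via
#' [bmr_reduce()]: random-effect estimates are pulled toward the empirical
#' prior (group) mean in proportion to their uncertainty; fixed-effect
#' dimensions keep their full priors.
#'
#' @param subject a `subject_inversion`.
#' @param empirical_prior a [gaussian_belief()] over the full parameter
#'   space.
#' @return the shrunk posterior, a [gaussian_belief()].
#' @export
apply_shrinkage <- function(subject, empirical_prior) {
  bmr_reduce(subject$full_prior, subject$full_posterior, empirical_prior,
             subject$evidence$F)$reduced_posterior
}

#' Re-package a second-level posterior as a pseudo-subject
#'
#' Treats the joint `(beta, gamma)` posterior of a PEB inversion as a single
#' "subject" (data = the original group), so the scheme can be applied
#' recursively to deeper hierarchies.
#'
#' @param slp a `second_level_posterior`.
#' @param random_effects logical mask over the joint `(beta, gamma)`
#'   dimensions; default: `beta` dimensions are random effects, `gamma`
#'   dimensions fixed.
#' @return a `subject_inversion`.
#' @export
as_subject_inversion <- function(slp, random_effects = NULL) {
  nm <- slp$joint$names
  BC <- slp$beta$space$M
  if (is.null(random_effects))
    random_effects <- c(rep(TRUE, BC), rep(FALSE, length(nm) - BC))
  sp <- parameter_space(nm, random_effects)
  prior_mean <- c(slp$ctx$beta_prior$mean,
                  if (length(nm) > BC) slp$ctx$gamma_prior$mean)
  prior_cov <- as.matrix(slp$joint$prior_precision)
  prior_cov <- psd_solve(prior_cov)
  prior <- gaussian_belief(sp, prior_mean, sym(prior_cov))
  post <- gaussian_belief(sp, slp$joint$mean, sym(as.matrix(slp$joint$cov)))
  structure(list(data = NULL, model = NULL, full_prior = prior,
                 full_posterior = post,
                 hyper_posterior = NULL,
                 evidence = evidence_record(slp$F2, 0),
                 trace = slp$F2, converged = slp$converged),
            class = "subject_inversion")
}

#' Recursive (third-level) empirical Bayes
#'
#' Applies [peb_invert()] to one or more second-level posteriors, each
#' treated as a pseudo-subject via [as_subject_inversion()]. With a single
#' posterior and an identity design this is a no-op on the expectations;
#' with several it pools groups (e.g. sites) at a third level.
#'
#' @param slps a `second_level_posterior` or a list of them.
#' @param higher_slm a [second_level_model()] with one row per second-level
#'   posterior.
#' @param opts passed to [peb_invert()].
#' @return a `second_level_posterior`.
#' @export
peb_recursive <- function(slps, higher_slm, opts = list()) {
  if (inherits(slps, "second_level_posterior")) slps <- list(slps)
  subjects <- lapply(slps, as_subject_inversion)
  peb_invert(subjects, higher_slm, opts)
}
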