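#' Nested model definitions
#'
#' A model definition is just a reduced prior over the same parameter space
#' (and the same likelihood) as the full model; dimensions may be switched
#' off entirely via the prior's support mask. The support of the reduced
#' prior must be contained in the support of the full prior: the full model
#' must contain every parameter of any model that will be entertained.
#'
#' @param name model label.
#' @param reduced_prior a [gaussian_belief()].
#' @return an object of class `model_definition`.
#' @export
model_definition <- function(name, reduced_prior) {
  stopifnot(inherits(reduced_prior, "gaussian_belief"))
  structure(list(name = as.character(name), reduced_prior = reduced_prior),
            class = "model_definition")
}

# Closed-form reduction on a subspace where all precisions are finite.
# Arguments are plain vectors/matrices over the active dimensions:
#   etaF/PiF  full prior mean/precision
#   muF/PF    full posterior mean/precision
#   etaR/PiR  reduced prior mean/precision
# Returns muR, CR, PR and the log evidence ratio dF. No validation: this is
# the hot path shared by bmr_reduce(), PEB and the predictive classifier.
bmr_core <- function(etaF, PiF, muF, PF, etaR, PiR) {
  PR <- sym(PF + PiR - PiF)
  ev <- eigen(PR, symmetric = TRUE)
  # relative tolerance must stay tiny: the large-precision fallback path
  # legitimately mixes eigenvalues across ~14 orders of magnitude
  tol <- 1e-15 * max(abs(ev$values), 1)
  if (min(ev$values) < tol) {
    i <- which.min(ev$values)
    stop("incompatible reduction: reduced posterior precision is not ",
         "positive definite (eigenvalue ", format(ev$values[i]),
         " along direction [", paste(round(ev$vectors[, i], 3), collapse = ", "),
         "])")
  }
  CR <- ev$vectors %*% (t(ev$vectors) / ev$values)
  muR <- drop(CR %*% (PF %*% muF + PiR %*% etaR - PiF %*% etaF))
  ld <- 0.5 * (logdet_psd(PiR) - logdet_psd(PiF) +
                 logdet_psd(PF) - sum(log(ev$values)))
  quad <- 0.5 * (drop(crossprod(muF, PF %*% muF)) +
                   drop(crossprod(etaR, PiR %*% etaR)) -
                   drop(crossprod(etaF, PiF %*% etaF)) -
                   drop(crossprod(muR, PR %*% muR)))
  list(muR = muR, CR = sym(CR), PR = PR, dF = ld - quad)
}

#' Bayesian model reduction
#'
#' Computes, in closed form, the posterior and the change in free energy of
#' any reduced (nested-prior) model from the full model's prior and
#' posterior, without touching the data. Writing `Pi`/`Sigma` for prior
#' precision/covariance and `P`/`C` for posterior precision/covariance, the
#' reduced posterior has precision `P_R = P_F + Pi_R - Pi_F`, mean
#' `mu_R = C_R (P_F mu_F + Pi_R eta_R - Pi_F eta_F)`, and the log evidence
#' ratio is
#' `dF = 1/2 [ln|Pi_R| - ln|Pi_F| + ln|P_F| - ln|P_R|]
#'       - 1/2 [mu_F' P_F mu_F + eta_R' Pi_R eta_R - eta_F' Pi_F eta_F
#'              - mu_R' P_R mu_R]`,
#' the split-determinant form being algebraically identical to the single
#' product determinant but numerically stable.
#'
#' Dimensions removed from the support of the reduced prior are handled by
#' exact subspace restriction: the evidence contribution of pinning
#' `theta_d = v` is the marginal Savage-Dickey ratio
#' `ln q(v) - ln p(v)`, and the remaining dimensions are conditioned on
#' `theta_d = v` before applying the finite-precision identity above.  A
#' large-precision fallback (`off_method = "precision"`, precision `2^32`)
#' is provided for cross-checking.
#'
#' @param full_prior,full_posterior [gaussian_belief()] objects sharing a
#'   parameter space and support.
#' @param reduced_prior a [gaussian_belief()] whose support is contained in
#'   the full prior's support.
#' @param F_full free energy of the full model in nats (default 0, in which
#'   case `F_R` equals the log evidence ratio).
#' @param off_method how to treat switched-off dimensions: `"subspace"`
#'   (exact restriction, default) or `"precision"` (variance `2^-32`).
#' @return an object of class `reduction_result`: fields `reduced_posterior`
#'   (a [gaussian_belief()]), `delta_F` and `F_R = F_full + delta_F` (nats).
#' @export
bmr_reduce <- function(full_prior, full_posterior, reduced_prior, F_full = 0,
                       off_method = c("subspace", "precision")) {
  off_method <- match.arg(off_method)
  if (!same_space(full_prior$space, full_posterior$space) ||
      !same_space(full_prior$space, reduced_prior$space))
    stop("beliefs live on different parameter spaces")
  s <- full_prior$support
  if (any(full_posterior$support != s))
    stop("full posterior support must equal full prior support")
  sR <- reduced_prior$support
  if (any(sR & !s))
    stop("nesting violation: reduced prior has mass off the full prior support")
  if (off_method == "subspace") {
    # reduced prior variances that are numerically indistinguishable from
    # zero (below 1e-9 of the full prior variance) would make the one-shot
    # identity catastrophically ill-conditioned; route them through the
    # exact zero-variance subspace path instead
    tiny <- sR & s & (diag(reduced_prior$cov) <
                        1e-9 * pmax(diag(full_prior$cov), 1e-300))
    if (any(tiny)) sR <- sR & !tiny
  }

  si <- which(s)
  etaF <- full_prior$mean[si]
  SF <- full_prior$cov[si, si, drop = FALSE]
  muF <- full_posterior$mean[si]
  CF <- full_posterior$cov[si, si, drop = FALSE]
  PiF <- psd_solve(SF, label = "full prior covariance")
  PF <- psd_solve(CF, label = "full posterior covariance")

  drop_loc <- which(!sR[si])            # positions within si to pin
  keep_loc <- which(sR[si])
  v <- reduced_prior$mean[si][drop_loc]

  if (off_method == "precision") {
    etaR <- reduced_prior$mean[si]
    SR <- reduced_prior$cov[si, si, drop = FALSE]
    if (length(drop_loc)) {
      SR[drop_loc, ] <- 0; SR[, drop_loc] <- 0
      diag(SR)[drop_loc] <- 2^-32
    }
    PiR <- psd_solve(SR, label = "reduced prior covariance")
    core <- bmr_core(etaF, PiF, muF, PF, etaR, PiR)
    muR_full <- core$muR
    CR_full <- core$CR
    dF <- core$dF
  } else {
    dF <- 0
    if (length(drop_loc)) {
      cp <- gaussian_condition(muF, CF, drop_loc, v)
      cq <- gaussian_condition(etaF, SF, drop_loc, v)
      dF <- cp$logdens - cq$logdens
      muF <- cp$mean; CF <- cp$cov
      etaF <- cq$mean; SF <- cq$cov
    }
    muR_full <- rep(0, length(si)); CR_full <- matrix(0, length(si), length(si))
    if (length(keep_loc)) {
      kk <- si[keep_loc]
      etaR <- reduced_prior$mean[kk]
      PiR <- psd_solve(reduced_prior$cov[kk, kk, drop = FALSE],
                       label = "reduced prior covariance")
      PiFc <- psd_solve(SF, label = "conditioned prior covariance")
      PFc <- psd_solve(CF, label = "conditioned posterior covariance")
      core <- bmr_core(etaF, PiFc, muF, PFc, etaR, PiR)
      dF <- dF + core$dF
      muR_full[keep_loc] <- core$muR
      CR_full[keep_loc, keep_loc] <- core$CR
    }
    muR_full[drop_loc] <- v
  }

  mean_out <- full_prior$mean
  mean_out[si] <- muR_full
  mean_out[which(s)[drop_loc]] <- v
  cov_out <- matrix(0, full_prior$space$M, full_prior$space$M)
  cov_out[si, si] <- CR_full
  post <- gaussian_belief(full_prior$space, mean_out, sym(cov_out), sR)
  structure(list(reduced_posterior = post, delta_F = dF, F_R = F_full + dF),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> delta_F = %.4f, F_R = %.4f\n",
              x$delta_F, x$F_R))
  invisible(x)
}

#' Savage-Dickey point reduction
#'
#' Evidence ratio for pinning a subset of parameters to fixed values: the
#' zero-variance limit of [bmr_reduce()], equal to the log ratio of the
#' posterior to the prior marginal density at the point (the Savage-Dickey
#' ratio), plus the posterior over the remaining parameters conditioned on
#' the pinned values.
#'
#' @param full_prior,full_posterior [gaussian_belief()] objects.
#' @param indices integer indices (into the parameter space) to pin; must be
#'   on the support of the full prior.
#' @param values the values at which to pin them.
#' @param F_full free energy of the full model (default 0).
#' @return a `reduction_result` whose `reduced_posterior` has the pinned
#'   dimensions off-support.
#' @export
bmr_point <- function(full_prior, full_posterior, indices, values, F_full = 0) {
  indices <- as.integer(indices)
  if (any(!full_prior$support[indices]))
    stop("pinned values are off the full prior support")
  if (length(values) != length(indices))
    stop("indices and values must have equal length")
  rp_support <- full_prior$support
  rp_support[indices] <- FALSE
  rp_mean <- full_prior$mean
  rp_mean[indices] <- values
  rp <- gaussian_belief(full_prior$space, rp_mean, full_prior$cov, rp_support)
  bmr_reduce(full_prior, full_posterior, rp, F_full)
}

#' Score a set of reduced models for one inverted subject
#'
#' Applies [bmr_reduce()] to every model in a model space, given the full
#' model's inversion: an efficient way to invert large numbers of reduced
#' models after the (usually expensive) inversion of the full model.
#'
#' @param subject a `subject_inversion` (see [invert_laplace()]) or any list
#'   with `full_prior`, `full_posterior` and `evidence$F`.
#' @param models list of [model_definition()] objects.
#' @return a list with `table` (data.frame: model, delta_F, F_R) and
#'   `results` (list of `reduction_result`).
#' @export
score_model_set <- function(subject, models) {
  stopifnot(length(models) > 0)
  F_full <- subject$evidence$F
  res <- lapply(models, function(m)
    bmr_reduce(subject$full_prior, subject$full_posterior, m$reduced_prior,
               F_full))
  tab <- data.frame(model = vapply(models, `[[`, "", "name"),
                    delta_F = vapply(res, `[[`, 0, "delta_F"),
                    F_R = vapply(res, `[[`, 0, "F_R"),
                    stringsAsFactors = FALSE)
  list(table = tab, results = res)
}
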