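#' Parameter spaces
#'
#' A parameter space is an ordered set of named, unitless (log-scale)
#' parameters together with a flag marking which of them are treated as
#' random effects at the between-subject level. Every Gaussian belief,
#' observation model and second-level design in the package is anchored to a
#' parameter space, so dimension and name mismatches are caught early.
#'
#' @param names character vector of unique parameter labels.
#' @param random_effects logical vector (length `length(names)`) marking the
#'   parameters that may express between-subject random effects. Defaults to
#'   all `TRUE`.
#' @return an object of class `parameter_space` with fields `names`, `M`
#'   (total dimension) and `random_effects`.
#' @export
parameter_space <- function(names, random_effects = rep(TRUE, length(names))) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("parameter names must be unique")
  if (length(names) == 0L) stop("empty parameter space")
  random_effects <- as.logical(random_effects)
  if (length(random_effects) != length(names))
    stop("random_effects mask length must equal the number of parameters")
  structure(list(names = names, M = length(names),
                 random_effects = random_effects),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("<parameter_space> M =", x$M, "(", sum(x$random_effects),
      "random effects )\n")
  invisible(x)
}

same_space <- function(a, b) {
  identical(a$names, b$names)
}

# symmetrise before any factorisation; float drift in iterative schemes
# otherwise trips the Cholesky
sym <- function(A) (A + t(A)) / 2

# Cholesky with a jitter ladder 1e-12 .. 1e-6 (relative to mean diagonal);
# errors only once the ladder is exhausted.
chol_jitter <- function(A, label = "matrix") {
  A <- sym(A)
  scale <- mean(abs(diag(A)))
  if (!is.finite(scale) || scale == 0) scale <- 1
  for (j in c(0, 10^seq(-12, -6, by = 2))) {
    R <- tryCatch(chol(A + diag(j * scale, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop(label, " is not positive definite (jitter ladder exhausted)")
}

# solve A x = b for symmetric positive-definite A
psd_solve <- function(A, b = diag(nrow(A)), label = "matrix") {
  R <- chol_jitter(A, label)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' Log pseudo-determinant of a PSD matrix on a support subspace
#'
#' Computes `log det` of the submatrix of `A` indexed by `support`,
#' via Cholesky with a jitter fallback and a spectral fallback. Dimensions
#' outside the support contribute nothing (pseudo-determinant).
#'
#' @param A symmetric positive-semidefinite matrix.
#' @param support logical mask of the active dimensions (default all).
#' @return the log pseudo-determinant in nats.
#' @export
logdet_psd <- function(A, support = rep(TRUE, nrow(A))) {
  A <- as.matrix(A)
  support <- rep_len(as.logical(support), nrow(A))
  if (!any(support)) return(0)
  As <- sym(A[support, support, drop = FALSE])
  R <- tryCatch(chol(As), error = function(e) NULL)
  if (!is.null(R)) return(2 * sum(log(diag(R))))
  ev <- eigen(As, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(abs(ev), 1)
  if (any(ev < -tol))
    stop("negative eigenvalue (", format(min(ev)), ") beyond tolerance in logdet_psd")
  sum(log(pmax(ev, tol)))
}

#' Gaussian beliefs over a parameter space
#'
#' A `gaussian_belief` is the package's single container for priors,
#' posteriors and empirical priors: a mean vector and a symmetric PSD
#' covariance over a [parameter_space()], plus a logical `support` mask.
#' Dimensions outside the support have exactly zero variance (the parameter
#' is "switched off", i.e. pinned to its mean); their covariance rows and
#' columns are stored as exact zeros.
#'
#' @param space a [parameter_space()].
#' @param mean numeric vector of length `space$M` (off-support entries hold
#'   the pinned values).
#' @param cov covariance matrix (`space$M` square), or a numeric vector of
#'   variances, or a scalar variance.
#' @param support logical mask of dimensions with nonzero variance.
#' @return an object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(space, mean, cov, support = rep(TRUE, space$M)) {
  stopifnot(inherits(space, "parameter_space"))
  M <- space$M
  mean <- as.numeric(mean)
  if (length(mean) == 1L) mean <- rep(mean, M)
  if (length(mean) != M) stop("mean length does not match parameter space")
  if (is.null(dim(cov))) {
    v <- as.numeric(cov)
    if (length(v) == 1L) v <- rep(v, M)
    cov <- diag(v, M)
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(M, M))) stop("covariance dimension mismatch")
  rel <- max(abs(cov - t(cov))) / max(abs(cov), 1e-300)
  if (rel > 1e-8) stop("covariance is not symmetric")
  cov <- sym(cov)
  if (any(diag(cov) < 0))
    stop("covariance has a negative eigenvalue beyond tolerance (negative variance)")
  support <- rep_len(as.logical(support), M)
  # zero variance on the diagonal also switches a dimension off
  support <- support & (diag(cov) > 0)
  cov[!support, ] <- 0
  cov[, !support] <- 0
  if (any(support)) {
    ev <- eigen(cov[support, support, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1))
      stop("covariance has a negative eigenvalue beyond tolerance")
  }
  structure(list(space = space, mean = mean, cov = cov, support = support),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("<gaussian_belief> M =", x$space$M, ", support =", sum(x$support), "\n")
  m <- rbind(mean = x$mean, sd = sqrt(diag(x$cov)))
  colnames(m) <- x$space$names
  print(round(m, 4))
  invisible(x)
}

#' Precision of a belief on its support
#'
#' @param b a [gaussian_belief()].
#' @return precision matrix over the support dimensions (a 0x0 matrix for a
#'   fully switched-off belief).
#' @export
belief_precision <- function(b) {
  s <- b$support
  if (!any(s)) return(matrix(0, 0, 0))
  psd_solve(b$cov[s, s, drop = FALSE], label = "belief covariance")
}

#' Kullback-Leibler divergence between two Gaussian beliefs
#'
#' `KL(q || p)` in nats, computed on the joint support subspace. The support
#' of `q` must be contained in the support of `p` (a point mass where `p`
#' has no mass would make the divergence undefined).
#'
#' @param q,p [gaussian_belief()] objects over the same parameter space.
#' @return a non-negative number of nats.
#' @export
kl_gaussian <- function(q, p) {
  if (!same_space(q$space, p$space)) stop("beliefs live on different parameter spaces")
  if (any(q$support & !p$support))
    stop("support violation: q has mass where p has none")
  s <- q$support
  k <- sum(s)
  if (k == 0L) return(0)
  Sq <- q$cov[s, s, drop = FALSE]
  Sp <- p$cov[s, s, drop = FALSE]
  d <- q$mean[s] - p$mean[s]
  Pp <- psd_solve(Sp, label = "p covariance")
  0.5 * (sum(Pp * Sq) + drop(crossprod(d, Pp %*% d)) - k +
           logdet_psd(Sp) - logdet_psd(Sq))
}

#' Log density of a Gaussian belief at a point
#'
#' Evaluated on the support subspace; off-support coordinates of `x` must
#' equal the pinned means (to 1e-8 absolute), otherwise the density is zero
#' and an error is raised.
#'
#' @param x numeric vector of length `space$M`.
#' @param b a [gaussian_belief()].
#' @return log density in nats.
#' @export
gaussian_log_density <- function(x, b) {
  x <- as.numeric(x)
  if (length(x) != b$space$M) stop("x length does not match parameter space")
  s <- b$support
  if (any(abs(x[!s] - b$mean[!s]) > 1e-8))
    stop("x is off the support of the belief")
  k <- sum(s)
  if (k == 0L) return(0)
  S <- b$cov[s, s, drop = FALSE]
  d <- x[s] - b$mean[s]
  P <- psd_solve(S, label = "covariance")
  -0.5 * (k * log(2 * pi) + logdet_psd(S) + drop(crossprod(d, P %*% d)))
}

#' Marginal of a belief over a subset of dimensions
#' @param b a [gaussian_belief()].
#' @param idx integer or logical index of the dimensions to keep.
#' @return list with `mean`, `cov`, `support` restricted to `idx`.
#' @keywords internal
belief_marginal <- function(b, idx) {
  list(mean = b$mean[idx], cov = b$cov[idx, idx, drop = FALSE],
       support = b$support[idx])
}

# Condition the Gaussian (mean, cov) on coordinates `idx` taking `values`.
# Returns the conditional mean/cov over the remaining coordinates plus the
# log marginal density of `values`. All coordinates in idx must be on
# support.
gaussian_condition <- function(mean, cov, idx, values) {
  keep <- setdiff(seq_along(mean), idx)
  Sbb <- cov[idx, idx, drop = FALSE]
  Sab <- cov[keep, idx, drop = FALSE]
  d <- values - mean[idx]
  K <- t(psd_solve(Sbb, t(Sab), label = "conditioning block"))
  ld <- -0.5 * (length(idx) * log(2 * pi) + logdet_psd(Sbb) +
                  drop(crossprod(d, psd_solve(Sbb, d))))
  list(mean = mean[keep] + drop(K %*% d),
       cov = sym(cov[keep, keep, drop = FALSE] - K %*% t(Sab)),
       logdens = ld, keep = keep)
}

#' Serialise a Gaussian belief to JSON
#'
#' Round-trips means and covariances at full float64 precision (17
#' significant digits), with row-major covariance storage.
#'
#' @param b a [gaussian_belief()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly if written to a file).
#' @export
belief_to_json <- function(b, path = NULL) {
  obj <- list(names = b$space$names,
              random_effects = b$space$random_effects,
              mean = b$mean,
              cov = as.numeric(t(b$cov)),   # row-major
              support = b$support)
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialise a Gaussian belief from JSON
#' @param x a JSON string or a file path produced by [belief_to_json()].
#' @return a [gaussian_belief()].
#' @export
belief_from_json <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- paste(readLines(x), collapse = "")
  obj <- jsonlite::fromJSON(x)
  sp <- parameter_space(obj$names, obj$random_effects)
  M <- sp$M
  gaussian_belief(sp, obj$mean,
                  matrix(obj$cov, M, M, byrow = TRUE),
                  obj$support)
}

#' Evidence records
#'
#' Bundles a free energy with its accuracy/complexity decomposition
#' (`F = accuracy - complexity`), all in nats.
#' @param accuracy,complexity numbers in nats.
#' @return an object of class `evidence_record` with fields `F`, `accuracy`,
#'   `complexity`.
#' @export
evidence_record <- function(accuracy, complexity) {
  structure(list(F = accuracy - complexity, accuracy = accuracy,
                 complexity = complexity),
            class = "evidence_record")
}

#' @export
print.evidence_record <- function(x, ...) {
  cat(sprintf("<evidence_record> F = %.4f (accuracy %.4f - complexity %.4f)\n",
              x$F, x$accuracy, x$complexity))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Draw n samples from N(mean, cov) (chol-based; no external dependency).
rmvnorm_chol <- function(n, mean, cov) {
  k <- length(mean)
  if (k == 0L) return(matrix(0, n, 0))
  R <- chol_jitter(cov, "sampling covariance")
  Z <- matrix(stats::rnorm(n * k), n, k)
  sweep(Z %*% R, 2, mean, "+")
}
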