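#' Simulation configuration for hierarchical group studies
#'
#' Describes a two-group study with the statistical structure of a typical
#' evoked-response group analysis: subject parameters are group means plus
#' Gaussian random effects whose variance is a fixed fraction (default a
#' sixteenth) of the first-level prior variance; group differences of a
#' fixed number of between-subject standard deviations (default two) are
#' restricted to one parameter block; observations mix the parameters
#' through per-subject random matrices (standing in for random lead
#' fields) and carry smoothed observation noise whose standard deviation is
#' a fixed fraction (default an eighth) of the signal standard deviation.
#'
#' The parameter space has three blocks of condition-effect parameters
#' ("forward", "backward", "intrinsic"); the generating model (default
#' model 3 of the 8-model lattice: intrinsic + forward) switches blocks
#' off by pinning them to zero. Group differences follow model 4
#' (intrinsic only): an attenuation of the condition effects in the second
#' group.
#'
#' @param n_per_group subjects per group (default 8).
#' @param block_sizes named sizes of the forward/backward/intrinsic blocks
#'   (default 2, 2, 4).
#' @param model_family `"linear"` (`y = A theta + e`) or `"sigmoid"`
#'   (`y = tanh(A theta) + e`, weakly nonlinear).
#' @param generating_model index into the Table-1-style lattice of
#'   [make_model_space()] (default 3: intrinsic + forward on).
#' @param effect_range range the true condition effects are drawn from
#'   (default `c(0.1, 0.4)`).
#' @param prior_var first-level prior variance per parameter (default 1/4).
#' @param between_var_ratio between-subject variance as a fraction of the
#'   prior variance (default 1/16).
#' @param group_diff_sd_units group difference in units of the
#'   between-subject SD (default 2), applied to the intrinsic block.
#' @param noise_sd_ratio observation-noise SD as a fraction of the signal
#'   SD (default 1/8).
#' @param noise_smoothing_bins moving-average kernel width for the noise
#'   (default 8).
#' @param n_obs number of observation samples per subject (default 32).
#' @param mixing per-subject random observation-mixing matrices (default
#'   TRUE).
#' @param seed RNG seed fixing the dataset bit-for-bit.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 8,
                              block_sizes = c(forward = 2, backward = 2,
                                              intrinsic = 4),
                              model_family = c("linear", "sigmoid"),
                              generating_model = 3,
                              effect_range = c(0.1, 0.4),
                              prior_var = 1 / 4,
                              between_var_ratio = 1 / 16,
                              group_diff_sd_units = 2,
                              noise_sd_ratio = 1 / 8,
                              noise_smoothing_bins = 8,
                              n_obs = 32,
                              mixing = TRUE,
                              seed = 1) {
  model_family <- match.arg(model_family)
  stopifnot(between_var_ratio >= 0, noise_sd_ratio >= 0, prior_var > 0,
            group_diff_sd_units >= 0, n_per_group >= 1,
            noise_smoothing_bins >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

sim_space <- function(config) {
  bs <- config$block_sizes
  nm <- unlist(lapply(names(bs), function(b) paste0(b, seq_len(bs[[b]]))))
  parameter_space(nm)
}

sim_blocks <- function(config) {
  bs <- config$block_sizes
  idx <- split(seq_len(sum(bs)), rep(names(bs), bs))
  idx[names(bs)]
}

# moving-average smoothing, edge-padded, then standardised
smooth_noise <- function(n, bins) {
  e <- stats::rnorm(n + bins - 1)
  k <- rep(1 / bins, bins)
  sm <- stats::filter(e, k, sides = 1)[bins:(n + bins - 1)]
  as.numeric(sm) / stats::sd(sm)
}

#' Simulate a hierarchical two-group study
#'
#' Draws true group effects, subject parameters and observations under the
#' stated generative model: `theta_i = (x_i kron I) beta_true + eps2` with
#' `eps2 ~ N(0, between_var)` on the blocks retained by the generating
#' model, and `y_i = Gamma_i(theta_i) + noise` with smoothed noise rescaled
#' to the configured signal-to-noise ratio. Two calls with the same seed
#' are bit-identical.
#'
#' @param config a [simulation_config()].
#' @return a list: `y` (list of observation vectors), `A` (list of mixing
#'   matrices), `models` (list of [nonlinear_model()] per subject),
#'   `theta_true` (`N x M` matrix), `X` (design: mean, group, confound),
#'   `beta_true` (`B x M` matrix of true effects), `space`, `prior`
#'   ([gaussian_belief()]), `blocks`, `config`.
#' @export
simulate_group_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    space <- sim_space(config)
    M <- space$M
    blocks <- sim_blocks(config)
    N <- 2 * config$n_per_group
    bv <- config$prior_var * config$between_var_ratio
    sigma_b <- sqrt(bv)

    on_idx <- sort(unlist(blocks[model_space_blocks_on(config$generating_model)]))
    ## true effects: condition means on the "on" blocks, group attenuation
    ## on the intrinsic block, zero confound effect
    beta_true <- matrix(0, 3, M,
                        dimnames = list(c("mean", "group", "confound"),
                                        space$names))
    beta_true["mean", on_idx] <- stats::runif(length(on_idx),
                                              config$effect_range[1],
                                              config$effect_range[2])
    diff_idx <- intersect(blocks$intrinsic, on_idx)
    beta_true["group", diff_idx] <-
      -config$group_diff_sd_units * sigma_b / 2

    X <- cbind(mean = 1,
               group = rep(c(-1, 1), each = config$n_per_group),
               confound = stats::rnorm(N))

    theta_true <- matrix(0, N, M, dimnames = list(NULL, space$names))
    for (i in seq_len(N)) {
      m <- drop(X[i, ] %*% beta_true)
      eps <- numeric(M)
      eps[on_idx] <- stats::rnorm(length(on_idx), 0, sigma_b)
      th <- m + eps
      th[setdiff(seq_len(M), on_idx)] <- 0   # off blocks are exactly absent
      theta_true[i, ] <- th
    }

    D <- config$n_obs
    A_common <- matrix(stats::rnorm(D * M), D, M) / sqrt(M)
    y <- vector("list", N); A <- vector("list", N)
    models <- vector("list", N)
    fam <- config$model_family
    for (i in seq_len(N)) {
      Ai <- if (config$mixing)
        matrix(stats::rnorm(D * M), D, M) / sqrt(M) else A_common
      signal <- if (fam == "linear") drop(Ai %*% theta_true[i, ])
      else tanh(drop(Ai %*% theta_true[i, ]))
      noise <- smooth_noise(D, config$noise_smoothing_bins) *
        stats::sd(signal) * config$noise_sd_ratio
      y[[i]] <- signal + noise
      A[[i]] <- Ai
      models[[i]] <- if (fam == "linear") linear_model(space, Ai)
      else local({
        Ai_local <- Ai
        nonlinear_model(space,
                        predict = function(theta) tanh(drop(Ai_local %*% theta)),
                        noise_components = list(diag(D)),
                        jacobian = function(theta) {
                          u <- drop(Ai_local %*% theta)
                          (1 / cosh(u)^2) * Ai_local
                        })
      })
    }
    prior <- gaussian_belief(space, 0, config$prior_var)
    list(y = y, A = A, models = models, theta_true = theta_true, X = X,
         beta_true = beta_true, space = space, prior = prior,
         blocks = blocks, config = config)
  })
}

# which blocks are "on" for model k of the Table-1-style lattice
# (1 = all three, 8 = none)
model_space_blocks_on <- function(k) {
  lattice <- list(c("intrinsic", "forward", "backward"),
                  c("intrinsic", "backward"),
                  c("intrinsic", "forward"),
                  "intrinsic",
                  c("forward", "backward"),
                  "backward",
                  "forward",
                  character(0))
  lattice[[k]]
}

#' The 8-model nested lattice over three parameter blocks
#'
#' All on/off combinations of the forward, backward and intrinsic blocks,
#' ordered with model 1 = all blocks on and model 8 = none; "off" means a
#' zero-mean, zero-variance reduced prior on the block.
#'
#' @param full_prior the full-model prior, a [gaussian_belief()].
#' @param blocks named list of disjoint index vectors `forward`,
#'   `backward`, `intrinsic`.
#' @return list of 8 [model_definition()] objects.
#' @export
make_model_space <- function(full_prior, blocks) {
  idx <- unlist(blocks)
  if (anyDuplicated(idx)) stop("parameter blocks must be disjoint")
  lapply(1:8, function(k) {
    on <- model_space_blocks_on(k)
    supp <- full_prior$support
    mn <- full_prior$mean
    for (b in setdiff(names(blocks), on)) {
      supp[blocks[[b]]] <- FALSE
      mn[blocks[[b]]] <- 0
    }
    nm <- if (length(on)) paste(on, collapse = "+") else "none"
    model_definition(sprintf("m%d:%s", k, nm),
                     gaussian_belief(full_prior$space, mn, full_prior$cov,
                                     supp))
  })
}

#' Invert every subject of a simulated study
#'
#' Convenience wrapper running [invert_laplace()] (or the conjugate exact
#' path for linear models with `exact = TRUE`) on every subject of a
#' [simulate_group_study()] dataset. The noise log-precision hyperprior is
#' `N(0, 16)`: weakly informative, because the signal scale (and hence the
#' noise precision) of the generator is not normalised.
#'
#' @param sim output of [simulate_group_study()].
#' @param exact use the conjugate closed form with the true noise variance
#'   (linear family only; default FALSE).
#' @param opts passed to [invert_laplace()].
#' @return list of `subject_inversion` objects.
#' @export
fit_group <- function(sim, exact = FALSE, opts = list()) {
  N <- length(sim$y)
  hs <- parameter_space("lambda1")
  hyper_prior <- gaussian_belief(hs, 0, 16)
  lapply(seq_len(N), function(i) {
    if (exact) {
      if (sim$config$model_family != "linear")
        stop("exact inversion is only available for the linear family")
      sd_sig <- stats::sd(drop(sim$A[[i]] %*% sim$theta_true[i, ]))
      nv <- (sd_sig * sim$config$noise_sd_ratio)^2
      conjugate_invert(sim$A[[i]], sim$y[[i]], sim$prior,
                       diag(nv, length(sim$y[[i]])))
    } else {
      suppressWarnings(invert_laplace(sim$models[[i]], sim$y[[i]], sim$prior,
                                      hyper_prior, opts))
    }
  })
}
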