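---
title: "Bayesian model reduction and parametric empirical Bayes: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian model reduction and parametric empirical Bayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Group studies with nonlinear within-subject models (dynamic causal models
being the canonical example) face three coupled inference problems:
which model architecture generated each subject's data, what the group-level
effects on the model parameters are, and how to use a fitted group model to
say something about a new subject. `pebr` addresses all three with a single
computational primitive — *Bayesian model reduction* (BMR) — embedded in a
two-level Gaussian hierarchy (*parametric empirical Bayes*, PEB).

## The generative model

At the first level, subject $i$'s data are
$y_i = \Gamma_i(\theta_i) + \varepsilon^{(1)}_i$, with a possibly nonlinear
observation mapping $\Gamma_i$, Gaussian prior
$\theta_i \sim \mathcal N(\eta, \Sigma_0)$ and noise covariance
$\Sigma(\lambda) = \sum_k e^{-\lambda_k} V_k$ parameterised by
log-precisions $\lambda$. Inversion maximises the Laplace free energy

$$F = \underbrace{E_q[\ln p(y\mid\theta)]}_{\text{accuracy}}
    - \underbrace{D_{KL}(q\,\|\,p)}_{\text{complexity}},$$

a lower bound on the log evidence, by Gauss–Newton ascent on $\theta$ with
Levenberg–Marquardt damping and a damped Newton step on $\lambda$
(mean-field alternation). When $\Gamma$ is linear the scheme is exact: the
posterior and $F$ coincide with the conjugate closed forms, which is the
backbone of the package's oracle tests.

At the second level, the random-effect parameters follow the linear model
$\theta_i = (x_i \otimes W)\beta + \varepsilon^{(2)}_i$ with between-subject
precision $\Pi^{(2)}(\gamma) = Q_0 + \sum_j e^{-\gamma_j} Q_j$: a design row
$x_i$ (constant first, then group/covariate columns), a within-subject
design $W$ selecting mixtures of parameters, precision components $Q_j$
scaled by log-precisions $\gamma$, and a precision floor $Q_0$. The
vectorisation convention is "within-subject index fast": $\beta$ is ordered
by design column (slow) and parameter pattern (fast), which makes
$X \otimes W$ literal.

## Bayesian model reduction

For two models sharing a likelihood and differing only in their Gaussian
priors, the posterior and evidence of the *reduced* (more constrained)
model follow in closed form from the full model's posterior:

$$P_R = P_F + \Pi_R - \Pi_F,\qquad
  \mu_R = C_R\,(P_F\mu_F + \Pi_R\eta_R - \Pi_F\eta_F),$$

with the evidence change given by split log-determinants and quadratic
forms (see `?bmr_reduce`). Two numerical choices matter:

* **Switched-off parameters.** Setting a prior variance to zero makes the
  printed formula singular, so zero-variance dimensions are handled by
  exact subspace restriction: the evidence contribution of pinning
  $\theta_d = v$ is the marginal Savage–Dickey ratio
  $\ln q(v) - \ln p(v)$, and the surviving dimensions are conditioned on
  $\theta_d = v$ before the finite-precision identity is applied. A
  large-precision fallback (precision $2^{32}$) is provided and tested to
  agree with the subspace path (to about $10^{-6}$ in posterior means;
  agreement in $\Delta F$ is problem-dependent at around $10^{-5}$, which
  is why the subspace path is the default).
* **Determinants.** $\tfrac12\ln|\Pi_R P_F C_R \Sigma_F|$ is computed as
  $\tfrac12[\ln|\Pi_R| - \ln|\Pi_F| + \ln|P_F| - \ln|P_R|]$ — algebraically
  identical, but each factor is symmetric positive definite so a Cholesky
  factorisation (with a jitter ladder $10^{-12}\ldots10^{-6}$ on failure)
  is stable. Every matrix is symmetrised before factorisation.

## The second level

PEB never re-inverts subjects: the second-level free energy is the sum of
each subject's *reduced* free energy under the empirical prior
$\mathcal N((x_i\otimes W)\beta,\ \Sigma^{(2)}(\gamma))$, plus prior terms
on $(\beta, \gamma)$. Because the reduced free energy is exactly quadratic
in the empirical prior *mean*, the $\beta$ step is a single exact Newton
step given $\gamma$; $\gamma$ enters through determinants, so its step uses
central finite differences (step $10^{-3}$) with backtracking. Convergence
is declared when $|\Delta F_2| < 10^{-4}$ on four consecutive iterations
(at most 64); the objective trace is non-decreasing by construction.

One genuine ambiguity in the source material had to be resolved: the
printed stationarity condition for the posterior precision over
$(\beta,\gamma)$ omits the second-level prior precision, while the free
energy it derives from carries it. The package defaults to the
self-consistent Laplace fixed point
$P^{(2)} = \Pi^{(2)}_{prior} - \partial^2_{\mu}\sum_i \Delta F_i$
(`hessian = "consistent"`) and exposes `hessian = "paper"` for the printed
form; the two coincide whenever the prior curvature is absorbed into the
per-subject terms.

### Defaults, with units and reasons

| quantity | default | why |
|---|---|---|
| $Q_0$ (precision floor) | $\mathrm{diag}(\Pi_{prior})/16$ | a between-subject variance can be at most 16 prior variances; keeps $\Sigma^{(2)}$ finite for any $\gamma$ |
| $Q_1$ (single component) | $16\,\mathrm{diag}(\Pi_{prior})$ | $\gamma = 0$ then means "between-subject variance = prior variance / 16", the canonical operating point for this model family; a unit matrix would put the plausible regime several prior SDs from the origin of the $\mathcal N(0,1)$ $\gamma$ prior |
| $\gamma$ prior | $\mathcal N(0, 1)$ (per component, nats) | unit prior variance on second-level log precisions |
| $\beta$ prior | first-level prior variances tiled over design columns; mean = first-level prior mean for the constant column, 0 elsewhere | the full priors play the role of second-level priors; using the first-level prior mean for the group-mean column makes the construction correct when prior means are nonzero (identical otherwise) |
| $W$ | identity over random effects | every random-effect parameter may express every group effect |
| first-level $\lambda$ prior | $\mathcal N(0, 1/16)$ per component | weakly informative around unit noise precision for normalised data |
| $|\gamma| \le 32$, $|\lambda| \le 32$ | overflow guard | $e^{32}$ is already beyond float-relevant precision ranges |

The group-study pipeline (`fit_group()`) overrides the $\lambda$ prior with
$\mathcal N(0, 16)$: the synthetic generator does not normalise signal
scale, so the true noise log-precision sits several nats from zero and a
prior standard deviation of 4 nats is the honest statement of ignorance.
This choice was fixed before any acceptance measurement.

## Model-space operators

Given an $N\times K$ array of subjects by (nested) models, the package
provides: fixed-effects comparison (sum $F$ over subjects, softmax),
random-effects comparison (variational Dirichlet over model frequencies,
exceedance probabilities by $10^5$ seeded Dirichlet draws), Bayesian model
averaging per subject (softmax weights inside an Occam's window, default 8
nats — windows in the source are display-only, so the averaging window is
an explicit, configurable choice here), and Bayesian parameter averaging
per model ($P = \sum_i P_i - (N-1)\Pi_{prior}$, which removes the
$N-1$-fold double-counting of the shared prior).

The second-level subset search scores every combination of non-constant
group effects by pinning them to zero in the $(\beta,\gamma)$ posterior
(exhaustive up to 16 candidates, greedy backward elimination beyond, ties
broken by lowest index). Scoring uses only the Savage–Dickey marginal
ratio over the pinned dimensions, so exhaustive searches stay cheap; full
reduced posteriors are materialised only inside the Occam window. The
greedy path can in principle miss the global optimum on strongly
correlated posteriors; the acceptance suite checks agreement with the
exhaustive argmax on ten-effect problems.

## Classification

Prediction for a held-out subject swaps the roles of the design row and
the effects: with trained expectations $(\tilde\beta, \tilde\gamma)$ the
empirical prior mean $(x\otimes W)\tilde\beta$ is *linear in the unknown
design entries* $x$, so their posterior is Gaussian and exact (single
Newton step). Known entries are fixed with tight priors (variance
$10^{-8}$; the value is a stated choice, the source gives none), unknown
entries get $\mathcal N(0,1)$ priors matching unit-scaled design columns.
Categorical labels are scored by reducing the $x$ posterior to a point
mass at each label — the Savage–Dickey ratio test — and probabilities are
the softmax of the resulting free energies. Only the trained
*expectations* are propagated by default; `integrate_training = TRUE`
additionally folds the trained $\beta$ covariance into the empirical prior
(documented extension, off by default).

## The synthetic world

The generator (`simulate_group_study()`) emulates the statistical
structure of a two-group evoked-response study without its biophysics:

* two groups of 8 subjects; 8 log-scale parameters in three blocks
  (forward 2, backward 2, intrinsic 4) mirroring the three-factor model
  lattice (`make_model_space()`, model 1 = all blocks, model 8 = none);
* condition effects drawn once per dataset from $U(0.1, 0.4)$ on the
  blocks of the generating model (default model 3: intrinsic + forward) —
  the source states the range but prints per-connection values only in a
  figure, so uniform sampling within the range is used;
* between-subject variance fixed at a sixteenth of the prior variance
  (prior variance 1/4 per parameter, a typical scale for log-scaling
  parameters; the source defines the ratio, not the absolute scale);
* group differences of two between-subject SDs, restricted to the
  intrinsic block (model-4 pattern), as an attenuation in the second
  group; a standard-normal "age" confound column with zero true effect;
* per-subject random mixing matrices $A_i$ (entries
  $\mathcal N(0, 1/M)$) standing in for random lead fields — these are
  *known* to the observation model, whereas the source estimates
  lead-field parameters as fixed effects; estimating them is out of scope
  here and this is the main respect in which a green test understates the
  difficulty of the real problem;
* observation noise built by moving-average smoothing of white noise over
  8 bins, rescaled to an eighth of the signal SD. The smoothing makes the
  noise mildly autocorrelated while the model assumes white noise — a
  deliberate, realistic mismatch;
* `model_family = "linear"` ($y = A\theta$) makes every assumption of the
  scheme true, enabling exact oracles (GLS/conjugate);
  `model_family = "sigmoid"` ($y = \tanh(A\theta)$) provides a weakly
  nonlinear surrogate. Neither reproduces neural-mass dynamics; green
  tests establish correctness of the inference machinery, not fidelity to
  any particular biophysical model.

Everything is driven by one seed per dataset and is bit-reproducible; the
generator restores the caller's RNG state.

## Known limitations

* Second-to-first-level mappings are restricted to the linear
  $(X\otimes W)\beta$ form; general nonlinear mappings are not supported.
* Reductions cannot compare models with different likelihoods.
* The noise model is a mixture of fixed covariance components; no AR or
  free-form covariance estimation.
* Serialisation is JSON/CSV only (no HDF5 backend in this build); files
  round-trip float64 bit-exactly.
* Exceedance probabilities are Monte-Carlo estimates; their error scales
  as $(p(1-p)/10^5)^{1/2}$ at the default draw count.
* Because classification propagates only the trained *expectations*, its
  categorical probabilities are overconfident when the trained group
  effect is spurious: under a permuted-label null the between-subject
  precision still makes the unknown design entry look identifiable. A
  permuted-label control of leave-one-out classification is therefore
  not centred on 0.5 — a training-only permutation
  (`loo_cross_validation(null_permute = TRUE)`) sits below chance
  (cross-validation pessimism), while permuting one shared label vector
  sits above it with large draw-to-draw variance. The acceptance suite
  reports this honestly rather than averaging it away.
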