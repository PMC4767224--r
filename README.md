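# pebr

Bayesian model reduction and parametric empirical Bayes for hierarchical
group studies with nonlinear first-level models.

## Who this is for

Analysts of group studies in which each subject is described by a
(possibly nonlinear) generative model with Gaussian priors — dynamic
causal models of neuroimaging time series being the canonical case, but
any observation mapping `theta -> prediction` fits the contract. The
package answers three questions without ever re-fitting models:

1. **Which architecture generated the data?** Invert the *full* model once
   per subject, then score arbitrarily many nested models analytically.
2. **What are the group effects?** Invert the between-subject level from
   the first-level posteriors alone, with empirical shrinkage priors.
3. **What group does a new subject belong to?** Use the trained empirical
   priors to estimate unknown design-matrix entries (e.g. diagnosis).

## The core identity

For two models sharing a likelihood and differing only in their Gaussian
priors (full: `eta_F, Sigma_F`; reduced: `eta_R, Sigma_R`), the reduced
posterior `N(mu_R, C_R)` and evidence change follow in closed form from
the full posterior `N(mu_F, C_F)`:

    P_R  = P_F + Pi_R - Pi_F
    mu_R = C_R (P_F mu_F + Pi_R eta_R - Pi_F eta_F)
    dF   = 1/2 [ln|Pi_R| - ln|Pi_F| + ln|P_F| - ln|P_R|]
         - 1/2 [mu_F' P_F mu_F + eta_R' Pi_R eta_R
                - eta_F' Pi_F eta_F - mu_R' P_R mu_R]

(`Pi`/`P` are prior/posterior precisions). Everything else in the package
— model comparison, empirical Bayes, subset search, Savage–Dickey
classification — is this identity applied in different directions. The
second level is the multivariate linear model `theta_i = (x_i (x) W) beta`
with between-subject precision `Q0 + sum_j exp(-gamma_j) Q_j`; see the
methods vignette (`vignettes/bmr-peb-methods.Rmd`) for conventions,
defaults and design choices.

## Worked example

```r
library(pebr)

sim  <- simulate_group_study(simulation_config(seed = 1))  # 8 + 8 subjects
subs <- fit_group(sim)                                     # variational Laplace
ms   <- make_model_space(sim$prior, sim$blocks)            # 8 nested models
ffx_bmc(model_array(subs, ms))$prob
#> m1:intrinsic+forward+backward  m2:intrinsic+backward  m3:intrinsic+forward ...
#>                             0                      0                     1 ...
```

The fixed-effects comparison puts probability 1 on model 3 — the model the
data were generated under (condition effects in the intrinsic and forward
blocks). The second level recovers the group effects:

```r
fit <- peb_invert(subs, second_level_model(sim$X))
fit
#> <second_level_posterior> N = 16, B = 3, C = 8, F2 = 610.992 (converged)
#>      mean:c5 mean:c6 mean:c7 mean:c8 ... group:c5 group:c6 group:c7 group:c8
#> mean  0.2698  0.4012  0.1314  0.4056 ...  -0.0655  -0.0832  -0.1065  -0.1741
#> sd    0.0233  0.0232  0.0234  0.0232 ...   0.0230   0.0229   0.0231   0.0229
```

The four `group:c5..c8` entries are the intrinsic-block group effects
(truth: -0.125 each, i.e. an attenuation of two between-subject SDs in the
second group); forward/backward group effects and all confound effects are
estimated near zero. Leave-one-out classification from the trained second
level labels every subject correctly:

```r
loo <- loo_cross_validation(subs, second_level_model(sim$X), "group")
sum(sign(loo$post_mean) == sign(loo$truth))
#> 16
head(loo[, c("post_mean", "post_sd", "1", "truth", "p_correct")], 4)
#>   post_mean post_sd     1 truth p_correct
#> 1    -0.738   0.433 0.000    -1     1.000
#> 2    -1.116   0.373 0.000    -1     1.000
#> 3    -0.036   0.324 0.337    -1     0.663
#> 4    -1.192   0.371 0.000    -1     1.000
```

`post_mean`/`post_sd` are the Gaussian posterior over the held-out
subject's group entry (truth is -1 or +1); `p_correct` is the
Savage–Dickey categorical probability of the true label.

## Command line

```sh
Rscript -e 'pebr::pebr_cli()' simulate --seed 1 --out out/   # X.csv, y.csv, truth.json
Rscript -e 'pebr::pebr_cli()' bmc      --seed 1 --out out/   # model-comparison CSV
Rscript -e 'pebr::pebr_cli()' loo      --seed 1 --out out/   # classification CSV
```

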