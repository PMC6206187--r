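# occutide

Dynamic (multi-season) Bayesian occupancy modelling for benthic marine
fish surveyed by replicate drop-camera deployments, where detectability is
driven by tidal bottom currents and canopy-forming algae.

Camera surveys of cryptic reef fish detect the animal only some of the
time it is present, so raw detection maps understate occupancy and conflate
non-detection with absence. `occutide` separates the two processes with the
dynamic occupancy model: a latent occupancy state per site and season that
evolves through persistence and colonization, observed through a detection
submodel whose probability varies replicate by replicate. It is written for
ecologists analysing repeat-visit video surveys in tidally energetic
habitats — and for anyone who wants a fully tested, self-contained
Metropolis-within-Gibbs implementation of this model class with indicator
variable selection.

## The model

For site *i*, season *t*, replicate *j*:

```
z[i,1]   ~ Bern(psi_i)
z[i,t+1] ~ Bern(z[i,t] * phi_t + (1 - z[i,t]) * gamma_t)
y[i,t,j] ~ Bern(z[i,t] * p[i,t,j])

logit(p)   = a1 + a2*Current + a3*none + a4*Current:none [+ ae*Effort]
logit(psi) = b1 [+ b2*Depth + b3*RDMV + b4*CurMax + b5*CurMax^2]   (model B)
```

`Current` is the bottom-current speed at the moment of the observation
(matched to the nearest 20-minute step of a tidal current series), `none`
indicates the bottom type without canopy-forming algae, and all continuous
covariates are standardized. Coefficients carry scaled-t priors
(0, 1.566, 7.763) and Bernoulli(0.5) inclusion indicators (Kuo–Mallick
selection; the interaction's effective indicator is the product with both
main effects). Persistence/colonization get uniform priors and exact
conjugate Beta updates; latent states are drawn by forward-filtering
backward-sampling. Everything is validated against a brute-force
enumeration of the latent states and a battery of calibration studies.

Because no field dataset ships with the package, a first-class synthetic
module generates study-like inputs — M2 tidal current series with per-site
phase lags, depth-stratified site covariates, RDMV terrain attributes, and
detection histories with known truth — so every stage is testable offline.

## Worked example

```r
library(occutide)

sim <- simulate_study(seed = 1)      # 14 sites, 4 seasons, mean 2 replicates
sim$data
#> Detection history: 14 sites x 4 seasons, up to 3 replicates
#>   119 observed replicates, 39 with detections

fit <- fit_dom(sim$data, sim$covs, model = "A",
               chains = chain_config(4, 4000, 1000, 3, seed = 2))
finite_sample_occupancy(fit)
#> Finite-sample occupancy (proportion of sampled sites occupied):
#>  season  mean median  q2.5   q25   q75 q97.5 observed
#>       1 0.510  0.500 0.357 0.429 0.571 0.786    0.357
#>       2 0.363  0.357 0.286 0.286 0.429 0.571    0.286
#>       3 0.549  0.571 0.429 0.500 0.571 0.786    0.429
#>       4 0.812  0.786 0.643 0.714 0.857 1.000    0.643
```

The estimated proportion of occupied sites sits well above the observed
(naive) proportion in every season — that gap is the detectability
correction, and it is one-directional by construction (a detection forces
occupancy, an empty video only makes it less likely). The summary table is
shaped like a coefficient table with posterior inclusion probabilities; on
this fixture the bottom-type term dominates detection:

```r
summary(fit)[1:5, ]
#>    submodel    parameter    mean    sd    q2.5 q97.5 inclusion
#> 1 detection    intercept -0.6484 0.546 -1.7352 0.453        NA
#> 2 detection      current -0.3775 1.507 -3.1715 3.252     0.422
#> 3 detection         none  1.8272 0.814  0.3262 3.292     0.969
#> 4 detection current_none  0.4979 1.666 -3.1196 3.203     0.348
#> 5 detection       effort -0.0389 1.702 -3.4880 3.530     0.162

gelman_rubin(fit)$mpsrf                       # 1.004 (< 1.1: converged)
bayesian_p_value(fit, n_draws = 1000)         # ~0.48 (near 0.5: adequate fit)
```

Diagnostics follow the model's standard validation suite: Gelman–Rubin
(univariate and multivariate), a posterior-predictive Bayesian p-value from
Pearson residuals, prior–posterior overlap for identifiability (< 35%
identifiable), and a three-prior sensitivity refit (`prior_sensitivity()`).
Derived outputs include colonization/extinction/growth summaries
(`turnover_summaries()`), detection-probability surfaces along a tidal
cycle (`predict_detection_surface()`), and the current-dependent difference
in detectability between bottom types (`detection_difference()`).

A thin command-line wrapper covering `simulate`, `fit`, `diagnose`,
`predict` and `sensitivity` lives at `inst/cli/occutide.R`, driven by a
YAML run configuration (`run_config()`).

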