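---
title: "Dynamic occupancy modelling with tidally driven detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic occupancy modelling with tidally driven detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occutide)
```

## The model

Replicate camera surveys of a benthic fish never observe the true occupancy
state directly: a site can be occupied and still yield an empty video. The
multi-season (dynamic) occupancy model separates the two processes. The
latent state $z_{i,t} \in \{0,1\}$ says whether site $i$ is occupied in
season $t$ (a primary period within which the population is closed):

$$z_{i,1} \sim \mathrm{Bern}(\psi_i), \qquad
  z_{i,t+1} \sim \mathrm{Bern}\!\left(z_{i,t}\,\phi_t + (1-z_{i,t})\,\gamma_t\right),$$

with persistence $\phi_t$ and colonization $\gamma_t$ constant across sites
within each between-season interval (extinction is reported as $1-\phi_t$).
Replicate $j$ at an occupied site is a detection with probability $p_{itj}$:

$$y_{itj} \sim \mathrm{Bern}(z_{i,t}\, p_{itj}).$$

Both probabilities are linear on the logit scale. Detection responds to the
bottom-current speed at the moment of the observation, the bottom type
(`none` = no canopy-forming algae), their interaction, and optionally
sampling effort:

$$\mathrm{logit}(p) = \alpha_1 + \alpha_2\,\mathrm{Current} +
  \alpha_3\,\mathrm{none} + \alpha_4\,\mathrm{Current \times none}
  \;[+\; \alpha_e\,\mathrm{Effort}],$$

and initial occupancy in model B responds to site covariates (model A keeps
it constant):

$$\mathrm{logit}(\psi) = \beta_1 + \beta_2\,\mathrm{Depth} +
  \beta_3\,\mathrm{RDMV} + \beta_4\,\mathrm{CurMax} + \beta_5\,\mathrm{CurMax}^2.$$

All continuous covariates are standardized before analysis (sample SD,
$n-1$ denominator; replicate-level covariates over the observed replicate
records, site-level covariates over the sites). The quadratic term is the
square of the *standardized* maximum current, so it is centred; this is one
of the places where the original convention is not documented and the
package fixes a choice. The printed detection equation omits effort while
the fitted models include it, so the effort term is an optional fifth
coefficient, enabled by default and removable with `effort = FALSE`.

Model assumptions worth keeping in mind: closure within seasons, no spatial
autocorrelation between sites (the likelihood factorizes over sites), and at
least one site-season with more than one replicate (`fit_dom()` refuses
designs without repeat visits).

## Priors and variable selection

Logit-scale coefficients get weakly informative scaled-$t$ priors,
$t(\mu = 0, \sigma = 1.566, \nu = 7.763)$ by default; $\phi_t$ and
$\gamma_t$ get uniform priors on $[0,1]$; every non-intercept term carries a
binary inclusion indicator $w_k \sim \mathrm{Bern}(0.5)$. A coefficient with
$w_k = 0$ contributes nothing to its linear predictor, and the interaction's
effective indicator is the product $w_{int} w_{Current} w_{none}$, so the
interaction can only act when both main effects are in the model. Terms are
kept when the posterior mean of their (effective) indicator exceeds 0.5
strictly. `prior_presets()` carries the two alternative priors used for the
sensitivity analysis — $t(0, 2.5, 7)$ (the $t$ approximation to Jeffreys'
prior; no data-dependent Jeffreys prior is computed) and the Cauchy
$t(0, 2.5, 1)$.

## The sampler

`fit_dom()` is a bespoke Metropolis-within-Gibbs sampler with explicit
latent-state augmentation — the sampler itself is the point of the package,
not a wrapper around a generic engine. One iteration cycles:

1. **Latent states.** Each site's $z_{i,\cdot}$ is drawn exactly from its
   joint full conditional by forward filtering / backward sampling over the
   two-state season chain (compiled kernel). Cells with a detection are
   forced occupied through a $-\infty$ observation likelihood for $z = 0$.
2. **Turnover.** Given $z$, the uniform priors make $\phi_t$ and $\gamma_t$
   conjugate: $\mathrm{Beta}(1 + \text{successes}, 1 + \text{failures})$
   draws from the transition counts. No tuning, no approximation.
3. **Coefficients.** Random-walk Metropolis, one coefficient at a time,
   with the complete-data (given-$z$) likelihood. Coefficients whose
   effective indicator is 0 are refreshed from the prior — the Kuo–Mallick
   scheme with the prior as pseudo-prior, which keeps the indicator
   conditional exact without reversible jump.
4. **Indicators.** Exact Gibbs: prior odds one times the likelihood ratio
   with the term in versus out at the current coefficient value. When the
   interaction is structurally inactive (a main effect is out), its
   conditional is exactly 0.5.

Proposal scales adapt toward a 0.2–0.5 acceptance rate in 50-iteration
windows **during burn-in only** and are frozen afterwards, so the kernel
used for stored draws satisfies detailed balance. Chains start
over-dispersed: coefficients from twice the prior scale, indicators
Bernoulli(0.5), $z$ set to 1 wherever detected and Bernoulli(0.5) elsewhere.

Default chain settings match the full-scale analysis (5 chains × 50,000
draws, 10,000 burn-in, thinning 10). The package's own tests and the
acceptance script run scaled-down settings (typically 4 × 4,000 with 1,000
burn-in and thinning 3, giving 4,000 stored draws), which the convergence
diagnostics show are ample for these designs; recovery studies use 200
sites × 4 seasons × 3 replicates and 20 replicate fits.

## Likelihood machinery and numerical choices

Three likelihood paths coexist and check each other: the complete-data
likelihood (used inside the sampler), a per-site forward recursion that
marginalizes $z$ exactly, and a brute-force enumerator over all
$2^{S \times T}$ latent configurations (refused above 16 cells) that serves
as the independent oracle in tests. All accumulation is in log space with a
two-term log-sum-exp that is exact at $-\infty$; Bernoulli terms use a
stable softplus, so extreme logits saturate without overflow. Detections at
sites with $z=0$ yield exactly $-\infty$, masked (never-run) replicates are
skipped, and a missing covariate for an active term is an error rather than
an imputation.

Other fixed numerical conventions:

* **Current matching.** Observations are matched to the nearest step of the
  20-minute current series; exact ties go to the earlier step.
* **RDMV.** $(z_c - \bar z_W)/(\max_W - \min_W)$ in a 3×3 window, 0 where
  the window range is 0; edge cells use the truncated window rather than
  invented off-grid elevations.
* **Pearson residuals.** $r = (y - zp)/\sqrt{zp(1-zp) + 10^{-6}}$; the
  constant guards unoccupied cells where mean and variance both vanish.
* **Overlap.** Prior–posterior overlap integrates the pointwise minimum of
  the prior density and a Gaussian KDE (Silverman bandwidth) on a
  1,024-point trapezoid grid spanning both distributions out to the prior's
  $10^{-4}$ quantiles.
* **Growth rates.** $\lambda_t$ is the ratio of finite-sample occupied
  proportions in successive seasons computed *per draw* and then
  summarized; the ratio of posterior means is a different (wrong) quantity,
  and a regression test keeps the two distinct. Zero-denominator draws are
  dropped and counted.

## The synthetic-data generator

No field dataset ships with the package, so every downstream stage is
exercised against a generator that emulates the study design rather than
any particular realization of it:

* 14 sites in three depth strata (2 shallow < 20 m, 6 intermediate 20–40 m,
  6 deep > 40 m), four seasons, 1–3 replicates per site-season with mean 2.
* Bottom type from a single canopy extinction depth (40 m): canopy above,
  `none` below. The deep stratum is drawn below that limit, matching the
  absence of canopy in deep samples; the three-zone algal scheme collapses
  to the two bottom types the model uses.
* Bottom currents as a rectified single-constituent sinusoid per site —
  amplitude 0.15–0.30 m/s, floor 0.01 m/s (so speeds span 0.01–0.31 m/s),
  period 12.42 h (M2), 20-minute step, inter-site phase lags up to 1 h.
  This is an emulator of a hydrodynamic model's *output statistics* (range,
  period, lag), not of its physics: there is no wave forcing, no
  topographic steering, and no coupling between sites beyond the lag.
* Observation times uniform within abutting equal-length season windows
  (for empty videos this mirrors drawing a random time from the video);
  effort uniform on 30–90 minutes of bottom time (deployments up to 1.5 h).
  The real calendar (one summer, then spring/summer/autumn of the following
  year) is not temporally modelled.
* Default generating parameters are the study-scale values: detection
  coefficients $(-1.57, -1.26, 3.01, 1.77)$ with effort $-0.37$,
  $\psi_1$ intercept 0.9, $\phi = (0.44, 0.56, 0.85)$ and
  $\gamma = (0.52, 0.77, 0.55)$.

Because the generator is the model plus this tidal emulator, passing
recovery and calibration tests demonstrates internal correctness of the
likelihood and sampler — not that real reef data meet the closure,
independence, or current-emulation assumptions. Features of real data the
generator does not produce include spatially correlated occupancy,
current–topography interaction, observer-specific detection variation, and
non-Bernoulli replicate dependence within a deployment.

```{r fixture}
sim <- simulate_study(seed = 1)
sim$data
range(sim$covs$current, na.rm = TRUE)
```

## Goodness of fit, convergence, identifiability

The Bayesian p-value simulates, for each stored draw, a replicate dataset
under that draw's parameters *conditional on that draw's latent states*
(residuals are defined at the observation level; regenerating $z$ per draw
is the other defensible reading, and the conditional construction is the
package's choice), and compares summed squared Pearson residuals. Values
near 0.5 indicate adequate fit; the calibration tests require the p-value
to stay inside (0.25, 0.75) on self-generated data.

Convergence uses the classic potential scale reduction factor (values
below 1.1 conventionally converged) plus the Brooks–Gelman multivariate
version over the coefficient block. Identifiability uses prior–posterior
overlap with the conventional 35% threshold: parameters whose posterior
still looks like the prior are flagged rather than interpreted.

```{r diagnostics, eval = FALSE}
fit <- fit_dom(sim$data, sim$covs, model = "A",
               chains = chain_config(4, 4000, 1000, 3, seed = 11))
gelman_rubin(fit)$mpsrf
bayesian_p_value(fit, n_draws = 1000)
prior_posterior_overlap(fit$draws$alpha[, "current"], fit$prior)
```

## Outputs

`finite_sample_occupancy()` reports the proportion of the *sampled* sites
occupied per season, computed from the latent-state draws; because $z = 1$
is forced wherever a detection occurred, the estimate can never fall below
the observed proportion — the gap between the two is the detectability
correction, and it closes exactly when detection is perfect. Point
estimates are posterior medians with 50% and 95% credible intervals.
`predict_detection_surface()` propagates the full posterior (per-draw
coefficients and indicators) over a grid of cells and times along the tidal
cycle, with a `means_only` switch for plug-in prediction; effort is held at
its sample mean. `detection_difference()` traces
$p_{\mathrm{none}} - p_{\mathrm{canopy}}$ against current speed with a 95%
band — where the band includes zero the bottom types are not credibly
different, which under the study-scale truth happens only at the lowest
current speeds.

## Known limitations

* Persistence and colonization carry no covariates (as in the source
  design); seasonally varying drivers of turnover are absorbed, not
  explained.
* The sampler is serial; chains are independent and could be parallelized,
  but the package keeps a single-process implementation.
* The tidal emulator's single constituent cannot produce spring–neap
  modulation; tests that depend on the 0.01–0.31 m/s envelope would need
  re-examination with a multi-constituent emulator.
* With very sparse designs (a single season, or no repeat visits) the
  model is unidentified or refused outright.
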