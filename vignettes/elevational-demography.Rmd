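---
title: "Elevational demography from mark-recapture data: models and design choices"
author: "elevcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elevational demography from mark-recapture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`elevcmr` estimates how annual apparent survival, recapture probability
and breeding/natal dispersal of a valley-slope songbird population vary
along an elevational gradient, from long-term ring-recapture data
collected at a fixed set of breeding farms. This vignette documents the
models, the tunable parameters, the synthetic world used for
verification, and the design decisions taken where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

Two tables describe a study: farms (`farm_id`, planar `x`/`y` in
meters, `elevation` in m a.s.l., and a logical `edge` marking sites
near the study-area boundary) and captures (`individual_id`, `year`,
`farm_id`, `age_class` at capture — nestling or adult — and `sex`,
blank when unknown). Sex can be determined only on full-grown birds, so
it is known exactly for adults and for nestlings that were recaptured
later.

`build_histories()` turns captures into one detection history per
individual, conditioned on first capture. Conventions:

* **Carry-forward covariates.** Between detections an individual's
  site (hence elevation, edge status and farm index) is carried forward
  from its most recent detection — the standard convention for
  time-varying individual covariates in capture-mark-recapture data,
  since the true site of an undetected bird is unobservable.
* **Age classes.** For survival and recapture, `first_year` applies
  only to the occasion immediately after ringing as a nestling;
  everything else is `adult`. Adult-ringed birds are adult throughout.
* **Dispersal events** pair every two *consecutive detections* of an
  individual, regardless of the gap length in years; an event is a
  dispersal when origin and destination farms differ. An event is
  natal (juvenile) when it leaves the natal record of a nestling-ringed
  bird, breeding (adult) otherwise. With ~90 recaptured individuals
  yielding ~125 events, consecutive pairing over gaps is the only
  reading consistent with the published counts; a stricter
  one-year-gap-only definition can be imposed downstream by filtering
  `year_to - year_from == 1`.
* Sex conflicts across records of one individual are errors, never
  silent overwrites.
* All numeric predictors are centred and scaled to unit variance
  (`standardize()`); the fitted standardizer travels with the designs
  so prediction grids in meters are mapped consistently.

## The survival model

The core model is a Cormack–Jolly–Seber likelihood with a categorical
sex mixture. With $y_{it}$ the detection indicator and $z_{it}$ the
latent alive state ( $z_{it}=1$ at first capture),

$$y_{it} \sim \mathrm{Bern}(z_{it}\,p_{it}), \qquad
  z_{it} \sim \mathrm{Bern}(z_{i,t-1}\,\Phi_{it}),$$

$$\mathrm{logit}(\Phi_{it}) = \beta_0[\mathrm{class}_{it}]
   + \beta_1[\mathrm{class}_{it}]\,\mathrm{elev}_{i,t-1}
   + \beta_2\,\mathrm{edge}_{i,t-1}
   + \delta_{\mathrm{farm}_{i,t-1}} + \gamma_t,$$

$$\mathrm{logit}(p_{it}) = \alpha_0[\mathrm{age}_{it}]
   + \alpha_1[\mathrm{age}_{it}]\,\mathrm{elev}_{it} + \rho_t,$$

with survival classes adult male / adult female / juvenile (juveniles
share one intercept and slope across the sexes), recapture
parameterized as an adult intercept/slope plus first-year offsets, and
independent Normal random intercepts
$\delta \sim N(0,\sigma_\delta^2)$ (farm),
$\gamma \sim N(0,\sigma_\gamma^2)$ (year, survival),
$\rho \sim N(0,\sigma_\rho^2)$ (year, recapture). Survival over the
interval ending at $t$ uses the origin site's (carried-forward)
covariates and the interval-ending year deviate $\gamma_t$; apparent
survival confounds death with permanent emigration, which is why the
edge covariate (coded centre = 0, edge = 1) is included.

Sex enters as $\mathrm{sex}_i \sim \mathrm{Categorical}(f)$ for every
individual: sexed birds contribute $\log f$ or $\log(1-f)$, and the
likelihood of an unsexed bird is the $f$-weighted mixture of its male-
and female-conditional likelihoods (computed via log-sum-exp). Because
the categorical term applies to sexed birds too, $f$ is informed by the
observed sex ratio rather than prior-dominated.

The latent state is marginalized exactly with the standard
decomposition: survival and detection factors up to the last detection,
times the tail probability $\chi_t$ (never seen after $t$) from the
backward recursion $\chi_T = 1$,
$\chi_t = (1-\Phi_{t+1}) + \Phi_{t+1}(1-p_{t+1})\chi_{t+1}$. The
per-history R implementation is the reference; a compiled kernel
evaluates the whole-data likelihood (identical histories are collapsed
into weighted rows) and the two paths are asserted equal in the tests,
alongside a brute-force enumeration oracle over all latent alive paths
and both sexes.

### Priors, sampler, diagnostics

No standard priors or fitting engine exist for this model family, so
the package declares its own defaults (configurable in `cjs_priors()`):
Normal(0, 10²) on all fixed effects (log-odds scale), flat Beta(1, 1)
on $f$, half-Normal(0, 2.5) on the three SDs. Sampling is adaptive
random-walk Metropolis in five blocks (fixed effects, farm deviates,
year deviates ×2, log-SDs), with per-block proposal covariance learned
during burn-in and scale tuned to a 0.234 acceptance rate; adaptation
freezes at the end of burn-in. Random effects are sampled
*non-centered* (standardized deviates scaled by $\sigma$ inside the
likelihood): with only ~90 recaptured individuals the hierarchy is
weakly informed and a centered chain stalls in the
$\sigma \to 0$ funnel — non-centering removed that pathology in the
recovery experiments. Defaults are 3 chains × 6000 iterations (half
burn-in); `fit_cjs()` reports per-parameter effective sample sizes
(initial-positive-sequence estimator), warns below 100, and flags the
fit when split $\hat R > 1.1$. Posterior summaries are means with
2.5%/97.5% quantiles over pooled post-burn-in draws, in the row order
of the standard results table.

## The dispersal regressions

Three mixed models over derived events, fitted with `lme4` (the tool
the original analysis used), all with random intercepts for individual,
origin farm ("location") and year:

* **Probability** (all events, binomial logit, Laplace approximation):
  intercept, standardized origin elevation, age (adult), sex (female),
  edge, elevation×sex, elevation×age. Treatment coding, reference
  juvenile/male/centre.
* **Distance** (dispersed events, Gaussian, REML, response in km) and
  **corrected shift** (response in meters): same but edge is dropped
  and age×sex added. Distance is modelled in raw km (a log-transform
  flag was considered and rejected: the response scale of the published
  distance table is ambiguous, so package acceptance for these models
  is structural and recovery-based rather than coefficient-matching).

Uncertainty is quantified sim-style: 2000 draws (default) of the fixed
effects from the multivariate normal centred at the estimates with the
fitted coefficient covariance — the posterior under flat priors — and
95% credible intervals as the 2.5%/97.5% empirical quantiles.
Random-effect uncertainty is deliberately not simulated, mirroring the
cited procedure; consequently the report tables give point estimates
but no intervals for the SD rows, and SDs below 0.01 are printed
`<0.01` as in the published tables.

Two numerical guards reflect genuinely reachable states of these data
sizes: (i) with mostly single observations per individual, the
Bernoulli-scale ML of a random-intercept variance can diverge;
`fit_glmm_binomial()` drops any intercept whose SD exceeds 10 logits,
reports it on the zero boundary, and warns. (ii) Under apparent
complete separation the coefficients come from a documented fallback, a
ridge-penalized logistic fit (Normal(0, 2.5²) penalty), flagged in the
result. Gaussian singular fits are returned with the boundary SD and a
warning, not an error.

## The corrected elevational shift

A bird dispersing from a high farm has mostly downhill options, so raw
elevation differences are biased. For each dispersal event the package
takes the disc around the *origin* farm whose radius is the realized
dispersal distance, averages the elevation of all farms inside it, and
reports `corrected_shift` = destination elevation − that mean.
Choices, each taken once:

* The origin farm itself counts as available (it lies in any disc); a
  flag flips this since the verbal definition is ambiguous.
* Farms exactly on the boundary are included, with a fixed 10⁻⁹ km
  tolerance, so the destination always qualifies.
* "Available farms" are the contents of the farm table: if mapped but
  unoccupied high stables should count, they belong in the table.
* The statistic is translation-invariant and unaffected by farms
  outside every radius; both are asserted, and the whole operation is
  checked exactly against a brute-force filter-and-average oracle.

## The synthetic world

The generator's defaults *are* the study design: 63 farms uniform over
a 10 × 3.5 km extent; elevations truncated-exponential on
[700, 1430] m with the rate calibrated (by root-finding on the
truncated mean) so the expected elevation is 1042 m, matching the
reported mean and the statement that farm abundance declines with
elevation; edge = outer 15% band of either axis; 15 annual occasions;
89 nestlings and 13 adults newly ringed per year (~1337/~194 total);
true parameters = the published point estimates (survival, recapture,
SDs, dispersal coefficients, male proportion 0.45). Destination choice
uses an exponential distance-decay kernel (scales 4 km natal, 1.25 km
breeding, the reported mean distances); no settlement kernel is
published, so only those means constrain it — in the bounded landscape
the realized mean natal distance comes out somewhat below 4 km.

One convention matters for what a green test establishes.
**Site changes are realized at capture.** Each year an alive bird's
detection is decided at its last *known* site; on capture, a move is
drawn from the dispersal-probability model (natal kernel if the bird
still sits on its natal record) and recorded. Undetected birds keep
their last known site. This makes the generative process agree exactly
with the information set of the fitted model — carry-forward
covariates are correct by construction, and the dispersal indicator of
a derived event follows the dispersal model with origin covariates
regardless of gap length. The alternative (latent moves every year)
was implemented first and rejected: it injects covariate measurement
error the CJS model cannot see, and large-sample ML showed biases up
to ~0.7 log-odds in recapture-elevation terms, i.e. the recovery suite
would have been testing a misspecified model rather than the
estimator. The cost is realism: in the real population birds also move
in years nobody catches them, and that unobservable movement is
precisely what "apparent" survival absorbs. Green recovery tests
therefore establish that the estimation machinery is correct, not that
carry-forward covariates are harmless in nature.

Determinism: a single integer seed fixes every stage; the farm stage
and the history stage draw from seeded streams in fixed order, and all
fits accept explicit seeds.

## Limitations

* Elevation is a covariate, not a state: no multi-state CMR model, no
  spatially explicit destination choice in inference (the kernel lives
  only in the generator).
* The sampler is random-walk Metropolis; it is adequate for this
  posterior (checked by recovery and $\hat R$/ESS diagnostics) but
  slower-mixing on the farm-SD than a gradient-based sampler would be.
* Credible intervals for random-effect SDs of the dispersal models are
  not reported (fixed-effect simulation only, by design).
* The corrected shift treats the farm table as the complete set of
  available sites and uses planar Euclidean distances; both are
  appropriate at a ~10 km valley scale and wrong for geographic
  coordinates.
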