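---
title: "Model-based geostatistical mapping of child underweight prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistical mapping of child underweight prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoprev)
```

## The problem

Household surveys such as the DHS measure child anthropometry at a few
hundred georeferenced cluster locations per survey wave. Policy questions,
however, are about *places*, not clusters: where is underweight prevalence
(weight-for-age below −2 SD of the reference median) highest, how has it
moved over two decades, and which environmental and accessibility
covariates drive it? Model-based geostatistics answers this by treating the
cluster data as a noisy sample of a smooth latent prevalence surface and
interpolating that surface with quantified uncertainty.

`geoprev` implements the full chain: a synthetic multi-wave DHS-like data
generator with known ground truth, descriptive prevalence tables and trend
statistics, covariate preparation, a Bayesian binomial spatial regression,
kriging-style prediction surfaces, and WAIC model comparison, orchestrated
by a reproducible CLI pipeline.

## The model

At cluster $j$, with $n_j$ children measured and $Y_j$ underweight,

$$Y_j \sim \mathrm{Binomial}(n_j, p_j), \qquad
\mathrm{logit}(p_j) = \alpha + \sum_z \beta_z X_{z,j} + \zeta_j ,$$

where $X$ is a design matrix of spatially referenced covariates and
$\zeta$ is a zero-mean Gaussian random field with Matérn covariance

$$\mathrm{Cov}(\zeta_i, \zeta_j) = \sigma^2 \,
\frac{2^{1-\nu}}{\Gamma(\nu)} (\kappa d_{ij})^\nu K_\nu(\kappa d_{ij}),
\qquad \kappa = \sqrt{8\nu}/\rho .$$

$\rho$ (km) is the *range*: the distance at which correlation falls to
roughly 0.1 (0.14 at $\nu = 1$), and $\sigma$ is the marginal standard
deviation of the field. $\nu$ is fixed at 1 by default — the convention
under which the range definition above holds — and is configurable.

Priors: improper flat on $\alpha$; independent $\mathrm{N}(0,
\text{precision } 10^{-4})$ on each $\beta_z$ (SD 100 — weakly informative
*only* if covariates are standardized, which is why `standardize()` is not
optional in the pipeline); and a penalized-complexity prior on
$(\rho, \sigma)$ with $P(\rho < \rho_0) = 0.05$, $\rho_0$ defaulting to 10%
of the projected domain diameter, and $P(\sigma > 1) = 0.05$.

Distances are computed after an equirectangular projection centred on the
mean data latitude ($x = R\,\Delta\mathrm{lon}\cos\bar\varphi$,
$y = R\,\Delta\mathrm{lat}$, $R = 6371$ km). At country scale the
distortion is well below the uncertainty in $\rho$.

## Inference

The reference analysis this package emulates used INLA; re-implementing a
Laplace-approximation engine is out of scope, so `fit_mcmc()` targets the
identical posterior with an asymptotically exact MCMC scheme:

* **latent field** $\zeta \mid \text{rest}$: elliptical slice sampling,
  which uses the Gaussian prior exactly and needs no step-size tuning;
* **$(\alpha, \beta)$**: joint random-walk Metropolis with Robbins–Monro
  adaptation of the log step size toward 0.234 acceptance;
* **$(\log\rho, \log\sigma)$**: joint adaptive random-walk Metropolis; the
  acceptance ratio needs only the MVN prior of $\zeta$ (plus the PC prior
  and log-transform Jacobians), since the likelihood does not involve the
  hyperparameters given $\zeta$.

Adaptation is frozen at the end of burn-in, so the retained chain is a
valid Markov chain with the posterior invariant. Every stochastic
component derives its stream from `sub_seed(seed, component)`, a stable
31-bit hash, making whole runs bit-reproducible.

The covariance is dense ($n \le$ a few thousand clusters), factorized by
Cholesky with a jitter of $10^{-8}\sigma^2 + 10^{-12}$ escalated ×10 up to
three times on failure. The dominant per-iteration cost is the Cholesky
refresh in the hyperparameter update; `hyper_every = 2` halves it by
updating $(\log\rho, \log\sigma)$ in a systematic scan every second
iteration, which leaves the target invariant.

Default chain settings (2 chains × 20 000 kept iterations after 5 000
burn-in) are sized so the stored draws stay within a budget of 150 000
values across all parameters via automatic thinning. Test and acceptance
runs use far shorter chains (documented per test); the coverage study in
the acceptance suite uses 1 800 kept iterations per fit, a length chosen
from a convergence diagnosis on a single replicate — materially shorter
chains produced overconfident intervals.

## Prediction

For each retained draw $s$, the field at prediction cells is the exact
Gaussian conditional (kriging) given $\zeta^{(s)}$ at the data locations
under $(\rho^{(s)}, \sigma^{(s)})$, with one conditional draw per state;
$\eta^{(s)}_g = \alpha^{(s)} + X_g\beta^{(s)} + \zeta^{(s)}_g$ is
back-transformed, and the surface reports the per-cell mean and equal-tailed
95% interval over draws. Two exactness properties are tested: a cell
coincident with a cluster reproduces that cluster's $\zeta$ with vanishing
variance, and a cell far beyond the range reverts to the prior
$(0, \sigma^2)$. Prediction-grid covariates are standardized with the
*training* constants; cells with nodata covariates stay nodata.

## The synthetic world

The generator emulates the five-wave design the package is tested against:
cluster counts 535, 517, 571, 619, 305 per wave (2 547 pooled), cluster
locations uniform over the grid bounding box, and 5–25 children per cluster
(DHS-like; the reference data report only pooled child totals, so the
per-cluster size is a design choice made once). Covariate layers are
standardized Gaussian random fields produced by separable Gaussian-kernel
smoothing of white noise — smooth like temperature or travel-time surfaces,
but with none of the real layers' sharp topographic structure. The latent
field is an exact MVN draw from the same Matérn covariance the model
assumes, with default range 25% of the projected domain diameter and
$\sigma = 0.5$; the default fixed effects ($\alpha = -0.55$; $\beta$ of
−0.39 on a temperature-like layer and +0.09 on a travel-time-like layer)
echo realistic effect sizes for this application.

A green recovery test therefore establishes that the *inference machinery*
is correct and calibrated under the model's own assumptions. It does not
establish robustness to what real data add: GPS jitter, urban/rural design
effects, survey weights, non-Matérn residual structure, or covariate
measurement error. Two honest caveats surface even inside the synthetic
world: the intercept is partially confounded with the field's domain-wide
average (a known feature of spatial intercepts, which is why recovery
criteria target $\beta$), and in occasional replicates the realized field
correlates with a covariate by chance, inflating that replicate's
posterior spread — the coverage criterion (≥16/20) absorbs this.

## Numerical and design choices

* Population (divide-by-$n$) SD in z-scoring; declared so tests can be
  exact. Standardization is idempotent; constant columns are zeroed and
  flagged rather than dropped silently.
* Collinearity screen: greedy pairwise |r| ≥ 0.8 walk in a configurable
  priority order (list temperature before altitude to reproduce the
  altitude-removal decision of the reference analysis). No VIF machinery.
* Prevalence tables are child-count-weighted (never means of cluster
  proportions), unweighted by survey design — a documented limitation, as
  the reference tables describe no weighting.
* Presentation rounding is half-away-from-zero to one decimal, applied only
  at print time; stored values are exact.
* Nearest-cell covariate extraction with ties to the smaller (row, col)
  index; out-of-bounds points and nodata hits are errors, never silent
  imputation.
* WAIC uses log-sum-exp for the lppd and the $n-1$ sample variance for
  $p_\mathrm{WAIC}$; the zero-variance-draws closed form is tested exactly.
* The pipeline manifest omits wall-clock timings (kept in `run.log`) so
  identical config + seed reproduce `manifest.json` byte for byte.
* Configuration files are JSON (not YAML) because the deployment
  environment guarantees a JSON parser only.

## Known limitations

Dense-covariance MCMC scales as $O(n^3)$ per hyperparameter refresh —
appropriate to a few thousand clusters, not to SPDE-mesh scale. Each survey
wave is fitted separately (plus pooled); there is no spatio-temporal
covariance. Hot-spot/cold-spot cluster detection and cartographic styling
are out of scope. The range parameter is weakly identified at these sample
sizes; its posterior is reported but should be read with that in mind.
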