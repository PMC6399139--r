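---
title: "Dasymetric refinement and count models of canine cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dasymetric refinement and count models of canine cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasycan)
```

## The scientific problem

Canine cancer registries promise a sentinel view of environmental cancer
risk — dogs share their owners' households and develop cancers on a
compressed timescale — but they suffer severe *underascertainment*: many
cancers are never diagnosed because the owner never seeks veterinary care.
When registry cases are enumerated within administrative units
(municipalities), any regression of incidence on explanatory variables is
additionally exposed to the modifiable areal unit problem (MAUP): summary
statistics depend on the arbitrary shape and extent of the enumeration
units.

`dasycan` implements a geographic correlation analysis designed around
both issues. Incidence counts per unit are modelled with count regressions
whose offset is the at-risk dog population, with covariates capturing
demographic risk (dog average age, female and mixed-breed ratios) and
proxies for access to veterinary care (income tax as a socioeconomic
surrogate, human population density as urbanicity, road-network distance
to the nearest veterinary practice). The whole analysis is then repeated
on *binary dasymetrically refined* units — each municipality reduced to
its residential-land cells on an hectometric (100 m) grid — and the two
spatial supports are compared head to head.

Because the underlying Swiss registry microdata and GIS layers are not
public, the package ships a synthetic-region generator that emulates the
documented statistical structure of that setting, so every stage of the
pipeline is testable offline with known ground truth.

## The count models

For unit $i$ with case count $y_i$ and $e_i$ dogs at risk, the baseline
Poisson model is

$$y_i \sim \mathrm{Poisson}(\mu_i), \qquad
\log \mu_i = \alpha + \sum_k \beta_k x_{ik} + \log e_i .$$

Three extensions relax its assumptions:

* **Negative binomial (NB2)** — variance $\mu + \mu^2/\theta$, for
  overdispersion ($\theta > 0$; $\theta \to \infty$ recovers Poisson).
* **Zero inflation (ZIP / ZINB)** — a separate logistic component
  generates *structural* zeros with probability
  $\pi_i = \mathrm{logit}^{-1}(\gamma^\top z_i)$, so
  $P(y_i = 0) = \pi_i + (1-\pi_i) f(0;\mu_i)$ and
  $P(y_i = k) = (1-\pi_i) f(k;\mu_i)$ for $k > 0$. Structural zeros are
  the model's handle on wholesale non-ascertainment within a unit.

The ZIP and ZINB likelihoods are the standard mixture forms with NB2
dispersion. Covariates are deliberately *not* centred, so each
$100(e^{\beta_k}-1)$ is the percentage change in the incidence rate per
one original unit of $x_k$ (`multiplicative_effect()`); the same
transform applied to $\gamma$ gives the percentage change in the odds of
a structural zero.

### Fitting

`fit_count_model()` maximises the likelihood with a fixed, reproducible
strategy: intercept initialised at the closed form
$\log(\sum y / \sum e)$ with zero slopes; NB families start from the
Poisson solution with a method-of-moments $\theta$; zero-inflated
families start from the corresponding non-inflated solution with
$\gamma = 0$. BFGS with analytic gradients is followed by Newton polishing
to a gradient-norm tolerance of $10^{-8}$ (the failure threshold scales
with the magnitude of the log-likelihood). Standard errors come from the
inverse observed information; $\theta$ is estimated on the log scale and
reported with a delta-method SE.

Two boundary situations get explicit treatment rather than being left to
the optimizer:

* **Equidispersed data.** The NB dispersion runs to $+\infty$; beyond
  $\theta = 10^7$ the likelihood is numerically Poisson, so $\theta$ is
  capped there, the surface is exactly flat in $\log\theta$ beyond the
  cap, and such fits count as boundary-converged. The linear predictor is
  likewise clamped at 500 so that no optimizer step can overflow `exp()`.
* **No structural zeros.** The zero-inflation component drifts to
  $\pi = 0$ and the observed information is singular; the unidentified
  parameters are reported with infinite SEs (never pseudo-inverse zeros),
  which makes backward selection drop them, as it should.
* **Quasi-separation.** With many zero-inflation covariates on few units
  the logistic component's MLE can lie at infinity; the optimizer then
  stalls on a flat ridge whose gradient restarts cannot improve although
  the likelihood is at its numerical maximum. Such fits are accepted with
  a warning (SEs along the ridge are unreliable, which again makes
  backward elimination drop the offending covariates); only genuine
  non-convergence raises an error.

### Diagnostics and model comparison

* `sqvif()` screens multicollinearity with the square root of the
  variance inflation factor against the critical value 2.0.
* `deviance_reduction()` quantifies per-covariate effect sizes as
  $100\,(\mathrm{dev}_{-k} - \mathrm{dev}_{\mathrm{full}}) /
  \mathrm{dev}_{\mathrm{null}}$, with drop-one refits against the
  offset-only null. Residual deviance is $2(\ell_{\mathrm{sat}} - \ell)$;
  within one computation all refits share the full model's
  $\hat\theta$ in the saturated reference so the comparison is internally
  consistent. Drop-one against the offset-only null is one of several
  defensible definitions of "percentage of deviance reduction"; it was
  chosen because it is symmetric in the covariates (no ordering
  dependence) and reduces to $100(\mathrm{dev}_0-\mathrm{dev}_1)/
  \mathrm{dev}_0$ in the single-covariate case.
* `select_zi_covariates()` applies the published model-building rule for
  the logistic component: start from all candidates, repeatedly drop the
  least significant (Wald $p \ge 0.05$) and refit, until all retained are
  significant.
* `aic()`, `relative_likelihood()` (`exp((AIC_{\min}-AIC_i)/2)`, reported
  raw and at two decimals) and `likelihood_ratio_test()` implement the
  comparison framework. The LRT is also computed for non-nested pairs
  (e.g. NB vs ZIP, or the same family across spatial supports) because
  the comparison framework calls for it, but such results are labelled
  "quasi-LRT, non-nested"; for the cross-support pair the parameter
  counts are identical, so `compare_supports()` reports the statistic
  with df = 0 and no p-value rather than inventing degrees of freedom.
  Boundary pairs (Poisson vs NB; non-inflated vs inflated) carry a note
  that the $\chi^2$ tail is conservative.

## The synthetic region

`generate_region()` builds a raster-lattice world — units are contiguous
cell sets, so all geometry (areas, centroids, zonal means) is exact and
every operation of the real analysis is exercised without polygon
topology:

* Unit centres are sampled on the lattice and cells join their nearest
  centre (ties to the lowest unit id, the same documented tie-break used
  by `allocate_cells()` for cell-centroid allocation).
* A configurable fraction of units (default one half) is labelled
  *mountain* and drawn from an enlarged southern band so mountain units
  are about twice the area of *plateau* units. Mountain units draw their
  residential-land fraction from 1–10%, plateau units from 10–60%,
  mirroring the documented contrast between alpine municipalities
  (mostly below 10% residential land) and the densely settled plateau.
* Residential land grows as a random 4-connected patch from a seed cell,
  giving one clustered (possibly ragged) residential core per unit.
* The road network is the Euclidean minimum spanning tree over unit
  centres, rasterised as L-shaped paths, plus a spur from each centre
  into the unit's residential patch — connectivity is guaranteed by
  construction, so road distances are finite.
* Veterinary practices are placed on residential road cells with
  probability proportional to unit population (care concentrates where
  people are), with an explicit error if the configuration asks for more
  practices than eligible cells exist.
* Human populations are lognormal by terrain (means 600 / 3,000; the
  national mean municipality is ~3,200 residents), allocated to
  residential cells by a Dirichlet-weighted multinomial, and truncated to
  400 residents per hectometric cell — the order of the densest Swiss
  residential hectares — so refined densities stay physically plausible.
* Dogs are generated at 6.54 per 100 inhabitants (the national ratio),
  with Gamma ages (mean 5 y), balanced sex, and a Beta-distributed
  per-unit mixed-breed probability centred on 0.3. No distributional
  detail for dog demographics beyond the national totals is documented,
  so these are stated defaults, not inferred ones.
* Cancer counts follow the generative mirror of the fitted ZINB model
  (`truth_params()`): the default truth uses the published
  municipal-support coefficients, $\theta = 1$, zero inflation driven by
  dog age, and an intercept calibrated once so the count component's mean
  incidence rate matches the national 7.3 cases per 1,000 dogs (observed
  rates are lower by the structural-zero fraction).

Every generator is a pure function of `(config, seed)` and restores the
global RNG state.

### What the generator does not emulate

Real topography and road curvature, commuting-time (rather than
distance) access, building-register semantics, spatial autocorrelation in
incidence beyond what the covariates induce, and registry idiosyncrasies
(postcode misassignment, multi-year pooling). Passing tests therefore
demonstrate that the *procedures* are correct and that the MAUP/support
effects they are designed to detect are detectable — not that the Swiss
effect sizes themselves are recovered, which would require the
non-public registry data.

## Covariates and the change of support

The distance grid is the multi-source shortest path along the road-cell
graph (8-connected, centre-to-centre costs: 0.1 km orthogonal,
$0.1\sqrt2$ km diagonal) from all veterinary practices at once, computed
with Dijkstra's algorithm. Off-road cells snap to their straight-line
nearest road cell (ties to the smallest cell index) and add the snap
length; road cells disconnected from every practice get the same
fallback with a warning. The off-road cost model of the original
cost-surface computation is not documented, so this explicit, testable
rule is adopted; an exhaustive brute-force oracle suite pins it down
exactly.

Only two covariates change under refinement, and that is the entire
point of the design: `HumanPopulationDensity` uses the residential area
instead of the full unit area, and `DistanceToVetCare` averages the grid
over residential cells only (the municipal support averages all cells —
whether the original analysis averaged all or only populated cells is
not documented, and the contrast between the two conventions is exactly
the studied change-of-support effect). Everything else — outcome, offset,
demographic ratios, the income surrogate (a unit-level attribute, neither
a density nor a distance) — is carried over bitwise, which
`run_pipeline()` asserts on every run together with the pycnophylactic
check. Units with no residential land are excluded from refined-support
analyses with a warning and kept in municipal-support tables; how the
original analysis handled such municipalities (if any arose) is not
documented.

## Study conditions used by the verification suite

The test suite re-derives every published derived quantity that is
computable from printed inputs (effect-size conversions, relative
likelihoods from the AIC table) and verifies the procedures by
simulation at these fixed sizes, chosen once as the package's study
conditions:

* pycnophylactic property: 100 seeded regions of 12 units on a 26×26
  lattice;
* distance oracle: 48 randomized grids up to 15×15, including
  deliberately disconnected road components;
* ZINB parameter recovery: 2,000 units × 200 replicates at truth
  $\alpha=-4$, $\beta=(0.3,-0.2)$, $\theta=1$, $\gamma=(-4,0.7)$ —
  checking mean bias against Monte-Carlo error and 95% Wald coverage
  (the $\theta$ interval is formed on the log scale);
* model-selection consistency: 100 replicates of the same design, ZINB
  expected to attain the lowest AIC in at least 90%;
* MAUP direction: 100 seeded desk-scale regions (200 units, 120×120)
  with truth defined on the refined support and a density coefficient of
  0.10 per 1,000 people/km² — chosen a priori so the support contrast
  carries signal at desk scale — with the refined-support ZINB expected
  to win the AIC comparison in at least 80%.

## Known limitations

* The lattice world has no genuine polygon boundaries, so the
  cell-centroid allocation rule is exercised through its tie-break
  convention rather than through point-in-polygon arithmetic.
* Wald inference near boundaries ($\theta \to \infty$, $\pi \to 0$) is
  reported but is inherently fragile; the LRT between boundary pairs is
  conservative.
* Like every ML estimator of the NB dispersion, $\hat\theta$ carries a
  small upward finite-sample bias of order $1/n$; at the recovery study's
  size this bias sits at the resolution of 200 Monte-Carlo replicates, so
  the bias check for $\log\theta$ is the one recovery assertion expected
  to sit on its bound (slope, intercept and zero-inflation parameters
  pass it comfortably, and interval coverage is nominal for all).
* The cross-support model comparison is not a valid hypothesis test (the
  models are not nested and have equal dimension); it is reported as
  descriptive evidence, as flagged in the output.
* Deviance reductions depend on the adopted drop-one definition; other
  partitions (sequential, pseudo-R²) would give different percentages.
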