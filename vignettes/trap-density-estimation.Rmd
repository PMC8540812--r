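---
title: "Estimating absolute insect population density from single trap catches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating absolute insect population density from single trap catches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapdensity)
```

## The problem

Absolute insect population density cannot be measured directly in the
field. What can be measured is the number `M` of insects caught in a trap,
and — through release–recapture experiments — the probability that an
insect at a known distance from the trap is eventually caught. This
package connects the two: it models the catch probability as a function of
distance, fits that model to release–recapture data, and inverts the
relationship to turn a single trap count into the most probable average
density over the trap's collection area, with exact confidence bounds.

## The catch-probability model

The model asserts one universal functional form for all trap–insect
systems:

$$ spTfer(r) = \frac{spTfer(0)}{1 + (r/D_{50})^2}, \quad r \le R_{max};
   \qquad spTfer(r) = 0, \quad r > R_{max}. $$

Its three parameters are measurable quantities:

* `sptfer0` — the probability of catching an insect released in the
  immediate proximity of the trap, in (0, 1]. It anchors the curve; it is
  best measured empirically, because estimating it by fitting an
  incomplete distance ladder can mis-scale everything downstream.
* `d50` — the distance (m) at which the catch probability falls to half of
  `sptfer0`; the effective attractive distance of the trap system. Across
  the bundled presets it spans 6.5 m (codling moth) to 250 m (European
  pine sawfly).
* `rmax` — the radius (m) of the collection area. The boundary uses the
  non-zero branch (closed interval). `rmax < d50` is mathematically
  admissible but suspicious, so the constructor warns rather than errors.

The form encodes three assumptions: insects move in an effectively
two-dimensional space, have a finite active life span, and the trapping
interval is long enough for the catch to converge (the count stops growing
with additional time). Because the model operates on converged catches,
time does not appear explicitly; the trapping interval is carried only as
metadata.

## From catch to density

For a spatially uniform density $\bar\rho$ (insects/m²), integrating the
curve over the collection disk gives the expected catch
$\bar M = \bar\rho\,/\,\mu$ with

$$ \mu = \frac{1}{spTfer(0)\,\pi D_{50}^2 \ln\!\big(1 + (R_{max}/D_{50})^2\big)}. $$

The placement of the logarithm inside the denominator is not a guess: the
integral $2\pi \int_0^{R_{max}} spTfer(r)\, r\, dr$ has the closed form
$spTfer(0)\,\pi D_{50}^2 \ln(1 + (R_{max}/D_{50})^2)$, and the package
verifies `1/compute_mu()` against adaptive quadrature of `expected_catch()`
(tolerances `1e-9` absolute and relative; the integrand is smooth) to a
relative error below `1e-6` for randomized parameter sets. Note the
dependence on `rmax` is only logarithmic, so a rough estimate of the
collection radius suffices, whereas errors in `d50` propagate
quadratically.

Given an observed count `M` (a Poisson variable under the uniform-density
model), the most probable density is $\mu M$ and the exact Garwood-type
bounds at confidence `p` are

$$ \tfrac{\mu}{2}\,\chi^2\!\big(\tfrac{1-p}{2};\,2M\big) \;\le\; \bar\rho
   \;\le\; \tfrac{\mu}{2}\,\chi^2\!\big(1-\tfrac{1-p}{2};\,2M+2\big), $$

with the chi-square quantile at zero degrees of freedom defined as 0 so
that the `M = 0` lower bound vanishes. The interval is exact and
conservative: its coverage is at least `p` for every true density. `M`
must be an integer count — fractional "average catches" are rejected,
because the degrees of freedom are `2M` and `2M + 2`. The default
confidence is `p = 0.95`. Internally all densities are per m²; the
per-hectare values (× 10,000) are carried alongside in every
`density_estimate`, and the CLI reports per-hectare by default for a
management audience.

```{r}
estimate_density(3, trap_preset("codling_moth"))
```

## Fitting the curve: the two-step protocol

Field designs are usually unbalanced: a handful of distances, mostly short
or mostly long. A plain least-squares fit of the untransformed proportions
is dominated by the large proportions near the trap and can leave `d50`
essentially unconstrained by the far data. The two-step protocol
(`fit_two_step()`) addresses this:

1. **Step 1** fits the untransformed proportions with both parameters free
   (bounded Levenberg–Marquardt, `sptfer0` in (0, 1], `d50 > 0`) and keeps
   only `sptfer0`.
2. **Step 2** fixes `sptfer0` and refits `d50` alone on the
   log-transformed proportions, so catches at large distances carry the
   same weight as catches near the trap.

When `spTfer(0)` was measured empirically, `fit_fixed_sptfer0()` runs only
step 2. Both steps use unweighted ordinary least squares by default —
published datasets do not consistently report SEMs — with `weighted = TRUE`
as an opt-in (inverse-variance weights; on the log scale the SEM is
transferred by the delta method).

Zero-catch records are excluded from step 2 (their log is undefined) and
listed with reasons in the result; a pseudo-count alternative is
deliberately not offered, since it would silently change the estimator.
Records at duplicate distances are pooled (counts summed) with a warning.
Starting values are deterministic and scale-aware: `sptfer0` starts at the
largest observed proportion and `d50` at the median distance whose
proportion still exceeds half that maximum. `rmax` is not identifiable
from recapture proportions (the data end where catches end), so fits take
it as an argument, defaulting to the largest release distance.

The goodness-of-fit `r_correlation` is the Pearson correlation between
observed and model-predicted proportions on the untransformed scale over
the non-excluded records. A correlation on the log scale would be an
equally defensible convention; the choice is recorded in the `trap_fit`
object so it is auditable.

### The standard error of D50

The conventional nonlinear-least-squares standard error (residual variance
× inverse curvature) is badly miscalibrated here: under binomial recapture
noise the log-scale errors are strongly heteroscedastic, and the noisiest
records — few recaptures, far from the trap — are precisely the ones that
carry the `d50` information. In simulation the homoscedastic SEM
understates the replicate-to-replicate spread of `d50` by roughly a factor
of two.

The package therefore reports a model-based SEM. Writing $J_i$ for the
gradient of the log-model in `d50`, the sampling variance of the
unweighted step-2 estimator is
$\sum_i J_i^2 s_i^2 / (\sum_i J_i^2)^2$, where $s_i^2$ is the mean squared
error of the log recapture proportion under binomial sampling at the
fitted proportion, computed from the zero-truncated binomial distribution.
Using the MSE rather than the first-order variance matters twice over: at
expected counts below ~15 the truncated variance exceeds the `1/(np)`
approximation by up to ~30%, and for sparse records (expected catch well
below one insect, e.g. a single recapture out of 100 at a far distance)
the log proportion is dominated by truncation *bias* rather than variance.
When `sptfer0` comes from step 1, its estimation variance (a sandwich
covariance from the step-1 fit with binomial variances) shifts the log
curve bodily and is propagated into the `d50` SEM through the factor
$\sum_i J_i / \sum_i J_i^2$. In seeded simulations this SEM tracks the
empirical SD of `d50` to within a few percent across the full published
parameter range, on both dense (10⁴ released per distance) and sparse
(10² per distance) designs. The homoscedastic covariance remains only as
a fallback for degenerate inputs.

## Dataset screening

`validate_recapture()` checks a dataset against three design criteria
before fitting: (1) converged catch reported for at least 4 distances,
(2) releases at far distances at least as large as at short distances,
(3) no zero-catch records between non-zero ones. Violations are warnings,
never errors — literature data are imperfect and a fit may still be
informative — and the CLI logs them with the criterion number for
traceability.

## The simulator

`simulate_recapture()` draws, for each release distance, a recapture count
`Binomial(n_released, sp_t_fer(distance))`, independent across distances;
`simulate_trap_catch()` draws wild-population counts
`Poisson(rho / mu)`. The split is deliberate: release cohorts are finite
with proportions bounded by 1 (binomial), while the wild population is
unbounded (Poisson — the sampling model under which the chi-square
interval is exact). Identical seeds reproduce datasets exactly.

The simulator emulates the sampling noise of a well-run release–recapture
experiment, and nothing else. It does not model insect movement or
diffusion, wind and plume structure, trap competition or interference,
temporal variation in activity, losses of marked insects before they can
respond, or digitization error in literature data. Passing recovery and
coverage tests therefore demonstrates that the estimators are correct
under the model's own sampling assumptions — not that any particular field
dataset satisfies those assumptions.

## Verification problem sizes

The test suite verifies, among other properties: the μ/quadrature identity
for the ten bundled presets plus 20 randomized parameter sets (relative
error < 10⁻⁶); exact recovery of both parameters from noiseless curves
(relative error < 10⁻⁴); recovery of `d50` over 50 seeded binomial
simulations with truths cycling across the published parameter range
(10⁴ released per distance; pooled relative bias under 5%, every replicate
within 3 reported SEM); and empirical coverage of the density interval of
at least 0.95 over a grid of true densities with 10⁴ Poisson draws each.
These sizes were chosen to make Monte-Carlo error small relative to the
assertions while keeping the default test run fast.

## Limitations

* Single trap, uniform density: no multi-trap fusion, no spatially varying
  density inference, no trap-interference modelling.
* `rmax` is taken as given; the package does not estimate it.
* The density estimate is an average over the converged-catch interval;
  the package treats that interval as opaque metadata and does not convert
  between trapping durations.
* No bootstrap or profile-likelihood intervals for `d50`; the reported
  uncertainty is the model-based SEM described above.
* The model is phenomenological by design — it does not mechanistically
  model plume dispersion or anemotaxis, which is exactly what lets one
  equation serve chemical and light traps alike.
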