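---
title: "Methods: modelling a century of smoking prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling a century of smoking prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smokedyn)
```

## The model

`smokedyn` treats smoking as a binary social choice. The smoker fraction
x(t) obeys

$$\frac{dx}{dt} = b\left[(1-x)\,x^{a}\,u_x - x\,(1-x)^{a}\,(1-u_x)\right],$$

where the adoption term is the non-smoker fraction times the total utility
of smoking — social utility (the prevalence x) weighted by the conformity
exponent $a$, times individual utility $u_x$ — and the cessation term is
its mirror image under $x \mapsto 1-x$, $u_x \mapsto 1-u_x$. That exchange
symmetry is exact and is enforced by a property test. The model inherits
its structure from binary-choice dynamics used for language death and
religious affiliation; the departure is a time-varying individual utility.

Individual utility declines as published knowledge of the health effects
accumulates. With $n(t)$ the cumulative article count,

$$u_x(t) = u_\infty + \delta^{n(t)}\,(u_0 - u_\infty),$$

so each article discounts the no-knowledge utility $u_0$ toward the
saturated utility $u_\infty$ by a factor $\delta \in [0,1]$ (temporal
discounting). Two alternatives are implemented for comparison: a constant
utility and a step function switching from $u_0$ to $u_\infty$ at a
threshold year $t^*$. The discounted family nests the constant one at
$\delta = 1$, which yields the testable inequality
$E_2(\text{discounted}) \le E_2(\text{constant}) + \text{optimizer slack}$.

### Dynamical structure worth knowing

For $a > 1$ the interior equilibrium of the rate law is *unstable*: with
utility $u$, prevalence collapses toward 0 unless it starts above

$$x^* = \frac{r}{1+r}, \qquad r = \left(\frac{1-u}{u}\right)^{1/(a-1)}.$$

Every realistic rise-and-fall trajectory therefore starts just above this
adoption threshold at the early-century utility $u_0$, rises while
$u_x > 1/2$, and declines once accumulated knowledge pushes $u_x$ below the
level sustaining the current prevalence. The synthetic-data generator
respects this structure explicitly (below); the fitted parameter
combinations for real countries sit in exactly this regime.

## Data flow

1. **Ingest** (`read_tobacco_csv`, `read_article_csv`,
   `read_country_table`): the four-column tobacco dialect (country, year,
   value, type flag), the three-column article dialect (year, published,
   cumulative), and the registry (id, name, IDV). Readers validate and
   reject — prevalence in percent, inconsistent cumulative counts,
   duplicate measurements and malformed rows all raise errors naming the
   offending line; nothing is silently repaired. Headers are optional and
   detected by a non-numeric first field. Prevalence is a fraction in
   $[0,1]$ everywhere in the package.
2. **Knowledge curve** (`knowledge_curve`): piecewise-linear interpolation
   of cumulative counts; 0 before the first sample year (no knowledge),
   held constant after the last. The boundary rules are our choice — the
   interpolation rule is only specified between samples — and follow the
   semantics of cumulative knowledge. $\delta^n$ is computed as
   $\exp(n \log \delta)$ with $0^0 := 1$.
3. **Prevalence estimation** (`fit_linear_map`, `estimate_prevalence`):
   OLS of survey prevalence on consumption over the overlap years gives
   $\hat x(t) = \hat C c(t) + \hat B$ at every consumption year. Estimates
   are deliberately *not* clamped to $[0,1]$: clamping would bias the
   calibration errors. The inclusion filter keeps countries with
   $R^2 \ge 0.7$, slope $p < 0.001$ (two-sided t test) and
   $n_{obs} \ge 15$; boundary semantics are $\ge,\,<,\,\ge$. Outlier
   removal is analyst-driven (a configured exclusion list applied before
   the regression); `grubbs_screen` is the audit tool, a two-sided
   single-outlier Grubbs test on the ratios $x/\hat x$ flagging at most one
   year per pass.
4. **Calibration** (`fit_smoking_model`): see below.
5. **Trend statistics** (`peak_year`, `average_slope`,
   `trend_correlations`): the peak year is the earliest argmax of the raw
   consumption series — no smoothing, since any smoothing algorithm is an
   arbitrary extra choice; the fitted model trajectory is available through
   `predict()` as a principled smoother for sensitivity checks but is never
   the default. The average slope is
   $s_x = (\hat x(t_{max}) - \hat x(t_0))/(t_{max} - t_0)$ with
   $t_0 = 1920$, requiring both endpoint years to be present exactly.
   Correlations are Pearson with two-sided p-values from the t statistic on
   $n-2$ degrees of freedom, reported with the y-on-x OLS line.

## Calibration

Four local parameters per country ($a_i$, $x_{i,0}$, $u_{i,0}$,
$u_{i,\infty}$) and two universal parameters ($b$, $\delta$) minimise

$$E_2 = \sum_i E_{i,2}, \qquad
  E_{i,2} = \lVert \tilde X_i - \hat X_i \rVert_2^2,$$

the squared-L2 distance between the model trajectory and the estimated
prevalence at that country's observation years. The mean absolute error
$E_{i,1}$ is reported alongside. The procedure:

1. holding universals, fit each country's locals by bounded least squares;
2. holding locals, fit $(b, \delta)$ on the concatenated residuals;
3. repeat until $|\Delta E_2| < tol$ (default $10^{-6}$) or `max_itn`
   (default 150) outer iterations.

Box bounds are $0 \le a_i, b \le 2$ and
$0 \le x_{i,0}, u_{i,0}, u_{i,\infty}, \delta \le 1$; initial guesses are
$u_0 = 0.51$, $u_\infty = 0.49$, $a = 1$, $b = 1$, $\delta = 0.9985$, and
$x_{i,0} = \hat x_i(t_{i,0})$ with $t_{i,0}$ the first consumption year.
The inner solver is trust-region Levenberg–Marquardt on the residual
vector (`minpack.lm::nls.lm`) with finite-difference Jacobians; the ODE is
integrated by adaptive Dormand–Prince 4(5) (`deSolve`, `rtol` $10^{-8}$,
`atol` $10^{-10}$) with dense output at the observation years. The rate law
is compiled (deSolve's compiled-model interface, with the knowledge curve
supplied as a linearly interpolated forcing series), which makes a single
93-year solve well under a millisecond and keeps nested-optimisation
runtimes in seconds; the compiled path reproduces the interpreted rate law
to the last bit. Trial states
escaping $[0,1]$ by more than $10^{-9}$ trigger re-integration at
100-fold tighter tolerance; $x^a$ at $x = 0$, $a < 1$ takes its continuous
extension 0, so boundary states cannot produce NaN.

Two numerical safeguards were added after studying the optimisation
landscape, and both are deterministic:

* **Fallback starts.** The canonical start has a nearly flat utility
  ($u_0 = 0.51$, $u_\infty = 0.49$), where the vector field is almost null
  and a local fit can settle in a spurious basin (typical symptom:
  $a \approx 0.65$, $u$'s far below $1/2$, an order-of-magnitude larger
  $E_{i,2}$). When a single-start country fit leaves more than 2% of the
  series variance unexplained, it is retried from a fixed two-member
  portfolio of wider utility-spread starts and the best result kept.
* **Joint refinement.** Block-coordinate alternation zigzags near the
  optimum: the locals absorb small errors in the universals, so the
  per-iteration change in $E_2$ drops below `tol` long before the joint
  minimum is reached (on noise-free synthetic panels the alternation
  stalls around $E_2 \sim 10^{-3}$; with refinement the same panels reach
  $E_2 \sim 10^{-29}$ and exact parameter recovery). After the alternation
  terminates, all locals and universals are polished in a single joint
  bounded least-squares pass. The refinement only ever decreases $E_2$ and
  can be disabled (`joint_refine = FALSE`) to study the pure alternation.

For the step-function utility the threshold $t^*$ is a per-country
parameter searched on a grid: a coarse pass over every 5th observation
year, then a 1-year-resolution refinement window ($\pm 5$ years) around the
incumbent, refitting the remaining locals at each candidate and breaking
ties toward the earliest year. The full every-year grid is available by
setting `t_star_stride = 1`; the coarse-then-refine default is a
resolution/cost tradeoff, since each candidate requires a complete
four-parameter refit.

$E_2$ is nonincreasing across outer iterations by construction (each block
solve starts from the incumbent), and identical data and configuration give
bitwise-identical results. Optimiser non-convergence is flagged on the
returned object, never raised as an error.

## The synthetic-data generator

`synth_panel` inverts the analysis chain so that the full pipeline is a
statistical identity in the noise-free limit:

* the article curve is a logistic yearly rate (asymptote 2000/yr, midpoint
  1990, steepness 0.12/yr) with Poisson jitter, placing the knowledge-driven
  utility transition in the 1955–1975 era; the cumulative column is the
  running sum, so generated files always pass the reader's consistency
  checks;
* per-country truths are drawn within the fitted ranges — $a$ uniform on
  $[0.9, 1.2]$, $x_0$ on $[0.05, 0.2]$, $u_\infty$ on $[0.475, 0.51]$, map
  slope $C$ on $[0.04, 0.07]$ and intercept $B$ on $[0, 0.03]$. For
  $a > 1$, $u_0$ is solved from the adoption threshold so the threshold
  sits at 55–85% of $x_0$ (large $a$ paired with large $u_0$, as in the
  fitted countries); each draw is rejection-sampled until the simulated
  trajectory peaks between 1945 and 2000 at a prevalence in
  $[0.15, 0.65]$, declines by at least 10% afterwards, and stays above
  $B$ so the implied consumption is positive throughout;
* consumption is observed annually over 1920–2012 as $(x - B)/C$ plus
  Gaussian noise ($\sigma_c = 0.1$ g/person/day, truncated at 0 — the
  truncation is negligible at this noise level); surveys are $x$ plus
  Gaussian noise ($\sigma_x = 0.01$) every 2–3 years from 1960, mimicking
  the sparse survey record (~21 observations);
* the individualism index is $IDV = 120 - 90a + N(0, 5)$, clamped to
  $[0, 100]$ — negatively related to the true conformity by construction;
* everything is driven by one master seed; the same seed reproduces the
  panel bitwise.

The default noise levels put overlap-regression $R^2$ in roughly
$[0.9, 0.999]$, inside the inclusion-filter regime. What the generator does
*not* emulate: country-specific historical shocks (wars, rationing),
survey-methodology drift, gender/age structure, or any nonlinearity in the
consumption–prevalence relationship. Passing recovery tests therefore
demonstrate the *procedure's* correctness under the model's own
assumptions, not the adequacy of those assumptions for real data.

## Problem sizes used in tests

The shipped tests favour small, deterministic problems: two- and
three-country panels with annual consumption over 1920–2012 (or shorter
spans for unit subproblems), three outer iterations plus joint refinement
for noise-free identities, and twenty replicate panels at survey noise
$\sigma_x = 0.01$ with a three-iteration alternation for the bias study of
the conformity estimate. These sizes were chosen as the smallest instances
that exercise every code path with stable statistics. The two reproduction
tests that need the published supplementary inputs (tobacco-use CSV,
article counts, Hofstede IDV registry, census population) fail with an
explanatory message when those files are absent; drop them under
`inst/extdata/real/` (documented in the test file) to run the full
reproduction.

## Counterfactual calculation

`counterfactual_consumption` answers "how much less would have been smoked
had a country been less individualistic?": shift the IDV multiplicatively
(a percentage of the index value, not index points), convert to a
conformity shift through the fitted a-on-IDV OLS slope, re-simulate with
the shifted $a$ (all other parameters fixed), convert both trajectories to
per-capita consumption through the inverse affine map
$c = (\hat x - \hat B)/\hat C$, weight by linearly interpolated population
and 365 days/year, and report the percent decrease of the cumulative total
over the window (default 1920–2010). The grams-per-cigarette conversion
cancels in the ratio. The exact published algorithm for this scenario lives
in supplementary material we do not ship; the reconstruction above fixes
the two open choices (multiplicative IDV shift; consumption, not
prevalence, as the integrand) and should be re-validated against that
source where available.

## Known limitations

* The calibration landscape is multimodal; the fallback-start portfolio
  handles the basin observed in practice but offers no global guarantee.
* $b$ and $\delta$ are weakly identified at realistic noise levels (their
  sampling spread across replicate panels is large even when $a$ recovers
  well); interpret their point estimates with care.
* The affine consumption-to-prevalence map inherits errors-in-variables
  attenuation when consumption is noisy; the slope is slightly biased
  toward zero, as in any OLS calibration of this form.
* No uncertainty quantification on fitted parameters is provided, matching
  the scope of the procedure the package implements.
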