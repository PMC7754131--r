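---
title: "Power-equivalent design analysis for latent growth curve models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-equivalent design analysis for latent growth curve models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`powerequiv` works with the linear latent growth curve model (LGCM). Each of
$N$ participants is observed at $k$ fixed occasions $t_1 < \dots < t_k$, and

$$ x_{ij} = I_i + \lambda_j S_i + e_{ij}, $$

where the latent intercept $I_i$ and slope $S_i$ are bivariate normal with
means $\mu_I, \mu_S$, variances $\sigma_I^2, \sigma_S^2$ and covariance
$\sigma_{IS}$, the residuals $e_{ij}$ are i.i.d. $N(0, \sigma_E^2)$, and the
slope loadings default to $\lambda_j = t_j$ (linear growth in study time).
The observation vector is multivariate normal with

$$ \Sigma = \sigma_I^2\,11' + \sigma_S^2\,\lambda\lambda' +
   \sigma_{IS}(1\lambda' + \lambda 1') + \sigma_E^2 I, \qquad
   \mu_j = \mu_I + \mu_S t_j . $$

Everything downstream operates on the sufficient statistics $(S, m, N)$ —
the maximum-likelihood (divisor-$N$) sample covariance and the sample mean —
through the minus-two log-likelihood

$$ N\left[\ln|\Sigma| + \operatorname{Tr}(\Sigma^{-1}S) +
   (m-\mu)'\Sigma^{-1}(m-\mu)\right]. $$

The additive $Nk\ln(2\pi)$ constant is omitted throughout: the package only
ever uses likelihood *differences* (Bayes factors), in which it cancels, and
dropping it avoids carrying an arbitrary convention. The divisor-$N$
covariance is the form under which this expression is exactly minus twice
the sum of per-observation log-densities (up to that constant); the test
suite verifies this against a per-row density oracle.

The focal hypothesis test is $H_0\!: \sigma_S^2 = 0$ against
$H_1\!: \sigma_S^2 \sim \pi_1$, with every other parameter treated as known
and fixed. That "known nuisance" assumption is strong but is what makes the
one-dimensional treatment exact; in practice the nuisance values come from a
prior study or pilot data, and the Bayes factor is invariant to the known
means (they subtract out), so `mu_I` and `mu_S` default to 0.
$\sigma_{IS}$ defaults to 0 as well; simulations may set it freely subject
to positive semidefiniteness of the latent covariance.

## Effective error variance and the minimal model

The value of a design for the slope-variance test collapses into a single
number. Writing $\Sigma_0 = \sigma_I^2 11' + \sigma_E^2 I$ for the null
covariance, the generalized-least-squares slope score of a participant,

$$ \hat s_i = \sigma_{\mathrm{eff}}^2\, \lambda' \Sigma_0^{-1} y_i, \qquad
   \sigma_{\mathrm{eff}}^2 = (\lambda' \Sigma_0^{-1} \lambda)^{-1}, $$

is distributed $N(\mu^*, \sigma_S^2 + \sigma_{\mathrm{eff}}^2)$ under the
model, and the likelihood *ratio* between any two values of $\sigma_S^2$
depends on the data only through these scores (the $\sigma_S^2$ term is a
rank-one update of $\Sigma_0$ in the direction of $\lambda$). The scores are
therefore a lossless reduction for this test: orthogonally rotating the
model space so that one axis aligns with the slope direction and discarding
the axes whose distribution does not involve $\sigma_S^2$ leaves a
univariate "minimal model" $N(\mu^*, \sigma_S^2 + \sigma_{\mathrm{eff}}^2)$.
Two consequences are load-bearing and are tested directly:

* the likelihood is invariant under joint orthogonal transformation of
  $(\Sigma, \mu, S, m)$ (checked over 200 random rotations at relative
  tolerance $10^{-10}$);
* the Bayes factor computed from the full $k$-variate data equals the one
  computed from the reduced scores (checked over 50 random datasets at
  absolute log tolerance $10^{-8}$).

By the Sherman–Morrison identity the effective error has the scalar form
$\sigma_{\mathrm{eff}}^2 = \sigma_E^2 / \bigl(\sum_j \lambda_j^2 -
(\sum_j \lambda_j)^2/(k + \sigma_E^2/\sigma_I^2)\bigr)$, with the limit
$\sigma_E^2/\sum\lambda_j^2$ when $\sigma_I^2 = 0$; the tests confirm the
scalar form against direct $k \times k$ inversion.

Designs with equal $\sigma_{\mathrm{eff}}^2$ share one minimal model and
hence one Bayes-factor distribution — they are *power equivalent*.
`solve_equivalent_design()` searches within the family of equally spaced
designs anchored at $t = 0$ with $\lambda = t$: for $k$ occasions over
duration $T$ the precision scales as $T^2 c(k, r)$ with
$r = \sigma_E^2/\sigma_I^2$ and
$c(k, r) = \sum_{j} (j/(k-1))^2 - \bigl(\sum_j j/(k-1)\bigr)^2/(k+r)$,
giving the closed form $T = \sqrt{\sigma_E^2 / (\sigma_{\mathrm{eff,ref}}^2\,
c(k,r))}$. Because $\sigma_{\mathrm{eff}}^2(T)$ is strictly decreasing, the
function confirms the closed form by `stats::uniroot()` on
$T \in (10^{-6}, 10^{3}]$ weeks (tolerance $10^{-10}$) before returning, and
an independent interval-bisection oracle re-derives the durations in the
test suite. Equal spacing from $t=0$ is the only automated family; arbitrary
(unequally spaced) designs are accepted as references but not solved for.
More occasions always buy shorter studies: the solved $T$ is strictly
decreasing in $k$, which the suite checks for $k = 2, \dots, 12$.

## The Bayes factor

For a point prior the marginal likelihood is just the likelihood at that
value. For the gamma prior $\pi_1 = \mathrm{Gamma}(\text{shape},
\text{rate})$ — default shape 1, rate 0.5, an informed prior putting most
mass on slope variances between 0 and 6 in squared outcome units per squared
unit of study time — the integral

$$ \log \int_0^\infty L(S, m \mid \sigma_S^2)\,
   \pi_1(\sigma_S^2)\, d\sigma_S^2 $$

is evaluated in log space: the integrand's mode $\hat v$ is located on a
coarse log-spaced grid and refined with `stats::optimize()`, the integrand
is normalised by its maximum, and `stats::integrate()` (adaptive
Gauss–Kronrod) is applied to the two pieces $(0, \hat v)$ and
$(\hat v, \infty)$ at relative tolerance $10^{-10}$. Splitting *at the mode*
puts the peak on a boundary of both pieces, which the adaptive rule always
resolves — including for needle-sharp integrands such as a gamma prior with
shape $10^4$, which the tests use to confirm convergence to the point-prior
limit. If either piece fails to converge, or the combined error estimate
exceeds $10^{-6}$ of the integral, the function *raises an error* rather
than returning a silently wrong number. Correctness of the quadrature is
pinned against a 20,000-node trapezoid rule on $\sigma_S^2 \in [0, 60]$
(the default prior puts $\sim 10^{-13}$ mass beyond 60) at absolute log
tolerance $10^{-6}$; the oracle's test datasets use small $N$ and designs
rescaled so $\sigma_{\mathrm{eff}}^2 \in [6, 10]$, keeping the fixed grid's
$O(h^2)$ discretisation error an order of magnitude below that comparison
tolerance.

$\log BF_{10}$ is the difference of the $H_1$ and $H_0$ log marginal
likelihoods; it is exact with respect to the omitted constant, invariant to
known mean shifts, and strictly increasing in the reduced-model score
variance (a monotone-likelihood-ratio property the tests check on a grid).
One practical caveat: the Bayes factor, unlike the power-equivalence
arithmetic, is *not* invariant to the time units of the slope loadings,
because the prior is expressed in slope-variance units (outcome² per
time-unit²). Rescaling the loadings rescales $\sigma_{\mathrm{eff}}^2$ but
not the prior, and changes the evidence. State the prior in the same time
units as the design, and treat its scale as a substantive choice.

## Bayes factor design analysis

`run_bfda()` repeats `n_iter` times: draw the true $\sigma_S^2$ from the
design prior, simulate $N$ participants from the implied LGCM
(`MASS::mvrnorm`), and compute $\log BF_{10}$. Iteration $i$ runs on an RNG
substream derived deterministically from `(seed, i)` (a pre-drawn vector of
sub-seeds), so results are bit-reproducible and do not depend on iteration
order. Summaries are the fractions of $BF_{10}$ beyond the evidence
thresholds — defaults $1/10$ and $10$, the conventional 10-fold bounds for
strong evidence — and the 1/5/25/50/75/95/99% quantiles of $\log BF_{10}$.
The CI-speed default is `n_iter = 500`; the acceptance script uses 1000.

`compare_bfda()` replaces an eyeball overlay of BFDA histograms with
pairwise two-sample Kolmogorov–Smirnov tests on the $\log BF_{10}$ samples,
at $\alpha = 0.01$. That level is chosen so the check has teeth both ways:
solved 3/5/7-occasion power-equivalent designs pass (the suite also runs 20
independent pairs and tolerates at most two flags, the expected false-flag
budget), while a deliberately non-equivalent design — same occasions, half
the duration — is reliably flagged.

## Costs

`cost_design()` charges `cost_per_wave_per_participant × N × k` (default
$10) plus `running_cost_per_week × duration` (default $500) with the
**unrounded** solved duration; rounding to whole currency units (half away
from zero) happens only at print time, so ranking and savings are computed
at full precision. `rank_equivalent_designs()` solves each requested
occasion count, costs it, sorts by total (ties broken by fewer waves) and
reports percent saving against the reference design's total.

## What the simulator does and does not emulate

The generator draws complete, balanced multivariate-normal data with a
fixed, known structure: every participant observed at every occasion,
linear growth, homoscedastic residuals, nuisance parameters known exactly.
This is precisely the regime in which power equivalence is an exact
theorem, and it is what the passing tests certify. Real longitudinal data
depart from it in ways the package deliberately does not model: dropout and
intermittent missingness, nonlinear or piecewise growth, occasion-specific
residual variances, and — most importantly — nuisance parameters that are
estimated, not known. Passing tests therefore show that the machinery is
correct under the stated model, not that a real study with estimated
$\sigma_I^2$ and $\sigma_E^2$ will enjoy exactly equal Bayes-factor
distributions across redesigns; when the nuisance values are uncertain, the
comparison should be repeated over a plausible range.

## Numerical choices and degenerate inputs

* Cholesky factorisation for $\ln|\Sigma|$ and $\Sigma^{-1}$; a
  non-positive-definite model covariance raises an error naming `Sigma`.
* Designs with all-zero slope loadings are rejected (no slope
  information); $\sigma_I^2 = 0$ uses the exact limiting effective error.
* `sample_moments()` accepts covariance matrices up to an $10^{-8}$
  asymmetry/negative-eigenvalue slack to absorb round-trip noise, and
  symmetrises on construction.
* Seeds are plain 32-bit integers; per-iteration sub-seeds are drawn below
  `.Machine$integer.max`.
* Configs load from YAML or JSON with unknown keys rejected and every
  violated constraint reported by key name; `save_config()` writes the
  fully resolved config at full numeric precision, and load–save–load is
  the identity (a tested round-trip).

## Problem sizes used in the checks

Moment-convergence and score-variance checks simulate $N = 50{,}000$
participants with tolerances set at five standard errors of the
corresponding sampling distributions. Distribution-level equivalence uses
three BFDAs of 500 iterations each at $N = 300$; the false-flag experiment
uses 20 pairs of 120-iteration runs; the planning-scenario BFDA uses 1000
iterations at $N = 50$. These sizes make the full suite run in a few
minutes on a single core while keeping every tolerance derived from the
statistics, not from the runtime.

## Limitations

Power equivalence as implemented requires a fixed structure matrix: the
loadings are design constants, not estimated quantities, which covers
LGCMs and close relatives (change-score models, latent difference models)
but not models with free loadings. The package fits nothing — it is a
planning tool, and nuisance parameters must be supplied. Sequential
designs, in which sampling continues until an evidence threshold is
reached, are out of scope; the BFDA here is fixed-$N$ only. And the
equivalence solver covers equally spaced designs anchored at zero;
irregular candidate designs can be evaluated via
`effective_error_variance()` but are not solved for automatically.
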