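---
title: "Measuring statistical evidence with relative belief ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring statistical evidence with relative belief ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relbelief)
```

## The model of evidence

Probability measures belief; evidence is what *changes* belief. relbelief
takes that distinction literally. Given a sampling model
$\{f_\theta : \theta \in \Theta\}$, a proper prior $\pi$, and observed data
$x$, the evidence that a value $\psi$ of the parameter of interest is the
true one is measured by the **relative belief ratio**

$$RB(\psi \mid x) \;=\; \frac{\pi(\psi \mid x)}{\pi(\psi)},$$

the factor by which the data moved the prior density to the posterior
density at $\psi$ (defined as a limit of shrinking-neighbourhood probability
ratios in the continuous case). $RB > 1$ is evidence in favour, $RB < 1$
evidence against, $RB = 1$ no evidence either way. Every inference the
package produces is ordered by this ratio:

* **Estimation.** The least relative surprise estimate (LRSE) is the value
  maximizing $RB(\cdot \mid x)$ — the best-supported value. Its accuracy is
  the size of the $\gamma$-relative belief credible region
  $C_\gamma = \{\psi : RB(\psi \mid x) \ge c_\gamma\}$, with $c_\gamma$ the
  smallest threshold whose region holds posterior content at least
  $\gamma$. Evidence ordering forces these regions: if $\psi_1$ is in the
  region and $\psi_2$ has at least as much evidence, $\psi_2$ must be in it
  too.
* **Hypothesis assessment.** The evidence for $H_0 : \psi = \psi_0$ is
  $RB(\psi_0 \mid x)$; its **strength** is the calibration
  $\Pi(RB(\psi \mid x) \le RB(\psi_0 \mid x) \mid x)$ — the posterior
  probability that the true value is no better supported than $\psi_0$. A
  large ratio with a small strength is *weak* evidence in favour: many
  values are better supported. The chain
  $\Pi(\{RB = RB(\psi_0\mid x)\}\mid x) \le \text{strength} \le RB(\psi_0 \mid x)$
  always holds and is asserted across randomized configurations in the test
  suite.

The Bayes factor of a set $A$ equals $RB(A)/RB(A^c)$ and is reported as a
companion quantity where both sides have positive prior mass; it is not the
primary measure, because for a continuous point hypothesis its limit *is*
the relative belief ratio.

## Backends: exact conjugate families and a generic grid

Two closed-form backends cover the package's sampling models:

* `beta_bernoulli(alpha0, beta0, ...)`: i.i.d. Bernoulli($\theta$) with a
  beta prior; posterior beta($\alpha_0 + s$, $\beta_0 + n - s$) with $s$ the
  success count, the minimal sufficient statistic.
* `normal_known_var(mu0, tau0_sq, sigma_sq, ...)`: i.i.d. normal with known
  variance and a normal prior on the mean; the sample mean is the
  sufficient statistic.

All density ratios are computed as differences of log densities and then
exponentiated: the gamma-function ratios of the textbook Bernoulli formula
overflow naive evaluation once $n$ reaches the hundreds, while the
log-space path is exact to machine precision at any practical $n$.

The generic engine (`discretize()`, `relative_belief()`, `lrse()`,
`credible_region()`, `strength()`) operates on paired prior/posterior cell
masses. Cell masses are **exact differences of distribution functions at
the cell edges** — not density values times a width — so each cell's mass
is correct to cdf precision and both vectors renormalize over the grid.
Statistical problems are finite in practice (finite populations, finite
measurement precision); the grid is the honest computational realization of
that, with continuity recovered by refinement. The default is 4096 cells
over the central $1 - 10^{-8}$ combined mass region of prior and posterior;
bounds that capture less than $1 - 10^{-6}$ of either distribution record a
warning in the report. With a conjugate model `assess_evidence()`
additionally refines the strength, region endpoints and estimate by
root-finding on the closed-form ratio curve (which is unimodal for both
families) with exact distribution functions, so the reported numbers carry
no grid resolution at all; the grid values are kept alongside.

For an arbitrary marginal parameter $\psi = \Psi(\theta)$ there is a Monte
Carlo path, `mc_marginal_belief()`: prior masses by binning prior draws of
$\psi$, posterior masses by importance-weighting the same draws with the
likelihood. It takes an explicit integer seed, leaves the global RNG state
untouched, and warns when the effective sample size of the weights drops
below 50. The tests require it to agree with the closed forms within Monte
Carlo error at a fixed seed.

### Numerical conventions

* Ratios are compared with relative tolerance $10^{-9}$ when forming the
  events $\{RB \le RB(\psi_0)\}$ and $\{RB = RB(\psi_0)\}$: exact-symmetry
  inputs (a symmetric prior with a symmetric count) produce floating-point
  ties that would otherwise flip the strength.
* The direction is "neutral" iff $|RB - 1| \le 10^{-9}$, giving the
  exact-equality branch of the evidence principle a numeric realization.
* LRSE ties break to the smallest grid value, with a `tied` flag.
* The region threshold is inclusive ($RB \ge c_\gamma$) and the attained
  content is reported, since exact content $\gamma$ is generally
  unattainable on a grid.
* $\theta \in \{0, 1\}$ is outside the Bernoulli domain: the prior density
  is 0 or $\infty$ there for general shapes. A model with $n = 0$ is legal
  everywhere and returns $RB \equiv 1$.

## Checking the prior before using it

Every subjective ingredient should be checkable against the data. The joint
distribution of $(\theta, x)$ factors through a minimal sufficient
statistic $T$ as posterior $\times$ prior predictive of $T$ $\times$
conditional data distribution given $T$; the three factors drive inference,
prior checking, and model checking respectively, so the activities never
contaminate each other. `prior_data_conflict()` implements the prior check:
the tail probability $M_T(m_T(t) \le m_T(t_{obs}))$, the prior predictive
mass of statistic values no more probable than the observed one. Values
near 0 mean the data arose where the prior assigns almost no belief. For
discrete predictives this sorts the masses and sums (ties included, so the
modal value scores exactly 1); for the normal predictive the equivalent
two-sided density tail has the closed form $2\Phi(-|t-\mu_0|/sd)$. The
package does not prescribe a one-sided variant for continuous $T$: the
density-based tail is two-sided by construction and is what is documented
and tested. The default advisory cutoff is 0.05, and `run_assess()` warns
on conflict but never blocks inference — checking and inference use
different factors of the joint, and inference presumes the checks passed.
Model checking via the third factor is deliberately out of scope.

## Bias: what the prior has already decided

Before data are collected, the prior may already make evidence against
$\psi_0$ (or for it) nearly unavoidable. By the Savage–Dickey identity,
$RB(\psi_0 \mid x) = m(x \mid \psi_0)/m(x)$, a ratio of prior predictive
densities, so it depends on the data only through $T$ — which collapses the
Bernoulli bias sums from $2^n$ data vectors to $n + 1$ lattice terms:

* `bias_against()`: the prior probability of $\{RB(\psi_0 \mid T) \le 1\}$
  with $T$ generated at $\psi_0$ — failing to find evidence for a true
  hypothesis.
* `bias_in_favor()`: the prior probability of $\{RB(\psi_0 \mid T) > 1\}$
  with $T$ generated at a meaningfully different $\psi_0'$ — failing to
  find evidence against a false one.

The inequality conventions matter on a discrete lattice where ties can
carry mass: the bias-against event uses $\le 1$ and the bias-in-favor event
uses strict $> 1$, following the worked convention; the two events then
partition the lattice exactly, which the tests assert. Bernoulli values
are exact finite sums; normal-family values are exact too, via the interval
of sample means where the log ratio (a downward quadratic, since the
conditional predictive variance is strictly smaller than the marginal's) is
positive, with the degenerate near-linear algebra handled analytically.

One caution established while validating: the common statement that both
biases decrease with sample size is asymptotic. At a deviation of 0.05
around $\psi_0 = 0.5$ with a beta(4, 4) prior, the bias in favor *rises*
from 0.690 at $n = 20$ to 0.779 at $n = 80$ before falling (0.016 by
$n = 2000$): until $n$ can resolve the deviation, extra data mostly
concentrate the ratio above 1. `design_sample_size()` therefore scans $n$
linearly (not by bisection) for the smallest value meeting both bias
targets, and returns the full trace.

## The two-state example

`two_state(epsilon, psi1, psi2)` is the closed-form classification
problem: a positive class of prior proportion $\varepsilon$, a binary trait
with rates $\psi_1$ (negative class) and $\psi_2$ (positive class).
Observing the trait gives $RB(\text{positive}) = \psi_2 / m$ with
$m = (1-\varepsilon)\psi_1 + \varepsilon\psi_2$, which exceeds 1 exactly
when the trait is informative ($\psi_2 > \psi_1$) — *regardless of how
small $\varepsilon$ is*. The protection against the prosecutor's fallacy is
the mandatory second half of the report: as $\varepsilon \to 0$ the
$\gamma$-region grows to both classes and the posterior probability of the
positive class vanishes, so the (real) evidence is exposed as arbitrarily
weak. On a two-point space the strength is reported both as the general
calibration and as the plain posterior class probability; with only two
values the latter is the more direct reading, and the report includes both
rather than choosing.

```{r two-state}
ts <- two_state(0.01, 0.01, 0.99)
two_state_evidence(ts, gamma = 0.95)
```

## Synthetic data and what the tests do and do not show

`generate_data()` draws i.i.d. Bernoulli or normal samples under an
explicit seed; the packaged worked example (`example_proportion_data()`,
twenty 0/1 observations with eight ones) was itself generated from
Bernoulli(1/2), and the prior-data conflict check confirms the beta(4, 4)
prior is compatible with it. The generator emulates exactly the two
sampling models the inference machinery assumes — independent, identically
distributed draws with known family. It does not produce overdispersion,
serial dependence, measurement error, or model misspecification of any
kind, so green tests certify the evidence machinery, not robustness of the
Bernoulli or normal model on messy real data; for real analyses the model
check (out of scope here) carries that burden.

Problem sizes used by the suite and the reproduction script were chosen to
keep every quantity either exact (lattice sums, closed forms) or
grid/Monte-Carlo converged: 4096 grid cells for reported inference, 256
cells inside 200-configuration property sweeps, and $2\text{–}4 \times
10^5$ draws for the Monte Carlo cross-checks, which puts the MC standard
error well inside the asserted three-standard-error bands.

## A worked run

```{r worked}
m <- beta_bernoulli(4, 4, data = example_proportion_data())
prior_data_conflict(prior_predictive(m), t_obs = m$s)
assess_evidence(m, psi0 = 0.5, gamma = 0.95)
bias_report(m, psi0 = 0.5, delta = 0.05)
```

The evidence for $\theta = 1/2$ is $RB = 1.421 > 1$ — belief in one half
increased — but the strength 0.311 says the posterior gives probability
0.689 to values with *more* evidence, so the favourable evidence is only
moderate. That is not evidence against 1/2 (belief increased); it is weak
evidence for it. The 0.95-region (0.227, 0.593) around the LRSE 0.400
quantifies the estimation uncertainty, and the pre-experimental biases
(0.263 against; 0.690 in favor at $\pm 0.05$) warn that with $n = 20$ this
prior makes evidence in favour of one half quite likely even when the truth
is 0.45 or 0.55.

## Known limitations

* One-dimensional parameters of interest only; the geometry generalizes,
  but no multidimensional grid is provided.
* Exactly two conjugate families; anything else must come through the
  Monte Carlo path.
* Proper priors only: the diffuse-prior behaviour (the ratio at any fixed
  point diverging as the prior variance grows, the formal route to the
  Jeffreys–Lindley paradox) is exercised with large finite prior variances,
  never improper limits.
* No decision layer: the package reports evidence and its strength, and
  deliberately stops there.
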