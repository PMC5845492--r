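---
title: "Correcting covariate misclassification in multilevel count models"
author: "miscount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting covariate misclassification in multilevel count models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miscount)
```

## The problem

Epidemiological exposures are often binary and often misreported: a survey
question about, say, domestic violence in the respondent's childhood home has
imperfect sensitivity (true cases denied) and, usually to a lesser degree,
imperfect specificity (non-cases affirmed). When such a fallible indicator is
plugged into a regression as if it were the truth — the *naive* analysis —
the estimated exposure effect is biased toward the null, and its credible or
confidence interval, being centred on the wrong value with optimistic width,
can have essentially zero coverage.

`miscount` addresses this for **two-level count data**: subjects
$i = 1,\dots,n_j$ nested in clusters $j = 1,\dots,N$ (states, sites,
villages), a count outcome, and a binary exposure observed only through one
or two fallible assessments.

## The joint model

Three submodels are fitted jointly.

**Outcome model** — hierarchical Poisson regression:
$$
y_{ij} \sim \mathrm{Poisson}(r_{ij}\lambda_{ij}), \qquad
\log \lambda_{ij} = \beta_0 + u_j + \beta_1 x_{ij} + \textstyle\sum_k \beta_k z_{ijk},
\qquad u_j \sim N(0, \sigma^2),
$$
with offset $r_{ij} > 0$ (defaulting to 1), true exposure $x_{ij}$, and
error-free covariates $z_{ijk}$.

**Exposure model** — hierarchical logistic regression for the true exposure:
$$
x_{ij} \sim \mathrm{Bernoulli}(\pi_{ij}), \qquad
\mathrm{logit}\,\pi_{ij} = \gamma_0 + v_j + \textstyle\sum_k \gamma_k z_{ijk},
\qquad v_j \sim N(0, \nu^2).
$$

**Measurement model** — nondifferential misclassification. Given
$x_{ij} = 1$ the assessment $x_{1ij}$ is Bernoulli with success probability
$S_1$ (sensitivity); given $x_{ij} = 0$ it is Bernoulli with success
probability $1 - C_1$ (one minus specificity). A second assessment
$x_{2ij}$, when available, is conditionally independent of the first given
$x_{ij}$, with its own $(S_2, C_2)$.

The joint posterior is proportional to the product of the three likelihoods
and the priors. The true exposure vector is latent and is imputed by data
augmentation inside the sampler.

### Priors, and a parameterization warning

* Every regression coefficient gets an independent mean-zero normal prior
  **parameterized by variance**: variance 10 for the logistic ($\gamma$)
  coefficients and variance 100 for the Poisson ($\beta$) coefficients by
  default. BUGS dialects write `dnorm(0, tau)` with a *precision*; a BUGS
  `dnorm(0, 10)` is *not* this prior. `prior_spec()` takes variances.
* $\sigma$ and $\nu$ get uniform $(0,\ \texttt{sd\_upper})$ priors,
  default upper bound 3 — a weakly-informative choice appropriate when
  cluster heterogeneity on the log/logit scale is plausibly well below 3.
* Each sensitivity and specificity gets a beta prior.

**Identifiability.** With two conditionally independent assessments all four
operating characteristics are identified and flat `beta(1, 1)` priors are the
default. With a single assessment $(S_1, C_1)$ are *not* identified from the
data; `prior_spec(mode = "one_test")` therefore refuses to default the
shapes and requires explicit, informative choices. The standard study
configuration uses `beta(10, 8)` for $S_1$ (mean 0.556, wide) and
`beta(165.7, 9.7)` for $C_1$ (mean 0.945, tight), reflecting the typical
survey situation of substantial underreporting but very few false
affirmatives. The one-test fit is best read as a Monte-Carlo sensitivity
analysis over the prior-plausible $(S_1, C_1)$ range.

A related failure mode is **label switching**: the likelihood is invariant
under $(x, S, C) \to (1-x, 1-C, 1-S)$ with the regression signs adjusted, so
a fit whose posterior puts mass on $S + C < 1$ has partially swapped the
labels of the latent classes. `run_chain()` warns when more than 1% of
retained draws fall on that side.

## The sampler

The paper trail for this class of models usually ends at "fit it in
BUGS/JAGS"; `miscount` instead ships its own Metropolis-within-Gibbs sampler
(C++ core, all randomness through R's RNG so `set.seed()` gives bitwise
reproducibility). One sweep does:

1. **Latent exposure:** every $x_{ij}$ is drawn from its *exact* Bernoulli
   full conditional $P(x_{ij}=1 \mid \cdot) = A/(A+B)$, where $A$ multiplies
   the exposure probability, the Poisson likelihood at $x=1$, and the
   measurement likelihood of the observed assessments at $x=1$, and $B$ is
   the $x=0$ analogue (assembled on the log-odds scale for stability).
2. **Coefficients:** each $\beta$ and $\gamma$ is updated by scalar
   random-walk Metropolis on the joint log posterior; the cluster intercepts
   $u$ and $v$ by independent per-cluster random walks.
3. **SDs:** $\sigma$ and $\nu$ by random walk on the log scale (with the
   log-scale Jacobian), respecting the uniform upper bound.
4. **Operating characteristics:** given the imputed exposures the $S$ and
   $C$ updates are conjugate beta draws — e.g.
   $S_1 \mid \cdot \sim \mathrm{beta}(a + \#\{x=1, x_1=1\},\ b + \#\{x=1, x_1=0\})$.

Proposal scales adapt by Robbins–Monro toward a 0.44 per-block acceptance
rate **during burn-in only** and are frozen afterwards, so the retained
draws come from a fixed kernel satisfying detailed balance. Exact conditional
draws are used wherever a closed form exists (latent exposure, $S$, $C$)
because they mix better and are directly testable against enumeration and
conjugacy oracles.

Initialization: coefficients at 0, both SDs at 0.1, $S$/$C$ at their prior
means, and the latent exposure at the first assessment — a deliberate
symmetry-breaker that starts the chain on the correct side of the
label-switching ridge.

The test suite validates the sampler three independent ways: the latent-x
conditional against brute-force two-point enumeration, the $S$/$C$ updates
against the closed-form beta posterior, and the whole sweep by a
joint-distribution ("getting it right") comparison of prior draws against
successive-conditional draws on a miniature model, with batch-means standard
errors and a $|z| < 4$ criterion.

## Posterior summaries

`summary()` reports the posterior mean, sample SD, and the **equal-tailed**
95% credible interval — the 2.5% and 97.5% empirical quantiles under R's
default type-7 rule. Equal-tailed (rather than HPD) intervals match the
convention of the BUGS-family tools this package replaces. Coverage
bookkeeping in simulation studies uses closed interval endpoints, a
measure-zero convention fixed for reproducibility.

## The simulator and the benchmark design

`sim_design()`/`simulate_misclass_data()` generate data with exactly the
structure the model assumes. The default design is the package's benchmark:
25 clusters of 200 subjects; exposure model
$\mathrm{logit}\,\pi = -1.5 + v_j - 0.21 z_1 - 0.16 z_2 + 0.19 z_3 - 0.29 z_4$;
outcome model
$\log \lambda = 0.85 + u_j + 0.4 x + 0.25 z_1 - 0.2 z_2 - 0.18 z_3 - 0.05 z_4$;
$\sigma = \nu = 0.1$; test 1 with $(S_1, C_1) = (0.55, 0.95)$ and test 2
with $(S_2, C_2) = (0.7, 0.8)$. This puts exposure prevalence near 0.18 and
mean counts near 2.4 — magnitudes typical of, e.g., parity counts with a
moderately rare exposure.

Two generative choices are genuinely open and were fixed once:

* **Covariate distribution:** the four $z$'s are independent standard
  normal. This is the largest unconstrained degree of freedom in the
  benchmark; `z_dist` is overridable for users who want correlated or
  non-normal covariates.
* **Offset:** $r \equiv 1$ in simulation.

What the simulator does *not* emulate: correlated covariates, unequal or
informative cluster sizes, overdispersion beyond the random intercept,
differential misclassification (error rates depending on the outcome), and
more than two assessments. Passing benchmarks therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to their violation.

## The simulation-study harness

`run_sim_study()` repeats simulate–fit–summarize over replicates and
tabulates, per mode and parameter: truth, average posterior mean, average
posterior SD, and empirical 95%-interval coverage. Replicate seeds derive
from a master seed by a documented splitting rule
(`replicate_seed()`), so studies are deterministic end to end and
replicates could be farmed out in parallel. A failed fit is excluded and
counted, never silently dropped.

The default profile uses 10 replicates with 3,000 post-burn-in draws after
1,500 burn-in — sizes chosen so a three-mode study completes in minutes on
one core while leaving Monte-Carlo error well below the effects being
measured (the attenuation gap is ~0.15–0.4; per-replicate posterior means
have MC error of a few thousandths). `cmd_sim_study()`'s `paper_profile`
flag switches to 50 replicates with 20,000 draws after 10,000 burn-in for a
longer offline run.

### What to expect, quantitatively

For a log-linear outcome model the naive estimand can be computed in closed
form: with prevalence $\pi(z)$ and assessment positive-predictive values
$P(x{=}1 \mid x_1{=}1, z)$ and $P(x{=}1 \mid x_1{=}0, z)$, the naive
coefficient converges to
$\log\{1 + (e^{\beta_1}-1) P(x{=}1 \mid x_1{=}1)\} -
 \log\{1 + (e^{\beta_1}-1) P(x{=}1 \mid x_1{=}0)\}$.
At the benchmark settings ($\pi \approx 0.18$, $S_1 = 0.55$, $C_1 = 0.95$,
$\beta_1 = 0.4$) this is $\approx 0.25$ — attenuated by roughly 40%, with
the displaced remainder absorbed into the intercept. Because the naive
posterior SD is an order of magnitude smaller than the bias-corrected one,
its intervals essentially never cover the truth, while the corrected models
re-centre on 0.4 at the price of posterior SDs around 0.1. Complete
attenuation to zero would require an assessment carrying *no* information
about the true exposure ($S + C = 1$); the benchmark's tests are informative,
so the naive estimate is biased toward, but not onto, the null.

## Numerical choices and degenerate inputs

* Log-densities return $-\infty$ exactly when a support constraint is
  violated ($\sigma$ or $\nu$ outside $(0,\ \texttt{sd\_upper})$); fits
  refuse to start from a state with non-finite joint log posterior.
* Conjugate beta draws are clamped to $[10^{-12}, 1 - 10^{-12}]$ so the
  log-odds terms of the latent-x conditional stay finite.
* Bernoulli-logit log likelihoods use a stable softplus; the latent-x
  conditional is assembled entirely on the log-odds scale.
* Cluster labels of any type are re-indexed to contiguous `1..N`; the
  original labels are preserved in outputs.
* Missing values in required columns are an error, never dropped.

## Known limitations

* Nondifferential misclassification only; a misclassified *outcome* is out
  of scope.
* At most two assessments.
* Single-chain inference; `run_chain()` is cheap enough to run at several
  seeds, but no multi-chain convergence orchestration is built in.
* The one-test posterior inherits its $(S_1, C_1)$ location mostly from the
  prior; that is a property of the model, not of the implementation.
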