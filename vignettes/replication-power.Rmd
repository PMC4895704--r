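---
title: "Designing GWAS replication studies with Empirical Bayes predictive power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing GWAS replication studies with Empirical Bayes predictive power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repower)
```

## The design problem

After a case-control GWAS identifies associations at a stringent
two-sided level $\alpha_1$, a replication study re-tests them one-sided
(sign-consistent) at level $\alpha_2$. The replication sample size should
be chosen so the identified *true* associations have a good chance of
replicating. The difficulty is that everything we know about the effect
sizes comes from the same scan that selected them: conditional on
passing the threshold, the observed log odds ratios are biased away from
zero (the winner's curse), so the obvious plug-in power estimate
$\beta^{(2)}(\hat\mu^{(1)})$ is optimistic, and a study sized from it is
underpowered.

`repower` treats this as an Empirical Bayes problem. All computation is
on per-SNP summary statistics: the allele-based $2\times 2$ table (or
directly a (log-OR, SE) pair), from which we form
$\hat\mu = \log n_{00} - \log n_{01} - \log n_{10} + \log n_{11}$, the
Woolf standard error
$\sigma = \sqrt{1/n_{00} + 1/n_{01} + 1/n_{10} + 1/n_{11}}$, and the Wald
statistic $z = \hat\mu/\sigma$.

## Model and estimators

Genome-wide, effect sizes are modelled by the two-component mixture
prior
$$\mu \sim \pi_0\,\delta_0 + (1-\pi_0)\,N(0, \sigma_0^2),$$
a point mass for the null SNPs plus a Gaussian for the associated ones.
Conditional on association, conjugacy gives the posterior
$\mu \mid z^{(1)} \sim N(\lambda\hat\mu^{(1)}, \lambda(\sigma^{(1)})^2)$
with shrinkage factor $\lambda = 1/(1 + (\sigma^{(1)}/\sigma_0)^2)$, and
the Bayesian predictive power of the replication study in closed form:
$$\eta^{(2)} = \Phi\!\left(\frac{\mathrm{sgn}(z^{(1)})\,z^* -
z_{\alpha_2}}{\sigma^*}\right),\qquad
z^* = \frac{\lambda\hat\mu^{(1)}}{\sigma^{(2)}},\quad
\sigma^* = \sqrt{1 + \lambda\left(\sigma^{(1)}/\sigma^{(2)}\right)^2}.$$
$\eta^{(2)}$ is the posterior mean of the power function and minimises
the mean squared error among power estimators when the error is averaged
over both the sampling distribution *conditioned on selection* and the
prior — this is the precise sense in which it is immune to the winner's
curse. The package verifies the closed form against numerical
integration of the posterior-averaged power, and checks the Bayes-risk
ordering empirically in its simulation experiments.

Three plug-in competitors are implemented for comparison, all mapped
through the same power function $\beta^{(2)}(\mu) =
\Phi(\mathrm{sgn}(z^{(1)})\mu/\sigma^{(2)} - z_{\alpha_2})$:

* **naive** — the observed $\hat\mu^{(1)}$ (upward-biased under selection);
* **CMLE** — the maximiser of the likelihood conditioned on
  $|Z^{(1)}| > z_{\alpha_1/2}$ (removes the selection bias of the effect
  estimate but over-corrects the *power* estimate downward);
* **EB plug-in** — the posterior mean $\lambda\hat\mu^{(1)}$ (shrunken,
  but still a point plug-in, hence biased upward through the nonlinear
  power function).

The design-phase replication standard error $\sigma^{(2)}$ is projected
from the primary table by rescaling its observed allele frequencies to
the replication group sizes:
$\sigma^{(2)} \approx \sqrt{(n_0^{(1)}/n_0^{(2)})(1/n_{00}+1/n_{01}) +
(n_1^{(1)}/n_1^{(2)})(1/n_{10}+1/n_{11})}$.

## Hyperparameter estimation

$\pi_0$ is estimated from the two-sided p-values with the Storey-type
tail estimator $\hat\pi_0(\gamma) = \#\{p_i > \gamma\}/(m(1-\gamma))$.
The automatic procedure evaluates it on the grid
$\gamma = 0, 0.05, \ldots, 0.90$, fits a natural cubic smoothing spline
with 3 equivalent degrees of freedom, and reads off the value at
$\gamma = 1$; the grid and spline flexibility are the conventional
choices for that procedure. The estimate is clamped into $[1/m, 1]$ —
a zero estimate would make the variance estimator below undefined.
Because the spline extrapolates through the noisiest part of the grid,
it needs a reasonably large $m$; below 100 p-values the function falls
back to the fixed threshold $\gamma = 0.5$ with a warning, and for
moderately small scans (a few thousand SNPs) the fixed-threshold
estimator (`fit_prior(..., gamma = 0.5)`) is the stabler choice.

$\sigma_0^2$ follows from the marginal second moment of the Wald
statistics, $E(\sum_i z_i^2) = m\pi_0 + (1-\pi_0)(m +
\sigma_0^2\sum_i \sigma_i^{-2})$, inverted and truncated at zero. Two
degenerate regimes are propagated deliberately: if the empirical mean of
$z^2$ is at most 1 (no more dispersion than the global null), then
$\hat\sigma_0^2 = 0$, $\lambda = 0$, and every predictive power
degenerates to $\alpha_2$; if $\hat\pi_0 = 1$ while the mean of $z^2$
exceeds 1, then $\hat\sigma_0^2 = +\infty$ is used as an explicit
sentinel under which $\lambda = 1$ exactly and shrinkage disappears.

## Credible intervals

The power is a monotone but nonlinear map of a Gaussian variable
restricted to $[0,1]$, so its posterior distribution is skewed and
normal-theory intervals are inappropriate. Per-SNP intervals are
equal-tailed sample quantiles (linear interpolation, the default type-7
definition) of Monte Carlo draws: effect sizes from the conjugate
posterior, mapped through the power function. Sampling under the fitted
prior alone ignores the estimation error in $(\pi_0, \sigma_0^2)$ and
under-covers; the combined method therefore resamples the $m$ primary
$(z, \sigma)$ pairs with replacement $N_1$ times, re-fits **both**
hyperparameters per resample, draws $N_2$ power values per resample, and
pools all $N_1 N_2$ values. (Re-fitting only $\sigma_0^2$ would
understate the hyperparameter uncertainty; re-fitting both is the
package's choice where the procedure is otherwise ambiguous.) One
resample sequence is shared by all SNPs in a call, reflecting that the
hyperparameters are study-level quantities. Defaults are
$N_1 = N_2 = 100$. The reported point estimate is always the closed-form
$\eta^{(2)}$ under the original prior. Resamples whose re-fitted
$\hat\pi_0$ caps at 1 keep their per-SNP draws (the power side is well
defined in the $\lambda = 1$ limit) but are skipped, with a message, in
the average-power interval where their ltdr weights vanish identically.

## Average power and sample size

The design criterion averages power over the identified set $T$,
weighting each SNP by its local true discovery rate — the posterior
probability of association given $z$ under the marginal mixture
$z \sim \pi_0 N(0,1) + \pi_1 N(0, 1 + \sigma_0^2/\sigma^2)$:
$$\bar\eta^{(2)} = \frac{\sum_{i\in T} \mathrm{ltdr}_i\,\eta_i^{(2)}}
{\sum_{i\in T} \mathrm{ltdr}_i}.$$
$T$ deliberately includes every significant SNP, false positives and
all: the ltdr weighting is what discounts them. The ltdr is computed
with the properly normalised non-null component density
$\phi(z/s)/s$, $s^2 = 1 + \sigma_0^2/\sigma^2$ — the form consistent
with Bayes' rule on the marginal mixture. Some published formulations
omit the $1/s$ factor; `ltdr(..., normalized = FALSE)` reproduces that
convention. With the $\sigma_0^2 = \infty$ sentinel the normalised
density collapses to zero everywhere, which would zero all weights, so
the sentinel case uses the unnormalised form's limit ($\phi(0)$ in the
numerator) in both modes.

`required_sample_size()` finds the smallest replication case count
(controls = ratio × cases, ratio defaulting to 1) whose ltdr-weighted
average predictive power reaches the target, by integer bisection —
power is monotone in the sample size because $\sigma^{(2)}$ scales as
$n^{-1/2}$. The per-SNP $\sigma^{(2)}$ is recomputed from the primary
counts at every candidate size, and the full power-vs-size curve is
returned for plotting.

## The simulator

`simulate_two_stage()` generates the data the experiments run on:
$m$ independent SNPs, effect-allele frequency $U(0.05, 0.5)$, and one of
three effect-size mixtures — $0.9\delta_0 + 0.1N(0, 0.04)$ (default),
$0.9\delta_0 + 0.1\,(0.2\,t_5)$ (heavy tails), or
$0.9\delta_0 + 0.07N(0,0.04) + 0.03N(0,0.16)$ (Gaussian mixture). The
default design is 1000 cases / 1000 controls in the primary study, 500 /
500 in the replication, disease prevalence 1 %, $\alpha_1 = 5\times
10^{-5}$, $\alpha_2 = 5\times 10^{-3}$ — a deliberately liberal primary
threshold so that a 10⁴-SNP scan yields a usable number of identified
SNPs.

Converting (frequency, log OR, prevalence) into case and control allele
frequencies needs a disease model, and the allele-level logistic model
$\operatorname{logit} P(D\mid \text{allele}) = c + \mu\,\mathbf 1[\text{effect}]$
is used, with $c$ solved in closed form so the allele-marginal
prevalence matches exactly. Its two exact identities — the expected
table's allele-based odds ratio equals $e^\mu$, and the
prevalence-weighted case/control frequencies return the population
frequency — are what the estimators assume, and both are unit-tested to
numerical precision. Allele counts are then binomial per group and
stage, independently across stages.

What the simulator does *not* emulate: linkage disequilibrium (SNPs are
independent), genotype-level sampling (counts are allele-based, so
Hardy-Weinberg structure never enters), covariates and population
stratification, and case-control ascertainment beyond the fixed group
sizes. Passing simulation checks therefore demonstrates correctness of
the statistical machinery under the model's own assumptions, not
robustness to correlated or stratified real data.

## Numerical choices

* Normal quantiles and tail probabilities via `qnorm`/`pnorm`; no
  approximations. The rejection boundary is strict
  ($|z| > z_{\alpha_1/2}$).
* The CMLE objective uses the two-sided conditional density (both tails
  in the denominator). Maximisation is bounded scalar optimisation on
  the standardised effect over sub-intervals of $[-2|z|, 2|z|]$ with
  restarts at $0, z/2, z$, because the conditional likelihood can be
  nearly flat between 0 and the threshold; near-ties resolve toward the
  sign of $z$. Every estimate is cross-checked against a dense grid
  search in the test suite.
* Zero table cells get the Haldane–Anscombe $+0.5$ correction on all
  four cells (on by default, with a warning; an error when disabled).
  With the simulator's frequency floor of 0.05 they are rare but
  possible.
* All stochastic functions accept an integer seed, restore the caller's
  RNG state, and are bit-reproducible for a fixed seed; draws inside a
  call come sequentially from one seeded stream.
* Experiment scale: the shipped studies use $m = 10^4$ SNPs, five runs
  for bias/RMSE tables, three runs with $N_1 = 50$, $N_2 = 100$ for the
  coverage study and five runs at the $N_1 = N_2 = 100$ defaults for the
  average-power study — sizes at which the reported contrasts are stable
  while a full suite completes in well under a minute of simulation
  time.

## Known limitations

The Gaussian non-null component is thin-tailed; the simulation study
shows the predictive power estimator remains the least biased and most
accurate under scaled-t and mixture alternatives, but the prior itself
is not re-fitted in those families. Independence across SNPs is assumed
throughout — with strong local LD the effective number of independent
statistics is smaller than $m$ and the bootstrap interval will be
somewhat anticonservative. The framework covers allele-based
case-control tests; quantitative-trait slope tests and covariate-adjusted
analyses are out of scope, as is any per-SNP (rather than average)
sample-size rule and multi-stage cost optimisation.
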