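---
title: "Point estimation after a two-stage group sequential trial: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point estimation after a two-stage group sequential trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grpseqest)
```

## The estimation problem

A two-stage group sequential trial analyses its accumulating data twice.
At the interim analysis the standardised test statistic $Z_1$ is compared
with a futility boundary $l$ and an efficacy boundary $u$: the trial stops
if $z_1 \le l$ or $z_1 \ge u$ and continues to a second, final analysis
otherwise. Early stopping is attractive — it saves patients and time — but
it distorts naive estimation: trials that stop early for efficacy tend to
have overshot, so the maximum likelihood estimator (MLE) of the effect
$\theta$ is biased, typically away from zero.

`grpseqest` works entirely on the *canonical joint distribution* scale:
$(Z_1, Z_2)$ bivariate normal with $E(Z_k) = \theta\sqrt{I_k}$ and
$\mathrm{Cov}(Z_1, Z_2) = \sqrt{I_1/I_2}$, where $I_k$ is the Fisher
information for $\theta$ at analysis $k$. This law holds, at least
approximately, for a very wide range of endpoint types — differences of
normal means, log hazard ratios tested by the log-rank statistic,
differences of proportions, crossover treatment contrasts — so a design is
fully described for estimation purposes by the tuple $(l, u, I_1, I_2)$
plus the powered effect $\delta$. The pair $(K, Z)$ — the terminal stage
and terminal statistic — is sufficient for $\theta$, and every estimator
in the package is a function of it alone.

## The sampling distribution

The stage-1 density is the $N(\theta\sqrt{I_1}, 1)$ density restricted to
the stopping region ($z \notin (l, u)$). The stage-2 density has the
closed form

$$f(2, z \mid \theta) = \phi(z - \theta\sqrt{I_2})\left[
  \Phi\!\left(\tfrac{u - z\sqrt{I_1/I_2}}{\sqrt{(I_2 - I_1)/I_2}}\right) -
  \Phi\!\left(\tfrac{l - z\sqrt{I_1/I_2}}{\sqrt{(I_2 - I_1)/I_2}}\right)
  \right],$$

i.e. the marginal normal density of $Z_2$ times a correction factor that
is *free of $\theta$*. The factor is the probability, under the
$\theta$-free conditional law $Z_1 \mid Z_2 = z \sim
N(z\sqrt{I_1/I_2},\ (I_2 - I_1)/I_2)$, that the trial continued. This
removes all integration from density evaluation; `gs_density()` is
validated in the test suite against the brute-force convolution integral
to well below $10^{-8}$. Stopping probabilities $s(k \mid \theta)$,
conditional densities, and the stage-wise-ordering exceedance probability
$P\{(K, Z) \succ (k, z)\}$ follow from it in `stop_probability()`,
`conditional_density()` and `exceedance_stagewise()`.

## The nine estimators

All estimators are functions $\hat\theta(k, z)$; `estimate_all()` returns
the full set for one outcome, with diagnostic flags.

* **MLE** $= z/\sqrt{I_k}$.
* **MAE1**: the fixed point $\hat\theta = \hat\theta_{MLE} -
  \mathrm{Bias}(\hat\theta_{MLE} \mid \hat\theta)$, using the analytic
  marginal bias
  $\mathrm{Bias}(\hat\theta_{MLE} \mid \theta) = \frac{I_2 - I_1}{I_2\sqrt{I_1}}
  \{\phi(u - \theta\sqrt{I_1}) - \phi(l - \theta\sqrt{I_1})\}$.
  (The prefactor was re-derived from first principles and is confirmed by
  the quadrature engine to $10^{-7}$ and by simulation.)
* **MAE2**: the one-step plug-in version, evaluating the bias at the MLE.
* **MUE**: the median unbiased estimator under the stage-wise ordering,
  $P\{(K, Z) \succ (k, z) \mid \hat\theta\} = 1/2$. For $k = 1$ this is
  exactly the MLE; for $k = 2$ a monotone root-find.
* **UMVUE**: the Rao–Blackwellisation $E(Z_1/\sqrt{I_1} \mid k, z)$ of
  the unbiased stage-1 estimator. For $k = 2$ it is the mean of the
  truncated ($\theta$-free) conditional law of $Z_1$, divided by
  $\sqrt{I_1}$ — a closed form. Marginally unbiased for every $\theta$
  (uniformly minimum variance among unbiased estimators that do not
  depend on what would have happened after the terminal analysis).
* **CMLE**: the maximiser of the likelihood conditional on the stopping
  stage. Equivalently, the solution of the *conditional* mean-adjustment
  fixed point $\hat\theta = \hat\theta_{MLE} -
  \mathrm{Bias}(\hat\theta_{MLE} \mid \hat\theta, k)$; both
  characterisations are verified against each other in the tests.
* **CWMAE**: a stage-1 shrinkage estimator; the MLE minus its conditional
  bias evaluated at $\theta^* = w\hat\theta_{MLE} + (1 - w)\theta_0$, with
  $w = (\hat\theta_{MLE} - \theta_0)^2 / \{(\hat\theta_{MLE} - \theta_0)^2
  + I_1^{-1}\}$ and $\theta_0$ a prior guess.
* **CMUE**: the conditional median, $\int_{-\infty}^{z}
  f_{cond}(k, x \mid \hat\theta)\,dx = 1/2$; for $k = 1$ the integral runs
  over the disconnected stopping region.
* **CUMVUE**: the Rao–Blackwellisation of the stage-2-increment estimator
  $(S_2 - S_1)/(I_2 - I_1)$; conditionally unbiased given continuation,
  closed form $\{z\sqrt{I_2} - I_1\hat\theta_{UMVUE}(2, z)\}/(I_2 - I_1)$.

### Conventions the proposals leave open

Three choices are not determined by the defining papers' proposals, and
the package fixes them explicitly:

* **Stage conventions.** The CWMAE defines no stage-2 estimate and the
  CUMVUE no stage-1 estimate. The package uses the MLE in both cases so
  that marginal performance can be reported, and attaches a
  `stage_convention` flag wherever the convention was used; other
  reasonable conventions exist, and marginal summaries of these two
  estimators should be read with that caveat.
* **CWMAE prior guess.** $\theta_0$ defaults to the powered effect
  $\delta$. For a design built for a *two-sided* alternative the trial was
  powered at $\pm\delta$, and shrinking a negative estimate towards
  $+\delta$ would be meaningless; the default is therefore sign-matched,
  $\theta_0 = \mathrm{sign}(\hat\theta_{MLE})\,\delta$, which also
  preserves the estimator's antisymmetry under symmetric boundaries (the
  rotational symmetry visible in the matched-pairs example). Any fixed
  $\theta_0$ can be supplied instead.
* **Boundary outcomes.** A stage-1 statistic exactly at $l$ or $u$ (a
  probability-zero event) is treated as stopped, on its own side of the
  continuation region; this matters only to the CMUE's disconnected
  stage-1 integral and is fixed for reproducibility.

## Performance evaluation

`evaluate_grid()` computes, for each estimator and each $\theta$ on a
grid, $\mathrm{Bias}(\hat\theta \mid \theta, k)$ and
$\mathrm{RMSE}(\hat\theta \mid \theta, k) = \mathrm{Var} +
\mathrm{Bias}^2$ conditional on each stopping stage, and the marginal
versions as the $s(k \mid \theta)$-weighted sums. Note the naming caveat:
**"RMSE" here is the residual mean square error** (variance plus squared
bias, i.e. the mean squared error), *not* its square root; the column
names reproduce the convention common in this literature.

The default grid is 81 equally spaced points on $[-2\delta, 2\delta]$ — a
deliberately wide survey range; a narrower range such as $[0, \delta]$ is
often more clinically relevant and can be requested via `theta_grid()`.

Because no estimator depends on $\theta$, estimator values are
precomputed once on shared quadrature nodes per stage and reused across
the whole grid; the root-finding estimators (MAE1, MUE, CMLE, CMUE) are
the cost centre, and this makes grid evaluation $O(\text{nodes} \times
\text{estimators} + \text{nodes} \times \text{grid})$.

Degenerate conditioning (stopping probability below $10^{-12}$, e.g.
stage 1 of a boundary-free design) yields `NA` conditional entries — the
row is reported as undefined rather than silently zero — and such stages
get zero weight in the marginal sums. Rows whose quadrature nodes
included any flagged estimator evaluation (e.g. a CMLE at its search
bound) carry a `truncated` flag: the numbers are finite but reflect the
clamped search.

## Numerical choices

* **Quadrature.** Composite Gauss–Legendre panels (64 nodes per panel,
  panel width at most 2) over the terminal-statistic support, truncated
  8.5 standard deviations beyond the range of terminal means and split at
  $l$ and $u$ so the disconnected stage-1 support is handled exactly. The
  integrands are smooth normal-mixture tails, so this comfortably beats
  the $10^{-10}$ absolute target; doubling the resolution changes no
  reported value by more than $10^{-8}$ (tested).
* **Truncated-region integrals.** Integrals over the continuation region
  (stage-2 joint probabilities, conditional CDFs) centre their window on
  the mode of the *truncated* stage-1 law, i.e. the point of $(l, u)$
  nearest $\theta\sqrt{I_1}$: during root-finding the continuation region
  can lie many standard deviations from the mean, where a window centred
  on the mean would miss all of the conditional mass.
* **Root-finding.** Brackets start at $\hat\theta_{MLE} \pm 10/\sqrt{I_1}$
  and double up to six times before a safeguarded `uniroot` at tolerance
  $10^{-12}$; defining-equation residuals are checked against $10^{-10}$.
  All defining functions are strictly monotone in $\theta$ (the stage-wise
  exceedance is increasing, conditional CDFs decreasing), so roots are
  unique. Bracket failure returns the best endpoint with a
  `hit_search_bound` flag rather than an error.
* **CMLE search.** The conditional likelihood is scanned on 81 points of
  $\hat\theta_{MLE} \pm 20/\sqrt{I_1}$, then the analytic conditional
  score is solved by `uniroot` between the best grid point's neighbours.
  Without an efficacy boundary the conditional bias of the CMLE is
  unbounded, and for terminal statistics deep in the tail the maximiser
  leaves any fixed window: the bound is then returned, flagged, keeping
  every evaluation finite while signalling the pathology. Multiple local
  maxima on the scan grid (not observed in the tested designs) would be
  flagged `multimodal`.
* **Tail-stable special functions.** Normal-CDF differences are computed
  on the log scale in the far tails, and the truncated-normal mean inside
  the UMVUE switches to scaled complementary (log-space, `expm1`) forms
  beyond 6 standard deviations, avoiding the catastrophic cancellation of
  the naive $\phi/\Phi$-difference ratio.
* **Tolerances are implementation choices.** No reference tolerances
  exist for these searches; the values above were fixed a priori from the
  smoothness of the defining functions.

## Design constructors

Five constructors reproduce standard boundary families; each returned
design is re-checked by quadrature against its requested error rates (to
$10^{-6}$ in the tests).

* `design_survival_spending()`: two-arm log-rank design with interim
  half-way through the events ($I_2 = 2I_1$, $I_k \approx d_k/4$), fixed
  futility bound $l = -0.674 \approx \Phi^{-1}(0.25)$ (a 25% chance of a
  futility stop under the null), efficacy bound from the Pocock-like
  spending function $f(t) = \alpha\ln\{1 + (e - 1)t\}$ at $t = 1/2$. The
  solve order is: $u$ from the stage-1 spend; the final critical value
  $c_2$ from the residual spend *with the futility bound binding* (both
  type-I integrals use the continuation region); then $I_1$ from the
  power requirement. This order reproduces the reference information
  levels: at one-sided $\alpha = 0.025$, power 0.9 at
  $\delta = -\log 0.8 \approx 0.223$ (a hazard ratio of 0.8), it yields
  $I_1 = 117.24$ with efficacy stopping and $I_1 = 105.54$ without,
  i.e. stage-1 event counts $d_1 = 4I_1$ of 469 and 423.
* `design_power_family()`: the one-sided two-boundary power family,
  bounds proportional to $(k/K)^{\Delta - 1/2}$ with the efficacy and
  futility boundaries meeting at the final analysis; the closure
  constraint $C_u + C_l = \delta\sqrt{I_2}$ reduces the problem to a
  two-dimensional Newton solve in $(C_u, C_l)$ with numerical Jacobian.
* `design_obrien_fleming()`: two-sided O'Brien–Fleming boundaries
  $C_B\sqrt{K/k}$ at equally spaced information; $C_B$ from the null
  crossing probability, then the maximal information from the power
  requirement (fixed-sample information
  $(z_{1-\alpha/2} + z_{1-\beta})^2/\delta^2$ inflated by the sequential
  design).
* `design_bernoulli()`: the arithmetic mapping of a Simon-type binomial
  futility rule to the canonical scale.
* `builtin_design()`: the five worked examples, including the single-arm
  normal-outcome minimax design ($n_1 = 92$, $n_2 = 139$, $l = 0$,
  $\sigma^2 = 1600$), which is stored as a fixture — the minimax *search*
  that produced it is out of scope here.

## Simulation: what it emulates and what it does not

`simulate_trials()` draws $(K, Z)$ by the independent-increment
construction — $Z_1 \sim N(\theta\sqrt{I_1}, 1)$, then on continuation a
score increment $X \sim N(\theta(I_2 - I_1), I_2 - I_1)$ gives $Z_2$ —
which realises the canonical covariance by construction and would extend
unchanged to more stages. It is the package's independent stochastic
oracle: stage frequencies, conditional statistic distributions
(Kolmogorov–Smirnov), and empirical bias/RMSE are compared against the
closed forms and quadrature in the tests, at batch size 200{,}000 with a
4-standard-error tolerance (large enough to make false alarms rare,
small enough to run in seconds).

The generator emulates the canonical *normal approximation only*. It does
not produce patient-level data, exact binomial outcomes, or small-sample
survival data; for small Bernoulli trials exact-binomial designs and
estimators are preferable, and for small time-to-event samples direct
simulation of study data is advisable. Passing tests therefore certify
the estimators under the canonical law — the law under which they are
defined — not the quality of that approximation for any particular
endpoint.

The property checks in the test suite use 41-point $\theta$ grids on
$[-2\delta, 2\delta]$ for the unbiasedness properties, spot outcomes for
the root-finding residuals, and one 200{,}000-trial batch for the
Monte-Carlo cross-check; these sizes were chosen to keep the whole suite
comfortably interactive while leaving the stochastic tolerances far above
the deterministic errors.

## Known limitations

* Exactly two stages; the closed forms (stage-2 density, UMVUE, CUMVUE)
  are specific to a single interim analysis.
* Point estimation only: no confidence intervals or p-values.
* The canonical normal approximation is assumed exact (see above).
* The CMLE (and less severely the CMUE) can behave arbitrarily badly
  without an efficacy boundary; the package reports rather than repairs
  this (flags, axis-clamp plotting option).
* Marginal summaries of the CWMAE and CUMVUE depend on the stage
  conventions described above.

## A worked example

```{r example}
d <- builtin_design("example2")   # single-arm phase II, futility-only
d
estimate_all(d, k = 2, z = 2.1)
evaluate_grid(d, estimators = c("MLE", "MAE2", "UMVUE"),
              grid = c(0, 5, 10))[, c("estimator", "theta", "bias_k1",
                                      "bias_k2", "bias_marginal")]
```
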