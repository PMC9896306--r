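# grpseqest

Point estimation after a two-stage group sequential trial.

## The problem

Group sequential trials analyse their data at an interim look and may stop
early — for futility (the stage-1 statistic falls at or below a boundary
`l`) or for efficacy (at or above `u`). Early stopping biases the ordinary
maximum likelihood estimate of the treatment effect: trials that stop
early for efficacy have typically overshot. Statisticians planning or
analysing such trials need (a) adjusted point estimators and (b) a way to
compare their conditional-on-stopping-stage and marginal bias and residual
mean square error, exactly, for the specific design at hand.

`grpseqest` provides both, for two-stage designs whose standardised
statistics follow the canonical joint distribution:

Z_1, Z_2 bivariate normal, E(Z_k) = θ√I_k, Cov(Z_1, Z_2) = √(I_1/I_2),

with continuation to stage 2 iff z_1 ∈ (l, u). The pair (K, Z) — terminal
stage and terminal statistic — is sufficient for θ, and the stage-2
density has the closed form

f(2, z | θ) = φ(z − θ√I_2) · [Φ{(u − z√(I_1/I_2))/v} − Φ{(l − z√(I_1/I_2))/v}],
v = √((I_2 − I_1)/I_2),

so all performance quantities are computed by fast deterministic
quadrature, with no simulation error.

Nine estimators are implemented: the MLE; two mean adjusted estimators
(fixed-point MAE1, plug-in MAE2) built on the analytic marginal MLE bias
(I_2 − I_1)/(I_2√I_1) · {φ(u − θ√I_1) − φ(l − θ√I_1)}; the stage-wise
median unbiased estimator (MUE); the Rao–Blackwell UMVUE; and four
conditional-on-stopping-stage counterparts (CMLE, CWMAE shrinkage, CMUE,
CUMVUE). Closed forms are used wherever they exist; the rest are monotone
one-dimensional root-finds.

## Worked example

A single-arm phase II trial with a normally distributed outcome
(σ² = 1600), futility-only stopping with l = 0, n₁ = 92, n₂ = 139,
powered at δ = 10 (10% mean tumour shrinkage). Suppose the trial went to
stage 2 and ended with z = 2.1:

```r
library(grpseqest)
d <- builtin_design("example2")
estimate_all(d, k = 2, z = 2.1)
#>   estimator estimate             flag
#> 1       MLE 7.124787
#> 2      MAE1 7.248967
#> 3      MAE2 7.255506
#> 4       MUE 7.125901
#> 5     UMVUE 7.137724
#> 6      CMLE 6.820139
#> 7     CWMAE 7.124787 stage_convention
#> 8      CMUE 6.919373
#> 9    CUMVUE 7.099463
```

The MLE estimates 7.12% shrinkage; the mean adjusted estimators push the
estimate *up* (≈7.25) because futility-only stopping biases the MLE
downwards marginally, while the conditional estimators (CMLE, CMUE),
which correct for the selection implied by *having continued*, pull it
down. The `stage_convention` flag records that the CWMAE has no stage-2
definition of its own and fell back to the MLE.

How do estimators compare across plausible effects? Exact bias, by stage
and marginally:

```r
evaluate_grid(d, estimators = c("MLE", "MAE2", "UMVUE"), grid = c(0, 5, 10))
#>   estimator theta      s1 bias_k1 bias_k2 bias_marginal rmse_marginal
#> 1       MLE     0 0.50000   -3.33  2.2023     -5.63e-01          14.5
#> 2       MLE     5 0.11527   -7.03  0.6066     -2.74e-01          14.5
#> 3       MLE    10 0.00824  -11.38  0.0626     -3.17e-02          12.1
#> 4      MAE2     0 0.50000   -2.93  2.6387     -1.45e-01          14.4
#> 5      MAE2     5 0.11527   -6.56  0.8625      7.35e-03          13.3
#> 6      MAE2    10 0.00824  -10.87  0.1370      4.63e-02          11.5
#> 7     UMVUE     0 0.50000   -3.33  3.3274      6.66e-16          15.6
#> 8     UMVUE     5 0.11527   -7.03  0.9165      2.78e-15          13.0
#> 9     UMVUE    10 0.00824  -11.38  0.0946      4.59e-15          11.7
```

(columns abridged). The UMVUE is exactly marginally unbiased but pays for
it conditionally on stage 2; MAE2 roughly halves the MLE's marginal bias
without giving up conditional performance. "RMSE" columns follow the
field's convention of reporting the residual mean square error
(variance + bias², i.e. the MSE), not its square root.

The same works from a shell:

```sh
./exec/grpseqest estimate --design example2 --k 2 --z 2.1
./exec/grpseqest evaluate --design example5 --theta-points 81 --out perf.csv
./exec/grpseqest design --family obrien-fleming --alpha 0.05 --beta 0.1 \
    --delta 1 --variance 6 --out design.json
./exec/grpseqest simulate --design example3 --theta 10 --n 10000 --seed 1
```

Design constructors rebuild the five reference designs from their error
rates: error-spending survival (`design_survival_spending`), power-family
crossover (`design_power_family`), two-sided O'Brien–Fleming matched
pairs (`design_obrien_fleming`), Simon-type Bernoulli mapping
(`design_bernoulli`), plus `builtin_design()` shortcuts. A Monte-Carlo
simulator (`simulate_trials`, `empirical_performance`) provides an
independent stochastic cross-check of every exact computation.

See the vignette (`vignettes/estimation-after-early-stopping.Rmd`) for
the full model description, estimator conventions, and numerical choices.

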