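# diffplm

Difference-based estimation for partially linear models with dependent
errors.

## The problem

A partially linear model combines a linear regression term with an unknown
smooth trend:

    y_i = x_i' beta + f(t_i) + e_i,    0 <= t_1 <= ... <= t_n <= 1,

where `beta` is the parameter of scientific interest, `f` is a nuisance
curve, and the errors `e_i` may be *dependent* — specifically, negatively
superadditive dependent (NSD), a negative-dependence class that arises
naturally when totals are constrained (e.g. counts conditioned on a fixed
sum). This situation is common in epidemiological and biostatistical
regressions where a smooth time or dose effect must be removed before the
covariate effect can be judged, and where the sampling scheme induces
negative correlation between observations.

`diffplm` implements:

* **DOLS** (difference-based ordinary least squares) for `beta`: a
  difference sequence `d_0, ..., d_m` with `sum(d_q) = 0` and
  `sum(d_q^2) = 1` is slid along the data, annihilating the smooth `f`,
  and OLS is run on the differenced model `Y~ = X~ beta + e~`, giving
  `beta_hat = (X~'X~)^{-1} X~'Y~`. Closed-form (iid) and HAC-type
  residual plug-in estimators of the limiting covariance `tau_beta^2` are
  provided, together with the standardized statistic
  `M = (n-m)^{-1/2} tau_beta^{-1} Sigma_n (beta_hat - beta_0)`, which is
  asymptotically standard normal.
* A **wavelet reproducing-kernel smoother** for `f`: with a Daubechies
  scaling function `phi` and resolution level `m~`, the kernel
  `E(t,s) = 2^{m~} sum_k phi(2^{m~}t - k) phi(2^{m~}s - k)` yields
  `f_hat(t) = sum_i (y_i - x_i' beta_hat) * integral of E(t,s) over A_i`,
  a weighted average of parametric residuals over a partition `A_i` of
  `[0,1]`, with the pointwise standardizer `tau_t^2 = w' Cov(e) w`.
* An **exact NSD error simulator**: iid draws from a base pmf conditioned
  on their sum, sampled exactly by dynamic programming (no rejection), with
  exact conditional moments.
* A **Monte-Carlo asymptotics lab** (`run_beta_study()`, `run_f_study()`,
  `check_moment_inequality()`) producing ECDF/QQ/Kolmogorov–Smirnov
  diagnostics of the normal approximations and checking Rosenthal-type
  maximal moment bounds for NSD partial sums.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods on all fitted objects, plus a small CLI
(`inst/cli/diffplm`) for shell use.

## Worked example

```r
library(diffplm)

# simulate the reference design: t_i = i/n, x = cos(2*pi*t),
# f = sin(2*pi*t), beta = 5, centered NSD errors conditioned on their sum
d <- simulate_plm(128, beta = 5, seed = 1)
fit <- dols(d, m = 3)
tidy(fit)
#> # A tibble: 1 × 4
#>   term  estimate std.error statistic
#>   <chr>    <dbl>     <dbl>     <dbl>
#> 1 x1        5.05     0.606      8.33

sm <- smooth_plm(d, fit, kernel = repro_kernel("daubechies-2", 3))
dplyr::filter(sm$estimate, t %in% c(0.25, 0.5, 0.75))
#> # A tibble: 3 × 4
#>       t  f_hat weight_sum boundary
#>   <dbl>  <dbl>      <dbl> <lgl>
#> 1  0.25  1.74       1.000 FALSE
#> 2  0.5  -0.274      1.000 FALSE
#> 3  0.75 -1.73       1.000 FALSE

glance(run_beta_study(n = 128, reps = 1000, seed = 1))
#> # A tibble: 1 × 7
#>   statistic     n  reps sample_mean sample_var ks_stat dropped
#>   <chr>     <dbl> <dbl>       <dbl>      <dbl>   <dbl>   <int>
#> 1 M_beta      128  1000      0.0127      0.966  0.0363       0
```

The `tidy()` row says the differenced least-squares estimate of the
covariate effect is 5.05 with a HAC plug-in standard error of 0.61 — the
true value is 5. The smoother recovers the sine trend (`sin(2*pi*0.25)=1`,
`sin(2*pi*0.75)=-1`; the remaining gap is the coarse-resolution projection
bias), and `weight_sum` near 1 confirms the evaluation points are away from
the boundary. The study report shows the standardized statistic
`M_beta` over 1000 replications has mean near 0, variance near 1 and a
Kolmogorov–Smirnov distance of 0.036 from N(0,1): the normal approximation
is already accurate at n = 128 despite the dependent errors.

`autoplot()` on a study report draws the ECDF-versus-normal comparison and
the QQ-plot; on a smooth fit, the estimated curve.

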