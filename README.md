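# gwnr

Geographically weighted nonparametric regression with a mixed
truncated-spline + Fourier basis, and the F test that decides whether
location-varying coefficients are worth having.

## The problem

Regression on spatial units (districts, monitoring sites, plots) faces two
separate sources of model failure at once:

* **Nonlinearity.** Predictors often relate to the response through unknown
  smooth or periodic shapes rather than straight lines.
* **Spatial nonstationarity.** The relationship itself may drift over the
  study area, so one global coefficient vector misdescribes every location.

Geographically weighted regression (GWR) addresses the second problem;
nonparametric regression the first. This package implements their
combination — **geographically weighted nonparametric regression (GWNR)** —
and, crucially, the goodness-of-fit test that tells you whether the extra
flexibility of geographic weighting is statistically justified against the
global **mixed nonparametric regression (MNR)** fitted with the identical
basis. The audience is applied spatial statisticians and epidemiologists /
regional scientists modelling area-level outcomes.

## The model and the test

Each spline-role predictor `x` enters through a truncated power basis of
degree M with R knots, `x, …, x^M, (x − t_1)_+^M, …, (x − t_R)_+^M`; each
Fourier-role predictor `z` enters through `θ0/2 + γ z + Σ_h θ_h cos(h z)`.
Stacking the blocks gives one design matrix `Q*` of width
`m = 2 + P(M+R) + Q(1+H)` shared by both models. At location `(u_i, v_i)`
the GWNR coefficients are weighted least squares,

    η̂(u_i, v_i) = (Q*' W_i Q*)^{-1} Q*' W_i y,

with `W_i` a diagonal spatial kernel (gaussian, bisquare or tricube; fixed
or adaptive bandwidth, optionally chosen by leave-one-out CV). Collecting
the rows `q_i'(Q*' W_i Q*)^{-1} Q*' W_i` yields the hat matrix `G`, with
residual sum of squares `SSE_GWNR = y'(I−G)'(I−G)y` and the unbiased
variance estimate `σ̂² = SSE_GWNR / γ1`, `γ1 = tr((I−G)'(I−G))`.

Because `(I−G)'(I−G)` is not idempotent, `SSE_GWNR/σ²` is only
approximately chi-square: matching its mean `γ1` and variance `2γ2`
(`γ2 = tr(((I−G)'(I−G))²)`) gives the Satterthwaite approximation
`c χ²_r` with `c = γ2/γ1`, `r = γ1²/γ2`. The same device applied to the
improvement `SSE_MNR − SSE_GWNR` (traces `τ1, τ2` of
`(I−L) − (I−G)'(I−G)`, `L` the MNR hat matrix) yields the test statistic

    F1* = [ y'((I−L) − (I−G)'(I−G)) y / τ1 ] / [ y'(I−G)'(I−G) y / γ1 ]

referred to an F distribution with non-integer degrees of freedom
`df1 = τ1²/τ2` and `df2 = γ1²/γ2`; reject the global model when
`F1* > F(α; df1, df2)`.

## Worked example

```r
library(gwnr)
sim <- gwnr_sim(n = 60, mode = "varying", amplitude = 2, seed = 7)
fit <- gwnr(y ~ sp(x1) + fr(z1), sim$data, coords = ~ u + v, bandwidth = 3)
gwnr_test(fit)
```

```
Goodness-of-fit test: geographically weighted vs global mixed model

  SSE (global MNR):  282.183
  SSE (GWNR):        92.0953
  F* = 6.6303 on df1 = 21.48, df2 = 47.78
  critical value F(0.05; 21.48, 47.78) = 1.7752,  p-value = 2.948e-08
  H0 rejected: location-varying coefficients fit significantly better.
```

The synthetic scenario has coefficients that drift smoothly over the map
(`amplitude = 2`), so the local fits cut the error sum of squares from
282.2 to 92.1; normalized by the trace degrees of freedom this gives
F\* = 6.63, far beyond the 5% critical value 1.78 — the test correctly
prefers the geographically weighted model. `summary(fit)` shows the spread
of each local coefficient across locations (e.g. the truncated-spline term
ranging from −4.33 to −0.09 around the global value −2.64), `coef(fit)`
returns the full n × m local coefficient matrix, and `plot(fit, coef = 2)`
maps a coefficient over the study area. On a null dataset
(`mode = "constant"`) the same pipeline retains the global model.

Everything is also reachable from a shell via the thin wrapper
`inst/cli/gwnr.R` (`fit`, `test`, `simulate`, `mc` subcommands driven by
YAML configs) or programmatically via `run_fit()` / `run_test()` /
`run_simulate()` / `run_mc()`.

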