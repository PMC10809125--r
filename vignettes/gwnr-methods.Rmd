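---
title: "Methods: geographically weighted nonparametric regression and its fit test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographically weighted nonparametric regression and its fit test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

For spatial units $i = 1, \dots, n$ at planar coordinates $(u_i, v_i)$ the
response is modelled as a sum of unknown smooth functions of the
predictors,
$$y_i = \sum_p f_p(x_{pi}) + \sum_q g_q(z_{qi}) + \varepsilon_i,
\qquad \varepsilon_i \overset{iid}{\sim} N(0, \sigma^2),$$
with each $f_p$ represented by a truncated power spline of degree $M$ with
knots $t_{p1} < \dots < t_{pR}$,
$$f_p(x) = \sum_{j=1}^{M}\beta_{pj}x^j + \sum_{r=1}^{R}\beta_{p,M+r}(x - t_{pr})_+^M,$$
and each $g_q$ by a Fourier series with $H$ cosine harmonics,
$$g_q(z) = \tfrac{1}{2}\theta_{q0} + \gamma_q z + \sum_{h=1}^{H}\theta_{qh}\cos(hz).$$
Stacked into one design matrix $Q^*$ of width
$m = 2 + P(M+R) + Q(1+H)$ (a shared intercept column, the spline blocks, a
half-constant column carrying the Fourier constants, the Fourier blocks),
this gives two nested estimators:

* **MNR** (mixed nonparametric regression): one global coefficient vector
  by ordinary least squares; hat matrix $L$, a symmetric idempotent
  projection.
* **GWNR**: the full coefficient vector re-estimated at every location by
  weighted least squares,
  $\hat\eta(u_i,v_i) = (Q^{*\top}W_iQ^*)^{-1}Q^{*\top}W_iy$, with spatial
  kernel weights $W_i$; stacking the rows
  $q_i^\top(Q^{*\top}W_iQ^*)^{-1}Q^{*\top}W_i$ gives the hat matrix $G$,
  which is neither symmetric nor idempotent.

The local estimator is weighted least squares; under the Normal error
assumption it coincides with the weighted maximum-likelihood estimator, so
nothing is lost by implementing it as WLS.

## The intercept aliasing and how it is resolved

The canonical column layout contains an all-ones intercept *and* the
all-$\tfrac12$ column of the Fourier constant, which are exactly
collinear: $Q^*$ always has rank $m - 1$. Only the combined constant
$\beta_0 + \theta_0/2$ is identified. All fits therefore solve the reduced
full-rank system with the half-constant column removed and split the
estimated constant $b$ back as $\beta_0 = 0.8b$, $\theta_0 = 0.4b$ — the
minimum-norm solution of $\beta_0 + \theta_0/2 = b$. This choice is purely
presentational: fitted values, both hat matrices, all sums of squares, the
trace quantities and the F test depend only on the column span and are
invariant to the split. The effective parameter count of the global model
is $\mathrm{tr}(L) = m - 1$, and `summary()` reports inference on the
identified (reduced) parameterization. Rank deficiency *beyond* this
structural aliasing — e.g. a knot placed outside the data range producing
a zero column — is a hard error naming the dependent columns, never a
silent pseudo-inverse, so reported SSEs are always reproducible.

## The goodness-of-fit test

The hypotheses are $H_0$: every basis coefficient is constant over space
(MNR suffices) against $H_1$: at least one coefficient varies with
location. With $A = (I-G)^\top(I-G)$ and $B = (I-L) - A$ the statistic is
$$F_1^* = \frac{y^\top B y / \tau_1}{y^\top A y / \gamma_1},
\qquad \gamma_i = \mathrm{tr}(A^i),\ \tau_i = \mathrm{tr}(B^i),$$
referred to $F(df_1, df_2)$ with $df_1 = \tau_1^2/\tau_2$ and
$df_2 = \gamma_1^2/\gamma_2$. The rationale is Satterthwaite's
moment-matching: $y^\top A y/\sigma^2$ has mean $\gamma_1$ and variance
$2\gamma_2$ (a sum $\sum_i \lambda_i\zeta_i^2$ over the eigenvalues of
$A$), so it is approximated by $c\chi^2_r$ with $c = \gamma_2/\gamma_1$,
$r = \gamma_1^2/\gamma_2$; for an idempotent quadratic form this recovers
the exact chi-square, which is why under uniform weights ($G \to L$) the
machinery collapses to the classical nested-model limit,
$\gamma_1 = n - \mathrm{tr}(L)$ and $(c, r) = (1, n - \mathrm{tr}(L))$.
Because $L$ is a projection, $y^\top B y = SSE_{MNR} - SSE_{GWNR}$; the
implementation computes both forms and asserts their agreement at run time
rather than assuming it. `sse_chi2_check()` exposes the approximation
quality directly as a KS distance between the simulated eigenvalue mixture
and the fitted $c\chi^2_r$.

Two degeneracies are surfaced as classed errors rather than NaNs:
$\tau_1 \le 0$ (the local fits do not improve on the global fit — the
uniform-weight limit, or an over-smoothed bandwidth), and
$SSE_{GWNR} = 0$ (saturated local fits). The Monte-Carlo harness counts
such replicates separately instead of dropping them. A p-value is reported
alongside the critical-value decision; the two are coherent by
construction ($F_1^* > F_{\alpha} \iff p < \alpha$). The boundary
$\alpha = 1$ is accepted, giving critical value 0 so that every
non-degenerate replicate rejects. The hypothesis is interpreted over all
$m$ basis coefficients jointly; per-coefficient stationarity tests are out
of scope.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| spline degree $M$ | 1 | piecewise-linear fits are the workhorse in the applications this method targets; higher degrees supported |
| knots per predictor $R$ | 1, at the median | no selection rule is established for this model class; equispaced-quantile placement keeps knots strictly inside the data and is overridable by explicit locations |
| harmonics $H$ | 1 | one cosine captures a single periodic mode; raw-scale angles (radians) by default, with an opt-in rescale of the predictor range to $[0, 2\pi]$ |
| kernel | gaussian | strictly positive weights avoid the zero-weight local singularities that compact kernels (bisquare, tricube; also provided) produce at small $n$ |
| bandwidth | LOO-CV over a 10-point grid | cross-validation with the self-weight forced to zero is the geographically-weighted convention; fixed and adaptive (k-nearest) bandwidths can be given directly |
| metric | euclidean | planar coordinates; haversine (great-circle km, sphere radius 6371 km) for lon/lat |
| $\alpha$ | 0.05 | conventional |

## The synthetic-data generator

`gwnr_sim()` draws $n$ locations (uniform on $[0,10]^2$, or a grid), one
spline predictor $x_1 \sim U(0,4)$ with true knot at 2, one Fourier
predictor $z_1 \sim U(0, 2\pi)$ (counts and hyperparameters configurable),
builds the mean from the same basis family with base coefficients
$(\beta_0, \beta_{11}, \beta_{12}, \theta_0, \gamma_1, \theta_{11}) =
(1, 1.5, -2, 1, 0.5, 2)$, and adds $N(0, \sigma^2)$ noise with
$\sigma = 1$. Under the alternative, every coefficient is modulated
multiplicatively by the smooth surface
$a\, s_j(\tilde u + \tilde v + \tilde u\tilde v)/3$ with alternating signs
$s_j$ and scaled coordinates $\tilde u, \tilde v \in [-1,1]$ — the
simplest smooth nonstationarity with both trend and interaction. Because
the generating mean lies exactly in the fitted basis span when the true
knots are supplied, the null calibration experiments are exact: the
identity $E(SSE_{GWNR}) = \sigma^2\gamma_1$ holds by construction and is
verified by simulation rather than assumed.

What the generator does **not** emulate: spatially correlated or
non-Gaussian errors (the test's distribution theory assumes i.i.d.
Normal), predictor collinearity, irregular strongly clustered spatial
layouts, and basis misspecification (real analyses never know the true
knot). Passing tests therefore certify the estimator and test machinery
under the model's own assumptions, not robustness to their violation.

The Monte-Carlo harness `mc_rejection_rate()` seeds replicate $r$ with
`seed + r`, so results are order-independent; its default bandwidth is
half the median pairwise distance, a fixed locality heuristic that keeps
roughly a quarter of the study area inside one bandwidth at the default
layout. Rates are reported over non-degenerate replicates with degenerate
counts alongside; more than 20% degenerate replicates aborts the scenario.

## Numerical choices

* Linear solves go through rank-revealing QR with relative tolerance
  `1e-10`; local systems additionally require reciprocal condition number
  above `1e-10`, otherwise a local-singularity error names the location
  and suggests a larger bandwidth.
* Trace quantities are computed from the symmetric products
  ($\gamma_1 = \sum A_{ij}^2$ form), never from the expanded
  $n - 2\mathrm{tr}(G) + \mathrm{tr}(G^\top G)$ arithmetic; eigenvalue
  decompositions appear only as independent oracles in the test suite.
* `tau_traces()` validates that $L$ is symmetric idempotent (tolerance
  `1e-8`) before using the form $(I-L) - A$, which presumes a projection.
* Hat matrices are materialized densely; the implementation targets
  $n$ up to a few thousand.
* CV ties are broken toward the larger bandwidth (smoother fit); knots at
  duplicated quantiles are an error asking for explicit locations.
* Reports serialize numbers at 10 significant digits so identical configs
  give byte-identical JSON.

## Problem sizes used in the checks

The test suite exercises basis and trace oracles at $n = 6$–$81$,
fitting equivalences at $n = 10$–$60$, and the simulation studies at
$n = 60$ with 400–500 replicates (size, power, unbiasedness) — sizes at
which every quantity is also verifiable against brute-force oracles. The
acceptance script uses the same scales.

## Known limitations

* The F approximation treats the numerator and denominator quadratic
  forms as independent; they are positively correlated, and the
  Monte-Carlo exercises in the test suite show the resulting test errs on
  the conservative side at these desk scales (empirical size below the
  nominal level, never above it). Users should read a rejection as
  strong evidence, and a marginal retention as potentially
  power-limited.
* No prediction at unobserved locations: the local coefficient field is
  defined only at the fitted sites; `predict()` on new locations is
  refused rather than silently interpolated.
* Bandwidth and knot/harmonic counts are chosen by the analyst (or CV for
  the bandwidth); no joint model-selection criterion is provided.
* Sine terms, interaction bases and B-spline reparameterizations are out
  of scope, as are robust/heteroscedastic weighting and non-Gaussian
  responses.
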