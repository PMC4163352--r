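---
title: "Smoothing-based one-step-ahead forecasting: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing-based one-step-ahead forecasting: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hankelcast)
```

`hankelcast` implements a two-stage scheme for one-step-ahead forecasting
of positive, regularly sampled surveillance series such as weekly
traffic-injury counts: smooth first, then regress the next observation on
lagged smoothed values. This vignette records the models, the numerical
choices, and — importantly — what the evaluation design does and does not
establish.

## Stage 1: smoothing

**3-point moving average.** Interior points are replaced by the centred
mean of themselves and their two neighbours; the endpoints are copied.
Affine series are fixed points, so the filter removes high-frequency
fluctuation without distorting a locally linear trend.

**HSVD.** The series is embedded in its Hankel trajectory matrix
$H_{ij} = x_{i+j-1}$ with $M$ rows and $L = n - M + 1$ columns. From the
SVD $H = USV^\top$, each singular value yields a rank-one matrix
$A_i = s_i u_i v_i^\top$, and the component series $C_i$ (length $n$) is
read off the first row of $A_i$ followed by rows $2..M$ of its last
column. Since $\sum_i A_i = H$ exactly and the read-off is linear,
$\sum_i C_i = x$ to machine precision — a property the test suite asserts
over hundreds of random series. $C_L = C_1$ carries the long-term trend;
$C_H = \sum_{i \ge 2} C_i$ the high-frequency fluctuation. Energies
$E_i = s_i^2 / \sum_j s_j^2$ report each component's share and sum to one
whenever the series is not identically zero (the all-zero series is
flagged degenerate rather than erroring).

Two numerical conventions: the trajectory matrix uses $L = n - M + 1$, the
only column count under which the embedding covers all $n$ observations
and reconstruction is exact (a truncated $L = n - M - 1$ variant circulates
but is inconsistent with length-$n$ components); and each left singular
vector is sign-fixed so its largest-magnitude entry is positive —
$A_i$ and $C_i$ are invariant to this, it only stabilises intermediate
comparisons. Singular-value ties keep the stable descending order returned
by the decomposition. The default $M = 2$ keeps one trend and one
fluctuation component; energy is reported, not used to select $M$.

## Stage 2: forecasters

Both forecasters consume a regressor set: for moving-average smoothing,
row $z(t) = (\tilde s_{t-1}, \dots, \tilde s_{t-K})$ with $K = P$; for
HSVD, $P$ lags of each component, $K = 2P$ (the default `"both"` mode).
An alternative `"shared"` mode uses $P$ lags of the reconstruction
$C_L + C_H$, for the reading of the HSVD network as having the same input
width as the moving-average one; we default to the literal two-component
form because it is the one the regressor definition states. Targets are
always the *original* (scaled) observations, not smoothed values. The
split is chronological at the regressor-row level — first 85% of rows
train, the rest test — which for a 531-point series and $K = 9$ gives
522 usable rows, 443 train and 79 test.

**Scaling.** Reported error magnitudes of order $10^{-3}$ on integer
count data only make sense on a normalised series, so the pipeline
min-max scales to $[0,1]$ using extremes of the *training portion* of the
raw series; test values may legitimately fall outside $[0,1]$ (no
clipping). Metrics are reported on this scale by default.

**Linear model with MA errors.** $\hat x_t = \sum_i \alpha_i z_i(t) +
\sum_{i=1}^{Q} \beta_i e_{t-i}$. This is not a textbook ARIMA — the
autoregressive structure acts on the smoothed regressor vector — so it is
estimated as a regression with MA($Q$) errors by conditional sum of
squares: pre-sample errors set to zero, $\alpha$ initialised by OLS and
$\beta$ at zero, then jointly minimised by BFGS (tolerance $10^{-8}$, 500
iterations, deterministic initialisation, so fits are bit-for-bit
reproducible). Exact-likelihood estimation via a state-space form was the
open alternative; CSS was chosen because the model's regressor part is
nonstandard and CSS extends to it directly. With $Q = 0$ the fit *is*
OLS, which the tests exploit as an oracle. Rank-deficient designs fall
back to the pseudo-inverse with a warning — this genuinely occurs with
HSVD regressors (see below). Differencing (order $D$) is available and
applied to the working series before smoothing; $D = 0$ throughout the
reference protocol.

**Test-time recursion.** How the MA error history continues past the
training boundary is undefined in one-step protocols unless stated; we
teacher-force: the history starts from the training residuals and is
extended with *observed* test errors as forecasting proceeds. Forecasts
are therefore order-dependent exactly when $Q > 0$, which the tests
assert both ways.

**Neural network.** ANN($K, Q, 1$): $\hat x = \sum_j v_j\,
f(\sum_i w_{ji} z_i)$ with logistic $f$; no bias units, so the parameter
count is $D = KQ + Q$ (this matches the swarm dimension convention; a
biased network would have a different $D$). Two trainers:

- **PSO**: $N_p$ particles in $\mathbb R^D$, velocity
  $V \leftarrow I_l V + c_1 r_1 (p_{best} - X) + c_2 r_2 (g_{best} - X)$
  with per-dimension uniform $r \in [0,1]$ and inertia decreasing
  linearly from $I_{max}$ to $I_{min}$. A published variant prints the
  attraction terms with $+X$; that form diverges and is treated as a
  typographical slip for the canonical $-X$. Hyperparameters are rarely
  reported in application papers; we fix $N_p = 30$, $c_1 = c_2 = 2$,
  $I_{max} = 0.9$, $I_{min} = 0.4$, 2500 iterations, positions initialised
  uniformly in $[-1, 1]$ and reflected at those bounds (velocity component
  negated), velocities initialised in $[-0.5, 0.5]$. Fitness is training
  RMSE; the global-best trace is non-increasing by construction.
- **RPROP**: batch, on the exact analytic gradient (verified against
  central finite differences). Per-weight steps multiply by
  $\eta^+ = 1.2$ on consistent gradient sign and by $\eta^- = 0.5$ on a
  sign flip, with the stored gradient zeroed so the succeeding step
  adapts nothing; steps clipped to $[10^{-6}, 50]$, initial step $0.1$,
  100 epochs, weights initialised uniformly in $[-0.5, 0.5]$. These are
  the standard published defaults.

Both trainers are seed-deterministic. Stochastic fits repeat `runs`
times (default 30) with seeds `seed_base + offset + run`, and the run
with the best *training* fitness is kept — test metrics are reported for
that single run, mirroring the usual best-of-runs protocol.

## Evaluation

Metrics on the $N_v$ test points: RMSE; GCV $= RMSE / (1 - K/N_v)^2$,
which penalises regressor width against test size; MAPE; per-point
relative errors and their sum. Relative-error band counts (e.g. the share
of points within $\pm 1.5\%$) use the *inclusive* inequality. Residual
whiteness uses the biased (divide-by-$N$) autocorrelation estimator with
$\pm 1.96/\sqrt N$ bands — the pairing under which the bands are the
correct 95% limits. Note that "all 20 lags inside" is itself a stringent
event ($\approx 0.95^{20} \approx 0.36$ under true whiteness), so the
`white` flag is a diagnostic label, not a calibrated test.

Pairwise comparison uses Pitman's test: $\Upsilon = e_1 + e_2$,
$\Psi = e_1 - e_2$, and since $\mathrm{cov}(\Upsilon, \Psi) =
\mathrm{var}(e_1) - \mathrm{var}(e_2)$, a correlation beyond
$1.96/\sqrt{N_v}$ rejects equal accuracy (negative ⇒ model 1 better).
The $\sqrt{N_v}$ is deliberate: the rule is sometimes misprinted as
$1.96/N_v$, but the standard critical value at $N_v = 78$ is
$1.96/\sqrt{78} = 0.2219$. Identical error vectors make $\Psi$
degenerate; this is flagged, not thrown. Null calibration (rejection rate
$5\% \pm 1.5\%$ at $N_v = 78$ over 2000 replicates) and exact
antisymmetry under model swap are asserted in the acceptance suite.

**Lag-order selection.** The MA order $Q$ may be chosen by a GCV scan.
The scan fits each candidate on the earlier 85% of the *training* rows
and scores on the remaining training tail (the test set is never
touched). One wrinkle: the GCV formula penalises the regressor width $K$,
which is constant along a $Q$ scan — verbatim use would reduce the scan
to holdout RMSE. The scan therefore penalises the fitted parameter count
$K + Q$; reported metrics still use the standard width-$K$ formula. Ties
break toward the smaller $Q$.

## The synthetic generator: what it emulates, what it does not

The reference data — 531 weekly counts of people injured in traffic
accidents in a Chilean region over a decade — is not publicly deposited,
so the package generates a stand-in:
$$x_t = base + trend\ g(t/n) + seas \cdot \sin(2\pi t/52) + \varepsilon_t,$$
with $g$ the smoothstep ramp $u^2(3-2u)$ and Gaussian
$\varepsilon$. Defaults $base = 50$, $trend = 15$, $seas = 8$,
$sd = 4$ give a weekly count level, a slow monotone drift of the size a
decade of exposure change produces, a mild annual cycle, and
week-to-week noise of roughly $\sqrt{base}$ — the magnitudes a
count-surveillance analyst would call realistic. Validation requires the
deterministic floor minus $5\sigma$ to stay positive, so series are
strictly positive (MAPE well defined) without clipping. A Poisson-noise
option exists for count realism; Gaussian is the default because the
pipeline treats values as reals. An ARMA generator with a stationarity
check provides the parameter-recovery oracle for the CSS fitter.

What a green test on this generator does **not** establish: performance
on real surveillance data with calendar effects, reporting artifacts,
regime changes, or overdispersion; none of these are simulated.

## The HSVD look-ahead property (read before citing accuracy numbers)

With $M = 2$, the rank-one structure of $A_1, A_2$ ties consecutive
columns of $H$ together: row 2 of $H$ is $x_{t+1}$, and each $A_i$
contributes a multiple of the same right-singular direction to both rows,
so $x_{t+1}$ is an **exact** linear combination of $C_L(t)$ and $C_H(t)$
for all but the final column. A linear forecaster on HSVD regressors
computed over the *full* series can therefore achieve near-machine-zero
one-step error — our experiments reproduce exactly this (RMSE
$\sim 10^{-16}$), and it explains how HSVD-ARIMA variants can report
MAPEs orders of magnitude below every competitor. It is a property of
decomposing the whole series (future observations shape the components at
past time points), not of genuine forecasting skill. The package
implements the protocol faithfully and surfaces the consequence; a
leakage-free variant (re-decomposing on data up to $t-1$ for every $t$)
is out of scope. The qualitative ranking — HSVD-based models beating
their moving-average counterparts, linear-with-MA-errors beating the
networks at this sample size — is robust across seeds and is what the
acceptance suite asserts.

## Degenerate inputs and numerical conventions

Constant series cannot be min-max scaled (error); all-zero series
decompose to zero components with energies flagged undefined; zero
observed values make MAPE/RE undefined and error with the offending
indices; identical forecast-error vectors give a flagged degenerate
Pitman result. CSS optimisation uses `reltol = 1e-8`, `maxit = 500`;
PSO/RPROP seeds derive from `seed_base` and stay below $2^{31}$.

## Known limitations

Single-channel series only; no diagonal-averaging (Hankelisation)
variant of component reconstruction; no automatic $M$ selection; no
multi-step forecasting; no exact-likelihood ARMA estimation; no
validation-based early stopping for the networks; runs are sequential.
The PSO hyperparameters of the reference experiments are unknown, so
network results are comparable in protocol but not numerically
reproducible even in principle.
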