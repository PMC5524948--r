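---
title: "Forecasting glucose dynamics from their chaotic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting glucose dynamics from their chaotic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucodyn)
```

## The problem and the modelling premise

Continuous glucose monitoring (CGM) sensors report subcutaneous glucose
every five minutes for days at a time.  Forecasting those readings 30 or
60 minutes ahead gives a person with type 1 diabetes time to act before a
hypo- or hyper-glycemic episode rather than after it.  The approach taken
here is deliberately *input-free*: no meal diary, insulin log, or activity
tracker — only the glucose trace itself.  The premise is that glucose
dynamics contain a low-dimensional deterministic, weakly chaotic
component, so that the recent history of the series, unfolded into a
phase space, carries usable information about its short-term future.

The workflow is: characterise each series' nonlinear structure; embed it
in phase space; fit a regime-switching autoregressive predictor to a
sliding training window; iterate one-step predictions out to the horizon;
and score the result both numerically (RMSE/MAE/MAPE) and clinically
(continuous glucose error-grid analysis, CG-EGA).  Alongside, the package
reports the standard glycemic-variability and risk indices per landmark
interval of the day.

## Phase-space reconstruction

A scalar series $\{x_t\}$ is unfolded with delay vectors
$z_t = [x_t, x_{t+\tau}, \dots, x_{t+(m-1)\tau}]$.  `embed_series()`
builds the matrix of these vectors; `reconstruct_series()` inverts it
exactly (first column plus the trailing coordinates of the final rows),
provided the matrix covers every source observation, which requires
$\tau \le T$ where $T$ is the number of rows; otherwise the embedding
discards samples and reconstruction refuses.

Two selection rules supply $\tau$:

* `average_mutual_information()` — equal-width histogram estimate of the
  mutual information between $x_t$ and $x_{t+\tau}$ (natural log;
  Freedman–Diaconis bin count by default, overridable).  The delay is the
  profile's first local minimum, the standard choice for nonlinear
  models.  A profile with no local minimum (e.g. a random walk) falls
  back to `max_lag` with a warning.
* `select_delay_acf()` — first lag at which the autocorrelation drops
  below $1/e$, used for the linear model family.

The embedding dimension comes from Cao's method
(`cao_embedding_dimension()`).  We compute both of Cao's statistics:
$E1(m) = E(m{+}1)/E(m)$ from nearest-neighbour distance ratios (max
norm), and $E2(m)$ from the extrapolated-coordinate gaps.  Two details
matter and were settled empirically:

* **Saturation is judged by increments, not by an absolute level.**  On
  long trajectories the finite-sample bias keeps the $E1$ plateau
  slightly below 1 (on the Hénon map, $E1(2)$ converges to about 0.94),
  so a fixed cut such as "$E1 \ge 0.95$" misses the true dimension no
  matter how much data is available.  We instead select the smallest $m$
  beyond which $|\Delta E1|$ stays below $1 - \text{threshold}$
  (default 0.05), which is Cao's own "E1 stops changing" criterion made
  quantitative.
* **Stochastic input is screened with $E2$.**  For noise, $E1$ creeps
  upward indefinitely (distance concentration in high dimensions) and
  would eventually satisfy any increment rule, but $E2$ stays
  indistinguishable from 1 at every $m$ because the extra coordinate has
  no deterministic relation to the others.  If $|E2 - 1|$ never exceeds
  the tolerance, the series is declared noise-like and `m_max` is
  returned with a warning.

Note one pitfall when validating against periodic signals: a sine whose
period is commensurate with the sampling grid visits only finitely many
distinct delay vectors, and all neighbour statistics degenerate.
Benchmarks here use incommensurate periods.

## Chaos diagnostics

`lyapunov_exponent()` implements the nearest-neighbour divergence method:
each embedded point is paired with its nearest neighbour outside a
temporal exclusion window (Theiler window, default $m\tau$ samples), the
mean log separation $S(k)$ is tracked over $k$ steps, and $\lambda$ is
the slope of $S$ over the initial growth phase, auto-detected as the
contiguous run of increments staying above a quarter of the initial
increment.  On the logistic map at $r = 4$ this recovers
$\ln 2 \approx 0.693$ within 0.03, on the Hénon map 0.37 (literature
value 0.42), and effectively zero on periodic signals.  Exponents are
reported per sample step (one step = 5 minutes for CGM data).

`correlation_dimension()` estimates $D_2$ from the Grassberger–Procaccia
correlation sum with the same Theiler exclusion.  The scaling region is
chosen automatically as the window of consecutive log-spaced radii whose
local slopes are most nearly constant (minimum slope standard deviation
over a 6-point window between the 0.5% and 50% distance quantiles); an
uneven best window flags the estimate low-confidence.  White noise at
$m = 2$ gives $D_2 \approx 1.94$, a line gives 0.99, the Hénon map 1.16
(literature 1.22).

`denoise_phase()` performs the phase-space denoising used before model
fitting: embed at delay 1, replace each vector by the mean of all vectors
within a Euclidean radius, and reconstruct by averaging overlapping
coordinates.  The radius schedule on standardised data runs from 0.2 at
$m \le 3$ down to $10^{-4}$ at $m \ge 6$, log-interpolated between — wide
neighbourhoods are only safe where the embedding is coarse.

## The five predictors

All families regress the next observation on the $m$ delay coordinates
(most recent coordinate first) and share one score convention so they can
be compared: Gaussian AIC $n\log(\text{RSS}/n) + 2(k{+}1)$ with $k$ the
(effective) number of mean parameters, and in-sample MAPE.

* **LAR** — ordinary least squares.  Zero-variance lags are dropped with
  zero coefficients; residual exact collinearity is an error.
* **AAR** — additive model with one penalized cubic regression spline per
  lag, fitted by `mgcv::gam` with GCV smoothness selection; $k$ is the
  total effective degrees of freedom.  Lags with too few distinct values
  enter linearly.
* **NNAR** — single hidden layer of $q$ tanh units with linear output,
  trained by `nnet` under a fixed seed with five random restarts;
  `q = "auto"` picks over 1–4 by AIC.  `nnet` optimises the same squared
  loss as backpropagation, with quasi-Newton steps; refits are
  bit-identical by construction.
* **SETAR** — two linear regimes switching on a delayed coordinate
  $Y_t$.  The threshold is searched over up to 200 candidate values of
  $Y_t$ that leave at least 10% of the observations in each regime, each
  candidate scored by pooled AIC (sum of per-regime Gaussian AICs); the
  threshold delay $\delta$ is likewise chosen by pooled AIC over
  $0..m{-}1$ unless fixed.
* **LSTAR** — the regimes blended by the logistic weight
  $G(Y_t;\gamma,c)$, low regime weighted by $1-G$ and high by $G$ (the
  standard form).  Linear parameters are exact least squares at every
  point of a 200 ($c$, between the 0.1/0.9 quantiles of $Y_t$) × 40
  ($\gamma \in [1, 40]$) grid — done in compiled code — and the best grid
  point is refined by bounded quasi-Newton search, with $c$ confined to
  its quantile range so the 10% occupancy floor survives refinement.

A caution on what LSTAR estimation can and cannot pin down: when the true
transition is gentle ($\gamma \sim 10$), $c$ and $\gamma$ form a weakly
identified ridge — the least-squares optimum genuinely sits a little away
from the truth, and no amount of grid refinement changes that.  With
steep transitions the location behaves like a SETAR threshold and is
recovered nearly at the resolution of the candidate grid.  The parameter
recovery checks therefore use steep-transition simulations; for
$\gamma = 10$ designs only order-of-magnitude recovery of $\gamma$
(within 50%) and coarse recovery of $c$ should be expected.

`select_model()` takes the AIC minimum, breaking ties by MAPE and then by
simplicity (LAR < AAR < SETAR < LSTAR < NNAR).

## The sliding forecasting pipeline

`sliding_predict()` walks origins along the series in steps of the
horizon (default), and at each origin:

1. takes the trailing 8-hour window (96 samples), a training size short
   enough for real-time refitting yet spanning several meal cycles;
2. log-transforms and first-differences it (`transform_series()`), the
   variance-stabilising transform under which the series tests
   stationary (`test_stationarity()`, an ADF regression with constant
   and trend, AIC lag selection, and p-values interpolated from the
   classical Dickey–Fuller table — rejecting the unit root declares
   stationarity, the test's conventional direction);
3. re-estimates $(m, \tau)$ from the training samples that share the
   origin's landmark interval (falling back to the whole window below 40
   samples), with ACF delays for linear models and AMI for nonlinear
   ones, and Cao's dimension clamped to `m_range`;
4. denoises the window in phase space (radius schedule above, on the
   standardised window) and fits the configured model;
5. iterates one-step predictions $h$ times (6 for 30 min, 12 for 60),
   feeding predictions back as inputs, then inverts the transform.

Only samples at or before the origin ever enter fitting or prediction;
the leakage test mutates everything after an origin and asserts the
forecast is bit-identical.

Two stabilisation rules are deliberate design choices.  Iterated
working-scale predictions are clipped to the window's observed increment
range, and the final mg/dL forecast to the window's glucose envelope
±10%: a nonlinear map overfitted to 90 noisy points can have spurious
unstable fixed points, and iterating it 6–12 steps otherwise produces
occasional forecasts of physically impossible glucose values.  Likewise,
when Cao's statistic finds no saturation on a training window — typical
for differenced, noise-dominated 8-hour windows — the pipeline uses the
parsimonious lower end of `m_range` rather than the no-evidence fallback
`m_max`; high-dimensional regime models on 90 observations were the
single largest source of forecast blow-ups during development.

## Evaluation

`compute_errors()` reports RMSE, MAE and MAPE (pairs with a zero actual
are excluded from MAPE and counted).  `cg_ega()` grades clinical
accuracy: point accuracy uses the classical Clarke error-grid zones with
the continuous variant's rate-dependent boundary expansion (limits
stretch by 10 mg/dL when the reference moves at 1–2 mg/dL/min, 20 beyond
that, on the side the movement hides); rate accuracy compares predicted
and reference rates of change on a zone grid whose inequalities are
spelled out in the source (agreement band ±1 mg/dL/min, widening to ±2
for fast reference excursions; opposite-direction errors grade E;
over-predicted change C; missed change D).  The combined zone is the
worse of the two, with E folded into D for four-zone A–D reporting,
stratified by the reference range (hypo < 70, eu 70–180, hyper > 180
mg/dL).  The published cell-by-cell combination matrix is not reproduced
in text form anywhere we can cite precisely, so borderline cells of this
reading may differ from other implementations; the extreme cells (perfect
agreement → A, dangerous discordance → C/D) are unambiguous and tested.

## Risk and variability indices

`risk_indices()` uses the standard symmetrising transform
$f(\mathrm{BG}) = 1.509\,[(\ln \mathrm{BG})^{1.084} - 5.381]$ (mg/dL),
per-reading risk $10 f^2$, averaged separately over the low ($f<0$) and
high ($f>0$) sides to give LGI and HGI.  Averaging, not raw summation,
keeps the indices on the scale the published category cut-points assume
(hypoglycemia: minimal < 1.1, low to 2.5, moderate to 5, high above;
hyperglycemia: low < 4.5, moderate to 9, high above; boundary values go
to the lower-severity category unless the defining wording is strict).

`intra_day_indices()` covers SD, CV, the J-index $0.001(\text{mean} +
\text{SD})^2$, MAGE (mean amplitude of excursions exceeding one SD
between turning points of a 3-point-smoothed trace — superimposed
small-ripple oscillations are not merged across, so MAGE is conservative
on very jittery traces), and CONGA$_n$ (SD of differences $n$ hours
apart, default 1 h).  `inter_day_indices()` covers MODD (mean absolute
difference at the same clock time on consecutive days; `NA` below two
days), GVI (trace arc length over the straight chord; exactly 1 for a
flat trace) and PGS (GVI × mean glucose × fraction of time outside
70–180 mg/dL).  `landmark_report()` assembles everything per (day,
landmark-interval) window; the seven landmark windows (morning 06–10,
late morning 10–12:30, noon 12:30–16, afternoon 16–18:30, early evening
18:30–21:30, evening 21:30–24, night 0–6) are half-open `[start, end)`
and tile the day exactly.

## The synthetic CGM generator

Real multi-day CGM traces from the clinical setting this package targets
are not publicly deposited, so `simulate_cgm()` provides the test bed.
Its construction, and what each piece emulates:

* **Chaotic core** — a logistic map ($r=4$) advanced once per 15 minutes
  (every third sample) and held between steps, then low-pass filtered by
  two recursive EMAs (coefficients 0.94 and 0.6) and scaled to 10 mg/dL.
  The sample-and-hold clock sets the largest Lyapunov exponent to
  $\ln 2 / 3 \approx 0.23$ per 5-min sample — the magnitude reported for
  real glucose series — and linear filtering preserves its positivity,
  which the test suite verifies on the noiseless trace.
* **Circadian baseline and meals** — a 24-h cosine around `basal_level`
  plus gamma-shaped meal responses (peak ≈ 90 min, decay over ≈ 4 h) at
  the configured meal times, amplitudes modulated by the chaotic state
  at mealtime.  `hyper_intensity` scales the excursions from ~30 mg/dL
  (0) to ~135 mg/dL (1).
* **Hypoglycemic dips** — Gaussian-shaped dips at 03:00 and 17:00 whose
  depth and width grow with `hypo_intensity`; at intensity 0 they are
  absent and the deterministic part is floored at $70 + 3\sigma$, so
  with the 3-sigma-truncated sensor noise no reading goes below 70.
* **Sensor noise** — additive Gaussian, default SD 5 mg/dL, truncated at
  three SDs.

The knobs map monotonically onto the risk indices (higher
`hypo_intensity` → higher LGI, similarly for HGI), and `cgm_presets()`
documents settings reaching every published risk category.  What the
generator does *not* emulate: insulin–glucose feedback, meal-size
variation, sensor dropout and drift, compression artefacts.  Passing
tests on this generator therefore demonstrate that the machinery is
implemented correctly and behaves sensibly on CGM-like chaotic data, not
that the error figures obtained on it transfer to real patients.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to make each property statistically
unambiguous while keeping a full run in a few minutes: chaos benchmarks at
$n = 5000$ (invariants stabilise around $n \approx 3000$), parameter
recovery at $n = 2000$ over 20 seeds, and end-to-end forecasting on 5-day
traces (3-day for the 10-seed horizon comparison, where only the ordering
of medians matters).  Errors at the 60-min horizon exceed those at 30 min
by roughly 1.7× on the synthetic traces.  Degenerate inputs are handled
explicitly throughout: constant series (zero-variance guards in every
fit; AMI and ADF warn), rank-deficient designs (dropped or an error
naming the lags), gapped series (flagged on read, refused by the
forecaster — downstream imputation is deliberately out of scope), and
threshold searches that cannot honour the 10% occupancy floor (an
explicit degenerate-regime error).

## Known limitations

* The CG-EGA cell combination is a documented reading of the cited
  grid figure; borderline cells may differ from other implementations.
* MAGE follows the classical one-SD excursion rule with a fixed 3-point
  smoother; algorithm variants in the literature differ on smoothing and
  on merging split excursions, and can disagree by several mg/dL on
  noisy traces.
* The ADF p-value is interpolated from the classical critical-value
  table and is truncated at [0.01, 0.99]; it is a decision tool at the
  5% level, not a precise p-value.
* Forecast accuracy figures quoted anywhere in this package refer to the
  synthetic generator; they are not clinical results.
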