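---
title: "Estimating the 1-hour ESR from seconds of aggregation data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the 1-hour ESR from seconds of aggregation data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esrcurve)
```

## The problem

The Westergren erythrocyte sedimentation rate (ESR) is a workhorse of
clinical haematology, but it takes an hour: citrated blood stands in a
200-mm tube and the fall of the cell–plasma interface is read at 0.5-mm
resolution. The physical driver of sedimentation is red-cell aggregation —
rouleaux and three-dimensional aggregates settle much faster than single
cells — and aggregation kinetics can be read optically in a few seconds from
a *syllectogram*: the transmitted-light intensity recorded after abruptly
stopping blood flow. esrcurve implements a pipeline that converts a 5-second
syllectogram plus the sample hematocrit into an estimate of the full
sedimentation curve and its 1-hour value.

Both the optical aggregation index and the sedimentation velocity depend
strongly on hematocrit, which is why naive AI-to-ESR regressions transfer
poorly across samples. The pipeline removes this confound explicitly, at two
places: a hematocrit correction of the aggregation index, and a
hindered-settling factor in the sedimentation model.

## The sedimentation model

The model composes four ingredients, each with few parameters and a clear
physical meaning.

**Stokes settling.** A single erythrocyte of effective radius
$R_{ef}$ settles in plasma at
$c = 2(\rho_e-\rho_p)\,g\,R_{ef}^2 / (9\mu_p)$.
With the literature constants used here ($\rho_e = 1100$, $\rho_p = 1025$
kg/m^3^, $R_{ef} = 3.084\times10^{-6}$ m, $\mu_p = 1.64\times10^{-3}$ Pa s,
$g = 9.81$ m/s^2^ — gravity is not usually quoted with these constants and
the standard value is adopted) this gives $c \approx 9.48\times10^{-7}$ m/s,
i.e. 0.057 mm/min: isolated cells barely settle on clinical timescales.

**Hindered settling.** In a suspension at volume fraction $Ht$ the settling
velocity is reduced by the Richardson–Zaki factor $\varphi = (1-Ht)^n$ with
$n = 4.65$ at low Reynolds number; $\varphi(0.40) \approx 0.093$.

**Aggregate growth.** After flow stops, the effective particle radius grows
as $R_{agg}(t) = R_{ef}\,[1 + \alpha(1 - e^{-t/\lambda})]$ with a
dimensionless size parameter $\alpha$ and time constant $\lambda$ (seconds).
The interface velocity is the Stokes expression with $R_{agg}$ in place of
$R_{ef}$, so it rises from $c\varphi$ to the plateau
$V_e = c\,\varphi\,(1+\alpha)^2$. Integrating this velocity in closed form
gives the lag and constant-velocity phases of the curve; the closed form is
validated in the test suite against adaptive quadrature of the velocity to
better than $10^{-8}$ relative, which also pins down the printed form of the
integral unambiguously.

**Packing.** Settled cells accumulate at the tube bottom and slow the
interface. The constant-velocity phase ends at an empirical transition time
$\tau = 10.317\,V_e^{-0.57}$ (with $V_e$ in mm/min and $\tau$ in minutes —
the coefficient is only dimensionally meaningful in these clinical units,
which is also how the final distance relation
$h_\infty = 102\,(1-0.8\,Ht)\,\alpha^{0.2}$ mm must be read; all unit
conversions in the package happen at the `build_curve()` boundary, with the
hydrodynamics in SI). After $\tau$ the interface relaxes exponentially
towards $h_\infty$ with the rate set by slope continuity:
`packing_distance()` is built so the curve is $C^1$ at the transition, with
the incoming velocity evaluated from the growth model at $\tau$ rather than
the plateau value.

Two degenerate corners are handled explicitly rather than silently. The
$h_\infty$ relation sends the final distance to zero as $\alpha \to 0$,
foreclosing non-aggregating sedimentation; `h_infinity()` therefore refuses
$\alpha \le 0$ and warns below $\alpha = 0.01$, and `build_curve()` falls
back to the lag/constant model (with a warning) when a zero-$\alpha$ curve
formally reaches its transition time. Slowly settling samples
($V_e \lesssim 0.1$ mm/min) have $\tau > 60$ min and never leave the
lag/constant regime on the default 0–60-min, 0.5-min grid.

## From syllectogram to aggregation index

The start of the syllectogram is the intensity minimum $I_{MIN}$ reached
just after flow cessation. The windowed aggregation index over a
$T$-second measurement is the area ratio $AI_T = A/(A+B)$, where $A$ is the
area between the trace and $I_{MIN}$ and $B$ the area between the trace and
$I_{MAX}$, so that $A + B = (I_{MAX}-I_{MIN})\,T$ identically. Integration
is trapezoidal on the recorded 10-ms grid with no resampling (halving the
sampling interval moves the index by less than $10^{-4}$ on smooth traces).

Two estimator conventions matter and are switchable:

* **$I_{MAX}$** is the mean intensity over the final 100 ms of the window
  (`imax_window_s`), not the single end sample, so $AI_T$ is computable and
  noise-robust from a $T$-second record alone. Whether the reference is the
  window end or the end of the full record is genuinely a convention;
  `compute_ai(imax_rule = "trace_end")` switches to the long-record variant.
  Note the window-end mean shifts noise-free synthetic ramps by
  $\approx T_{avg}/2T$ (0.5051 rather than 0.5000 for a pure 5-s ramp).
* **Start detection** runs on a 0.2-s moving-average smoothed copy of each
  channel within the first 2 s: among samples whose smoothed intensity lies
  within twice the smoothed-series noise floor of the window minimum
  (noise estimated from the median absolute first difference), the earliest
  is taken. Without the near-minimum rule, the argmin of a noisy
  flat-bottomed trace is biased late and the index is biased high. A raw
  sample far below the smoothed floor (a sharp dip, e.g. an isolated
  transient) is trusted directly. $I_{MIN}$ itself is the trailing 0.2-s
  mean at the detected start, which reduces exactly to the first sample on
  traces that begin at their minimum.

With these conventions the index of a noise-free trace matches its closed
form to a few $10^{-6}$, and at 50 ADC counts of Gaussian noise on a 12-bit
range the mean index bias on a representative trace stays below 0.005
(measured by Monte Carlo in the test suite). The bias does grow for slowly
aggregating traces, whose 5-s dynamic range is small relative to the noise
— a measurement-physics limitation, not an estimator artefact.

Two detectors view the same sample; `average_detectors()` takes their mean
and flags disagreement above 0.10 (the signature of a bubble in one path).

## The hematocrit-corrected index and the calibration

At fixed plasma composition the AI rises almost linearly with hematocrit.
The corrected index references everything to $Ht = 0.40$:
$HAI = AI - k\,(Ht - 0.40)$, with $k = 0.284$ as the default (the mean
AI-vs-Ht slope across fibrinogen levels; `fit_k()` refits it from a cohort,
and whether $k$ should be refit per instrument is left to the user — the
default is the fixed value, and `calibrate()` refits everything).

The calibration then links $HAI_5$ (the 5-s index, the window with the
strongest association with sedimentation) to the model:

* $V_s = a\,(HAI_5 - b)^4 + c$ in m/s, with defaults $a = 0.0541$,
  $b = 0.426$. $b$ is the minimum physiological $HAI_5$ and $c$ is always
  the Stokes velocity computed from the physical constants, never fitted.
  The quartic reflects $V_s \propto (1+\alpha)^2$ with $\alpha$ roughly
  quadratic in $HAI_5$. Below $b$ the (even) quartic would rise again, so
  $V_s$ is clamped to $c$ there. The m/s scale is forced by magnitude:
  $a(HAI-b)^4$ only matches observed $V_s$ (order $10^{-5}$–$10^{-4}$ m/s)
  in SI.
* $\lambda = d\,HAI_5 + e\,Ht + f$ in minutes, defaults $d = -0.816$,
  $e = 0.887$, $f = 0.357$, floored at one second. `fit_lambda_regression()`
  reproduces the two-stage estimation: $d$ as the mean per-hematocrit slope
  at $Ht$ 0.25 and 0.30 (where the $\lambda$ fit is reliable), then
  $(e, f)$ by ordinary least squares on the residual. Ordinary least
  squares is used throughout; no alternative loss is documented for these
  fits, and OLS is the natural default.

`estimate_esr()` chains the pieces:
$AI_5 \to HAI_5 \to V_s \to (\alpha, V_e) \to \lambda \to$ curve $\to$
value at 60 min, returning every intermediate for audit.

## Inverse analyses of measured Westergren curves

`wg_esr_1h()` reads (or linearly interpolates) the 60-min value — export
schedules do not always contain an exact 60-min row. `extract_ve()` fits
the constant-velocity slope by least squares. The analysis window is
chosen by an explicit, reproducible rule standing in for the usual manual
"adjust to the constant range": a first R²-maximising scan over windows
starting at 5–25 min and ending at 40–60 min, then an iterative refinement
that caps the window end at the transition time implied by the current
slope (with starts down to 1 min). The refinement matters: fast settlers
(above ~1 mm/min) leave the constant phase before 10 minutes, and a fixed
15–60-min window would regress mostly packing-phase readings and
underestimate $V_e$ by tens of percent. On noise-free model curves the
refined rule recovers $V_e$ to ~0.1% except in the corner where a large
$\tau/\lambda$ ratio never materialises and no constant phase exists to
measure.

$\alpha$ then follows from $\alpha = \sqrt{V_s/c} - 1$ with
$V_s = V_e/(1-Ht)^n$ (sub-Stokes values are clamped to zero with a
warning), and $\lambda$ from a one-dimensional least-squares fit of the
lag/constant-phase model to the readings before $\min(\tau, 60)$ min,
searched on $[1, 600]$ s — aggregation time constants live on the
seconds-to-minutes scale and the growth law saturates beyond $t \gg
\lambda$, so a wider search adds nothing. The fit loss, range and equal
weighting are package choices; nothing canonical prescribes them.
Samples with $V_e < 0.1$ mm/min are excluded from the $\lambda$ analysis
(the 0.5-mm reading resolution dominates the curve shape there) and
reported with an `excluded` flag. The Westergren protocol's 4:1 citrate
dilution is upstream sample preparation; hematocrit inputs refer to the
prepared sample.

`fit_puccini()` provides the descriptive three-parameter sigmoid
$h(t) = h_\infty[1 - 1/((t/t_{50})^\beta + 1)]$ as a comparison fit.

## The synthetic cohort generator

`synthetic_spec()` + `generate_truth()` produce seeded cohorts with exact
ground truth, emulating a two-donor, four-fibrinogen-level (normal, +0.4,
+0.8, +1.2 g/dL), four-hematocrit (0.25/0.30/0.35/0.40) calibration study:

* The **factorial design** assigns one aggregation state per
  donor–fibrinogen cell (a geometric ladder over `alpha_range` with a
  per-donor multiplier — fibrinogen spiking increases aggregate size), and
  draws $\lambda$ from the calibration regression, reflecting the empirical
  $\lambda$–$HAI$–$Ht$ structure of real cohorts and keeping noiseless
  calibration recovery well-posed. The **random design** draws
  $(Ht, \alpha, \lambda)$ independently, $\lambda$ uniform on
  `lambda_range_s`.
* `alpha_range` defaults to $[2, 13]$. This is the range consistent with
  the cohort the generator emulates: interface velocities from a few
  hundredths of a mm/min up to ~3 mm/min, so that a realistic minority of
  slow samples (4 of 32 in the factorial design) falls under the 0.1-mm/min
  exclusion threshold while fast samples show clinically elevated 1-h
  values (tens of mm). Below $\alpha \approx 2$ essentially every
  high-hematocrit sample would be unmeasurably slow.
* The AI-level truth is exact by construction: the generator inverts the
  estimation pipeline ($V_s = c(1+\alpha)^2$,
  $HAI_5 = b + ((V_s - c)/a)^{1/4}$, $AI_5 = HAI_5 + k(Ht - 0.40)$), so
  estimating from a generated $(AI_5, Ht)$ pair with the generating
  calibration reproduces $V_e$ to machine precision — the round-trip
  identity the test suite asserts.
* Syllectograms come from a two-component shape family: a *squared*
  exponential fast term ($p = 0.85$ of the amplitude, emulating rouleaux
  formation with a brief nucleation delay) plus a slow 40-s term for
  three-dimensional aggregation, scaled to a 12-bit ADC range
  ($I_0 = 400$, $\Delta I = 3400$ counts) with Gaussian channel noise
  (default 20 counts) and integer rounding. A plain concave bi-exponential
  cannot produce $AI_5 < 0.5$, which weakly aggregating samples require;
  the squared fast term gives the family a convex start and a monotone
  $AI_5$ range of about (0.43, 0.97) in its fast time constant, which is
  solved per sample so the noise-free trace reproduces the row's $AI_5$.
  The family is a test harness, not a physiological claim.
* Westergren series sample the model curve on a realistic visual schedule
  (every minute to 30 min, then 40/50/60), add uniform reading jitter
  (default ±0.25 mm, half the scale quantum), quantize to 0.5 mm and
  enforce monotone readings. `observe_cohort()` adds replicate AI noise
  (default sd 0.01) and a jittered, quantized 1-h reading.

What the generator does **not** emulate: bubbles and detector drift,
hemolysis, temperature effects, tube-geometry (Boycott) effects, and any
departure of real blood from the growth law and the empirical
$\tau$/$h_\infty$ relations. Passing the recovery suite therefore shows the
pipeline is a faithful, well-conditioned inverse of the stated model under
realistic reading noise — not that the model captures every real sample.

## Problem sizes and numerical choices

The test suite and the acceptance script use: an 81-point
$(Ht, \alpha, \lambda, t)$ grid for the closed-form-vs-quadrature identity
(relative $10^{-8}$); a 32-sample factorial cohort for exact calibration
recovery (relative $10^{-6}$); a 100-sample random cohort for end-to-end
correlation (noise-free $r > 0.999$, with reading quantization and AI noise
$r > 0.95$); and 100 Monte-Carlo replicates for the AI noise-bias bound.
Nonlinear fits (sigmoid, quartic calibration) use Levenberg–Marquardt
(minpack.lm) with bound constraints and data-driven starts; the
one-dimensional $\lambda$ search uses golden-section `optimize()`. Ties in
the $V_e$ window selection break towards more readings, then earlier
starts, after rounding R² to 12 decimals to avoid floating-point
order-dependence.

## Known limitations

* The AI noise bias grows for slowly aggregating traces (small 5-s dynamic
  range); at 50 ADC counts of noise it can reach ~0.01 near the bottom of
  the family's range.
* $V_e$ (and hence everything downstream of it in the inverse analysis) is
  weakly identified for samples that are simultaneously fast-settling and
  slow-aggregating, where no constant-velocity phase exists at 1-min
  reading resolution.
* The empirical transition-time and final-distance coefficients are taken
  as fixed; no refitting interface is provided, and the packing tail of
  high-hematocrit curves inherits their error.
* The quartic $V_s$ calibration is flat near its floor $b$, so estimates
  for weak aggregators saturate at near-zero sedimentation; conversely its
  fourth power amplifies AI noise for strong aggregators.
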