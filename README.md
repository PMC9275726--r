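# esrcurve

Rapid estimation of the 1-hour Westergren erythrocyte sedimentation rate
(ESR) from a few seconds of optical red-cell aggregation data.

The Westergren ESR — how far the red-cell/plasma interface falls in a
vertical 200-mm tube in one hour — is a standard clinical test that takes an
hour by construction. The physics behind it is red-cell aggregation:
rouleaux and 3-D aggregates settle much faster than single cells, and the
kinetics of aggregation can be read in seconds from a *syllectogram*, the
transmitted-light intensity recorded after abruptly stopping blood flow.
esrcurve turns a 5-second syllectogram plus the sample hematocrit into an
estimate of the full three-phase sedimentation curve and its 1-hour value,
handling the strong hematocrit dependence of both measurements explicitly.

## The model

* **Aggregation index**: `AI_T = A/(A+B)`, the area ratio of the
  syllectogram between its post-stop minimum `I_MIN` and window-end level
  `I_MAX` over a `T`-second window (`A + B = (I_MAX − I_MIN) T`).
* **Hematocrit correction**: `HAI = AI − k (Ht − 0.40)` with `k = 0.284`,
  making aggregability comparable across hematocrits.
* **Calibration to the model**: the free single-aggregate settling velocity
  `Vs = a (HAI5 − b)^4 + c` (m/s) with `a = 0.0541`, `b = 0.426` and `c`
  the Stokes velocity of a single erythrocyte computed from physical
  constants; the aggregation time constant
  `λ = d·HAI5 + e·Ht + f` minutes (`d = −0.816`, `e = 0.887`, `f = 0.357`).
* **Modified Stokes' sedimentation model**: interface velocity
  `V(t) = c (1−Ht)^n [1 + α(1 − e^(−t/λ))]²`, combining Richardson–Zaki
  hindered settling (`n = 4.65`) with aggregate growth
  `Ragg = Ref (1 + α(1 − e^(−t/λ)))`; `α = sqrt(Vs/c) − 1`. Its closed-form
  integral gives the lag and constant-velocity phases up to the transition
  time `τ = 10.317 Ve^(−0.57)` min, then an exponential packing relaxation
  towards `h∞ = 102 (1 − 0.8 Ht) α^0.2` mm, slope-matched at `τ`.
* **Inverse analyses**: 1-h value, constant-phase slope `Ve`, `α`, `Vs` and
  `λ` extracted from measured Westergren time–distance series, and
  calibration refits (`k`; `a, b`; `d, e, f`) from cohort tables.
* **Synthetic cohorts**: seeded generators for paired syllectograms and
  quantized Westergren series with exact ground truth, emulating a
  2-donor × 4-fibrinogen × 4-hematocrit calibration study.

See the vignette (`vignettes/esr-estimation.Rmd`) for assumptions, estimator
conventions, parameter defaults and limitations.

## Worked example

Estimate the 1-hour ESR from a 5-s aggregation index of 0.62 at hematocrit
0.31:

```r
library(esrcurve)
est <- estimate_esr(ai5 = 0.62, ht = 0.31)
print(as.data.frame(est), digits = 4)
#>    ai5   ht   hai5    vs_m_s ve_mm_min alpha lambda_s tau_min h_inf_mm esr_1h_mm
#> 1 0.62 0.31 0.6456 0.0001267     1.354 10.56    6.312   8.682    122.9     63.23
```

Reading the audit trail: the hematocrit-corrected index is 0.646; the
quartic calibration maps it to a free aggregate settling velocity of
1.27×10⁻⁴ m/s, i.e. an aggregate size parameter α ≈ 10.6 and an interface
velocity of 1.35 mm/min after hindered settling at Ht 0.31; the predicted
aggregation time constant is 6.3 s; the assembled curve leaves its
constant-velocity phase at 8.7 min and yields an estimated 1-hour ESR of
63 mm — a markedly elevated value, consistent with strong aggregation.

Validation against a seeded synthetic study (2 donors × 4 fibrinogen
levels × 4 hematocrits, replicate AI noise and 0.5-mm tube quantization):

```r
spec   <- synthetic_spec(seed = 42)
cohort <- observe_cohort(generate_truth(spec), spec)
ev     <- evaluate_cohort(cohort, spec$params)
print(as.data.frame(ev$summary), digits = 3)
#>                 metric value  n
#> 1             r_esr_1h 0.982 32
#> 2                 r_ve 0.973 32
#> 3 slope_esr_rate_vs_ve 0.703 32
#> 4             r_lambda 0.995 32
```

Estimated 1-h ESR and interface velocity track their measured counterparts
with r ≈ 0.97–0.98 across the full hematocrit and fibrinogen range; the
slope of the 1-h-rate versus `Ve` regression is below 1 because packing
flattens fast curves before the hour.

A command-line wrapper is installed with the package
(`inst/scripts/esrtool`): subcommands `ai`, `estimate`,
`analyze-westergren`, `calibrate`, `simulate`, `evaluate`, e.g.

```sh
Rscript inst/scripts/esrtool estimate --ai5 0.62 --ht 0.31
Rscript inst/scripts/esrtool simulate --n 10 --seed 7 --out cohort_dir
```

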