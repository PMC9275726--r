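# Seeded synthetic cohorts: paired syllectograms and quantized Westergren
# series with known ground truth (Ht, alpha, lambda, Ve, ESR_1h), emulating a
# 2-donor x 4-hematocrit x 4-fibrinogen calibration study design.

# run code under a temporary RNG state so generation is deterministic given
# the cohort seed and leaves the caller's stream untouched
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# syllectogram shape family: squared-exponential fast (rouleaux) component
# plus slow 3-D aggregation component; dimensionless rise in [0, 1)
SYL_SPLIT <- 0.85   # amplitude fraction of the fast component
SYL_TAU_SLOW <- 40  # slow time constant, s
SYL_I0 <- 400       # baseline ADC counts
SYL_DI <- 3400      # full dynamic range, ADC counts (12-bit instrument)

syl_shape <- function(t, tau_f) {
  SYL_SPLIT * (1 - exp(-t / tau_f))^2 +
    (1 - SYL_SPLIT) * (1 - exp(-t / SYL_TAU_SLOW))
}

# closed-form time integral of syl_shape from 0 to T
syl_shape_int <- function(T, tau_f) {
  q2 <- T - 2 * tau_f * (1 - exp(-T / tau_f)) +
    (tau_f / 2) * (1 - exp(-2 * T / tau_f))
  q1 <- T - SYL_TAU_SLOW * (1 - exp(-T / SYL_TAU_SLOW))
  SYL_SPLIT * q2 + (1 - SYL_SPLIT) * q1
}

# closed-form AI of the family under the estimator conventions
# (I_MAX = mean over the final imax_w seconds of the window)
syl_ai_closed <- function(tau_f, window_s = 5, imax_w = 0.1) {
  a <- syl_shape_int(window_s, tau_f)
  imax <- (syl_shape_int(window_s, tau_f) -
             syl_shape_int(window_s - imax_w, tau_f)) / imax_w
  a / (imax * window_s)
}

# invert the family: fast time constant hitting a target 5-s AI
syl_solve_tau <- function(ai5_target, window_s = 5, interval = c(0.05, 9.5)) {
  lo <- syl_ai_closed(interval[2], window_s)
  hi <- syl_ai_closed(interval[1], window_s)
  if (ai5_target < lo || ai5_target > hi)
    abort(sprintf("target AI5 %.3f outside achievable range (%.3f, %.3f) of the trace family",
                  ai5_target, lo, hi))
  stats::uniroot(function(lt) syl_ai_closed(exp(lt), window_s) - ai5_target,
                 lower = log(interval[1]), upper = log(interval[2]),
                 tol = 1e-12)$root |> exp()
}

#' Specification of a synthetic cohort
#'
#' Captures the study conditions the generator emulates: the hematocrit
#' levels and fibrinogen design of a two-donor calibration experiment, the
#' ranges of the aggregation parameters, and the measurement noise model
#' (ADC noise on the syllectogram, visual-reading quantum and jitter on the
#' Westergren tube, and the residual standard deviation of replicate AI
#' measurements).
#'
#' @param n_samples Number of samples for `design = "random"`; the factorial
#'   design always has `2 x 4 x length(ht_levels)` samples.
#' @param seed Integer seed; every generated artefact is deterministic given
#'   it and is stamped with it.
#' @param design `"factorial"` (2 donors x 4 fibrinogen levels x `ht_levels`,
#'   one aggregation state per donor-fibrinogen cell, lambda following the
#'   calibration regression) or `"random"` (independent draws, lambda uniform
#'   on `lambda_range_s`).
#' @param ht_levels Hematocrit levels.
#' @param alpha_range Range of the aggregate size parameter.
#' @param lambda_range_s Range of the aggregation time constant, seconds.
#' @param intensity_sd Gaussian ADC noise on syllectogram samples.
#' @param reading_quantum Westergren reading resolution, mm.
#' @param reading_jitter Half-width of the uniform visual-reading error, mm.
#' @param ai_sd Replicate noise of an AI measurement.
#' @param params Generating [calibration_params()].
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 32, seed = 1,
                           design = c("factorial", "random"),
                           ht_levels = c(0.25, 0.30, 0.35, 0.40),
                           alpha_range = c(2, 13),
                           lambda_range_s = c(5, 120),
                           intensity_sd = 20, reading_quantum = 0.5,
                           reading_jitter = 0.25, ai_sd = 0.01,
                           params = calibration_params()) {
  design <- match.arg(design)
  stopifnot(n_samples >= 1, length(ht_levels) >= 1,
            diff(alpha_range) > 0, diff(lambda_range_s) > 0,
            intensity_sd >= 0, reading_quantum >= 0, reading_jitter >= 0,
            ai_sd >= 0, inherits(params, "calibration_params"))
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 design = design, ht_levels = ht_levels,
                 alpha_range = alpha_range, lambda_range_s = lambda_range_s,
                 intensity_sd = intensity_sd,
                 reading_quantum = reading_quantum,
                 reading_jitter = reading_jitter, ai_sd = ai_sd,
                 params = params),
            class = "synthetic_spec")
}

#' Generate the ground-truth table of a synthetic cohort
#'
#' Draws aggregation states and maps them through the inverse of the
#' estimation pipeline, so the AI-level ground truth is exact: the free
#' settling velocity `Vs = c (1 + alpha)^2`, the corrected index
#' `HAI5 = b + ((Vs - c)/a)^(1/4)`, the raw index
#' `AI5 = HAI5 + k (Ht - 0.40)`, the interface velocity
#' `Ve = Vs (1 - Ht)^n`, and the modelled 1-h ESR from the three-phase
#' curve. The fast time constant of the syllectogram shape family is solved
#' per sample so a noise-free generated trace reproduces `AI5`; the longer
#' windows (`ai10` ... `ai120`) are the closed-form indices of that shape.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with one row per sample: identifiers and design labels,
#'   `ht`, `alpha`, `lambda_s`, `vs_m_s`, `ve` (mm/min), `hai5`,
#'   `ai5`...`ai120`, `tau_f_s` (trace family parameter), `esr_1h_true` (mm).
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$params
  constants <- p$constants
  with_seed(spec$seed, {
    if (spec$design == "factorial") {
      fib_levels <- c("normal", "Fib+", "Fib++", "Fib+++")
      cells <- expand.grid(donor = c("A", "B"), fib_level = fib_levels,
                           stringsAsFactors = FALSE)
      # one aggregation state per donor-fibrinogen cell: a geometric ladder
      # over the alpha range with a per-donor multiplier
      ladder <- spec$alpha_range[1] *
        (spec$alpha_range[2] / spec$alpha_range[1])^
          ((match(cells$fib_level, fib_levels) - 1) / (length(fib_levels) - 1))
      mult <- runif(nrow(cells), 0.85, 1.15)
      cells$alpha <- pmin(pmax(ladder * mult, spec$alpha_range[1]),
                          spec$alpha_range[2])
      d <- tidyr::crossing(as_tibble(cells), ht = spec$ht_levels) |>
        arrange(.data$donor, .data$fib_level, .data$ht)
    } else {
      d <- tibble(donor = NA_character_, fib_level = NA_character_,
                  ht = sample(spec$ht_levels, spec$n_samples, replace = TRUE),
                  alpha = runif(spec$n_samples, spec$alpha_range[1],
                                spec$alpha_range[2]))
    }
    c_ms <- p$c_m_s
    d <- d |>
      mutate(vs_m_s = c_ms * (1 + .data$alpha)^2,
             hai5 = p$b + ((.data$vs_m_s - c_ms) / p$a)^0.25,
             ai5 = .data$hai5 + p$k * (.data$ht - 0.40),
             ve = ms_to_mmmin(.data$vs_m_s) *
               hindered_factor(.data$ht, constants$n))
    # resample any state whose AI5 leaves [0, 1] (not reachable by a trace)
    redrawn <- 0L
    bad <- which(d$ai5 < 0 | d$ai5 > 1)
    while (length(bad)) {
      redrawn <- redrawn + length(bad)
      d$alpha[bad] <- runif(length(bad), spec$alpha_range[1], spec$alpha_range[2])
      d$vs_m_s[bad] <- c_ms * (1 + d$alpha[bad])^2
      d$hai5[bad] <- p$b + ((d$vs_m_s[bad] - c_ms) / p$a)^0.25
      d$ai5[bad] <- d$hai5[bad] + p$k * (d$ht[bad] - 0.40)
      d$ve[bad] <- ms_to_mmmin(d$vs_m_s[bad]) *
        hindered_factor(d$ht[bad], constants$n)
      bad <- which(d$ai5 < 0 | d$ai5 > 1)
    }
    d$lambda_s <- if (spec$design == "factorial")
      60 * predict_lambda(d$hai5, d$ht, p, units = "min")
    else runif(nrow(d), spec$lambda_range_s[1], spec$lambda_range_s[2])
    d <- d |>
      mutate(sample_id = sprintf("S%03d", dplyr::row_number()),
             tau_f_s = purrr::map_dbl(.data$ai5, syl_solve_tau),
             ai10 = syl_ai_closed(.data$tau_f_s, 10),
             ai30 = syl_ai_closed(.data$tau_f_s, 30),
             ai60 = syl_ai_closed(.data$tau_f_s, 60),
             ai120 = syl_ai_closed(.data$tau_f_s, 120),
             esr_1h_true = purrr::pmap_dbl(
               list(.data$ht, .data$alpha, .data$lambda_s),
               function(h, a, l) {
                 cu <- build_curve(h, a, l, constants)
                 cu$h_mm[which.min(abs(cu$t_min - 60))]
               })) |>
      select("sample_id", "donor", "fib_level", "ht", "alpha", "lambda_s",
             "vs_m_s", "ve", "hai5", "ai5", "ai10", "ai30", "ai60", "ai120",
             "tau_f_s", "esr_1h_true")
    attr(d, "seed") <- spec$seed
    attr(d, "redrawn") <- redrawn
    d
  })
}

row_index <- function(row) as.integer(gsub("\\D", "", row$sample_id[1]))

#' Generate a synthetic syllectogram for one truth row
#'
#' Builds the two-channel stopped-flow trace of the sample's shape family
#' (fast rouleaux component with a nucleation delay plus slow 3-D
#' aggregation), scaled onto the 12-bit ADC range, with independent Gaussian
#' noise per channel, rounded to integer counts. With zero noise,
#' [compute_ai()] at 5 s reproduces the row's `ai5` to well within 1e-3.
#'
#' @param row One row of [generate_truth()] output.
#' @param spec The generating [synthetic_spec()].
#' @param duration_s,dt Trace length and sampling interval, seconds.
#' @return A [syl_trace()] with channels `ch1`, `ch2`.
#' @export
generate_syllectogram <- function(row, spec, duration_s = 120, dt = 0.01) {
  stopifnot(inherits(spec, "synthetic_spec"), nrow(row) == 1L)
  t <- seq(0, duration_s, by = dt)
  clean <- SYL_I0 + SYL_DI * syl_shape(t, row$tau_f_s)
  with_seed(spec$seed + 10000L + row_index(row), {
    mk <- function() {
      x <- clean + rnorm(length(t), 0, spec$intensity_sd)
      pmin(pmax(round(x), 0), 4095)
    }
    syl_trace(tibble(t_s = t, ch1 = mk(), ch2 = mk()),
              sample_id = row$sample_id)
  })
}

# visual reading schedule: every minute while sedimentation develops, then
# every 10 minutes to the hour
westergren_schedule <- function() c(0:30, 40, 50, 60)

#' Generate a synthetic Westergren series for one truth row
#'
#' Samples the modelled three-phase curve on the visual reading schedule,
#' adds uniform reading jitter, quantizes to the reading resolution, and
#' enforces monotone non-decreasing readings.
#'
#' @inheritParams generate_syllectogram
#' @return A [westergren_series()].
#' @export
generate_westergren <- function(row, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), nrow(row) == 1L)
  sched <- westergren_schedule()
  curve <- suppressWarnings(
    build_curve(row$ht, row$alpha, row$lambda_s, spec$params$constants,
                t_grid = sched))
  with_seed(spec$seed + 20000L + row_index(row), {
    h <- curve$h_mm +
      runif(length(sched), -spec$reading_jitter, spec$reading_jitter)
    if (spec$reading_quantum > 0)
      h <- round(h / spec$reading_quantum) * spec$reading_quantum
    h <- cummax(pmax(h, 0))
    h[1] <- 0
    westergren_series(tibble(t_min = sched, h_mm = h),
                      sample_id = row$sample_id,
                      resolution = max(spec$reading_quantum, 0.5))
  })
}

#' Apply the measurement-noise model to a truth table
#'
#' Produces the observed cohort: AI columns perturbed by replicate noise
#' (truncated to `[0, 1]`) and the measured 1-h ESR read off the tube
#' (jittered and quantized). Model parameters (`ve`, `alpha`, `lambda_s`)
#' are carried over unchanged; use [analyze_westergren()] on
#' [generate_westergren()] output to emulate their measurement as well.
#'
#' @param truth Output of [generate_truth()].
#' @param spec The generating [synthetic_spec()].
#' @return Cohort tibble with the same columns, plus `wg_esr_1h`.
#' @export
observe_cohort <- function(truth, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 30000L, {
    d <- truth
    for (col in intersect(c("ai5", "ai10", "ai30", "ai60", "ai120"), names(d)))
      d[[col]] <- pmin(pmax(d[[col]] + rnorm(nrow(d), 0, spec$ai_sd), 0), 1)
    wg <- d$esr_1h_true +
      runif(nrow(d), -spec$reading_jitter, spec$reading_jitter)
    if (spec$reading_quantum > 0)
      wg <- round(wg / spec$reading_quantum) * spec$reading_quantum
    d$wg_esr_1h <- pmax(wg, 0)
    d
  })
}

#' Write a full synthetic cohort to disk
#'
#' Writes `truth.csv`, the observed `cohort.csv`, per-sample trace and
#' Westergren CSVs, and a `manifest.json` recording the spec and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param traces If `FALSE`, skip the (large) per-sample syllectogram files.
#' @return Invisibly, a list with `truth`, `cohort` and the output paths.
#' @export
simulate_cohort <- function(spec, dir, traces = TRUE) {
  truth <- generate_truth(spec)
  cohort <- observe_cohort(truth, spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  readr::write_csv(cohort, file.path(dir, "cohort.csv"))
  dir.create(file.path(dir, "westergren"), showWarnings = FALSE)
  if (traces) dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    write_westergren(generate_westergren(row, spec),
                     file.path(dir, "westergren", paste0(row$sample_id, ".csv")))
    if (traces)
      write_trace(generate_syllectogram(row, spec),
                  file.path(dir, "traces", paste0(row$sample_id, ".csv")))
  }
  manifest <- c(unclass(spec)[setdiff(names(unclass(spec)), "params")],
                list(k = spec$params$k, a = spec$params$a, b = spec$params$b,
                     d = spec$params$d, e = spec$params$e, f = spec$params$f,
                     n_written = nrow(truth)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, cohort = cohort, dir = dir))
}
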