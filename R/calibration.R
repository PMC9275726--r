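# Calibration of the rapid-ESR pipeline and the forward estimation:
# (AI5, Ht) -> HAI5 -> Vs -> (Ve, alpha) -> lambda -> curve -> ESR at 1 h.

cohort_required <- c("sample_id", "ht", "ai5")

check_cohort <- function(cohort, cols = cohort_required) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    abort(paste0("cohort missing columns: ", paste(miss, collapse = ", ")))
  if (any(cohort$ht <= 0 | cohort$ht >= 1)) abort("cohort ht must lie in (0, 1)")
  invisible(cohort)
}

#' Fit the hematocrit correction factor k
#'
#' Within each fibrinogen level the AI rises nearly linearly with hematocrit;
#' `k` is the unweighted mean of the per-level least-squares slopes of AI
#' against Ht. Levels with fewer than two distinct hematocrits are skipped
#' with a warning.
#'
#' @param cohort Data frame with columns `fib_level`, `ht` and the AI column
#'   for the requested window (`ai5` for `window_s = 5`).
#' @param window_s Measurement window of the AI used, seconds.
#' @return A `k_fit` list: `k`, tibble `slopes` (per level), `window_s`.
#' @export
fit_k <- function(cohort, window_s = 5) {
  aicol <- paste0("ai", window_s)
  check_cohort(cohort, c("fib_level", "ht", aicol))
  slopes <- purrr::map_dfr(split(as_tibble(cohort), cohort$fib_level),
                           function(d) {
    tibble(fib_level = d$fib_level[1], n_ht = dplyr::n_distinct(d$ht),
           slope = if (dplyr::n_distinct(d$ht) >= 2L)
             unname(coef(lm(d[[aicol]] ~ d$ht))[2]) else NA_real_)
  })
  skipped <- slopes$fib_level[is.na(slopes$slope)]
  if (length(skipped))
    warn(paste0("fibrinogen levels skipped (single hematocrit): ",
                paste(skipped, collapse = ", ")))
  keep <- dplyr::filter(slopes, !is.na(.data$slope))
  if (!nrow(keep)) abort("no fibrinogen level has two hematocrit values; k unidentifiable")
  structure(list(k = mean(keep$slope), slopes = slopes, window_s = window_s),
            class = "k_fit")
}

#' @export
print.k_fit <- function(x, ...) {
  cat(sprintf("k = %.4f (mean of %d fibrinogen-level slopes, AI window %g s)\n",
              x$k, sum(!is.na(x$slopes$slope)), x$window_s))
  invisible(x)
}

#' @export
tidy.k_fit <- function(x, ...) {
  dplyr::transmute(x$slopes, term = paste0("slope[", .data$fib_level, "]"),
                   estimate = .data$slope)
}

#' @export
glance.k_fit <- function(x, ...)
  tibble(k = x$k, n_levels = sum(!is.na(x$slopes$slope)))

#' Predict the free settling velocity from HAI5
#'
#' Quartic calibration `Vs = a (HAI5 - b)^4 + c` (m/s), reflecting that `Vs`
#' scales with the square of the aggregate size parameter, itself roughly
#' quadratic in HAI5. Below the physiological floor `b` the quartic (an even
#' function) would spuriously rise again, so `Vs` is clamped to the
#' no-aggregation velocity `c` with a warning.
#'
#' @param hai5 Hematocrit-corrected 5-s aggregation index (vectorised).
#' @param params [calibration_params()].
#' @return `Vs` in m/s.
#' @export
predict_vs <- function(hai5, params = calibration_params()) {
  stopifnot(inherits(params, "calibration_params"))
  below <- hai5 <= params$b
  if (any(hai5 < params$b))
    warn("HAI5 below the physiological floor b; Vs clamped to the Stokes velocity")
  ifelse(below, params$c_m_s,
         params$a * (hai5 - params$b)^4 + params$c_m_s)
}

#' Predict the aggregation time constant from HAI5 and hematocrit
#'
#' Linear calibration `lambda = d HAI5 + e Ht + f` in minutes, floored at
#' 1/60 min (one second) with a warning when the linear form goes lower.
#'
#' @inheritParams predict_vs
#' @param ht Hematocrit fraction (vectorised).
#' @param units `"min"` or `"s"`.
#' @return Time constant in the requested units.
#' @export
predict_lambda <- function(hai5, ht, params = calibration_params(),
                           units = c("min", "s")) {
  stopifnot(inherits(params, "calibration_params"))
  units <- match.arg(units)
  lam <- params$d * hai5 + params$e * ht + params$f
  if (any(lam < 1 / 60))
    warn("lambda regression below 1 s; floored")
  lam <- pmax(lam, 1 / 60)
  if (units == "s") lam * 60 else lam
}

#' Fit the quartic Vs calibration (a, b)
#'
#' Nonlinear least squares of measured `Vs` (m/s) against HAI5 with the
#' no-aggregation velocity `c` fixed at the Stokes value derived from the
#' physical constants (never fitted).
#'
#' @param cohort Data frame with columns `hai5` and `vs_m_s` (or `ve` mm/min
#'   plus `ht`, from which `Vs` is derived via the hindered-settling factor).
#' @param constants [physical_constants()].
#' @return A `vs_fit` list: `a`, `b`, `c_m_s`, `resid_norm`, `n`.
#' @export
fit_vs_regression <- function(cohort, constants = physical_constants()) {
  stopifnot(is.data.frame(cohort))
  d <- as_tibble(cohort)
  if (!"hai5" %in% names(d)) abort("cohort missing 'hai5'")
  if (!"vs_m_s" %in% names(d)) {
    check_cohort(d, c("ve", "ht"))
    d$vs_m_s <- mmmin_to_ms(compute_vs(d$ve, d$ht, constants$n))
  }
  d <- dplyr::filter(d, is.finite(.data$hai5), is.finite(.data$vs_m_s))
  if (nrow(d) < 4L) abort("need at least 4 samples to fit (a, b)")
  if (dplyr::n_distinct(round(d$hai5, 12)) < 3L)
    abort("degenerate HAI5 spread; (a, b) unidentifiable")
  c_ms <- stokes_velocity(constants)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vs_m_s ~ a * (hai5 - b)^4 + c_ms, data = d,
      start = list(a = 0.05, b = min(d$hai5) - 0.01),
      lower = c(a = 1e-12, b = -1), upper = c(a = 10, b = min(d$hai5)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("Vs calibration fit failed: ",
                                     conditionMessage(e))))
  est <- coef(fit)
  structure(list(a = unname(est["a"]), b = unname(est["b"]), c_m_s = c_ms,
                 resid_norm = sqrt(sum(stats::residuals(fit)^2)), n = nrow(d)),
            class = "vs_fit")
}

#' @export
print.vs_fit <- function(x, ...) {
  cat(sprintf("Vs calibration: a = %.4g m/s, b = %.4g (c fixed at %.4g m/s, n = %d)\n",
              x$a, x$b, x$c_m_s, x$n))
  invisible(x)
}

#' @export
tidy.vs_fit <- function(x, ...)
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))

#' @export
glance.vs_fit <- function(x, ...)
  tibble(resid_norm = x$resid_norm, n = x$n, c_m_s = x$c_m_s)

#' Fit the lambda regression (d, e, f)
#'
#' `d` is the mean of the per-hematocrit least-squares slopes of `lambda`
#' (minutes) against HAI5 at Ht 0.25 and 0.30 (the hematocrits where the
#' lambda fit is reliable); `(e, f)` then come from ordinary least squares of
#' `lambda - d HAI5` against Ht over all samples with a non-excluded lambda.
#'
#' @param cohort Data frame with columns `hai5`, `ht` and `lambda_s`
#'   (seconds; `NA` for excluded samples).
#' @param slope_hts Hematocrits used for the `d` slopes.
#' @return A `lambda_reg_fit` list: `d`, `e`, `f`, per-Ht `slopes`, `n`.
#' @export
fit_lambda_regression <- function(cohort, slope_hts = c(0.25, 0.30)) {
  stopifnot(is.data.frame(cohort))
  check_cohort(cohort, c("hai5", "ht", "lambda_s"))
  d0 <- cohort |>
    dplyr::filter(is.finite(.data$lambda_s)) |>
    mutate(lambda_min = .data$lambda_s / 60)
  if (!nrow(d0)) abort("all lambda values excluded; regression impossible")
  slopes <- purrr::map_dbl(slope_hts, function(h) {
    dd <- dplyr::filter(d0, abs(.data$ht - h) < 1e-09)
    if (nrow(dd) < 2L || dplyr::n_distinct(round(dd$hai5, 12)) < 2L)
      return(NA_real_)
    unname(coef(lm(lambda_min ~ hai5, data = dd))[2])
  })
  if (any(is.na(slopes)))
    abort(paste0("lambda regression needs >= 2 HAI5 values at Ht ",
                 paste(slope_hts[is.na(slopes)], collapse = ", ")))
  d_hat <- mean(slopes)
  m <- lm(I(lambda_min - d_hat * hai5) ~ ht, data = d0)
  structure(list(d = d_hat, e = unname(coef(m)[2]), f = unname(coef(m)[1]),
                 slopes = tibble(ht = slope_hts, slope = slopes),
                 n = nrow(d0)),
            class = "lambda_reg_fit")
}

#' @export
print.lambda_reg_fit <- function(x, ...) {
  cat(sprintf("lambda regression: d = %.4g, e = %.4g, f = %.4g min (n = %d)\n",
              x$d, x$e, x$f, x$n))
  invisible(x)
}

#' @export
tidy.lambda_reg_fit <- function(x, ...)
  tibble(term = c("d", "e", "f"), estimate = c(x$d, x$e, x$f))

#' @export
glance.lambda_reg_fit <- function(x, ...) tibble(n = x$n)

#' Fit the full calibration from a cohort
#'
#' Chains [fit_k()], [fit_vs_regression()] and [fit_lambda_regression()];
#' HAI5 is recomputed from the freshly fitted `k`.
#'
#' @param cohort Cohort table with columns `fib_level`, `ht`, `ai5`, `ve`
#'   and `lambda_s`.
#' @param constants [physical_constants()].
#' @return A [calibration_params()] object.
#' @export
calibrate <- function(cohort, constants = physical_constants()) {
  kf <- fit_k(cohort, window_s = 5)
  cohort$hai5 <- compute_hai(cohort$ai5, cohort$ht, k = kf$k)
  vf <- fit_vs_regression(cohort, constants)
  lf <- fit_lambda_regression(cohort)
  calibration_params(k = kf$k, a = vf$a, b = vf$b,
                     d = lf$d, e = lf$e, f = lf$f, constants = constants)
}

#' Estimate the 1-hour ESR from a 5-second aggregation measurement
#'
#' The forward pipeline: correct AI5 for hematocrit (HAI5), map HAI5 to the
#' free settling velocity `Vs` through the quartic calibration, recover the
#' aggregate size parameter `alpha = sqrt(Vs/c) - 1` and the interface
#' velocity `Ve = Vs (1 - Ht)^n`, predict the aggregation time constant from
#' the linear calibration, assemble the three-phase sedimentation curve, and
#' read it at 60 minutes.
#'
#' @param ai5 5-s aggregation index in `[0, 1]` (vectorised).
#' @param ht Hematocrit fraction in (0, 1) (vectorised or scalar).
#' @param params [calibration_params()].
#' @param t_grid Curve grid in minutes (must reach 60).
#' @param keep_curves If `TRUE`, attach the modelled curves as a list column.
#' @return An `esr_estimate` tibble, one row per input, with the audit trail
#'   of intermediates: `ai5`, `ht`, `hai5`, `vs_m_s`, `ve_mm_min`, `alpha`,
#'   `lambda_s`, `tau_min`, `h_inf_mm`, `esr_1h_mm` (plus `curve` when
#'   requested).
#' @examples
#' estimate_esr(ai5 = 0.55, ht = 0.30)
#' @export
estimate_esr <- function(ai5, ht, params = calibration_params(),
                         t_grid = seq(0, 60, by = 0.5),
                         keep_curves = FALSE) {
  stopifnot(inherits(params, "calibration_params"))
  if (max(t_grid) < 60) abort("t_grid must reach 60 min for a 1-h estimate")
  n_out <- max(length(ai5), length(ht))
  ai5 <- rep_len(ai5, n_out)
  ht <- rep_len(ht, n_out)
  constants <- params$constants
  hai5 <- compute_hai(ai5, ht, k = params$k)
  vs <- predict_vs(hai5, params)
  alpha <- pmax(sqrt(vs / params$c_m_s) - 1, 0)
  ve_mm <- ms_to_mmmin(vs) * hindered_factor(ht, constants$n)
  lam_s <- predict_lambda(hai5, ht, params, units = "s")
  rows <- purrr::pmap(list(ht, alpha, lam_s), function(h, al, lm_) {
    curve <- withCallingHandlers(
      build_curve(h, al, lm_, constants, t_grid),
      warning = function(w) invokeRestart("muffleWarning"))
    p <- curve_params(curve)
    list(esr = curve$h_mm[which.min(abs(curve$t_min - 60))],
         tau = p$tau_min, h_inf = p$h_inf_mm, curve = curve)
  })
  out <- tibble(ai5 = ai5, ht = ht, hai5 = hai5, vs_m_s = vs,
                ve_mm_min = ve_mm, alpha = alpha, lambda_s = lam_s,
                tau_min = purrr::map_dbl(rows, "tau"),
                h_inf_mm = purrr::map_dbl(rows, "h_inf"),
                esr_1h_mm = purrr::map_dbl(rows, "esr"))
  if (keep_curves) out$curve <- purrr::map(rows, "curve")
  class(out) <- c("esr_estimate", class(out))
  attr(out, "params") <- params
  out
}

#' @export
tidy.esr_estimate <- function(x, ...) as_tibble(x)

#' @export
glance.esr_estimate <- function(x, ...)
  tibble(n = nrow(x), mean_esr_1h_mm = mean(x$esr_1h_mm))

#' Correlation table between aggregation indices and sedimentation parameters
#'
#' Pearson correlations of each windowed AI against the 1-h Westergren ESR
#' (pooled over hematocrits) and against `Ve`, `alpha` and `lambda`
#' stratified by hematocrit. Strata with fewer than `min_n` samples are
#' reported as `NA`.
#'
#' @param cohort Cohort table with `ai<window>` columns plus `wg_esr_1h`,
#'   `ve`, `alpha`, `lambda_s`, `ht`.
#' @param windows AI windows (seconds) to evaluate.
#' @param min_n Minimum stratum size.
#' @return Long tibble: `parameter`, `stratum`, `window_s`, `r`, `n`.
#'   Pivot with [correlation_table()] for the classic layout.
#' @export
evaluate_correlations <- function(cohort, windows = c(5, 10, 30, 60),
                                  min_n = 3L) {
  stopifnot(is.data.frame(cohort))
  aicols <- paste0("ai", windows)
  check_cohort(cohort, c("ht", aicols))
  cor_or_na <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(list(r = NA_real_, n = sum(ok)))
    list(r = stats::cor(x[ok], y[ok]), n = sum(ok))
  }
  out <- list()
  for (w in windows) {
    ai <- cohort[[paste0("ai", w)]]
    if ("wg_esr_1h" %in% names(cohort)) {
      cc <- cor_or_na(ai, cohort$wg_esr_1h)
      out[[length(out) + 1L]] <- tibble(parameter = "wg_esr_1h",
                                        stratum = "pooled", window_s = w,
                                        r = cc$r, n = cc$n)
    }
    for (param in intersect(c("ve", "alpha", "lambda_s"), names(cohort))) {
      for (h in sort(unique(cohort$ht))) {
        sel <- abs(cohort$ht - h) < 1e-09
        cc <- cor_or_na(ai[sel], cohort[[param]][sel])
        out[[length(out) + 1L]] <- tibble(parameter = param,
                                          stratum = sprintf("Ht %.2f", h),
                                          window_s = w, r = cc$r, n = cc$n)
      }
    }
  }
  bind_rows(out)
}

#' @rdname evaluate_correlations
#' @param correlations Output of [evaluate_correlations()].
#' @export
correlation_table <- function(correlations) {
  correlations |>
    mutate(window = paste0("ai", .data$window_s)) |>
    select("parameter", "stratum", "window", "r") |>
    tidyr::pivot_wider(names_from = "window", values_from = "r")
}

#' Compare estimated against measured sedimentation parameters in a cohort
#'
#' Runs [estimate_esr()] on every row and reports Pearson correlations of the
#' estimates against the measured values: 1-h ESR, `Ve`, and (over
#' non-excluded samples) `lambda`, together with the slope of the
#' ESR-rate-vs-Ve regression.
#'
#' @param cohort Cohort table with `ai5`, `ht` and any of `wg_esr_1h`, `ve`,
#'   `lambda_s`.
#' @param params [calibration_params()].
#' @return List with elements `estimates` (the [estimate_esr()] tibble bound
#'   to the cohort ids) and `summary` (tibble of `metric`, `value`, `n`).
#' @export
evaluate_cohort <- function(cohort, params = calibration_params()) {
  check_cohort(cohort)
  est <- estimate_esr(cohort$ai5, cohort$ht, params)
  est$sample_id <- cohort$sample_id
  summ <- list()
  add <- function(metric, value, n)
    summ[[length(summ) + 1L]] <<- tibble(metric = metric, value = value, n = n)
  if ("wg_esr_1h" %in% names(cohort)) {
    ok <- is.finite(cohort$wg_esr_1h)
    add("r_esr_1h", stats::cor(est$esr_1h_mm[ok], cohort$wg_esr_1h[ok]), sum(ok))
  }
  if ("ve" %in% names(cohort)) {
    ok <- is.finite(cohort$ve)
    add("r_ve", stats::cor(est$ve_mm_min[ok], cohort$ve[ok]), sum(ok))
    if ("wg_esr_1h" %in% names(cohort)) {
      ok2 <- ok & is.finite(cohort$wg_esr_1h)
      m <- lm(I(cohort$wg_esr_1h[ok2] / 60) ~ 0 + cohort$ve[ok2])
      add("slope_esr_rate_vs_ve", unname(coef(m)[1]), sum(ok2))
    }
  }
  if ("lambda_s" %in% names(cohort)) {
    ok <- is.finite(cohort$lambda_s)
    if (sum(ok) >= 3L)
      add("r_lambda", stats::cor(est$lambda_s[ok], cohort$lambda_s[ok]), sum(ok))
  }
  list(estimates = est, summary = bind_rows(summ))
}
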