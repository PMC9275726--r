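make_exact_cohort <- function() {
  # AI exactly linear in Ht with slope 0.284 within every fibrinogen level
  tidyr::crossing(fib_level = c("normal", "Fib+", "Fib++", "Fib+++"),
                  ht = c(0.25, 0.30, 0.35, 0.40)) |>
    dplyr::mutate(sample_id = sprintf("X%02d", dplyr::row_number()),
                  ai5 = 0.3 + 0.284 * (ht - 0.40) +
                    0.05 * as.integer(factor(fib_level)))
}

test_that("k is the mean of per-level AI-vs-Ht slopes", {
  co <- make_exact_cohort()
  kf <- fit_k(co)
  expect_equal(kf$k, 0.284, tolerance = 1e-12)
  expect_equal(glance(kf)$n_levels, 4L)

  # two levels with different slopes average
  co2 <- tidyr::crossing(fib_level = c("lo", "hi"), ht = c(0.25, 0.40)) |>
    dplyr::mutate(sample_id = as.character(dplyr::row_number()),
                  ai5 = ifelse(fib_level == "lo", 0.26, 0.30) * ht)
  expect_equal(fit_k(co2)$k, 0.28, tolerance = 1e-12)

  # single hematocrit per level is unidentifiable
  co3 <- dplyr::filter(co, ht == 0.40)
  expect_error(suppressWarnings(fit_k(co3)), "unidentifiable")
  # one usable level among skipped ones still works, with a warning
  co4 <- dplyr::bind_rows(dplyr::filter(co, fib_level == "normal"),
                          dplyr::filter(co3, fib_level != "normal"))
  expect_warning(kf4 <- fit_k(co4), "skipped")
  expect_equal(kf4$k, 0.284, tolerance = 1e-12)
})

test_that("quartic Vs calibration evaluates with the floor clamp", {
  p <- calibration_params()
  expect_equal(predict_vs(p$b, p), p$c_m_s)
  expect_equal(predict_vs(p$b + 0.3, p), p$c_m_s + 0.0541 * 0.3^4)
  expect_equal(predict_vs(p$b + 0.3, p) - p$c_m_s, 4.3821e-04,
               tolerance = 1e-04)
  expect_warning(v <- predict_vs(p$b - 0.1, p), "floor")
  expect_equal(v, p$c_m_s)
})

test_that("lambda regression evaluates in minutes with a 1-second floor", {
  p <- calibration_params()
  expect_equal(predict_lambda(0, 1e-12, p), 0.357, tolerance = 1e-09)
  expect_equal(predict_lambda(0.6, 0.30, p), 0.1335, tolerance = 1e-12)
  expect_equal(predict_lambda(0.6, 0.30, p, units = "s"), 8.01,
               tolerance = 1e-12)
  expect_warning(lam <- predict_lambda(0.9, 0.01, p), "floored")
  expect_equal(lam, 1 / 60)
})

test_that("(a, b) are recovered from noiseless and noisy synthetic cohorts", {
  cst <- physical_constants()
  c_ms <- stokes_velocity(cst)
  withr::with_seed(21, {
    hai5 <- runif(32, 0.48, 0.75)
    co <- tibble::tibble(hai5 = hai5,
                         vs_m_s = 0.0541 * (hai5 - 0.426)^4 + c_ms)
    vf <- fit_vs_regression(co, cst)
    expect_equal(vf$a, 0.0541, tolerance = 1e-06)
    expect_equal(vf$b, 0.426, tolerance = 1e-06)
    expect_equal(vf$c_m_s, c_ms)

    # 5 % multiplicative noise: recovery within 10 %
    co$vs_m_s <- co$vs_m_s * (1 + rnorm(32, 0, 0.05))
    vfn <- fit_vs_regression(co, cst)
    expect_lt(abs(vfn$a - 0.0541) / 0.0541, 0.10)
    expect_lt(abs(vfn$b - 0.426) / 0.426, 0.10)
  })
  expect_error(fit_vs_regression(tibble::tibble(hai5 = rep(0.5, 8),
                                                vs_m_s = rep(1e-05, 8))),
               "degenerate")
})

test_that("(d, e, f) are recovered and require both anchor hematocrits", {
  withr::with_seed(22, {
    co <- tidyr::crossing(ht = c(0.25, 0.30, 0.35, 0.40), rep = 1:8) |>
      dplyr::mutate(hai5 = runif(32, 0.45, 0.65),
                    lambda_s = 60 * (-0.816 * hai5 + 0.887 * ht + 0.357))
    lf <- fit_lambda_regression(co)
    expect_equal(lf$d, -0.816, tolerance = 1e-09)
    expect_equal(lf$e, 0.887, tolerance = 1e-09)
    expect_equal(lf$f, 0.357, tolerance = 1e-09)
  })

  # d is the mean of the per-Ht slopes
  co2 <- dplyr::bind_rows(
    tibble::tibble(ht = 0.25, hai5 = c(0.5, 0.6, 0.7),
                   lambda_s = 60 * (1 - 0.7 * c(0.5, 0.6, 0.7))),
    tibble::tibble(ht = 0.30, hai5 = c(0.5, 0.6, 0.7),
                   lambda_s = 60 * (1 - 0.9 * c(0.5, 0.6, 0.7))))
  expect_equal(fit_lambda_regression(co2)$d, -0.8, tolerance = 1e-12)

  # all lambdas excluded
  co3 <- tibble::tibble(ht = c(0.25, 0.30), hai5 = c(0.5, 0.6),
                        lambda_s = c(NA_real_, NA_real_))
  expect_error(fit_lambda_regression(co3), "excluded")
  # missing an anchor hematocrit
  co4 <- dplyr::filter(co2, ht != 0.30)
  expect_error(fit_lambda_regression(co4), "Ht 0.3")
})

test_that("the full calibration recovers the generating constants from a cohort", {
  spec <- synthetic_spec(seed = 42)
  truth <- generate_truth(spec)
  params <- calibrate(truth)
  expect_equal(params$k, 0.284, tolerance = 1e-06)
  expect_equal(params$a, 0.0541, tolerance = 1e-06)
  expect_equal(params$b, 0.426, tolerance = 1e-06)
  expect_equal(params$d, -0.816, tolerance = 1e-06)
  expect_equal(params$e, 0.887, tolerance = 1e-06)
  expect_equal(params$f, 0.357, tolerance = 1e-06)
})

test_that("ESR estimation composes the verified pieces and behaves monotonically", {
  p <- calibration_params()
  # at the physiological floor there is essentially no settling
  est <- suppressWarnings(estimate_esr(p$b, 0.40, p))
  expect_equal(est$alpha, 0)
  expect_equal(est$ve_mm_min, ms_to_mmmin(p$c_m_s) * hindered_factor(0.40),
               tolerance = 1e-09)
  expect_equal(est$ve_mm_min, 0.0053, tolerance = 0.01)
  expect_lt(est$esr_1h_mm, 1)

  # non-decreasing in ai5 at fixed ht
  ai <- seq(0.426, 0.95, length.out = 15)
  est <- suppressWarnings(estimate_esr(ai, 0.30, p))
  expect_true(all(diff(est$esr_1h_mm) >= -1e-09))

  # decreasing in ht at fixed ai5
  ht <- seq(0.25, 0.40, by = 0.025)
  est <- estimate_esr(0.60, ht, p)
  expect_true(all(diff(est$esr_1h_mm) < 0))

  # intermediates are mutually consistent
  est <- estimate_esr(0.58, 0.32, p, keep_curves = TRUE)
  expect_equal(est$hai5, compute_hai(0.58, 0.32, p$k))
  expect_equal(est$vs_m_s, predict_vs(est$hai5, p))
  expect_equal(est$alpha, sqrt(est$vs_m_s / p$c_m_s) - 1)
  expect_equal(est$ve_mm_min,
               ms_to_mmmin(est$vs_m_s) * hindered_factor(0.32), tolerance = 1e-12)
  expect_equal(est$lambda_s, predict_lambda(est$hai5, 0.32, p, units = "s"))
  expect_equal(curve_params(est$curve[[1]])$ve_mm_min, est$ve_mm_min,
               tolerance = 1e-09)
})

test_that("correlation table matches a direct covariance computation", {
  # perfectly (anti-)linear strata
  co <- tibble::tibble(sample_id = as.character(1:8),
                       ht = rep(0.25, 8),
                       ai5 = seq(0.4, 0.75, length.out = 8)) |>
    dplyr::mutate(ai10 = ai5 + 0.05, ai30 = ai5 + 0.1, ai60 = ai5 + 0.12,
                  ve = 2 * ai5 + 0.1, alpha = 5 * ai5,
                  lambda_s = 100 - 50 * ai5, wg_esr_1h = 30 * ai5)
  cors <- evaluate_correlations(co)
  expect_equal(cors$r[cors$parameter == "ve" & cors$window_s == 5], 1)
  expect_equal(cors$r[cors$parameter == "lambda_s" & cors$window_s == 5], -1)

  # 5-point stratum against the textbook covariance formula
  x <- c(0.42, 0.51, 0.55, 0.61, 0.70)
  y <- c(3.0, 2.1, 2.6, 1.2, 0.7)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  co2 <- tibble::tibble(sample_id = as.character(1:5), ht = 0.30,
                        ai5 = x, ve = y)
  cors2 <- evaluate_correlations(co2, windows = 5)
  expect_equal(cors2$r[cors2$parameter == "ve"], r_direct, tolerance = 1e-12)

  # undersized strata are reported as missing
  co3 <- co2[1:2, ]
  cors3 <- evaluate_correlations(co3, windows = 5)
  expect_true(all(is.na(cors3$r)))

  # wide layout puts windows in columns
  wide <- correlation_table(cors)
  expect_true(all(c("ai5", "ai10", "ai30", "ai60") %in% names(wide)))
})

test_that("calibration parameters survive a JSON round trip", {
  p <- calibration_params(k = 0.3, a = 0.06, b = 0.44, d = -0.8, e = 0.9,
                          f = 0.35, constants = physical_constants(r_ef = 3e-06))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(p, path)
  p2 <- read_calibration(path)
  for (fld in c("k", "a", "b", "d", "e", "f"))
    expect_equal(p2[[fld]], p[[fld]], tolerance = 1e-12)
  # c is recomputed from the stored constants, not persisted
  expect_equal(p2$c_m_s, stokes_velocity(physical_constants(r_ef = 3e-06)))
  expect_error(read_calibration(withr::local_tempfile(fileext = ".json")),
               "not found")
})
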