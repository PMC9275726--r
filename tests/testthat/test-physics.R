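test_that("Stokes velocity reproduces direct arithmetic on the constants", {
  cst <- physical_constants()
  direct <- 2 * (1100 - 1025) * 9.81 * (3.084e-06)^2 / (9 * 1.64e-03)
  expect_equal(stokes_velocity(cst), direct, tolerance = 1e-12)
  expect_equal(stokes_velocity(cst), 9.482e-07, tolerance = 1e-04)

  # neutral buoyancy is rejected at construction (settling requires rho_e > rho_p)
  expect_error(physical_constants(rho_e = 1025), "exceed")
  # quadratic scaling in the radius
  expect_equal(stokes_velocity(physical_constants(r_ef = 2 * 3.084e-06)),
               4 * stokes_velocity(cst))
})

test_that("hindered-settling factor follows Richardson-Zaki", {
  expect_equal(hindered_factor(0), 1)
  expect_equal(hindered_factor(1), 0)
  expect_equal(hindered_factor(0.40), exp(4.65 * log(0.6)), tolerance = 1e-12)
  expect_equal(hindered_factor(0.40), 0.0930, tolerance = 1e-03)
  expect_error(hindered_factor(1.3), "\\[0, 1\\]")
})

test_that("aggregate radius grows from r_ef to r_ef(1 + alpha)", {
  cst <- physical_constants()
  expect_equal(aggregate_radius(0, 2, 30), cst$r_ef)
  expect_equal(aggregate_radius(1e9, 2, 30), cst$r_ef * 3, tolerance = 1e-12)
  expect_equal(aggregate_radius(30, 1, 30), cst$r_ef * (2 - exp(-1)),
               tolerance = 1e-12)
  expect_error(aggregate_radius(-1, 1, 30), "non-negative")
})

test_that("instantaneous velocity composes Stokes, crowding and aggregate growth", {
  cst <- physical_constants()
  expect_equal(instantaneous_velocity(0, 0.3, 1.5, 20),
               stokes_velocity(cst) * hindered_factor(0.3))
  expect_equal(instantaneous_velocity(1e7, 0.3, 1.5, 20),
               plateau_velocity(0.3, 1.5), tolerance = 1e-12)
  # cross-check via the radius composition at t = lambda
  r <- aggregate_radius(20, 1.5, 20, cst)
  expect_equal(instantaneous_velocity(20, 0.3, 1.5, 20),
               stokes_velocity(cst) * hindered_factor(0.3) * (r / cst$r_ef)^2)
})

test_that("plateau velocity scales as (1 + alpha)^2 and responds to ht and units", {
  v0 <- plateau_velocity(0.3, 0)
  expect_equal(v0, stokes_velocity() * hindered_factor(0.3))
  expect_equal(plateau_velocity(0.3, 1), 4 * v0)
  expect_equal(plateau_velocity(0.25, 2),
               9 * stokes_velocity() * hindered_factor(0.25))
  expect_equal(plateau_velocity(0.3, 1, units = "mm_min"),
               ms_to_mmmin(plateau_velocity(0.3, 1)))
  # strictly increasing in alpha, strictly decreasing in ht
  expect_true(all(diff(plateau_velocity(0.3, seq(0, 5, 0.5))) > 0))
  expect_true(all(diff(sapply(seq(0.2, 0.5, 0.05),
                              function(h) plateau_velocity(h, 2))) < 0))
})

test_that("lag/constant-phase distance equals adaptive quadrature of the velocity", {
  cst <- physical_constants()
  worst <- 0
  for (ht in c(0.25, 0.32, 0.40))
    for (alpha in c(0.5, 2, 8))
      for (lam in c(5, 30, 120))
        for (t_s in c(15, 600, 3600)) {
          q <- integrate(function(u)
            instantaneous_velocity(u, ht, alpha, lam, cst),
            0, t_s, rel.tol = 1e-12, abs.tol = 0)$value
          h <- distance_lag_constant(t_s, ht, alpha, lam, cst)
          worst <- max(worst, abs(h - q) / q)
        }
  expect_lt(worst, 1e-08)

  expect_equal(distance_lag_constant(0, 0.3, 2, 30), 0)
  # no aggregation: constant integrand
  expect_equal(distance_lag_constant(100, 0.3, 0, 30),
               stokes_velocity(cst) * hindered_factor(0.3) * 100)
  # instant-aggregation limit: lambda -> 0 gives the plateau line
  expect_equal(distance_lag_constant(600, 0.3, 2, 1e-09),
               plateau_velocity(0.3, 2) * 600, tolerance = 1e-06)
})

test_that("transition time follows the empirical power law in clinical units", {
  expect_equal(transition_time(1), 10.317)
  expect_equal(transition_time(2), 10.317 * 2^(-0.57), tolerance = 1e-12)
  expect_equal(transition_time(2), 6.95, tolerance = 1e-03)
  expect_error(transition_time(0), "positive")
  # vanishing velocity: the transition recedes beyond any observation
  expect_gt(transition_time(1e-04), 60)
})

test_that("final settling distance matches the empirical Ht-alpha relation", {
  expect_equal(h_infinity(0.25, 1), 81.6)
  expect_equal(h_infinity(0.40, 1), 69.36)
  expect_error(h_infinity(0.25, 0), "alpha")
  expect_warning(h_infinity(0.25, 0.005), "extrapolated")
  expect_true(all(diff(sapply(seq(0.2, 0.5, 0.05),
                              function(h) h_infinity(h, 2))) < 0))
})

test_that("packing phase is continuous, slope-matched and converges to h_inf", {
  tau <- 12; h_tau <- 20; v_tau <- 1.8; h_inf <- 85
  expect_equal(packing_distance(tau, tau, h_tau, v_tau, h_inf), h_tau)
  expect_equal(packing_distance(1e6, tau, h_tau, v_tau, h_inf), h_inf)
  # analytic derivative at tau equals the incoming velocity
  eps <- 1e-06
  slope <- (packing_distance(tau + eps, tau, h_tau, v_tau, h_inf) - h_tau) / eps
  expect_equal(slope, v_tau, tolerance = 1e-05)
  expect_error(packing_distance(15, tau, 90, v_tau, h_inf), "below current front")
})

test_that("assembled curve is continuous, monotone and matches brute-force integration", {
  for (case in list(c(0.25, 8, 20), c(0.30, 4, 60), c(0.40, 10, 10))) {
    ht <- case[1]; alpha <- case[2]; lam <- case[3]
    curve <- build_curve(ht, alpha, lam)
    p <- curve_params(curve)
    expect_equal(curve$h_mm[1], 0)
    expect_true(all(diff(curve$h_mm) >= -1e-12))
    if (is.finite(p$h_inf_mm)) expect_true(all(curve$h_mm <= p$h_inf_mm + 1e-09))

    # continuity and slope agreement across the phase transition
    tau <- p$tau_min
    if (tau < 60) {
      h_left <- 1000 * distance_lag_constant(60 * tau, ht, alpha, lam)
      eps <- 1e-07
      h_right <- packing_distance(tau + eps, tau, h_left,
                                  ms_to_mmmin(instantaneous_velocity(60 * tau, ht, alpha, lam)),
                                  p$h_inf_mm)
      expect_lt(abs(h_right - h_left), 1e-05)
      v_left <- ms_to_mmmin(instantaneous_velocity(60 * tau, ht, alpha, lam))
      v_right <- (packing_distance(tau + eps, tau, h_left, v_left, p$h_inf_mm) - h_left) / eps
      expect_equal(v_right, v_left, tolerance = 1e-06)
    }

    # brute-force velocity integrator agrees within 0.05 mm
    bf <- brute_force_curve(ht, alpha, lam)
    on_grid <- bf[bf$t_min %in% curve$t_min, ]
    expect_lt(max(abs(on_grid$h_mm - curve$h_mm)), 0.05)
  }

  # slow samples never leave the lag/constant regime on a 60-min grid
  slow <- build_curve(0.40, 1, 30)
  expect_true(all(slow$phase == "lag-constant"))
  expect_true(is.na(curve_params(slow)$h_inf_mm))
})

test_that("sigmoid comparison curve evaluates and round-trips its parameters", {
  expect_equal(puccini_eval(0, 80, 20, 3), 0)
  expect_equal(puccini_eval(20, 80, 20, 3), 40)
  expect_equal(puccini_eval(1e9, 80, 20, 3), 80, tolerance = 1e-06)

  t <- seq(0, 90, by = 2)
  clean <- tibble::tibble(t_min = t, h_mm = puccini_eval(t, 80, 20, 3))
  fit <- fit_puccini(clean)
  expect_equal(fit$h_inf, 80, tolerance = 1e-06)
  expect_equal(fit$t50, 20, tolerance = 1e-06)
  expect_equal(fit$beta, 3, tolerance = 1e-06)
  expect_equal(tidy(fit)$estimate, c(80, 20, 3), tolerance = 1e-05)

  expect_error(fit_puccini(tibble::tibble(t_min = t, h_mm = 0 * t)),
               "degenerate|half-height")

  # 0.5-mm reading quantization still recovers within 2 %
  quant <- tibble::tibble(t_min = t, h_mm = round(clean$h_mm / 0.5) * 0.5)
  fitq <- fit_puccini(quant)
  expect_lt(abs(fitq$h_inf - 80) / 80, 0.02)
  expect_lt(abs(fitq$t50 - 20) / 20, 0.02)
  expect_lt(abs(fitq$beta - 3) / 3, 0.02)
})
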