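# Independent oracles and fixture builders shared across the suite. These
# deliberately avoid the package's own code paths (direct arithmetic,
# quadrature via stats::integrate, pracma::trapz) so round-trip tests compare
# two routes to the same quantity.

# closed-form AI of a saturating-exponential rise over a T-second window with
# I_MAX taken at the window end point
ai_exponential_closed <- function(T, tau_c) {
  (T - tau_c * (1 - exp(-T / tau_c))) / (T * (1 - exp(-T / tau_c)))
}

# closed-form AI of the generator's trace family (squared-exponential fast
# component + slow exponential), under the estimator's I_MAX convention
# (mean over the final imax_w seconds of the window)
ai_family_closed <- function(tau_f, window_s = 5, p = 0.85, tau_s = 40,
                             imax_w = 0.1) {
  intS <- function(T) {
    q2 <- T - 2 * tau_f * (1 - exp(-T / tau_f)) +
      (tau_f / 2) * (1 - exp(-2 * T / tau_f))
    q1 <- T - tau_s * (1 - exp(-T / tau_s))
    p * q2 + (1 - p) * q1
  }
  a <- intS(window_s)
  imax <- (intS(window_s) - intS(window_s - imax_w)) / imax_w
  a / (imax * window_s)
}

# the family's clean intensity signal on the ADC scale used by the generator
family_signal <- function(t, tau_f, p = 0.85, tau_s = 40,
                          i0 = 400, di = 3400) {
  i0 + di * (p * (1 - exp(-t / tau_f))^2 + (1 - p) * (1 - exp(-t / tau_s)))
}

make_family_trace <- function(tau_f, duration = 7, dt = 0.01, two_ch = FALSE) {
  t <- seq(0, duration, by = dt)
  d <- tibble::tibble(t_s = t, ch1 = family_signal(t, tau_f))
  if (two_ch) d$ch2 <- d$ch1
  syl_trace(d, sample_id = "fixture")
}

# brute-force integration of the velocity model: forward Euler on a fine grid
# through both phases, switching to the packing relaxation at tau
brute_force_curve <- function(ht, alpha, lambda_s,
                              constants = physical_constants(),
                              t_end = 60, dt_min = 0.01) {
  ts <- seq(0, t_end, by = dt_min)
  ve_mm <- plateau_velocity(ht, alpha, constants, "mm_min")
  tau <- transition_time(ve_mm)
  h <- numeric(length(ts))
  reached_pack <- FALSE
  h_tau <- v_tau <- h_inf <- NA_real_
  for (i in seq_along(ts)[-1]) {
    t_mid <- (ts[i - 1] + ts[i]) / 2
    if (t_mid <= tau) {
      v <- ms_to_mmmin(instantaneous_velocity(60 * t_mid, ht, alpha,
                                              lambda_s, constants))
      h[i] <- h[i - 1] + v * dt_min
    } else {
      if (!reached_pack) {
        h_tau <- h[i - 1] +
          ms_to_mmmin(instantaneous_velocity(60 * tau, ht, alpha, lambda_s,
                                             constants)) * (tau - ts[i - 1])
        v_tau <- ms_to_mmmin(instantaneous_velocity(60 * tau, ht, alpha,
                                                    lambda_s, constants))
        h_inf <- h_infinity(ht, alpha)
        reached_pack <- TRUE
      }
      v <- v_tau * exp(v_tau / (h_inf - h_tau) * (tau - t_mid))
      h[i] <- h[i - 1] + v * dt_min
    }
  }
  tibble::tibble(t_min = ts, h_mm = h)
}

# a noiseless linear Westergren series, optionally quantized
make_line_series <- function(slope, times = seq(15, 60, by = 1),
                             quantum = 0) {
  h <- slope * times
  if (quantum > 0) h <- round(h / quantum) * quantum
  westergren_series(tibble::tibble(t_min = times, h_mm = h))
}

default_c_mm <- ms_to_mmmin(stokes_velocity())
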