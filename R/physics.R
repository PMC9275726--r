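#' Stokes settling velocity of a single erythrocyte
#'
#' The terminal settling velocity of an isolated rigid sphere of effective
#' erythrocyte radius in plasma, `2 (rho_e - rho_p) g r_ef^2 / (9 mu_p)`.
#' This is the velocity scale of the whole sedimentation model and also the
#' no-aggregation floor `c` of the calibration regression.
#'
#' @param constants [physical_constants()].
#' @return Velocity in m/s.
#' @examples
#' ms_to_mmmin(stokes_velocity()) # about 0.057 mm/min
#' @export
stokes_velocity <- function(constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  2 * (constants$rho_e - constants$rho_p) * constants$g * constants$r_ef^2 /
    (9 * constants$mu_p)
}

#' Richardson-Zaki hindered-settling factor
#'
#' In a suspension at volume fraction `ht`, crowding reduces the settling
#' velocity by the factor `(1 - ht)^n`; `n = 4.65` applies at low Reynolds
#' number.
#'
#' @param ht Hematocrit (volume fraction), in `[0, 1]`.
#' @param n Richardson-Zaki exponent.
#' @return Dimensionless factor in `[0, 1]`. Vectorised over `ht`.
#' @export
hindered_factor <- function(ht, n = 4.65) {
  if (any(!is.finite(ht)) || any(ht < 0) || any(ht > 1))
    abort("hematocrit must lie in [0, 1]")
  (1 - ht)^n
}

#' Effective aggregate radius at time t
#'
#' Aggregate growth after flow stop: `r_ef (1 + alpha (1 - exp(-t/lambda)))`,
#' rising from the single-cell radius at `t = 0` to `r_ef (1 + alpha)` at
#' saturation, with time constant `lambda` seconds.
#'
#' @param t_s Time since flow stop, seconds (vectorised).
#' @param alpha Dimensionless aggregate size parameter (>= 0).
#' @param lambda_s Aggregation time constant, seconds (> 0).
#' @param constants [physical_constants()].
#' @return Radius in m.
#' @export
aggregate_radius <- function(t_s, alpha, lambda_s,
                             constants = physical_constants()) {
  if (any(t_s < 0)) abort("time must be non-negative")
  if (alpha < 0) abort("alpha must be non-negative")
  if (lambda_s <= 0) abort("lambda must be positive")
  constants$r_ef * (1 + alpha * (1 - exp(-t_s / lambda_s)))
}

#' Instantaneous sedimentation velocity of the cell-plasma interface
#'
#' Modified Stokes' law with hindered settling and growing aggregates:
#' the Stokes velocity scaled by `(1 - ht)^n` and by the squared ratio of the
#' current aggregate radius to the single-cell radius.
#'
#' @inheritParams aggregate_radius
#' @param ht Hematocrit fraction.
#' @return Velocity in m/s (vectorised over `t_s`).
#' @export
instantaneous_velocity <- function(t_s, ht, alpha, lambda_s,
                                   constants = physical_constants()) {
  r <- aggregate_radius(t_s, alpha, lambda_s, constants)
  stokes_velocity(constants) * hindered_factor(ht, constants$n) *
    (r / constants$r_ef)^2
}

#' Plateau (constant-phase) sedimentation velocity
#'
#' Once aggregate growth has saturated the interface settles at
#' `stokes_velocity * (1 - ht)^n * (1 + alpha)^2`.
#'
#' @inheritParams instantaneous_velocity
#' @param units `"m_s"` or `"mm_min"`.
#' @return Velocity in the requested units.
#' @export
plateau_velocity <- function(ht, alpha, constants = physical_constants(),
                             units = c("m_s", "mm_min")) {
  if (any(alpha < 0)) abort("alpha must be non-negative")
  units <- match.arg(units)
  v <- stokes_velocity(constants) * hindered_factor(ht, constants$n) *
    (1 + alpha)^2
  if (units == "mm_min") ms_to_mmmin(v) else v
}

#' Settling distance through the lag and constant-velocity phases
#'
#' Closed-form time integral of [instantaneous_velocity()]: with
#' `A = 1 + alpha`,
#' `K phi r_ef^2 [A^2 t + alpha lambda ((2 alpha + 2) e^(-t/lambda)
#'  - (alpha/2) e^(-2 t/lambda) - (3/2) alpha - 2)]`,
#' where `K = 2 (rho_e - rho_p) g / (9 mu_p)`. The bracket vanishes at
#' `t = 0` and its derivative reproduces the instantaneous velocity exactly.
#'
#' @inheritParams instantaneous_velocity
#' @return Distance in m (vectorised over `t_s`).
#' @export
distance_lag_constant <- function(t_s, ht, alpha, lambda_s,
                                  constants = physical_constants()) {
  if (any(t_s < 0)) abort("time must be non-negative")
  if (alpha < 0) abort("alpha must be non-negative")
  if (lambda_s <= 0) abort("lambda must be positive")
  K <- 2 * (constants$rho_e - constants$rho_p) * constants$g /
    (9 * constants$mu_p)
  A <- 1 + alpha
  bracket <- A^2 * t_s + alpha * lambda_s *
    ((2 * alpha + 2) * exp(-t_s / lambda_s) -
       (alpha / 2) * exp(-2 * t_s / lambda_s) - 1.5 * alpha - 2)
  K * hindered_factor(ht, constants$n) * constants$r_ef^2 * bracket
}

#' Transition time from constant-velocity to packing phase
#'
#' Empirical relation `tau = 10.317 Ve^(-0.57)` with the plateau velocity in
#' mm/min and `tau` in minutes. Slowly settling samples may never reach the
#' packing phase within a 60-minute observation.
#'
#' @param ve_mm_min Plateau sedimentation velocity, mm/min (> 0).
#' @return Transition time in minutes (vectorised).
#' @export
transition_time <- function(ve_mm_min) {
  if (any(!is.finite(ve_mm_min)) || any(ve_mm_min <= 0))
    abort("plateau velocity must be positive")
  10.317 * ve_mm_min^(-0.57)
}

#' Final settling distance
#'
#' Empirical asymptote of the sedimentation curve,
#' `h_inf = 102 (1 - 0.8 ht) alpha^0.2` mm. The relation forecloses
#' non-aggregating sedimentation (`h_inf -> 0` as `alpha -> 0`), so values of
#' `alpha` below 0.01 trigger a warning rather than a silent extrapolation.
#'
#' @param ht Hematocrit fraction in (0, 1).
#' @param alpha Aggregate size parameter (> 0).
#' @return Distance in mm.
#' @export
h_infinity <- function(ht, alpha) {
  if (any(ht <= 0) || any(ht >= 1)) abort("hematocrit must lie in (0, 1)")
  if (any(alpha <= 0))
    abort("h_infinity requires alpha > 0 (no-aggregation limit is outside the packing model)")
  if (any(alpha < 0.01))
    warn("alpha < 0.01: final settling distance relation extrapolated far below its fitted range")
  102 * (1 - 0.8 * ht) * alpha^0.2
}

#' Settling distance in the packing phase
#'
#' After the transition time the deposited cell column slows the interface,
#' which relaxes exponentially towards `h_inf`:
#' `h(t) = h_inf - (h_inf - h(tau)) exp[v(tau) / (h_inf - h(tau)) (tau - t)]`.
#' By construction the curve is continuous at `tau` and its slope there equals
#' the incoming velocity `v(tau)`.
#'
#' @param t_min Time, minutes (>= `tau_min`; vectorised).
#' @param tau_min Transition time, minutes.
#' @param h_tau Settling distance at the transition, mm.
#' @param v_tau Interface velocity at the transition, mm/min (> 0).
#' @param h_inf Final settling distance, mm (> `h_tau`).
#' @return Distance in mm.
#' @export
packing_distance <- function(t_min, tau_min, h_tau, v_tau, h_inf) {
  if (h_inf <= h_tau) abort("packing target below current front (h_inf <= h(tau))")
  if (v_tau <= 0) abort("transition velocity must be positive")
  if (any(t_min < tau_min - 1e-09)) abort("packing phase requires t >= tau")
  h_inf - (h_inf - h_tau) * exp(v_tau / (h_inf - h_tau) * (tau_min - t_min))
}

new_esr_curve <- function(t_min, h_mm, phase, params, source = "modeled") {
  out <- tibble(t_min = t_min, h_mm = h_mm, phase = phase)
  class(out) <- c("esr_curve", class(out))
  attr(out, "params") <- params
  attr(out, "source") <- source
  out
}

#' Parameters of a sedimentation curve
#'
#' @param curve An `esr_curve` as returned by [build_curve()].
#' @return Named list with `ht`, `ve_mm_min`, `alpha`, `lambda_s`, `tau_min`,
#'   `h_inf_mm`.
#' @export
curve_params <- function(curve) attr(curve, "params")

#' Assemble the three-phase sedimentation curve
#'
#' Builds the modelled Westergren curve for a sample of hematocrit `ht` with
#' aggregation state `(alpha, lambda_s)`: the closed-form lag/constant-phase
#' integral up to the transition time `tau`, then the exponential packing
#' relaxation towards `h_inf`. The hydrodynamic part is evaluated in SI and
#' converted to clinical units (mm, minutes) here, at the model boundary.
#' If `tau` falls beyond the grid the curve is the lag/constant form
#' throughout and `h_inf` is not evaluated.
#'
#' @inheritParams instantaneous_velocity
#' @param t_grid Ascending time grid in minutes starting at 0.
#' @return An `esr_curve` tibble with columns `t_min`, `h_mm`, `phase` and a
#'   `params` attribute (`ht`, `ve_mm_min`, `alpha`, `lambda_s`, `tau_min`,
#'   `h_inf_mm`); see [curve_params()].
#' @examples
#' curve <- build_curve(ht = 0.30, alpha = 2, lambda_s = 30)
#' curve_params(curve)$ve_mm_min
#' @export
build_curve <- function(ht, alpha, lambda_s, constants = physical_constants(),
                        t_grid = seq(0, 60, by = 0.5)) {
  if (length(t_grid) < 2L || is.unsorted(t_grid, strictly = TRUE) ||
      t_grid[1] != 0)
    abort("t_grid must be strictly ascending from 0")
  ve_mm <- plateau_velocity(ht, alpha, constants, units = "mm_min")
  tau <- transition_time(ve_mm)
  h_lag <- function(t_min)
    1000 * distance_lag_constant(60 * t_min, ht, alpha, lambda_s, constants)
  h_inf <- NA_real_
  if (tau <= max(t_grid) && alpha > 0) {
    h_tau <- h_lag(tau)
    v_tau <- ms_to_mmmin(instantaneous_velocity(60 * tau, ht, alpha,
                                                lambda_s, constants))
    h_inf <- h_infinity(ht, alpha)
    if (h_inf <= h_tau) abort("packing target below current front (h_inf <= h(tau))")
    pack <- t_grid > tau
    h <- ifelse(pack, NA_real_, h_lag(pmin(t_grid, tau)))
    h[pack] <- packing_distance(t_grid[pack], tau, h_tau, v_tau, h_inf)
    phase <- ifelse(pack, "packing", "lag-constant")
  } else {
    if (tau <= max(t_grid) && alpha <= 0)
      warn("alpha = 0: packing phase undefined, lag/constant model used throughout")
    h <- h_lag(t_grid)
    phase <- rep("lag-constant", length(t_grid))
  }
  new_esr_curve(t_grid, h, phase,
                params = list(ht = ht, ve_mm_min = ve_mm, alpha = alpha,
                              lambda_s = lambda_s, tau_min = tau,
                              h_inf_mm = h_inf))
}

#' Sigmoidal (Puccini-type) sedimentation curve
#'
#' Purely descriptive three-parameter sigmoid
#' `h(t) = h_inf [1 - 1 / ((t/t50)^beta + 1)]`, used as a comparison fit: it
#' interpolates measured curves well but its coefficients carry no physical
#' meaning and require long observation to pin down `h_inf`.
#'
#' @param t_min Time, minutes (vectorised).
#' @param h_inf Final settling distance, mm.
#' @param t50 Time at half the final distance, minutes (> 0).
#' @param beta Shape exponent.
#' @return Distance in mm.
#' @export
puccini_eval <- function(t_min, h_inf, t50, beta) {
  if (t50 <= 0) abort("t50 must be positive")
  if (any(t_min < 0)) abort("time must be non-negative")
  h_inf * (1 - 1 / ((t_min / t50)^beta + 1))
}

#' Fit the sigmoidal comparison curve to a measured series
#'
#' Nonlinear least squares (Levenberg-Marquardt) over `(h_inf, t50, beta)`.
#'
#' @param curve A data frame with columns `t_min` and `h_mm` (e.g. an
#'   `esr_curve` or `westergren_series`).
#' @return A `puccini_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_puccini <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("t_min", "h_mm") %in% names(curve)))
  d <- dplyr::filter(as_tibble(curve), is.finite(.data$t_min), is.finite(.data$h_mm))
  if (nrow(d) < 4L) abort("need at least 4 points to fit the sigmoid")
  hmax <- max(d$h_mm)
  if (hmax <= 0) abort("degenerate series: no settling, half-height undefined")
  past <- d$t_min[d$h_mm >= hmax / 2 & d$t_min > 0]
  if (!length(past)) abort("no reading past half-height; cannot initialise t50")
  start <- list(h_inf = hmax, t50 = min(past), beta = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      h_mm ~ h_inf * (1 - 1 / ((t_min / t50)^beta + 1)),
      data = d, start = start,
      lower = c(h_inf = 1e-06, t50 = 1e-06, beta = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("sigmoid fit did not converge: ",
                                     conditionMessage(e))))
  est <- coef(fit)
  structure(list(h_inf = unname(est["h_inf"]), t50 = unname(est["t50"]),
                 beta = unname(est["beta"]),
                 resid_norm = sqrt(sum(stats::residuals(fit)^2)),
                 n = nrow(d), fit = fit),
            class = "puccini_fit")
}

#' @export
print.puccini_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit: h_inf = %.3f mm, t50 = %.3f min, beta = %.3f (n = %d, ||resid|| = %.3g)\n",
              x$h_inf, x$t50, x$beta, x$n, x$resid_norm))
  invisible(x)
}

#' @export
tidy.puccini_fit <- function(x, ...) {
  tibble(term = c("h_inf", "t50", "beta"),
         estimate = c(x$h_inf, x$t50, x$beta))
}

#' @export
glance.puccini_fit <- function(x, ...) {
  tibble(resid_norm = x$resid_norm, n = x$n)
}
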