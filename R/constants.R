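#' Physical constants of the sedimentation model
#'
#' Bundles the literature values used by the modified Stokes' model of
#' erythrocyte sedimentation: densities of the erythrocyte and plasma,
#' gravitational acceleration, the effective radius of a single (disaggregated)
#' erythrocyte, plasma viscosity, and the Richardson-Zaki hindered-settling
#' exponent appropriate for low-Reynolds-number suspensions.
#'
#' @param rho_e Erythrocyte density, kg/m^3.
#' @param rho_p Plasma density, kg/m^3.
#' @param g Gravitational acceleration, m/s^2.
#' @param r_ef Effective erythrocyte radius, m.
#' @param mu_p Plasma viscosity, Pa s.
#' @param n Richardson-Zaki exponent (dimensionless).
#' @return An object of class `physical_constants` (a named list).
#' @examples
#' physical_constants()
#' stokes_velocity(physical_constants(r_ef = 2 * 3.084e-06))
#' @export
physical_constants <- function(rho_e = 1100, rho_p = 1025, g = 9.81,
                               r_ef = 3.084e-06, mu_p = 1.64e-03, n = 4.65) {
  vals <- list(rho_e = rho_e, rho_p = rho_p, g = g,
               r_ef = r_ef, mu_p = mu_p, n = n)
  bad <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    abort(paste0("physical constants must be positive finite scalars; bad: ",
                 paste(bad, collapse = ", ")))
  if (rho_e <= rho_p)
    abort("rho_e must exceed rho_p for cells to settle")
  structure(vals, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (modified Stokes' sedimentation model)\n")
  cat(sprintf("  rho_e = %g kg/m^3, rho_p = %g kg/m^3, g = %g m/s^2\n",
              x$rho_e, x$rho_p, x$g))
  cat(sprintf("  r_ef = %g m, mu_p = %g Pa s, n = %g\n", x$r_ef, x$mu_p, x$n))
  cat(sprintf("  Stokes velocity: %.4g m/s (%.4g mm/min)\n",
              stokes_velocity(x), ms_to_mmmin(stokes_velocity(x))))
  invisible(x)
}

#' Calibration parameters of the rapid ESR estimation pipeline
#'
#' Holds the instrument calibration constants linking the 5-second
#' hematocrit-corrected aggregation index (HAI5) to the sedimentation model:
#' `k` corrects the aggregation index to the reference hematocrit 0.40;
#' `(a, b)` parameterise the quartic regression from HAI5 to the free
#' single-aggregate settling velocity Vs; `c` is the settling velocity with no
#' aggregation, always derived from the physical constants (Stokes' law) and
#' never fitted; `(d, e, f)` form the linear regression predicting the
#' aggregation time constant (minutes) from HAI5 and hematocrit.
#'
#' @param k Hematocrit correction factor, AI units per Ht fraction.
#' @param a Quartic coefficient, m/s per (HAI unit)^4.
#' @param b Minimum physiological HAI5 (quartic floor), dimensionless.
#' @param d Minutes per HAI unit.
#' @param e Minutes per Ht fraction.
#' @param f Intercept, minutes.
#' @param constants [physical_constants()] used to derive `c`.
#' @return An object of class `calibration_params` (named list with element
#'   `c_m_s`, the derived Stokes velocity in m/s).
#' @examples
#' calibration_params()
#' @export
calibration_params <- function(k = 0.284, a = 0.0541, b = 0.426,
                               d = -0.816, e = 0.887, f = 0.357,
                               constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  for (v in list(k = k, a = a, b = b, d = d, e = e, f = f))
    if (!(is.numeric(v) && length(v) == 1L && is.finite(v)))
      abort("calibration parameters must be finite numeric scalars")
  if (a <= 0) abort("quartic coefficient 'a' must be positive")
  if (b <= 0 || b >= 1) abort("HAI floor 'b' must lie in (0, 1)")
  structure(list(k = k, a = a, b = b, d = d, e = e, f = f,
                 c_m_s = stokes_velocity(constants),
                 constants = constants),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("ESR calibration parameters\n")
  cat(sprintf("  k = %g (AI per Ht), a = %g m/s, b = %g\n", x$k, x$a, x$b))
  cat(sprintf("  d = %g, e = %g, f = %g (lambda regression, minutes)\n",
              x$d, x$e, x$f))
  cat(sprintf("  c = %.4g m/s (Stokes velocity, derived)\n", x$c_m_s))
  invisible(x)
}

#' Read or write calibration parameters as JSON
#'
#' The JSON schema is `{k, a, b, d, e, f, constants: {rho_e, rho_p, g, r_ef,
#' mu_p, n}}`. The no-aggregation velocity `c` is recomputed from the constants
#' at load time rather than stored, so the file cannot drift out of
#' consistency with Stokes' law.
#'
#' @param path File path.
#' @param params A [calibration_params()] object (for writing).
#' @return [read_calibration()] returns a [calibration_params()] object;
#'   [write_calibration()] returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(paste0("calibration file not found: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k", "a", "b", "d", "e", "f")
  miss <- setdiff(need, names(j))
  if (length(miss))
    abort(paste0("calibration JSON missing fields: ", paste(miss, collapse = ", ")))
  cst <- if (!is.null(j$constants)) do.call(physical_constants, as.list(j$constants))
         else physical_constants()
  calibration_params(k = j$k, a = j$a, b = j$b, d = j$d, e = j$e, f = j$f,
                     constants = cst)
}

#' @rdname read_calibration
#' @export
write_calibration <- function(params, path) {
  stopifnot(inherits(params, "calibration_params"))
  out <- list(k = params$k, a = params$a, b = params$b,
              d = params$d, e = params$e, f = params$f,
              constants = unclass(params$constants))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
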