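#' Maximum angular displacement of the hands
#'
#' Energy conservation between take-off (arm horizontal, tangential speed
#' `V_H0`) and the turning point gives
#' `phi_max = asin(V_H0^2 / (2 g L_OW))`. The argument reaches 1 exactly at
#' the admissible-velocity bound `V_H0 = sqrt(2 g L_OW)`, where the hands
#' would just reach the height of the pivot (`phi_max = pi/2`).
#'
#' @param V_H0 Initial tangential hand velocity (m/s).
#' @param L_OW Hand arc radius (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return Maximum angle above the horizontal (rad), in `[0, pi/2]`.
#' @examples
#' max_hand_angle(2.5, 0.5)    # asin(6.25/9.81) = 0.6907 rad
#' @export
max_hand_angle <- function(V_H0, L_OW, g = 9.81) {
  check_velocity(V_H0, g)
  check_radius(L_OW)
  bound <- sqrt(2 * g * L_OW)
  if (V_H0 > bound)
    stop_pendupush(
      sprintf("V_H0 = %g m/s exceeds the admissible bound sqrt(2 g L_OW) = %.6f m/s (hands cannot rise past the pivot)",
              V_H0, bound),
      "pendupush_error_inadmissible_velocity")
  asin(min(1, V_H0^2 / (2 * g * L_OW)))
}

#' Pendulum flight time by singularity-regularized quadrature
#'
#' Flight time of the hands under the pendulum equation of motion
#' `phi'' = -(g / L_OW) cos(phi)` started from `phi = 0` with angular
#' velocity `omega0 = V_H0 / L_OW`. The raw period integral
#' `t_H = 2 * integral dphi / sqrt(omega0^2 - (2 g / L_OW) sin phi)` has a
#' square-root singularity at the turning point, so the substitution
#' `sin(phi) = sin(phi_max) sin^2(u)` is applied, yielding the bounded,
#' smooth integrand
#' `t_H = (4 sin(phi_max) / omega0) * integral_0^{pi/2} sin(u) /
#'  sqrt(1 - sin^2(phi_max) sin^4(u)) du`,
#' evaluated with adaptive 15-point Gauss-Kronrod quadrature
#' (`stats::integrate`, relative tolerance 1e-10, up to 1000 subdivisions).
#' The raw truncated form is never used in production.
#'
#' @param V_H0 Initial tangential hand velocity (m/s),
#'   `0 < V_H0 < sqrt(2 g L_OW)`.
#' @param L_OW Hand arc radius (m).
#' @param g Gravitational acceleration (m/s^2).
#' @param rel_tol Quadrature relative tolerance.
#' @param abs_err_max Maximum accepted reported absolute error (s) before a
#'   numeric error is raised.
#' @return A list of class `pendulum_flight`: `L_OW`, `V_H0`, `omega0`,
#'   `phi_max` (rad), `t_H` (s) and `quad_error_estimate` (s).
#' @examples
#' flight_time_quadrature(2.5, 0.5)$t_H   # 0.58298 s
#' @export
flight_time_quadrature <- function(V_H0, L_OW, g = 9.81,
                                   rel_tol = 1e-10, abs_err_max = 1e-8) {
  check_velocity(V_H0, g)
  check_radius(L_OW)
  bound <- sqrt(2 * g * L_OW)
  if (V_H0 <= 0 || V_H0 >= bound)
    stop_pendupush(
      sprintf("V_H0 = %g m/s must lie strictly inside (0, sqrt(2 g L_OW) = %.6f m/s)",
              V_H0, bound),
      "pendupush_error_inadmissible_velocity")
  omega0 <- V_H0 / L_OW
  s <- V_H0^2 / (2 * g * L_OW)      # sin(phi_max)
  q <- tryCatch(
    stats::integrate(function(u) sin(u) / sqrt(1 - s^2 * sin(u)^4),
                     0, pi / 2, rel.tol = rel_tol, subdivisions = 1000L),
    error = function(e) stop_pendupush(
      paste("flight-time quadrature failed:", conditionMessage(e)),
      "pendupush_error_numeric")
  )
  pref <- 4 * s / omega0
  err <- pref * q$abs.error
  if (err > abs_err_max)
    stop_pendupush(
      sprintf("flight-time quadrature error estimate %.3e s exceeds %.1e s",
              err, abs_err_max),
      "pendupush_error_numeric")
  structure(list(L_OW = L_OW, V_H0 = V_H0, omega0 = omega0,
                 phi_max = asin(s), t_H = pref * q$value,
                 quad_error_estimate = err),
            class = "pendulum_flight")
}

#' @export
print.pendulum_flight <- function(x, ...) {
  cat("Pendulum flight (hand-referenced)\n")
  cat(sprintf("  arc radius L_OW  = %8.4f m\n", x$L_OW))
  cat(sprintf("  take-off  V_H0   = %8.4f m/s  (omega0 = %.4f rad/s)\n",
              x$V_H0, x$omega0))
  cat(sprintf("  max angle        = %8.4f rad (%.2f deg)\n",
              x$phi_max, x$phi_max * 180 / pi))
  cat(sprintf("  flight time t_H  = %10.6f s  (quadrature error %.1e s)\n",
              x$t_H, x$quad_error_estimate))
  invisible(x)
}

#' Pendulum flight time by ODE integration with event detection
#'
#' Independent cross-check of [flight_time_quadrature()]: integrates the
#' first-order system `(phi, phi')' = (phi', -(g/L_OW) cos phi)` from
#' `(0, omega0)` with `deSolve::lsodar` (relative tolerance 1e-10, absolute
#' tolerance 1e-12), terminated by the zero-crossing event `phi = 0` with
#' `phi' < 0` (hands returning to ground level). A safety horizon of four
#' times the quadrature estimate guards against a missed event. The relative
#' drift of mechanical energy along the trajectory is reported; the flight
#' phase is conservative, so drift is a direct measure of integration error.
#'
#' @inheritParams flight_time_quadrature
#' @param rel_tol,abs_tol Solver tolerances.
#' @param n_dense Number of dense output points used for the energy-drift
#'   diagnostic.
#' @return A list of class `ode_solution`: `t_H_ode` (s) and `energy_drift`
#'   (max relative deviation of total mechanical energy from its initial
#'   value).
#' @examples
#' flight_time_ode(2.5, 0.5)$t_H_ode
#' @export
flight_time_ode <- function(V_H0, L_OW, g = 9.81,
                            rel_tol = 1e-10, abs_tol = 1e-12,
                            n_dense = 201L) {
  t_quad <- flight_time_quadrature(V_H0, L_OW, g)$t_H
  omega0 <- V_H0 / L_OW
  horizon <- 4 * t_quad
  deriv <- function(t, y, p) list(c(y[2], -(g / L_OW) * cos(y[1])))
  rootf <- function(t, y, p) y[1]
  out <- deSolve::lsodar(
    y = c(phi = 0, omega = omega0),
    times = seq(0, horizon, length.out = n_dense),
    func = deriv, parms = NULL, rootfunc = rootf,
    rtol = rel_tol, atol = abs_tol)
  troot <- attr(out, "troot")
  if (is.null(troot) || length(troot) == 0L)
    stop_pendupush(
      sprintf("no ground-return event detected before the safety horizon %.4f s", horizon),
      "pendupush_error_numeric")
  # energy per unit hand mass: E = 0.5 L^2 phi'^2 + g L sin(phi)
  E <- 0.5 * L_OW^2 * out[, "omega"]^2 + g * L_OW * sin(out[, "phi"])
  E0 <- 0.5 * L_OW^2 * omega0^2
  structure(list(t_H_ode = troot[1],
                 energy_drift = max(abs(E - E0)) / E0),
            class = "ode_solution")
}

#' Theoretical maximum pendulum flight time
#'
#' Evaluates the flight-time quadrature just below the admissible-velocity
#' bound, at `V = sqrt(2 g L_OW) - 1e-6` m/s. The period integral diverges
#' logarithmically as the turning point approaches `pi/2` (the pendulum
#' lingers near the unstable horizontal-through-pivot configuration), so
#' this value is a numerical ceiling tied to the fixed 1e-6 m/s offset, not
#' a finite physical limit.
#'
#' @param L_OW Hand arc radius (m).
#' @param g Gravitational acceleration (m/s^2).
#' @param offset Velocity offset below the bound (m/s).
#' @return Flight time (s).
#' @export
max_flight_time <- function(L_OW, g = 9.81, offset = 1e-6) {
  check_radius(L_OW)
  flight_time_quadrature(sqrt(2 * g * L_OW) - offset, L_OW, g)$t_H
}

#' Invert an observed flight time to the pendulum-consistent velocity
#'
#' Finds the unique take-off velocity whose pendulum flight time equals the
#' observed `t`, by bracketed root-finding (`stats::uniroot`) on
#' `[1e-6, V_max - 1e-6]` m/s with tolerance 1e-12 and at most 1000
#' iterations. Uniqueness follows from the strict monotonicity of the flight
#' time in the take-off velocity. Because the pendulum flight time exceeds
#' the free-fall time at any velocity, the recovered velocity is always
#' smaller than the free-fall estimate `g t / 2`.
#'
#' @param t Observed flight time (s), `0 < t < max_flight_time(L_OW)`.
#' @param L_OW Hand arc radius (m).
#' @param g Gravitational acceleration (m/s^2).
#' @param tol Root-finding tolerance (m/s).
#' @return Take-off velocity (m/s).
#' @examples
#' invert_flight_time(0.50, 0.50)   # 2.2585 m/s  (< g t / 2 = 2.4525)
#' @export
invert_flight_time <- function(t, L_OW, g = 9.81, tol = 1e-12) {
  check_radius(L_OW)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop_pendupush("flight time must be a single positive finite number",
                   "pendupush_error_domain")
  t_max <- max_flight_time(L_OW, g)
  if (t >= t_max)
    stop_pendupush(
      sprintf("flight time t = %g s is at or above the model ceiling t_max = %.4f s for L_OW = %g m",
              t, t_max, L_OW),
      "pendupush_error_out_of_range")
  V_max <- sqrt(2 * g * L_OW)
  f <- function(V) flight_time_quadrature(V, L_OW, g)$t_H - t
  r <- tryCatch(
    stats::uniroot(f, c(1e-6, V_max - 1e-6), tol = tol, maxiter = 1000L),
    error = function(e) stop_pendupush(
      paste("flight-time inversion failed:", conditionMessage(e)),
      "pendupush_error_numeric"))
  r$root
}

#' Pendulum-consistent maximum height from a measured flight time
#'
#' Two steps: invert the flight time to the pendulum-consistent take-off
#' velocity ([invert_flight_time()]), then apply the hand-referenced height
#' relation `h = V^2 / (2 g)`. The result is strictly below the free-fall
#' estimate [ff_height_from_time()] because the recovered velocity is
#' strictly below `g t / 2`.
#'
#' @inheritParams invert_flight_time
#' @return Maximum hand height (m).
#' @examples
#' pendulum_height_from_time(0.50, 0.50)   # 0.260 m vs free-fall 0.307 m
#' @export
pendulum_height_from_time <- function(t, L_OW, g = 9.81, tol = 1e-12) {
  V <- invert_flight_time(t, L_OW, g, tol)
  V^2 / (2 * g)
}

check_radius <- function(L_OW) {
  if (!is.numeric(L_OW) || length(L_OW) != 1L || !is.finite(L_OW) || L_OW <= 0)
    stop_pendupush("arc radius L_OW must be a single positive finite number",
                   "pendupush_error_domain")
  invisible(TRUE)
}
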