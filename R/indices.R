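#' Hand-referenced performance indices
#'
#' Flight-phase indices with the hands treated as the end-effector of the
#' arm of radius `L_OW`: maximum angular displacement `phi_max`, arc
#' displacement `S_hand = L_OW * phi_max`, maximum vertical hand height
#' `h_max_H = V_H0^2 / (2 g)`, the quarter-period push-off time
#' `t_push_H = (pi/2) sqrt(L_OW / g)` of the linearized (simple harmonic)
#' pendulum, and the mean mechanical power
#' `P_hand = (M_W V_H0^2 / 2) / t_push_H`.
#'
#' The quarter-period estimate is a small-amplitude approximation; when
#' `phi_max` exceeds 0.5 rad the returned `small_angle_ok` flag is `FALSE`
#' and the power value should be read as an overestimate of duration
#' validity, not silently trusted.
#'
#' @param V_H0 Take-off hand velocity (m/s), within `[0, V_H0_max]`.
#' @param geom A [derive_geometry()] object.
#' @param M_W Hand-supported mass (kg); used only for the power index.
#' @return A list of class `hand_indices`: `phi_max` (rad), `S_hand` (m),
#'   `h_max_H` (m), `t_push_H` (s), `P_hand` (W), `small_angle_ok`.
#' @examples
#' g <- derive_geometry(anthropometry(80, 44, 1.10, 0.25))
#' hand_indices(2.0, g, M_W = 44)
#' @export
hand_indices <- function(V_H0, geom, M_W) {
  stopifnot(inherits(geom, "pendulum_geometry"))
  check_velocity(V_H0, geom$g)
  if (V_H0 > geom$V_H0_max)
    stop_pendupush(
      sprintf("V_H0 = %g m/s exceeds the admissible bound sqrt(2 g L_OW) = %.6f m/s",
              V_H0, geom$V_H0_max),
      "pendupush_error_inadmissible_velocity")
  phi_max <- asin(min(1, V_H0^2 / (2 * geom$g * geom$L_OW)))
  t_push <- (pi / 2) * sqrt(geom$L_OW / geom$g)
  structure(list(
    phi_max = phi_max,
    S_hand = geom$L_OW * phi_max,
    h_max_H = V_H0^2 / (2 * geom$g),
    t_push_H = t_push,
    P_hand = (0.5 * M_W * V_H0^2) / t_push,
    small_angle_ok = phi_max <= 0.5
  ), class = "hand_indices")
}

#' Center-of-mass-referenced performance indices
#'
#' Flight-phase indices for the whole-body centre of mass, which rides the
#' effective (torque-equivalent) arm of length `L` starting from the initial
#' angle `theta0`. The rigid-body constraint ties the CoM velocity to the
#' hand velocity: `V_G0 = V_H0 * L / L_OW = V_H0 * M_W / (M cos(theta0))`.
#' Indices: `theta_max = asin(V_G0^2 / (2 g L) + sin(theta0))`, arc
#' `S_G = L (theta_max - theta0)`, height `h_max_G = V_G0^2 / (2 g)`,
#' quarter-period push-off time `t_push_G = (pi/2) sqrt(L / g)`, and mean
#' power `P_G = (M V_G0^2 / 2) / t_push_G`. Note the deliberate asymmetry:
#' hand power uses the hand-supported mass, CoM power the full body mass.
#'
#' The height ratio `h_max_G / h_max_H = (L / L_OW)^2` lies around
#' 0.26-0.39 for typical adults: the CoM rises to a substantially smaller
#' height than the hands.
#'
#' @param V_H0 Take-off hand velocity (m/s).
#' @param geom A [derive_geometry()] object.
#' @param anthro The matching [anthropometry()] object.
#' @return A list of class `com_indices`: `V_G0` (m/s), `theta_max` (rad),
#'   `S_G` (m), `h_max_G` (m), `t_push_G` (s), `P_G` (W), `small_angle_ok`.
#' @export
com_indices <- function(V_H0, geom, anthro) {
  stopifnot(inherits(geom, "pendulum_geometry"), inherits(anthro, "anthropometry"))
  check_velocity(V_H0, geom$g)
  V_G0 <- V_H0 * geom$L / geom$L_OW
  if (V_G0 > geom$V_G0_max)
    stop_pendupush(
      sprintf("implied CoM velocity V_G0 = %.4f m/s exceeds the bound sqrt(2 g L (1 - sin theta0)) = %.6f m/s",
              V_G0, geom$V_G0_max),
      "pendupush_error_inadmissible_velocity")
  theta_max <- asin(min(1, V_G0^2 / (2 * geom$g * geom$L) + sin(geom$theta0)))
  t_push <- (pi / 2) * sqrt(geom$L / geom$g)
  structure(list(
    V_G0 = V_G0,
    theta_max = theta_max,
    S_G = geom$L * (theta_max - geom$theta0),
    h_max_G = V_G0^2 / (2 * geom$g),
    t_push_G = t_push,
    P_G = (0.5 * anthro$M * V_G0^2) / t_push,
    small_angle_ok = (theta_max - geom$theta0) <= 0.5
  ), class = "com_indices")
}

#' Ratio of CoM-referenced to hand-referenced mean power
#'
#' Closed form `P_G / P_hand = (M / M_W) * (L / L_OW)^(3/2)`, algebraically
#' equal to `sqrt(M_W / M) / cos(theta0)^(3/2)`. Independent of the take-off
#' velocity, and below unity for physiological mass partitions
#' (`M_W < M`): the CoM estimate integrates a smaller effective mass moving
#' at a smaller velocity.
#'
#' @param geom A [derive_geometry()] object.
#' @param anthro The matching [anthropometry()] object.
#' @return Dimensionless power ratio.
#' @export
power_ratio <- function(geom, anthro) {
  stopifnot(inherits(geom, "pendulum_geometry"), inherits(anthro, "anthropometry"))
  sqrt(anthro$M_W / anthro$M) / cos(geom$theta0)^1.5
}

#' First-order CoM displacement under a flexion perturbation
#'
#' A small flexion angle `delta` during flight displaces the CoM off the
#' nominal pendular arc by approximately `L * cos(theta0) * delta` — a
#' first-order rigid-body perturbation estimate, useful for judging how much
#' non-rigid technique can bias the model.
#'
#' @param L Effective pendulum length (m).
#' @param theta0 Initial pendulum angle (rad).
#' @param delta Perturbation angle (rad), >= 0.
#' @return Displacement (m).
#' @examples
#' flexion_displacement(0.60, 12 * pi / 180, 5 * pi / 180)  # ~0.05 m
#' @export
flexion_displacement <- function(L, theta0, delta) {
  if (delta < 0)
    stop_pendupush("perturbation angle must be non-negative", "pendupush_error_domain")
  L * cos(theta0) * delta
}

#' Power-prediction bias implied by a flight-time overestimate
#'
#' Published flight-time regressions for ballistic push-up peak power carry
#' a flight-time coefficient of 2012.3 W/s. A relative overestimate of the
#' flight time therefore propagates to a power overestimate of
#' `2012.3 * relative_overestimate * t_flight` W (the mass term cancels in
#' the difference). This is an order-of-magnitude illustration only: the
#' regression was itself calibrated under free-fall assumptions, so the
#' calculation is inherently circular.
#'
#' @param t_flight Flight time (s), > 0.
#' @param relative_overestimate Relative flight-time overestimate
#'   (dimensionless, e.g. 0.10 for 10 percent), >= 0.
#' @return Power difference (W).
#' @examples
#' wang_power_delta(0.35, 0.10)   # ~70 W
#' @export
wang_power_delta <- function(t_flight, relative_overestimate) {
  if (t_flight <= 0)
    stop_pendupush("flight time must be positive", "pendupush_error_domain")
  if (relative_overestimate < 0)
    stop_pendupush("relative overestimate must be non-negative", "pendupush_error_domain")
  2012.3 * relative_overestimate * t_flight
}
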