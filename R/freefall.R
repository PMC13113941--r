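#' Free-fall (point-mass) flight prediction
#'
#' The conventional baseline used in flight-time scoring: the hands are
#' treated as a point mass in purely vertical ballistic motion, so
#' `t_FF = 2 V_H0 / g` and `h_FF = V_H0^2 / (2 g)`. Closed form, no
#' iteration, independent of any pendulum geometry.
#'
#' @param V_H0 Take-off velocity (m/s), >= 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return A list of class `freefall_prediction` with fields `V_H0`, `t_FF`
#'   (s) and `h_FF` (m).
#' @examples
#' ff_predict(2.5)$t_FF   # 0.5097 s
#' @export
ff_predict <- function(V_H0, g = 9.81) {
  check_velocity(V_H0, g)
  structure(list(V_H0 = V_H0, t_FF = 2 * V_H0 / g, h_FF = V_H0^2 / (2 * g)),
            class = "freefall_prediction")
}

#' Free-fall height from a measured flight time
#'
#' The standard contact-mat formula `h = g t^2 / 8`, obtained by
#' substituting `V = g t / 2` into `h = V^2 / (2 g)`.
#'
#' @param t Flight time (s), >= 0.
#' @param g Gravitational acceleration (m/s^2).
#' @return Maximum height (m).
#' @examples
#' ff_height_from_time(0.50)   # 0.3066 m
#' @export
ff_height_from_time <- function(t, g = 9.81) {
  if (!is.numeric(t) || any(t < 0) || any(!is.finite(t)))
    stop_pendupush("flight time must be non-negative and finite",
                   "pendupush_error_domain")
  g * t^2 / 8
}

check_velocity <- function(V, g) {
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V) || V < 0)
    stop_pendupush("take-off velocity must be a single non-negative finite number",
                   "pendupush_error_domain")
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop_pendupush("g must be a single positive number", "pendupush_error_domain")
  invisible(TRUE)
}
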