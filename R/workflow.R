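#' Practitioner workflow: from field measurements to corrected indices
#'
#' Implements the sequential field protocol: derive the pendulum geometry
#' from the four anthropometric measurements, invert the measured flight
#' time to the pendulum-consistent take-off velocity, and report the
#' corrected maximum hand height and hand arc displacement, together with
#' the conventional free-fall height for contrast and the relative
#' difference between the two.
#'
#' @param anthro An [anthropometry()] object.
#' @param t_flight Measured flight time (s); must be below the subject's
#'   flight-time ceiling for the derived arm radius.
#' @param g Gravitational acceleration (m/s^2).
#' @return A list of class `pushup_report` with elements `anthro`, `geom`,
#'   `t_flight`, `V_H0_P` (pendulum-consistent take-off velocity, m/s),
#'   `h_max_P` (m), `S_hand` (m), `h_FF` (free-fall contrast, m) and
#'   `relative_diff_pct` (100 (h_FF - h_P) / h_FF).
#' @examples
#' a <- anthropometry(80, 44, 1.10, 0.25)
#' practitioner_workflow(a, t_flight = 0.40)
#' @export
practitioner_workflow <- function(anthro, t_flight, g = 9.81) {
  stopifnot(inherits(anthro, "anthropometry"))
  geom <- derive_geometry(anthro, g)
  t_max <- max_flight_time(geom$L_OW, g)
  if (t_flight >= t_max)
    stop_pendupush(
      sprintf("measured flight time %g s is at or above this subject's ceiling t_max = %.4f s (L_OW = %.4f m); check the measurement",
              t_flight, t_max, geom$L_OW),
      "pendupush_error_out_of_range")
  V <- invert_flight_time(t_flight, geom$L_OW, g)
  h_P <- V^2 / (2 * g)
  h_FF <- ff_height_from_time(t_flight, g)
  structure(list(
    anthro = anthro, geom = geom, t_flight = t_flight,
    V_H0_P = V,
    h_max_P = h_P,
    S_hand = geom$L_OW * asin(min(1, h_P / geom$L_OW)),
    h_FF = h_FF,
    relative_diff_pct = 100 * (h_FF - h_P) / h_FF
  ), class = "pushup_report")
}

#' @export
print.pushup_report <- function(x, ...) {
  cat("Plyometric push-up assessment (pendulum model)\n")
  cat(sprintf("  initial angle theta0          = %7.2f deg\n",
              x$geom$theta0 * 180 / pi))
  cat(sprintf("  hand arc radius L_OW          = %7.4f m\n", x$geom$L_OW))
  cat(sprintf("  effective pendulum length L   = %7.4f m\n", x$geom$L))
  cat(sprintf("  measured flight time          = %7.4f s\n", x$t_flight))
  cat(sprintf("  pendulum take-off velocity    = %7.4f m/s\n", x$V_H0_P))
  cat(sprintf("  pendulum maximum hand height  = %7.4f m\n", x$h_max_P))
  cat(sprintf("  hand arc displacement         = %7.4f m\n", x$S_hand))
  cat(sprintf("  free-fall height (contrast)   = %7.4f m\n", x$h_FF))
  cat(sprintf("  free-fall minus pendulum      = %+6.2f %%\n",
              x$relative_diff_pct))
  invisible(x)
}

#' Default run configuration
#'
#' Houses the numerical protocol constants: gravitational acceleration,
#' quadrature/ODE/root-finding tolerances, sweep grid size and the default
#' arm-length grid.
#'
#' @return A list of class `run_config` with elements `g`, `tolerances`
#'   (`quad_rel`, `ode_rel`, `ode_abs`, `root_tol`), `grid_n`, `lengths`,
#'   `log_level`.
#' @export
default_config <- function() {
  structure(list(
    g = 9.81,
    tolerances = list(quad_rel = 1e-10, ode_rel = 1e-10,
                      ode_abs = 1e-12, root_tol = 1e-12),
    grid_n = 500L,
    lengths = default_lengths(),
    log_level = "info"
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Every numeric protocol constant can be overridden; unknown keys are
#' rejected so typos fail loudly. An empty file yields all defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list; see [default_config()].
#' @export
load_config <- function(path) {
  cfg <- default_config()
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_pendupush(paste("cannot parse config file:", conditionMessage(e)),
                   "pendupush_error_config"))
  if (is.null(raw)) return(cfg)
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop_pendupush(paste("unknown config keys:", paste(unknown, collapse = ", ")),
                   "pendupush_error_config")
  if (!is.null(raw$tolerances)) {
    bad <- setdiff(names(raw$tolerances), names(cfg$tolerances))
    if (length(bad))
      stop_pendupush(paste("unknown tolerance keys:", paste(bad, collapse = ", ")),
                     "pendupush_error_config")
    cfg$tolerances[names(raw$tolerances)] <- raw$tolerances
    raw$tolerances <- NULL
  }
  cfg[names(raw)] <- raw
  if (any(unlist(cfg$tolerances) <= 0))
    stop_pendupush("tolerances must be positive", "pendupush_error_config")
  if (cfg$g <= 0)
    stop_pendupush("g must be positive", "pendupush_error_config")
  cfg$grid_n <- as.integer(cfg$grid_n)
  cfg
}
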