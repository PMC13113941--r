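#' Anthropometric input for the pendulum model
#'
#' Bundles the four primary measurements that parameterize the push-up
#' pendulum: total body mass, the mass supported by the hands in the static
#' push-up position, the ankle-to-acromion (shoulder) length, and the
#' acromion-to-wrist (upper-limb) length. Validation is eager: physically
#' infeasible values fail here, not at first numeric use.
#'
#' @param M Total body mass (kg), > 0.
#' @param M_W Hand-supported mass (kg), measured by a scale under the hands
#'   in static equilibrium; must satisfy 0 < M_W < M.
#' @param L_OS Shoulder height (m): straight-line ankle-to-acromion distance
#'   in the static push-up position.
#' @param L_SW Upper-limb length (m): acromion-to-wrist distance with the
#'   arms perpendicular to the floor; must satisfy 0 < L_SW < L_OS.
#' @return An object of class `anthropometry`.
#' @examples
#' a <- anthropometry(M = 80, M_W = 44, L_OS = 1.10, L_SW = 0.25)
#' derive_geometry(a)
#' @export
anthropometry <- function(M, M_W, L_OS, L_SW) {
  for (nm in c("M", "M_W", "L_OS", "L_SW")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_pendupush(sprintf("'%s' must be a single finite number", nm),
                     "pendupush_error_domain")
  }
  if (M <= 0)
    stop_pendupush("total mass M must be positive", "pendupush_error_domain")
  if (M_W <= 0 || M_W >= M)
    stop_pendupush(
      sprintf("hand-supported mass M_W = %g kg must lie strictly between 0 and the total mass M = %g kg",
              M_W, M),
      "pendupush_error_mass_partition")
  if (L_SW <= 0 || L_SW >= L_OS)
    stop_pendupush(
      sprintf("upper-limb length L_SW = %g m must lie strictly between 0 and the shoulder height L_OS = %g m",
              L_SW, L_OS),
      "pendupush_error_geometry_infeasible")
  structure(list(M = M, M_W = M_W, L_OS = L_OS, L_SW = L_SW),
            class = "anthropometry")
}

#' @export
print.anthropometry <- function(x, ...) {
  cat("Anthropometry\n")
  cat(sprintf("  total mass          M    = %8.3f kg\n", x$M))
  cat(sprintf("  hand-supported mass M_W  = %8.3f kg  (M_W/M = %.3f)\n",
              x$M_W, x$M_W / x$M))
  cat(sprintf("  shoulder height     L_OS = %8.3f m\n", x$L_OS))
  cat(sprintf("  upper-limb length   L_SW = %8.3f m\n", x$L_SW))
  invisible(x)
}

#' Derive pendulum geometry from anthropometry
#'
#' Converts the four anthropometric measurements into the geometric and
#' inertial parameters of the push-up pendulum:
#' \itemize{
#'   \item initial pendulum angle `theta0 = asin(L_SW / L_OS)` (rad), the
#'     inclination of the ankle-shoulder axis above the horizontal;
#'   \item hand arc radius `L_OW = sqrt(L_OS^2 - L_SW^2)` (m), the radius of
#'     the circular path of the hands about the ankle pivot;
#'   \item effective (torque-equivalent) pendulum length
#'     `L = (M_W / M) * L_OS` (m), the ratio of gravitational torque about
#'     the pivot to total gravitational force — not the Euclidean
#'     ankle-to-CoM distance;
#'   \item Euclidean ankle-to-CoM distance `d_OG = L * cos(theta0)` (m);
#'   \item admissible take-off velocity bounds
#'     `V_H0_max = sqrt(2 g L_OW)` (hands just reaching pivot height) and
#'     `V_G0_max = sqrt(2 g L (1 - sin(theta0)))` (CoM just reaching the
#'     vertical through the pivot).
#' }
#'
#' @param anthro An [anthropometry()] object.
#' @param g Gravitational acceleration (m/s^2). Default 9.81.
#' @return An object of class `pendulum_geometry`: a list with fields
#'   `theta0`, `L_OW`, `L`, `d_OG`, `V_H0_max`, `V_G0_max`, `g`.
#' @examples
#' g <- derive_geometry(anthropometry(80, 44, 1.10, 0.25))
#' g$L        # (44/80) * 1.10 = 0.605 m
#' @export
derive_geometry <- function(anthro, g = 9.81) {
  stopifnot(inherits(anthro, "anthropometry"))
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop_pendupush("g must be a single positive number", "pendupush_error_domain")
  theta0 <- asin(anthro$L_SW / anthro$L_OS)
  L_OW <- sqrt(anthro$L_OS^2 - anthro$L_SW^2)
  L <- (anthro$M_W / anthro$M) * anthro$L_OS
  structure(list(
    theta0 = theta0,
    L_OW = L_OW,
    L = L,
    d_OG = L * cos(theta0),
    V_H0_max = sqrt(2 * g * L_OW),
    V_G0_max = sqrt(2 * g * L * (1 - sin(theta0))),
    g = g
  ), class = "pendulum_geometry")
}

#' @export
print.pendulum_geometry <- function(x, ...) {
  cat("Pendulum geometry\n")
  cat(sprintf("  initial angle        theta0   = %8.4f rad (%.2f deg)\n",
              x$theta0, x$theta0 * 180 / pi))
  cat(sprintf("  hand arc radius      L_OW     = %8.4f m\n", x$L_OW))
  cat(sprintf("  effective length     L        = %8.4f m\n", x$L))
  cat(sprintf("  ankle-CoM distance   d_OG     = %8.4f m\n", x$d_OG))
  cat(sprintf("  hand velocity bound  V_H0_max = %8.4f m/s\n", x$V_H0_max))
  cat(sprintf("  CoM velocity bound   V_G0_max = %8.4f m/s\n", x$V_G0_max))
  cat(sprintf("  gravitational accel. g        = %8.4f m/s^2\n", x$g))
  invisible(x)
}

#' Equivalent length of a compound pendulum
#'
#' Static distributed-mass correction to the simple-pendulum length:
#' `L_eq = I_O / (M * L_CoM)`. By the parallel-axis theorem
#' `I_O >= M * L_CoM^2`, so `L_eq >= L_CoM`, with equality for a point mass.
#' For a uniform rod pivoted at one end, `L_eq = 2/3` of the rod length,
#' i.e. `L_eq / L_CoM = 4/3`.
#'
#' Only this static formula is provided; the compound-pendulum equation of
#' motion is out of scope.
#'
#' @param I_O Moment of inertia about the pivot (kg m^2).
#' @param M Mass (kg).
#' @param L_CoM Pivot-to-CoM distance (m).
#' @return Equivalent simple-pendulum length (m).
#' @examples
#' compound_equivalent_length(I_O = 80 * 0.6^2, M = 80, L_CoM = 0.6)  # 0.6
#' @export
compound_equivalent_length <- function(I_O, M, L_CoM) {
  if (any(c(I_O, M, L_CoM) <= 0) || !all(is.finite(c(I_O, M, L_CoM))))
    stop_pendupush("I_O, M and L_CoM must all be positive and finite",
                   "pendupush_error_domain")
  if (I_O < M * L_CoM^2 * (1 - 1e-12))
    stop_pendupush(
      sprintf("I_O = %g kg m^2 is below the parallel-axis lower bound M*L_CoM^2 = %g kg m^2",
              I_O, M * L_CoM^2),
      "pendupush_error_inconsistent_inertia")
  I_O / (M * L_CoM)
}

#' Generate synthetic anthropometric profiles
#'
#' Draws reproducible synthetic subjects spanning the admissible parameter
#' space of the model: hand arc radius L_OW uniform on \[0.50, 2.00\] m,
#' hand-supported mass fraction M_W/M uniform on \[0.50, 0.60\], initial
#' pendulum angle uniform on \[10, 16\] degrees, and total mass uniform on
#' \[55, 100\] kg. The measured lengths are back-solved so every profile
#' satisfies the [anthropometry()] invariants exactly. These are synthetic
#' study conditions, not measured subjects.
#'
#' @param n Number of profiles (>= 0).
#' @param seed Integer seed; mandatory, same seed gives the identical
#'   sequence. The global RNG state is left untouched.
#' @return A data.frame with columns `M`, `M_W`, `L_OS`, `L_SW` (one row per
#'   profile). Use [anthropometry()] on a row to get a validated object.
#' @examples
#' p <- sample_profiles(5, seed = 1)
#' derive_geometry(anthropometry(p$M[1], p$M_W[1], p$L_OS[1], p$L_SW[1]))
#' @export
sample_profiles <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n))
    stop_pendupush("n must be a non-negative integer", "pendupush_error_domain")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop_pendupush("an integer 'seed' is required", "pendupush_error_domain")
  n <- as.integer(n)
  if (n == 0L)
    return(data.frame(M = numeric(0), M_W = numeric(0),
                      L_OS = numeric(0), L_SW = numeric(0)))
  with_preserved_seed(seed, {
    theta0 <- runif(n, 10, 16) * pi / 180
    L_OW <- runif(n, 0.50, 2.00)
    ratio <- runif(n, 0.50, 0.60)
    M <- runif(n, 55, 100)
    L_OS <- L_OW / cos(theta0)
    data.frame(M = M, M_W = ratio * M, L_OS = L_OS,
               L_SW = L_OS * sin(theta0))
  })
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Classed errors so callers and tests can distinguish domain violations
# from numerical failures.
stop_pendupush <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pendupush_error")))
}
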