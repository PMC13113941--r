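#' Default arm-length grid for the sweep campaigns
#'
#' Seven hand arc radii spanning the anthropometrically relevant range,
#' 0.50 m to 2.00 m in 0.25 m steps.
#' @return Numeric vector of lengths (m).
#' @export
default_lengths <- function() seq(0.50, 2.00, by = 0.25)

# Uniformly spaced grid on [eps, upper): x_i = eps + (i-1) (upper - eps) / n.
open_grid <- function(eps, upper, n) eps + (seq_len(n) - 1) * (upper - eps) / n

#' Flight-time comparison sweep (velocity campaign)
#'
#' For each arm length, builds a uniform grid of take-off velocities on
#' `[1e-4, sqrt(2 g L_OW))` (open upper endpoint) and computes free-fall and
#' pendulum flight times, their difference `delta = t_FF - t_H`, and the
#' relative difference in percent. Under this model the pendulum flight
#' time exceeds the free-fall time at every admissible velocity, so `delta`
#' is negative throughout: the free-fall baseline *understates* flight time
#' at fixed take-off velocity. Rows with take-off velocity above 3.0 m/s
#' are flagged as outside the physiologically reported range (flagged, not
#' removed).
#'
#' @param lengths Arm lengths (m). Default [default_lengths()].
#' @param grid_n Grid points per length (>= 2). Default 500.
#' @param g Gravitational acceleration (m/s^2).
#' @param cross_validate If `TRUE`, additionally run the ODE event solver at
#'   every grid point and record the maximum absolute quadrature-ODE
#'   discrepancy in the `max_quad_ode_discrepancy` attribute.
#' @param eps Grid lower bound (m/s).
#' @return A long-format data.frame of class `sweep_table` with columns
#'   `campaign`, `L_OW_m`, `input_name`, `input_value`, `freefall_value`,
#'   `pendulum_value`, `delta`, `relative_delta_pct`, `physiological_flag`,
#'   and attributes `campaign`, `grid_n`, `g`, `n_failed`, and (when
#'   cross-validating) `max_quad_ode_discrepancy`.
#' @examples
#' s <- sweep_flight_time(lengths = c(0.5, 1.0), grid_n = 25)
#' head(s)
#' @export
sweep_flight_time <- function(lengths = default_lengths(), grid_n = 500L,
                              g = 9.81, cross_validate = FALSE, eps = 1e-4) {
  stopifnot(grid_n >= 2, all(lengths > 0))
  rows <- lapply(lengths, function(L) {
    V <- open_grid(eps, sqrt(2 * g * L), grid_n)
    t_H <- vapply(V, function(v) {
      tryCatch(flight_time_quadrature(v, L, g)$t_H, error = function(e) NA_real_)
    }, numeric(1))
    ode_gap <- if (cross_validate) {
      vapply(V, function(v) {
        tryCatch(flight_time_ode(v, L, g)$t_H_ode, error = function(e) NA_real_)
      }, numeric(1)) - t_H
    } else rep(NA_real_, grid_n)
    t_FF <- 2 * V / g
    data.frame(campaign = "flight-time", L_OW_m = L, input_name = "V_H0",
               input_value = V, freefall_value = t_FF, pendulum_value = t_H,
               delta = t_FF - t_H,
               relative_delta_pct = 100 * (t_FF - t_H) / t_FF,
               physiological_flag = V > 3.0,
               .ode_gap = ode_gap)
  })
  tab <- do.call(rbind, rows)
  out <- tab[setdiff(names(tab), ".ode_gap")]
  attr(out, "campaign") <- "flight-time"
  attr(out, "grid_n") <- as.integer(grid_n)
  attr(out, "g") <- g
  attr(out, "n_failed") <- sum(is.na(tab$pendulum_value))
  if (cross_validate)
    attr(out, "max_quad_ode_discrepancy") <- max(abs(tab$.ode_gap), na.rm = TRUE)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Maximum-height comparison sweep (flight-time campaign)
#'
#' For each arm length, builds a uniform grid of observed flight times on
#' `[1e-4, max_flight_time(L_OW))` and computes the free-fall height
#' `g t^2 / 8`, the pendulum height via flight-time inversion, their
#' difference `delta = h_FF - h_P` (positive throughout: the free-fall
#' formula overstates height at fixed flight time) and the relative
#' difference in percent. Rows with flight time above 0.60 s are flagged as
#' outside the physiologically reported range.
#'
#' @inheritParams sweep_flight_time
#' @param eps Grid lower bound (s).
#' @return A `sweep_table` data.frame; see [sweep_flight_time()].
#' @export
sweep_height <- function(lengths = default_lengths(), grid_n = 500L,
                         g = 9.81, eps = 1e-4) {
  stopifnot(grid_n >= 2, all(lengths > 0))
  rows <- lapply(lengths, function(L) {
    t_grid <- open_grid(eps, max_flight_time(L, g), grid_n)
    h_P <- vapply(t_grid, function(t) {
      tryCatch(pendulum_height_from_time(t, L, g), error = function(e) NA_real_)
    }, numeric(1))
    h_FF <- g * t_grid^2 / 8
    data.frame(campaign = "height", L_OW_m = L, input_name = "t_flight",
               input_value = t_grid, freefall_value = h_FF,
               pendulum_value = h_P, delta = h_FF - h_P,
               relative_delta_pct = 100 * (h_FF - h_P) / h_FF,
               physiological_flag = t_grid > 0.60)
  })
  out <- do.call(rbind, rows)
  attr(out, "campaign") <- "height"
  attr(out, "grid_n") <- as.integer(grid_n)
  attr(out, "g") <- g
  attr(out, "n_failed") <- sum(is.na(out$pendulum_value))
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Admissible-velocity bounds and flight-time ceilings per arm length
#'
#' For each arm length reports the admissible take-off velocity bound
#' `V_H0_max = sqrt(2 g L_OW)` and the flight-time ceiling evaluated just
#' below it ([max_flight_time()]).
#'
#' @inheritParams sweep_flight_time
#' @return A data.frame with columns `L_OW_m`, `V_H0_max`, `t_H_max`.
#' @export
max_flight_time_table <- function(lengths = default_lengths(), g = 9.81) {
  stopifnot(all(lengths > 0))
  data.frame(
    L_OW_m = lengths,
    V_H0_max = sqrt(2 * g * lengths),
    t_H_max = vapply(lengths, max_flight_time, numeric(1), g = g))
}

#' Golden-table comparison against reference rows
#'
#' Compares model output at specified `(arm length, input)` pairs against a
#' reference table of expected values, after rounding absolute quantities to
#' `digits_abs` decimals and percentages to `digits_pct` decimals. Values
#' are recomputed at the exact reference inputs (a sweep grid generally does
#' not contain them); a `sweep_table` may be supplied to reuse its campaign
#' type and gravitational constant.
#'
#' @param reference A data.frame with columns `L_OW_m`, `input_value`,
#'   `freefall_value`, `pendulum_value`, `delta`, `relative_delta_pct`.
#' @param campaign Either `"flight-time"` (inputs are velocities) or
#'   `"height"` (inputs are flight times).
#' @param table Optional `sweep_table`; if given, its `campaign` and `g`
#'   attributes override the arguments.
#' @param g Gravitational acceleration (m/s^2).
#' @param digits_abs,digits_pct Rounding applied before comparison.
#' @return A data.frame echoing the reference with computed (full-precision)
#'   columns, per-cell match indicators and an `all_match` column; empty
#'   reference gives an empty report.
#' @export
report_printed_rows <- function(reference, campaign = c("flight-time", "height"),
                                table = NULL, g = 9.81,
                                digits_abs = 3, digits_pct = 2) {
  campaign <- match.arg(campaign)
  if (!is.null(table)) {
    stopifnot(inherits(table, "sweep_table"))
    campaign <- attr(table, "campaign")
    g <- attr(table, "g")
  }
  needed <- c("L_OW_m", "input_value", "freefall_value", "pendulum_value",
              "delta", "relative_delta_pct")
  stopifnot(all(needed %in% names(reference)))
  if (nrow(reference) == 0L) {
    out <- reference
    out$all_match <- logical(0)
    return(out)
  }
  comp <- lapply(seq_len(nrow(reference)), function(i) {
    L <- reference$L_OW_m[i]; x <- reference$input_value[i]
    if (campaign == "flight-time") {
      ff <- 2 * x / g
      pe <- flight_time_quadrature(x, L, g)$t_H
    } else {
      ff <- g * x^2 / 8
      pe <- pendulum_height_from_time(x, L, g)
    }
    c(ff = ff, pe = pe)
  })
  comp <- do.call(rbind, comp)
  out <- reference
  out$computed_freefall <- comp[, "ff"]
  out$computed_pendulum <- comp[, "pe"]
  out$computed_delta <- comp[, "ff"] - comp[, "pe"]
  out$computed_relative_pct <- 100 * out$computed_delta / comp[, "ff"]
  out$match_freefall <- round(comp[, "ff"], digits_abs) == round(reference$freefall_value, digits_abs)
  out$match_pendulum <- round(comp[, "pe"], digits_abs) == round(reference$pendulum_value, digits_abs)
  out$match_delta <- round(out$computed_delta, digits_abs) == round(reference$delta, digits_abs)
  out$match_relative <- abs(out$computed_relative_pct - reference$relative_delta_pct) <= 0.05
  out$all_match <- out$match_freefall & out$match_pendulum &
    out$match_delta & out$match_relative
  out
}

#' Two-panel comparison plot for a sweep table
#'
#' Values (free-fall solid, pendulum dashed) in the upper panel and the
#' free-fall-minus-pendulum difference in the lower panel, one curve per arm
#' length. Requires ggplot2.
#'
#' @param table A `sweep_table`.
#' @return A patchwork-free list of two ggplot objects (`values`, `delta`).
#' @export
plot_sweep <- function(table) {
  stopifnot(inherits(table, "sweep_table"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_pendupush("ggplot2 is required for plotting", "pendupush_error_domain")
  xlab <- if (attr(table, "campaign") == "flight-time")
    "take-off velocity (m/s)" else "flight time (s)"
  ylab <- if (attr(table, "campaign") == "flight-time")
    "flight time (s)" else "maximum height (m)"
  tab <- as.data.frame(table)
  tab$L_OW <- factor(tab$L_OW_m)
  p1 <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$input_value, colour = .data$L_OW)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$freefall_value), linetype = "solid") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pendulum_value), linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab, colour = "L_OW (m)") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$input_value, y = .data$delta,
                                          colour = .data$L_OW)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "free-fall minus pendulum", colour = "L_OW (m)") +
    ggplot2::theme_minimal()
  list(values = p1, delta = p2)
}

#' Write a sweep table to CSV
#'
#' Long/tidy format, one row per grid point, `.` decimal radix regardless of
#' locale.
#'
#' @param table A `sweep_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, path) {
  stopifnot(inherits(table, "sweep_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
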