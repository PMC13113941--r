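# Independent oracles kept deliberately separate from the production path.

# Raw pendulum period integral truncated just below the turning-point
# singularity; production code never evaluates this form.
raw_flight_time <- function(V_H0, L_OW, g = 9.81, trunc = 1e-10) {
  omega0 <- V_H0 / L_OW
  phi_max <- asin(V_H0^2 / (2 * g * L_OW))
  f <- function(phi) 1 / sqrt(omega0^2 - (2 * g / L_OW) * sin(phi))
  2 * stats::integrate(f, 0, phi_max - trunc, rel.tol = 1e-10,
                       subdivisions = 1000L)$value
}

# Turning time of the pendulum (first zero of the angular velocity) via an
# ODE root independent of the quadrature path.
ode_turning_time <- function(V_H0, L_OW, g = 9.81) {
  deriv <- function(t, y, p) list(c(y[2], -(g / L_OW) * cos(y[1])))
  rootf <- function(t, y, p) y[2]
  out <- deSolve::lsodar(c(phi = 0, omega = V_H0 / L_OW),
                         times = c(0, 10), func = deriv, parms = NULL,
                         rootfunc = rootf, rtol = 1e-10, atol = 1e-12)
  attr(out, "troot")[1]
}

profile_geometries <- function(n, seed) {
  p <- sample_profiles(n, seed)
  lapply(seq_len(nrow(p)), function(i) {
    a <- anthropometry(p$M[i], p$M_W[i], p$L_OS[i], p$L_SW[i])
    list(anthro = a, geom = derive_geometry(a))
  })
}
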