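# Frozen expected values below were computed with the raw truncated period
# integral and cross-checked against an external adaptive ODE solver before
# being frozen; quadrature error estimates are < 1e-10 s at every point.

test_that("maximum hand angle follows energy conservation", {
  expect_equal(max_hand_angle(0, 1), 0)
  expect_equal(max_hand_angle(sqrt(2 * 9.81 * 0.8), 0.8), pi / 2)
  expect_equal(max_hand_angle(2.5, 0.5), asin(6.25 / 9.81))
  expect_equal(max_hand_angle(2.5, 0.5), 0.6907, tolerance = 1e-4)
  expect_error(max_hand_angle(10, 0.5),
               class = "pendupush_error_inadmissible_velocity")
  expect_error(max_hand_angle(10, 0.5), "3.132",
               info = "error names the admissible bound")
})

test_that("regularized quadrature matches the raw truncated integral", {
  for (p in list(c(0.5, 0.5), c(1.5, 0.5), c(2.5, 0.5), c(3.0, 1.0), c(4.0, 2.0))) {
    q <- flight_time_quadrature(p[1], p[2])
    expect_equal(q$t_H, raw_flight_time(p[1], p[2]), tolerance = 1e-4)
    expect_lte(q$quad_error_estimate, 1e-8)
    expect_equal(q$omega0, p[1] / p[2])
    expect_gte(q$phi_max, 0); expect_lte(q$phi_max, pi / 2)
  }
})

test_that("quadrature reproduces frozen reference flight times", {
  expect_equal(flight_time_quadrature(2.5, 0.5)$t_H, 0.5829848933, tolerance = 1e-8)
  expect_equal(flight_time_quadrature(3.0, 1.0)$t_H, 0.6507924401, tolerance = 1e-8)
  expect_equal(flight_time_quadrature(0.5, 2.0)$t_H, 0.1019379026, tolerance = 1e-8)
})

test_that("pendulum flight time exceeds free fall and converges to it at low speed", {
  # tangential gravity g cos(phi) <= g, so the pendulum decelerates less
  # than a free-falling point and stays aloft longer
  for (L in c(0.5, 1.0, 2.0))
    for (V in c(0.2, 1.0, 2.0) * sqrt(L)) {
      gap <- flight_time_quadrature(V, L)$t_H - 2 * V / 9.81
      expect_gt(gap, 0)
    }
  # asymptotic convergence as V -> 0
  r <- flight_time_quadrature(1e-3, 1.0)$t_H / (2 * 1e-3 / 9.81)
  expect_gt(r, 0.999)
  expect_lt(r, 1.001)
  r4 <- flight_time_quadrature(1e-4, 0.5)$t_H / (2 * 1e-4 / 9.81)
  expect_equal(r4, 1, tolerance = 1e-3)
})

test_that("flight time is strictly increasing in take-off velocity", {
  for (L in c(0.5, 1.25, 2.0)) {
    V <- seq(0.05, 0.98, length.out = 40) * sqrt(2 * 9.81 * L)
    t <- vapply(V, function(v) flight_time_quadrature(v, L)$t_H, numeric(1))
    expect_true(all(diff(t) > 0))
  }
})

test_that("inadmissible velocities are rejected by the quadrature", {
  expect_error(flight_time_quadrature(0, 1), class = "pendupush_error_inadmissible_velocity")
  expect_error(flight_time_quadrature(sqrt(2 * 9.81), 1),
               class = "pendupush_error_inadmissible_velocity")
})

test_that("ODE event solution agrees with the quadrature", {
  for (p in list(c(2.5, 0.5), c(3.0, 1.0), c(1.0, 1.5))) {
    q <- flight_time_quadrature(p[1], p[2])
    o <- flight_time_ode(p[1], p[2])
    expect_lt(abs(o$t_H_ode - q$t_H), 2.5e-7)
    expect_lte(o$energy_drift, 1e-8)
  }
})

test_that("ODE trajectory is time-reversal symmetric about the turning point", {
  t_full <- flight_time_ode(2.5, 0.5)$t_H_ode
  t_turn <- ode_turning_time(2.5, 0.5)
  expect_lt(abs(t_turn - t_full / 2), 1e-7)
})

test_that("flight-time ceiling scales as the square root of the arm radius", {
  t1 <- max_flight_time(0.5)
  t2 <- max_flight_time(2.0)
  # period scaling t ~ sqrt(L/g); the fixed 1e-6 m/s boundary offset breaks
  # exactness only logarithmically
  expect_equal(t2 / t1, 2, tolerance = 0.05)
  expect_gt(max_flight_time(1.0), t1)
})

test_that("flight-time inversion is a tight round trip", {
  for (p in list(c(1.2, 0.5), c(2.5, 0.5), c(3.0, 1.0), c(2.0, 2.0))) {
    t <- flight_time_quadrature(p[1], p[2])$t_H
    expect_equal(invert_flight_time(t, p[2]), p[1], tolerance = 1e-6)
  }
})

test_that("inverted velocity lies below the free-fall estimate", {
  for (p in list(c(0.30, 0.5), c(0.50, 0.5), c(0.60, 1.0), c(0.90, 2.0))) {
    V <- invert_flight_time(p[1], p[2])
    expect_lt(V, 9.81 * p[1] / 2)
    expect_gt(V, 0)
  }
  # continuity at the degenerate boundary: t -> 0+ gives V -> 0+
  expect_lt(invert_flight_time(1e-3, 1.0), 0.01)
})

test_that("inversion rejects flight times outside the admissible window", {
  expect_error(invert_flight_time(100, 0.5), class = "pendupush_error_out_of_range")
  expect_error(invert_flight_time(100, 0.5), "t_max")
  expect_error(invert_flight_time(0, 0.5), class = "pendupush_error_domain")
})

test_that("pendulum height from time reproduces frozen inversions and sits below free fall", {
  expect_equal(pendulum_height_from_time(0.50, 0.50), 0.2599791700, tolerance = 1e-7)
  expect_equal(pendulum_height_from_time(0.30, 0.50), 0.1076137722, tolerance = 1e-7)
  expect_equal(pendulum_height_from_time(0.60, 1.00), 0.4022115050, tolerance = 1e-7)
  for (p in list(c(0.30, 0.5), c(0.50, 0.5), c(0.60, 1.0)))
    expect_lt(pendulum_height_from_time(p[1], p[2]), ff_height_from_time(p[1]))
})
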