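mk <- function(M = 80, ratio = 0.55, L_OS = 1.10, theta_deg = 12) {
  th <- theta_deg * pi / 180
  a <- anthropometry(M, ratio * M, L_OS, L_OS * sin(th))
  list(anthro = a, geom = derive_geometry(a))
}

test_that("hand indices follow the closed forms", {
  s <- mk()
  z <- hand_indices(0, s$geom, s$anthro$M_W)
  expect_equal(z$phi_max, 0); expect_equal(z$S_hand, 0)
  expect_equal(z$h_max_H, 0); expect_equal(z$P_hand, 0)

  h <- hand_indices(2.0, s$geom, s$anthro$M_W)
  expect_equal(h$phi_max, asin(4 / (2 * 9.81 * s$geom$L_OW)))
  expect_equal(h$S_hand, s$geom$L_OW * h$phi_max)
  expect_equal(h$h_max_H, 4 / (2 * 9.81))
  expect_equal(h$t_push_H, (pi / 2) * sqrt(s$geom$L_OW / 9.81))
  expect_equal(h$P_hand, 0.5 * s$anthro$M_W * 4 / h$t_push_H)
  expect_error(hand_indices(s$geom$V_H0_max + 0.1, s$geom, s$anthro$M_W),
               class = "pendupush_error_inadmissible_velocity")
})

test_that("quarter-period push-off time and power match a worked unit-radius case", {
  # L_OW = 1 m, M_W = 44 kg, V = 2.5 m/s
  th <- 12 * pi / 180
  a <- anthropometry(80, 44, 1 / cos(th), tan(th))
  ge <- derive_geometry(a)
  expect_equal(ge$L_OW, 1)
  h <- hand_indices(2.5, ge, 44)
  expect_equal(h$t_push_H, 0.5015, tolerance = 1e-4)
  expect_equal(h$P_hand, 274.2, tolerance = 1e-3)
})

test_that("small-angle validity flag trips above half a radian of amplitude", {
  s <- mk()
  V_small <- sqrt(2 * 9.81 * s$geom$L_OW * sin(0.4))
  V_big <- sqrt(2 * 9.81 * s$geom$L_OW * sin(0.6))
  expect_true(hand_indices(V_small, s$geom, s$anthro$M_W)$small_angle_ok)
  expect_false(hand_indices(V_big, s$geom, s$anthro$M_W)$small_angle_ok)
})

test_that("CoM indices follow the rigid-body velocity coupling", {
  s <- mk(ratio = 0.55, theta_deg = 12)
  z <- com_indices(0, s$geom, s$anthro)
  expect_equal(z$theta_max, s$geom$theta0)
  expect_equal(z$S_G, 0); expect_equal(z$h_max_G, 0)

  c1 <- com_indices(1.5, s$geom, s$anthro)
  expect_equal(c1$V_G0 / 1.5, 0.55 / cos(12 * pi / 180))
  expect_equal(c1$V_G0 / 1.5, 0.562, tolerance = 1e-3)
  expect_equal(c1$theta_max,
               asin(c1$V_G0^2 / (2 * 9.81 * s$geom$L) + sin(s$geom$theta0)))
  expect_equal(c1$S_G, s$geom$L * (c1$theta_max - s$geom$theta0))
  expect_equal(c1$h_max_G, c1$V_G0^2 / (2 * 9.81))
  expect_equal(c1$t_push_G, (pi / 2) * sqrt(s$geom$L / 9.81))
  expect_error(com_indices(50, s$geom, s$anthro),
               class = "pendupush_error_inadmissible_velocity")
})

test_that("CoM height is the squared length-ratio fraction of hand height", {
  for (cfg in list(c(0.50, 10), c(0.55, 12), c(0.60, 15))) {
    s <- mk(ratio = cfg[1], theta_deg = cfg[2])
    h <- hand_indices(1.2, s$geom, s$anthro$M_W)
    cm <- com_indices(1.2, s$geom, s$anthro)
    expect_equal(cm$h_max_G / h$h_max_H, (s$geom$L / s$geom$L_OW)^2)
    expect_lt(cm$h_max_G, h$h_max_H)   # M_W < M cos(theta0) here
  }
  # the squared ratio band for typical adults
  lo <- (0.50 / cos(10 * pi / 180))^2
  hi <- (0.60 / cos(15 * pi / 180))^2
  expect_gt(lo, 0.25); expect_lt(hi, 0.39)
})

test_that("power ratio closed form equals the quotient of the two power indices", {
  for (cfg in list(c(0.50, 10), c(0.55, 12), c(0.60, 15))) {
    s <- mk(ratio = cfg[1], theta_deg = cfg[2])
    pr <- power_ratio(s$geom, s$anthro)
    for (V in c(0.5, 1.0, 1.6)) {
      h <- hand_indices(V, s$geom, s$anthro$M_W)
      cm <- com_indices(V, s$geom, s$anthro)
      expect_equal(pr, cm$P_G / h$P_hand, tolerance = 1e-12)
    }
    # equivalent (M/M_W) (L/L_OW)^1.5 form
    expect_equal(pr, (s$anthro$M / s$anthro$M_W) *
                   (s$geom$L / s$geom$L_OW)^1.5, tolerance = 1e-12)
    expect_lt(pr, 1)
  }
  # degenerate identity: M_W -> M, theta0 -> 0 gives ratio -> 1
  a <- anthropometry(80, 80 - 1e-9, 1.10, 1e-9)
  expect_equal(power_ratio(derive_geometry(a), a), 1, tolerance = 1e-6)
})

test_that("arc displacement dominates vertical rise over the profile sample", {
  for (s in profile_geometries(50, seed = 11)) {
    V <- 0.8 * s$geom$V_H0_max
    h <- hand_indices(V, s$geom, s$anthro$M_W)
    expect_gte(h$S_hand, h$h_max_H)   # L phi >= L sin(phi)
  }
})

test_that("flexion perturbation displacement is first-order in the angle", {
  expect_lt(abs(flexion_displacement(0.60, 12 * pi / 180, 5 * pi / 180) - 0.05),
            0.005)
  expect_equal(flexion_displacement(0.60, 12 * pi / 180, 0), 0)
  expect_equal(flexion_displacement(1, 0, 1), 1)
  expect_error(flexion_displacement(0.6, 0.2, -0.1), class = "pendupush_error_domain")
})

test_that("regression-based power bias is linear in the overestimate", {
  expect_equal(wang_power_delta(0.35, 0.10), 70, tolerance = 1)
  expect_equal(wang_power_delta(0.35, 0), 0)
  expect_equal(wang_power_delta(0.35, 0.01), 7.04, tolerance = 0.01)
  expect_equal(wang_power_delta(0.35, 0.10) / wang_power_delta(0.35, 0.01), 10)
})
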