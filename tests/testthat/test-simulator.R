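test_that("vertical organ is a fixed point", {
  p <- tropic_params(beta = 2, gamma = 1, nu = 0, A0 = 0)
  kin <- simulate_tropism("AC", p, t_end = 2, n_nodes = 51)
  expect_true(all(kin$A == 0))
  expect_true(all(kin$C == 0))
})

test_that("AaC trajectory matches the closed-form transient", {
  p <- tropic_params(beta = 0, gamma = 1, nu = 4, A0 = 0.5, A_P = 0)
  Tc <- derived_numbers(p)$T_c
  kin <- simulate_tropism("AaC", p, t_end = 3 * Tc, dt = Tc / 100,
                          output_every = 10)
  an <- aac_transient(p, kin$s, kin$t)
  expect_lt(max(abs(kin$A - an$angle)) / max(abs(an$angle)), 1e-4)
  expect_lt(max(abs(kin$C - an$curvature)) / max(abs(an$curvature)), 1e-4)
})

test_that("RK4 agrees with the exact matrix-exponential stepper", {
  for (v in c("AC", "ARaC")) {
    p <- params_for_variant(v, 3)
    k1 <- simulate_tropism(v, p, t_end = 4, n_nodes = 101)
    k2 <- simulate_tropism(v, p, t_end = 4, n_nodes = 101, method = "expm")
    expect_lt(max(abs(k1$A - k2$A)), 1e-8)
  }
})

test_that("halving the time step shrinks the error at RK4 order", {
  p <- full_params()
  ref <- simulate_tropism("ARC", p, t_end = 2, n_nodes = 41,
                          method = "expm", dt = 0.08)
  e <- sapply(c(0.08, 0.04), function(dd) {
    k <- simulate_tropism("ARC", p, t_end = 2, n_nodes = 41, dt = dd,
                          output_every = 1e6)
    max(abs(k$A[, ncol(k$A)] - ref$A[, ncol(ref$A)]))
  })
  expect_gt(e[1] / e[2], 4)
})

test_that("simulation converges to the closed-form steady state", {
  for (Bp in c(0.5, 6)) {
    for (v in c("AC", "AaC", "ARC", "ARaC")) {
      p <- params_for_variant(v, Bp)
      kin <- simulate_tropism(v, p, t_end = 30, n_nodes = 151)
      ss <- steady_state(v, p, kin$s)
      expect_lt(max(abs(kin$A[, ncol(kin$A)] - ss$angle)), 1e-3)
    }
  }
})

test_that("mirroring the cues mirrors the whole trajectory bitwise", {
  p <- full_params()
  for (v in c("AC", "AaC", "ARC", "ARaC")) {
    k1 <- simulate_tropism(v, p, t_end = 3, n_nodes = 81)
    k2 <- simulate_tropism(v, symmetry_transform(p), t_end = 3, n_nodes = 81)
    expect_identical(k1$A, -k2$A)
    expect_identical(k1$C, -k2$C)
  }
})

test_that("ARC trajectory is the rotated AC trajectory, step-wise", {
  p <- full_params()
  A_R <- derived_numbers(p)$A_R
  kARC <- simulate_tropism("ARC", p, t_end = 3, dt = 0.01, n_nodes = 101,
                           output_every = 1)
  pAC <- tropic_params(beta = p$beta + p$nu, gamma = p$gamma, nu = 0,
                       A0 = p$A0 - A_R)
  kAC <- simulate_tropism("AC", pAC, t_end = 3, dt = 0.01, n_nodes = 101,
                          output_every = 1)
  expect_lt(max(abs(kARC$A - (kAC$A + A_R))), 1e-12)
  expect_lt(max(abs(kARC$C - kAC$C)), 1e-12)
})

test_that("apical photoception keeps the organ an arc of a circle", {
  p <- tropic_params(beta = 0, gamma = 1, nu = 4, A0 = 0.5, A_P = 0)
  kin <- simulate_tropism("AaC", p, t_end = 2, n_nodes = 101)
  cv <- apply(kin$C, 2, function(col) {
    if (stats::sd(col) == 0) 0 else stats::sd(col) / abs(mean(col))
  })
  expect_true(all(cv < 1e-6))
})

test_that("steady-state detection: immediate, arc, and never", {
  # vertical AC organ is steady from t0
  p0 <- tropic_params(beta = 2, gamma = 1, nu = 0, A0 = 0)
  k0 <- simulate_tropism("AC", p0, t_end = 1, n_nodes = 51)
  d0 <- detect_steady_state(k0)
  expect_true(d0$converged)
  expect_equal(d0$t_steady, 0)
  # AaC steady shape has uniform curvature
  p1 <- tropic_params(beta = 0, gamma = 1, nu = 3, A0 = 0.5, A_P = 0)
  k1 <- simulate_tropism("AaC", p1, t_end = 10, n_nodes = 101)
  d1 <- detect_steady_state(k1)
  expect_true(d1$converged)
  expect_lt(stats::sd(d1$shape$curvature), 1e-6)
  # graviception without proprioception never converges
  p2 <- tropic_params(beta = 2, gamma = 0, nu = 0, A0 = 0.5)
  k2 <- simulate_tropism("AC", p2, t_end = 20, n_nodes = 51)
  d2 <- detect_steady_state(k2)
  expect_false(d2$converged)
  expect_identical(d2$status, "not_converged")
  # but apical photoception alone does converge without proprioception
  p3 <- tropic_params(beta = 0, gamma = 0, nu = 2, A0 = 0.5, A_P = 0)
  k3 <- simulate_tropism("AaC", p3, t_end = 10, n_nodes = 51)
  d3 <- detect_steady_state(k3)
  expect_true(d3$converged)
  expect_lt(abs(d3$shape$angle[51]), 1e-3)  # tip at the light direction
})

test_that("tip angle converges to its closed-form limit", {
  # apical photoproprioceptive: tip -> A0 / (1 + D)
  p1 <- tropic_params(beta = 0, gamma = 1, nu = 4, A0 = 0.5, A_P = 0)
  k1 <- simulate_tropism("AaC", p1, t_end = 20)
  ts1 <- tip_angle_series(k1)
  expect_equal(ts1$tip_angle[nrow(ts1)], 0.5 / 5, tolerance = 1e-6)
  # local photo-gravi-proprioceptive: tip -> (A0 - A_R) e^{-(B+D)} + A_R
  p2 <- full_params()
  dn <- derived_numbers(p2)
  k2 <- simulate_tropism("ARC", p2, t_end = 30)
  ts2 <- tip_angle_series(k2)
  expect_equal(ts2$tip_angle[nrow(ts2)],
               (p2$A0 - dn$A_R) * exp(-dn$B_prime) + dn$A_R,
               tolerance = 1e-5)
  # photoception dominant (D large): tip driven to the light direction
  p3 <- tropic_params(beta = 1e-4, gamma = 1, nu = 500, A0 = 0.3,
                      A_P = pi / 2)
  k3 <- simulate_tropism("ARaC", p3, t_end = 10)
  ts3 <- tip_angle_series(k3)
  expect_equal(ts3$tip_angle[nrow(ts3)], pi / 2, tolerance = 1e-2)
})

test_that("transient oscillations increase with the control number", {
  osc <- sapply(c(1, 5, 10), function(Bp) {
    p <- tropic_params(beta = Bp, gamma = 1, nu = 0, A0 = 0.5)
    kin <- simulate_tropism("AC", p, t_end = 40, n_nodes = 101)
    tip <- tip_angle_series(kin)$tip_angle
    sum(diff(sign(tip - 0.5 * exp(-Bp))) != 0)
  })
  expect_true(all(diff(osc) >= 0))
  expect_gt(osc[3], osc[1])
})

test_that("zero propagation time reproduces the instantaneous stepper bitwise", {
  p <- tropic_params(beta = 0.5, gamma = 1, nu = 4, A0 = 0.5, A_P = 0.4)
  k0 <- simulate_tropism("ARaC", p, t_end = 2, n_nodes = 81)
  kp <- simulate_with_propagation("ARaC", p, t_end = 2, T_B = 0,
                                  n_nodes = 81)
  expect_identical(k0$A, kp$A)
  expect_identical(k0$C, kp$C)
  expect_error(simulate_with_propagation("AC", p, 1, T_B = 0.1), "apical")
  expect_error(simulate_with_propagation("AaC", p, 1, T_B = -1), ">= 0")
})

test_that("slow propagation degrades the solution monotonically", {
  p <- tropic_params(beta = 0, gamma = 1, nu = 4, A0 = 0.5, A_P = 0)
  Tc <- derived_numbers(p)$T_c
  k0 <- simulate_tropism("AaC", p, t_end = 5 * Tc, dt = Tc / 200,
                         n_nodes = 101)
  devs <- sapply(c(0.01, 0.1, 1), function(r) {
    kd <- simulate_with_propagation("AaC", p, t_end = 5 * Tc, T_B = r * Tc,
                                    dt = Tc / 200, n_nodes = 101)
    max(abs(kd$A - k0$A)) / max(abs(k0$A))
  })
  expect_lt(devs[1], 0.01)
  expect_true(all(diff(devs) > 0))
})

test_that("growth-zone restriction freezes the basal region", {
  p <- full_params(L_gz = 0.5)
  kin <- simulate_tropism("ARaC", p, t_end = 3, n_nodes = 101)
  basal <- kin$s < 0.5 - 1e-9
  expect_true(all(kin$C[basal, ] == 0))
  expect_true(any(kin$C[!basal, ncol(kin$C)] != 0))
  # basal angle stays clamped at A0 everywhere below the growth zone
  expect_true(all(abs(kin$A[basal, ] - p$A0) < 1e-12))
})

test_that("instability is reported as a solver error, advising a smaller step", {
  p <- tropic_params(beta = 80, gamma = 0.01, nu = 0, A0 = 0.5)
  expect_error(simulate_tropism("AC", p, t_end = 200, dt = 3, n_nodes = 41),
               "instability|reduce")
})
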