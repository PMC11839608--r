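test_that("joint kinetics follow Newton's law and trapezoidal kinematics", {
  tt <- seq(0, 2, by = 0.01)
  # constant acceleration a = (3, 0, 0): p = 1.5 t^2
  pos <- cbind(1.5 * tt^2, 0, 0)
  traj <- joint_trajectory(pos, dt = 0.01, mass = 2)
  f <- joint_kinetics(traj)
  interior <- 5:(nrow(f) - 5)
  expect_equal(f[interior, 1], rep(6, length(interior)), tolerance = 1e-6)
  expect_equal(max(abs(f[, 2:3])), 0)
  # constant velocity: reconstructed displacement matches v * t
  posv <- cbind(tt, 0, 0)
  trajv <- joint_trajectory(posv, dt = 0.01, mass = 1)
  disp <- sum((trajv$velocities[-1, 1] + trajv$velocities[-nrow(posv), 1]) / 2) * 0.01
  expect_equal(disp, 2, tolerance = 1e-6)
  expect_equal(max(abs(joint_kinetics(trajv)[5:(nrow(posv) - 5), ])), 0,
               tolerance = 1e-9)
  expect_error(joint_trajectory(cbind(1:2, 0, 0), 0.01, 1),
               class = "apeo_insufficient_data")
})

test_that("inverse dynamics matches statics and the energy-gradient oracle", {
  pend <- pendulum_model(m = 1, l = 1, g = 9.81)
  # static posture: torque equals gravity term
  expect_equal(inverse_dynamics(pi / 2, 0, 0, pend), 9.81)
  # inertial term only
  m0 <- rigid_joint_model(inertia = 2)
  expect_equal(inverse_dynamics(0.3, 1, 3, m0), 6)
  expect_error(inverse_dynamics(NaN, 0, 0, pend), class = "apeo_domain_error")
  # finite-difference gradient of V = -m g l cos(q) across 20 random angles
  set.seed(12)
  v <- function(q) -9.81 * cos(q)
  h <- 1e-6
  for (q in runif(20, -pi, pi)) {
    oracle <- (v(q + h) - v(q - h)) / (2 * h)
    expect_equal(inverse_dynamics(q, 0, 0, pend), oracle, tolerance = 1e-4)
  }
})

test_that("mechanical energy sums kinetic and accumulated work terms", {
  n <- 201; dt <- 0.01
  # constant speed 3, no force: E = 0.5 * 2 * 9 = 9 J throughout
  traj <- joint_trajectory(matrix(0, n, 3), dt, mass = 2,
                           velocities = cbind(rep(3, n), 0, 0),
                           accelerations = matrix(0, n, 3))
  e <- mechanical_energy(traj, matrix(0, n, 3))
  expect_equal(e, rep(9, n))
  # v = 0, F = 0 -> E = 0
  tr0 <- joint_trajectory(matrix(0, n, 3), dt, mass = 2,
                          velocities = matrix(0, n, 3),
                          accelerations = matrix(0, n, 3))
  expect_equal(mechanical_energy(tr0, matrix(0, n, 3)), rep(0, n))
  # 1 N parallel to 1 m/s for 2 s: KE 1 J plus work 2 J
  trw <- joint_trajectory(matrix(0, n, 3), dt, mass = 2,
                          velocities = cbind(rep(1, n), 0, 0),
                          accelerations = matrix(0, n, 3))
  ew <- mechanical_energy(trw, cbind(rep(1, n), 0, 0))
  expect_equal(ew[n], 3, tolerance = 1e-9)
  expect_error(mechanical_energy(trw, matrix(0, 5, 3)),
               class = "apeo_shape_error")
})

test_that("force optimization takes exact gradient steps and contracts geometrically", {
  r1 <- optimize_forces(2, 0, eta = 0.25, max_iter = 1)
  expect_equal(as.numeric(r1$forces), 1)  # 2 - 0.25 * 2 * 2
  r2 <- optimize_forces(2, 0, eta = 0.5, max_iter = 1)
  expect_equal(as.numeric(r2$forces), 0)  # exact quadratic step
  r3 <- optimize_forces(1.5, 1.5, eta = 0.3, max_iter = 5)
  expect_equal(as.numeric(r3$forces), 1.5)
  expect_equal(r3$loss_trace$loss[1], 0)
  # geometric contraction with ratio |1 - 2 eta| on the gap
  for (eta in c(0.1, 0.3, 0.45)) {
    out <- optimize_forces(4, 1, eta = eta, max_iter = 6, tol = 0)
    ratio <- (1 - 2 * eta)^2
    expect_equal(out$loss_trace$loss[-1] / out$loss_trace$loss[-7],
                 rep(ratio, 6), tolerance = 1e-10)
  }
  expect_true(all(diff(optimize_forces(4, 1, 0.4, max_iter = 20)$loss_trace$loss) <= 0))
  expect_error(optimize_forces(1, 0, eta = -0.1),
               class = "apeo_invalid_argument")
  expect_warning(optimize_forces(1, 0, eta = 1.5, max_iter = 1), "diverg")
})

test_that("energy projection keeps the iterate inside the budget", {
  n <- 101
  traj <- joint_trajectory(matrix(0, n, 1), dt = 0.01, mass = 1,
                           velocities = matrix(1, n, 1),
                           accelerations = matrix(0, n, 1))
  f0 <- matrix(0.1, n, 1)
  f_opt <- matrix(10, n, 1)  # pulls toward a high-work profile
  budget <- energy_budget(e_max = 2)
  out <- optimize_forces(f0, f_opt, eta = 0.4, budget = budget, traj = traj,
                         max_iter = 25)
  e_final <- sum(utils::tail(mechanical_energy(traj, out$forces), 1))
  expect_lte(e_final, 2 + 1e-9)
})

test_that("modality templates produce valid trajectories scaled by intensity", {
  tr_lo <- modality_trajectory("relaxation", 0.1)
  tr_hi <- modality_trajectory("high_energy", 0.9)
  expect_s3_class(tr_lo, "joint_trajectory")
  expect_gt(max(abs(tr_hi$positions[, 1])), max(abs(tr_lo$positions[, 1])))
  expect_error(modality_trajectory("swimming", 0.5),
               class = "apeo_invalid_argument")
  expect_equal(scale_reference_forces(c(1, 2), 70), c(70, 140))
})
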