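test_that("forward kinematics places a straight arm at full reach", {
  m <- fix_model()
  L <- m$geometry$segment_lengths
  # colinear chain: all distal joints at zero relative angle
  for (q1 in c(0, 0.5, 1.2)) {
    fk <- forward_kinematics(m, c(q1, 0, 0))
    expect_equal(sqrt(sum(fk$endpoint^2)), sum(L), tolerance = 1e-12)
    expect_equal(atan2(fk$endpoint[2], fk$endpoint[1]), q1, tolerance = 1e-12)
  }
})

test_that("rotating the shoulder rotates the endpoint rigidly about the origin", {
  m <- fix_model()
  set.seed(11)
  for (i in 1:20) {
    q <- random_q(m)
    delta <- runif(1, -0.5, 0.5)
    p0 <- forward_kinematics(m, q)$endpoint
    p1 <- forward_kinematics(m, q + c(delta, 0, 0))$endpoint
    Rm <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2)
    expect_equal(p1, as.numeric(Rm %*% p0), tolerance = 1e-12)
  }
})

test_that("forward kinematics rejects non-finite input", {
  expect_error(forward_kinematics(fix_model(), c(NA, 0, 0)), "finite")
  expect_error(forward_kinematics(fix_model(), c(1, 2)), "three")
})

test_that("endpoint Jacobian matches central finite differences", {
  m <- fix_model()
  set.seed(21)
  eps <- 1e-6
  worst <- 0
  for (i in 1:100) {
    q <- random_q(m)
    J <- endpoint_jacobian(m, q)
    Jfd <- vapply(1:3, function(j) {
      e <- numeric(3); e[j] <- eps
      (forward_kinematics(m, q + e)$endpoint -
         forward_kinematics(m, q - e)$endpoint) / (2 * eps)
    }, numeric(2))
    worst <- max(worst, max(abs(J - Jfd)) / max(abs(J)))
  }
  expect_lt(worst, 1e-6)
})

test_that("Jacobian limiting cases: straight arm and zero joint velocity", {
  m <- fix_model()
  L <- sum(m$geometry$segment_lengths)
  J <- endpoint_jacobian(m, c(0.7, 0, 0))
  expect_equal(sqrt(sum(J[, 1]^2)), L, tolerance = 1e-12)
  q <- random_q(m)
  expect_equal(as.numeric(endpoint_jacobian(m, q) %*% c(0, 0, 0)), c(0, 0))
})

test_that("mass matrix is symmetric positive definite across the joint box", {
  m <- fix_model()
  g <- m$geometry
  grid <- expand.grid(q1 = seq(g$joint_min[1], g$joint_max[1], length.out = 5),
                      q2 = seq(g$joint_min[2], g$joint_max[2], length.out = 5),
                      q3 = seq(g$joint_min[3], g$joint_max[3], length.out = 5))
  for (i in seq_len(nrow(grid))) {
    M <- mass_matrix(m, as.numeric(grid[i, ]))
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("forward and inverse dynamics are exact mutual inverses", {
  m <- fix_model()
  set.seed(31)
  worst <- 0
  for (i in 1:100) {
    q <- random_q(m)
    qd <- runif(3, -3, 3)
    qdd <- runif(3, -20, 20)
    tau <- inverse_dynamics(m, q, qd, qdd)
    back <- forward_dynamics(m, q, qd, tau, limits = FALSE)
    worst <- max(worst, max(abs(back - qdd)))
  }
  expect_lt(worst, 1e-8)
})

test_that("no gravity in the horizontal plane: static states need no torque", {
  m <- fix_model()
  q <- random_q(m)
  expect_equal(inverse_dynamics(m, q, c(0, 0, 0), c(0, 0, 0)), c(0, 0, 0))
  expect_equal(forward_dynamics(m, q, c(0, 0, 0), c(0, 0, 0), limits = FALSE),
               c(0, 0, 0))
})

test_that("wrist acceleration demands reaction torques at proximal joints", {
  m <- fix_model()
  q <- m$geometry$initial_joint_angles
  tau <- inverse_dynamics(m, q, c(0, 0, 0), c(0, 0, 5))
  # interaction torques: the shoulder and elbow must brace against the
  # accelerating hand even though they do not move
  expect_gt(abs(tau[1]), 1e-6)
  expect_gt(abs(tau[2]), 1e-6)
  expect_gt(abs(tau[3]), 1e-6)
})

test_that("kinetic energy is conserved in a free passive swing", {
  m <- fix_model()
  a <- reacharm:::model_args(m)
  q0 <- m$geometry$initial_joint_angles
  qd0 <- c(0.8, -0.5, 0.3)  # stays away from the joint limits over 1 s
  out <- reacharm:::cpp_integrate_arm(a$geom, a$mus, a$scen, q0, qd0,
                                      c(0, 0, 0), 1.0, 1e-4, FALSE)
  ke <- out$kinetic_energy
  expect_lt(max(abs(ke - ke[1])) / ke[1], 1e-6)
})

test_that("the endpoint never leaves the full-reach disc", {
  m <- fix_model()
  R <- sum(m$geometry$segment_lengths)
  set.seed(41)
  for (i in 1:200) {
    p <- forward_kinematics(m, random_q(m))$endpoint
    expect_lte(sqrt(sum(p^2)), R + 1e-12)
  }
})

test_that("geometry constructor enforces physical invariants", {
  expect_error(arm_geometry(segment_lengths = c(-0.3, 0.25, 0.18)), "positive")
  expect_error(arm_geometry(joint_min = c(0, 0, 0), joint_max = c(-1, 1, 1)),
               "below")
  expect_error(arm_geometry(initial_joint_angles = c(10, 0, 0)), "within")
})
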