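test_that("control parameters are exactly seven validated scalars", {
  cp <- control_params(kp = c(1, 2, 3), kd = c(4, 5, 6), t_pred = 0.02)
  expect_length(c(cp$kp, cp$kd, cp$t_pred), 7)
  expect_error(control_params(kp = c(-1, 0, 0), kd = c(0, 0, 0), t_pred = 0))
  expect_error(control_params(kp = c(1, 2), kd = c(0, 0, 0), t_pred = 0))
  expect_error(control_params(kp = c(1, 2, 3), kd = c(0, 0, 0), t_pred = -1))
})

test_that("predict_state with zero horizon is the identity", {
  m <- fix_model()
  state <- c(m$geometry$initial_joint_angles, 0.1, -0.2, 0.3, runif(18, 0, 0.5))
  expect_identical(predict_state(m, state, rep(0, 6), 0), state)
})

test_that("prediction matches the simulator over the same interval", {
  m <- fix_model()
  scen <- scenario_params("A")
  state <- c(m$geometry$initial_joint_angles + c(0.1, -0.1, 0.05),
             0.5, -0.3, 0.2, rep(0.1, 18))
  u <- c(0.3, 0, 0.2, 0, 0, 0.1)
  one <- predict_state(m, state, u, 0.05, scen)
  # two half-horizon predictions compose to the full one
  half <- predict_state(m, predict_state(m, state, u, 0.025, scen), u, 0.025, scen)
  expect_equal(one, half, tolerance = 1e-8)
  # ballistic advance is consistent with forward dynamics to first order
  h <- 1e-4
  adv <- predict_state(m, state, u, h, scen, dt = h)
  qdd <- forward_dynamics(m, state[1:3], state[4:6],
                          muscle_joint_torques(m, state[1:3], state[4:6],
                                               state[6 + 3 * (1:6)],
                                               scen)$tau)
  expect_equal((adv[4:6] - state[4:6]) / h, qdd, tolerance = 1e-2)
})

test_that("prediction error grows with the horizon on a perturbed state", {
  m <- fix_model()
  scen <- scenario_params("no_passive")
  state <- c(m$geometry$initial_joint_angles, 1.0, -0.8, 0.5, rep(0, 18))
  drift <- vapply(c(0.01, 0.05, 0.1), function(tp)
    max(abs(predict_state(m, state, rep(0, 6), tp, scen)[1:3] - state[1:3])),
    numeric(1))
  expect_true(all(diff(drift) > 0))
})

test_that("control step is pure feedforward at zero tracking error, zero at rest", {
  m <- fix_model()
  cp <- fix_control()
  q <- m$geometry$initial_joint_angles
  tau <- control_step(m, q, c(0, 0, 0), q, c(0, 0, 0), c(0, 0, 0), cp)
  expect_equal(tau, c(0, 0, 0))
  # positive position error in the flexion direction demands flexion torque
  tau2 <- control_step(m, q - c(0.1, 0, 0), c(0, 0, 0), q, c(0, 0, 0),
                       c(0, 0, 0), cp)
  expect_gt(tau2[1], 0)
})

test_that("feedforward alone reproduces the reference accelerations", {
  m <- fix_model()
  pl <- plan_reach(m, c(0.3, 0.45))
  k <- 300  # mid-movement sample
  tau <- inverse_dynamics(m, pl$refq[k, ], pl$refqd[k, ], pl$refqdd[k, ])
  qdd <- forward_dynamics(m, pl$refq[k, ], pl$refqd[k, ], tau, limits = FALSE)
  expect_equal(qdd, pl$refqdd[k, ], tolerance = 1e-8)
})

test_that("excitations: zero demand at rest gives zero, never co-excites, stays in [0,1]", {
  m <- fix_model()
  rest <- c(m$geometry$initial_joint_angles, rep(0, 3), rep(0, 18))
  expect_equal(torques_to_excitations(m, rest, c(0, 0, 0)), rep(0, 6))
  set.seed(61)
  for (i in 1:50) {
    state <- c(random_q(m), runif(3, -2, 2), runif(18, 0, 1))
    tau_des <- runif(3, -40, 40)
    u <- torques_to_excitations(m, state, tau_des,
                                scenario_params(sample(c("no_passive", "A", "H"), 1)),
                                t_pred = runif(1, 0, 0.06))
    expect_true(all(u >= 0 & u <= 1))
    expect_equal(u[1] * u[2], 0)
    expect_equal(u[3] * u[4], 0)
    expect_equal(u[5] * u[6], 0)
  }
})

test_that("passive antagonist force demands more agonist drive in closed loop", {
  # the inversion itself is blind to passive forces, so holding an elongated
  # posture under stiff passive muscles must recruit more agonist activation
  # through the feedback loop than with no passive force
  m <- fix_model()
  st <- fix_settings()
  cp <- fix_control()
  tgt <- c(-0.55, 0.4)  # long reach toward the contralateral distal region
  pl <- plan_reach(m, tgt, settings = st)
  r_ref <- simulate_reach(m, "no_passive", cp, tgt, st, plan = pl)
  r_H <- simulate_reach(m, "H", cp, tgt, st, plan = pl)
  i <- r_ref$t >= r_ref$T  # homing phase: near-static force balance
  mean_act <- function(r) mean(r$activation[i, ])
  expect_gt(mean_act(r_H), mean_act(r_ref))
  # and the stiff scenario tracks worse under identical gains
  expect_gt(r_H$e_h, r_ref$e_h)
})

test_that("demands beyond capacity saturate at full excitation", {
  m <- fix_model()
  rest <- c(m$geometry$initial_joint_angles, rep(0, 3), rep(0, 18))
  u <- torques_to_excitations(m, rest, c(1e4, -1e4, 1e4))
  expect_equal(u, c(1, 0, 0, 1, 1, 0))
})
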