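test_that("passive force curve matches its closed form and piecewise zero", {
  A <- scenario_params("A")
  expect_identical(passive_force(A, 1.05), 0)           # below slack length
  expect_identical(passive_force(A, A[["l_p"]]), 0)     # continuous at slack
  expect_equal(passive_force(A, 1.3), 0.05 * (exp(1.0) - 1),
               tolerance = 1e-12)
  H <- scenario_params("H")
  expect_equal(passive_force(H, 1.2), 0.075 * (exp(1.6) - 1),
               tolerance = 1e-12)
  expect_equal(passive_force(H, 1.2), 0.296477, tolerance = 1e-5)
})

test_that("passive force is non-negative, continuous and monotone for every scenario", {
  lbar <- seq(0.5, 1.5, by = 1e-3)
  tab <- ageing_scenarios()
  for (i in seq_len(nrow(tab))) {
    p <- scenario_params(tab$label[i])
    f <- passive_force(p, lbar)
    expect_true(all(f >= 0))
    expect_true(all(diff(f) >= 0))
    # continuity at the slack point: values just above l_p are tiny
    expect_lt(passive_force(p, p[["l_p"]] + 1e-9), 1e-6)
  }
})

test_that("passive force is conservative: zero net work over a closed loop", {
  p <- scenario_params("H")
  up <- stats::integrate(function(l) passive_force(p, l), 0.9, 1.25,
                         rel.tol = 1e-12)$value
  down <- stats::integrate(function(l) passive_force(p, l), 1.25, 0.9,
                           rel.tol = 1e-12)$value
  expect_equal(up + down, 0, tolerance = 1e-12)
})

test_that("no-passive-force scenario generates exactly zero passive force in range", {
  ref <- scenario_params("no_passive")
  lbar_max <- max_normalized_length(fix_model(), 150)
  expect_lt(lbar_max, 1.26)
  lbar <- seq(0.7, lbar_max, length.out = 500)
  expect_true(all(passive_force(ref, lbar) == 0))
})

test_that("total force composes active and passive terms", {
  mus <- fix_model()$muscles
  A <- scenario_params("A")
  ref <- scenario_params("no_passive")
  expect_equal(total_force(mus, A, lbar = 1.05, a = 0), 0)
  expect_equal(total_force(mus, ref, lbar = 1.2, a = 0), 0)
  # isometric optimum normalization f_a(1, 0) = 1
  expect_equal(total_force(mus, ref, lbar = 1, ldot = 0, a = 1),
               mus$fmax[1], tolerance = 1e-12)
  # composition at half activation on an elongated muscle
  fa <- active_force_scale(mus, 1.3, 0)
  expect_equal(total_force(mus, A, lbar = 1.3, ldot = 0, a = 0.5),
               mus$fmax[1] * (0.5 * fa + 0.05 * (exp(1) - 1)),
               tolerance = 1e-10)
})

test_that("active scaling is normalized at the isometric optimum", {
  mus <- fix_model()$muscles
  expect_equal(active_force_scale(mus, 1, 0), 1, tolerance = 1e-14)
  # eccentric force exceeds isometric, concentric falls below
  expect_gt(active_force_scale(mus, 1, 2), 1)
  expect_lt(active_force_scale(mus, 1, -2), 1)
  expect_equal(active_force_scale(mus, 1, -mus$v_max), 0, tolerance = 1e-14)
})

test_that("activation dynamics: fixed points, monotone step response, bounds", {
  mus <- fix_model()$muscles
  s <- c(0, 0, 0)
  for (i in 1:50) s <- activation_step(mus, s, u = 0, dt = 0.01)
  expect_equal(s, c(0, 0, 0))
  s <- c(0, 0, 0)
  a_hist <- numeric(60)
  for (i in 1:60) {
    s <- activation_step(mus, s, u = 1, dt = 0.01)
    a_hist[i] <- s[3]
  }
  expect_true(all(diff(a_hist[1:30]) > 0))
  expect_true(all(diff(a_hist) >= 0))
  expect_true(all(a_hist <= 1))
  expect_gt(a_hist[60], 0.99)  # converges to the excitation
})

test_that("activation stays within [0,1] under random admissible excitation", {
  mus <- fix_model()$muscles
  set.seed(7)
  for (rep in 1:10) {
    s <- runif(3)
    for (i in 1:100) {
      s <- activation_step(mus, s, u = runif(1), dt = runif(1, 1e-3, 0.03))
      expect_true(all(s >= 0 & s <= 1))
    }
  }
})

test_that("antagonist pairs have opposite length derivatives and correct moment arms", {
  m <- fix_model()
  set.seed(51)
  eps <- 1e-7
  for (i in 1:25) {
    q <- random_q(m)
    ml <- muscle_lengths(m, q)
    expect_true(all(ml$l > 0))
    for (j in 1:3) {
      e <- numeric(3); e[j] <- eps
      dl <- (muscle_lengths(m, q + e)$l - muscle_lengths(m, q - e)$l) / (2 * eps)
      fi <- 2 * j - 1; ei <- 2 * j
      expect_lt(dl[fi] * dl[ei], 0)  # one shortens as the other lengthens
      # moment arm equals -dl/dq (virtual work)
      expect_equal(ml$moment_arm[fi], -dl[fi], tolerance = 1e-6)
      expect_equal(ml$moment_arm[ei], -dl[ei], tolerance = 1e-6)
    }
  }
})

test_that("every muscle sits at optimal length in the reset posture", {
  m <- fix_model()
  ml <- muscle_lengths(m, m$geometry$initial_joint_angles)
  expect_equal(ml$lbar, rep(1, 6), tolerance = 1e-12)
})

test_that("normalized length never reaches 1.26 over a dense joint sweep", {
  lbar_max <- max_normalized_length(fix_model(), 200)
  expect_lt(lbar_max, 1.26)
})

test_that("muscle joint torques: rest cases and passive restoring torques", {
  m <- fix_model()
  q0 <- m$geometry$initial_joint_angles
  r <- muscle_joint_torques(m, q0, scenario = scenario_params("no_passive"))
  expect_equal(r$tau, c(0, 0, 0))
  expect_equal(r$force, rep(0, 6))
  # scenario H: any elongation evokes passive force pulling back
  q <- q0 + c(0.4, -0.3, 0.2)
  rH <- muscle_joint_torques(m, q, scenario = scenario_params("H"))
  expect_true(any(rH$force > 0))
  # restoring: flexed shoulder (extensor stretched) gets extension torque
  expect_lt(rH$tau[1], 0)
  expect_gt(rH$tau[2], 0)
  expect_lt(rH$tau[3], 0)
})

test_that("matched antagonistic activations with equal torque capacity cancel", {
  m <- fix_model()
  mus <- m$muscles
  q0 <- m$geometry$initial_joint_angles  # all muscles at lbar = 1
  # equal fmax and moment arms within each pair, equal activations: net zero
  r <- muscle_joint_torques(m, q0, activations = rep(0.4, 6),
                            scenario = scenario_params("no_passive"))
  expect_equal(r$tau, c(0, 0, 0), tolerance = 1e-10)
})

test_that("elongation work: closed form matches quadrature, ordering A to H strict", {
  ref <- scenario_params("no_passive")
  expect_identical(elongation_work(ref, 1.25), 0)
  A <- scenario_params("A")
  w_quad <- stats::integrate(function(l) passive_force(A, l), A[["l_p"]], 1.26,
                             rel.tol = 1e-12)$value
  expect_equal(elongation_work(A, 1.26), w_quad, tolerance = 1e-10)
  expect_equal(elongation_work(A, 1.26), 0.00425541, tolerance = 1e-6)
  # severity ordering at the model's own computed maximal length
  lbar_max <- max_normalized_length(fix_model(), 150)
  w <- vapply(LETTERS[1:8], function(s)
    elongation_work(scenario_params(s), lbar_max), numeric(1))
  expect_true(all(diff(w) > 0))
  expect_lt(elongation_work(ref, lbar_max), w[["A"]])
})

test_that("Table-1 scenario parameters resolve exactly", {
  tab <- ageing_scenarios()
  expect_equal(nrow(tab), 9)
  expect_equal(unname(scenario_params("no_passive")), c(0.05, 5, 1.3))
  expect_equal(unname(scenario_params("E")), c(0.05, 5, 1.0))
  expect_equal(unname(scenario_params("H")), c(0.075, 8, 1.0))
  expect_error(scenario_params("Z"), "unknown")
})
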