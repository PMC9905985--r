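test_that("holding the initial endpoint is a perfect degenerate reach", {
  m <- fix_model()
  r <- simulate_reach(m, "no_passive", fix_control(), fix_initial_endpoint(),
                      fix_settings())
  expect_lt(r$e_h, 1e-6)
  expect_lt(r$e_mv, 1e-6)
  expect_equal(r$failure, "success")
})

test_that("a mid-workspace reach with tuned gains is sub-0.1 mm accurate", {
  m <- fix_model()
  cp <- default_control_params("no_passive", "reference")
  r <- simulate_reach(m, "no_passive", cp, c(0.3, 0.45), fix_settings())
  expect_lt(r$e_h, 0.1)
  expect_false(r$unstable)
})

test_that("simulation is deterministic and uses no random numbers", {
  m <- fix_model()
  st <- fix_settings()
  pl <- plan_reach(m, c(0.25, 0.5), settings = st)
  set.seed(1)
  r1 <- simulate_reach(m, "A", fix_control(), c(0.25, 0.5), st, plan = pl)
  rng1 <- .Random.seed
  set.seed(999)
  r2 <- simulate_reach(m, "A", fix_control(), c(0.25, 0.5), st, plan = pl)
  expect_identical(r1$e_h, r2$e_h)
  expect_identical(r1$endpoint, r2$endpoint)
  set.seed(1)
  invisible(simulate_reach(m, "A", fix_control(), c(0.25, 0.5), st, plan = pl,
                           keep_series = FALSE))
  expect_identical(.Random.seed, rng1)
})

test_that("halving the integrator substep changes the homing error by < 1%", {
  m <- fix_model()
  st4 <- fix_settings()
  st8 <- sim_settings(n_sub = 8L)
  pl <- plan_reach(m, c(-0.3, 0.5), settings = st4)
  r4 <- simulate_reach(m, "A", fix_control(), c(-0.3, 0.5), st4, plan = pl,
                       keep_series = FALSE)
  r8 <- simulate_reach(m, "A", fix_control(), c(-0.3, 0.5), st8, plan = pl,
                       keep_series = FALSE)
  expect_lt(abs(r8$e_h - r4$e_h) / max(r4$e_h, 1e-6), 0.01)
})

test_that("no co-excitation on every control step of a simulated reach", {
  m <- fix_model()
  for (scen in c("no_passive", "H")) {
    r <- simulate_reach(m, scen, fix_control(), c(-0.45, 0.45), fix_settings())
    u <- r$excitation
    expect_true(all(u >= 0 & u <= 1))
    expect_true(all(u[, 1] * u[, 2] == 0))
    expect_true(all(u[, 3] * u[, 4] == 0))
    expect_true(all(u[, 5] * u[, 6] == 0))
    expect_true(all(r$activation >= 0 & r$activation <= 1))
  }
})

test_that("with zero excitation, mechanical plus elastic energy never grows", {
  m <- fix_model()
  a <- reacharm:::model_args(m, scenario_params("H"))
  # release from an elongated posture with some speed; only the limit
  # penalty's one-sided damping may remove energy
  q0 <- m$geometry$initial_joint_angles + c(0.5, -0.5, 0.3)
  y <- c(q0, 0.5, 0.5, -0.5, rep(0, 18))
  H <- scenario_params("H")
  energy <- function(yy) {
    ke <- kinetic_energy(m, yy[1:3], yy[4:6])
    ml <- muscle_lengths(m, yy[1:3])
    pe <- sum(m$muscles$fmax * m$muscles$l0 *
                vapply(ml$lbar, function(l) elongation_work(H, l), numeric(1)))
    ke + pe
  }
  es <- numeric(40)
  for (k in 1:40) {
    y <- predict_state(m, y, rep(0, 6), 0.01, H, dt = 5e-4)
    es[k] <- energy(y)
  }
  expect_true(all(diff(es) < 1e-8))
})

test_that("batches are order-invariant with one summary row per target", {
  m <- fix_model()
  ts <- fix_targets()
  sub <- ts[ts$set_id == "opt_sequence", ]
  out <- run_target_set(sub, m, "A", fix_control())
  expect_equal(nrow(out), nrow(sub))
  expect_true(all(out$e_h >= 0))
  rev_out <- run_target_set(sub[4:1, ], m, "A", fix_control())
  expect_equal(out$e_h, rev_out$e_h[4:1], tolerance = 1e-12)
})

test_that("out-of-workspace targets are flagged but still simulated", {
  m <- fix_model()
  b <- fix_boundary()
  R <- sum(m$geometry$segment_lengths)
  tg <- tibble::tibble(target_id = c("in", "out"),
                       x = c(0.3, R + 0.1), y = c(0.45, 0),
                       boundary_side = "none")
  tg$in_workspace <- in_workspace(cbind(tg$x, tg$y), b)
  out <- run_target_set(tg, m, "no_passive", fix_control())
  expect_equal(out$in_workspace, c(TRUE, FALSE))
  expect_equal(nrow(out), 2)
  # the unreachable target carries a large but finite error
  expect_gt(out$e_h[out$target_id == "out"], 50)
  expect_true(is.finite(out$e_h[out$target_id == "out"]))
})

test_that("tidy and glance expose the series and the metrics", {
  m <- fix_model()
  r <- simulate_reach(m, "A", fix_control(), c(0.3, 0.45), fix_settings())
  ser <- tidy(r)
  expect_s3_class(ser, "tbl_df")
  expect_equal(nrow(ser), length(r$t))
  expect_true(all(c("t", "x", "y", "a_sh_flex", "u_wr_ext") %in% names(ser)))
  g <- glance(r)
  expect_equal(nrow(g), 1)
  expect_equal(g$e_h, r$e_h)
  r2 <- simulate_reach(m, "A", fix_control(), c(0.3, 0.45), fix_settings(),
                       keep_series = FALSE)
  expect_error(tidy(r2), "keep_series")
})
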