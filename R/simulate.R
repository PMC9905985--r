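#' Simulation settings
#'
#' Numerical settings for reach simulation and planning.  The controller runs
#' at a fixed rate (`1 / dt`, default 1 kHz) with zero-order-hold
#' excitations; the plant is integrated with fixed-step RK4 using `n_sub`
#' substeps per control interval.  The reach duration follows an
#' average-speed rule (`T = max(t_min, d / v_avg)`), and every reach is
#' followed by a homing window of fixed length over which the homing-in error
#' is averaged.
#'
#' @param dt Control step (s).
#' @param n_sub RK4 substeps per control interval.
#' @param homing Homing window after the planned trajectory reaches the
#'   target (s).
#' @param v_avg Average reach speed used to set the movement duration (m/s).
#' @param t_min Minimum movement duration (s).
#' @param k_ik Feedback gain of the closed-loop inverse kinematics (1/s).
#' @param ik_damping Damping of the least-squares IK (m).
#' @param k_ns Null-space attraction rate towards mid-range angles (1/s).
#' @return A list of class `sim_settings`.
#' @export
sim_settings <- function(dt = 0.001, n_sub = 4L, homing = 1.0, v_avg = 0.5,
                         t_min = 0.4, k_ik = 20, ik_damping = 0.005,
                         k_ns = 0.5) {
  stopifnot(dt > 0, n_sub >= 1, homing > 0, v_avg > 0, t_min > 0)
  structure(list(dt = dt, n_sub = as.integer(n_sub), homing = homing,
                 v_avg = v_avg, t_min = t_min, k_ik = k_ik,
                 ik_damping = ik_damping, k_ns = k_ns),
            class = "sim_settings")
}

#' Simulate one reach
#'
#' Integrates the full model (three joints plus six muscles with third-order
#' activation dynamics, 24 states) from the reset posture at rest through the
#' planned movement and the homing window, under the predictive PD +
#' inverse-dynamics controller with the no-co-excitation rule.  The
#' simulation is fully deterministic for fixed inputs and settings.
#' Integrator blow-ups are caught and flagged `unstable` rather than raised,
#' with the trajectory frozen at the last finite state so the metrics report
#' the correspondingly large errors.
#'
#' @param model An [arm_model()].
#' @param scenario Passive parameters from [scenario_params()] (or a label).
#' @param cp A [control_params()].
#' @param target Target endpoint `c(x, y)` (m).
#' @param settings A [sim_settings()].
#' @param plan Optional precomputed [plan_reach()] for this target (plans do
#'   not depend on scenario or controller, so batches reuse them).
#' @param keep_series Keep the full time series in the result?  Metrics are
#'   always computed.
#' @return An object of class `reach_result`: metrics (`e_h`, `e_mv` in mm,
#'   per-joint co-activation, failure class, flags) and, if kept, the time
#'   series tibble.
#' @export
simulate_reach <- function(model, scenario, cp, target,
                           settings = sim_settings(), plan = NULL,
                           keep_series = TRUE) {
  if (is.character(scenario)) scenario <- scenario_params(scenario)
  if (is.null(plan)) plan <- plan_reach(model, target, settings = settings)
  a <- model_args(model, scenario)
  raw <- cpp_simulate_reach(a$geom, a$mus, a$scen, cp$kp, cp$kd, cp$t_pred,
                            plan$refq, plan$refqd, plan$refqdd, plan$p_ref,
                            plan$dt, settings$n_sub)
  t <- plan$t
  dist <- sqrt((raw$endpoint[, 1] - plan$target[1])^2 +
               (raw$endpoint[, 2] - plan$target[2])^2)
  dev <- sqrt((raw$endpoint[, 1] - plan$p_ref[, 1])^2 +
              (raw$endpoint[, 2] - plan$p_ref[, 2])^2)
  res <- structure(
    list(target = plan$target, T = plan$T, horizon = plan$horizon, t = t,
         dist = dist, dev = dev, endpoint = raw$endpoint, q = raw$q,
         qdot = raw$qdot, activation = raw$activation, force = raw$force,
         excitation = raw$excitation, p_ref = plan$p_ref,
         unstable = raw$unstable == 1, saturated = raw$saturated == 1,
         scenario = scenario, control = cp, dt = plan$dt,
         settings = settings),
    class = "reach_result")
  res$e_h <- homing_in_error(res)
  res$e_mv <- movement_error(res)
  res$coactivation <- vapply(c(shoulder = 1L, elbow = 2L, wrist = 3L),
                             function(j) co_activation(res, j), numeric(1))
  res$failure <- classify_failure(res)
  if (!keep_series) {
    res[c("endpoint", "q", "qdot", "activation", "force", "excitation",
          "p_ref", "dist", "dev", "t")] <- NULL
  }
  res
}

#' @export
print.reach_result <- function(x, ...) {
  cat(sprintf("reach_result: target (%.3f, %.3f) m, e_h = %.4g mm, e_mv = %.4g mm, %s\n",
              x$target[1], x$target[2], x$e_h, x$e_mv, x$failure))
  invisible(x)
}

#' Run a whole target set under one scenario/controller pairing
#'
#' Simulates each target from the reset posture (reaches are independent, so
#' results are order-invariant) and returns one summary row per target.
#' Per-reach failures are recorded in the table; the batch continues.
#'
#' @param targets A target-set tibble (see [make_target_sets()]) with at
#'   least `x`, `y` columns; `target_id`, `in_workspace`, `boundary_side` are
#'   carried through if present.
#' @param model An [arm_model()].
#' @param scenario Scenario label or parameters.
#' @param cp A [control_params()].
#' @param settings A [sim_settings()].
#' @param plans Optional named list of precomputed plans keyed by
#'   `target_id` (built once here otherwise).
#' @param keep_results Also return the `reach_result` objects (as the
#'   `results` attribute)?
#' @return A tibble with one row per target: coordinates, annotations,
#'   `e_h`, `e_mv`, co-activations, `failure`, `unstable`.
#' @export
run_target_set <- function(targets, model, scenario, cp,
                           settings = sim_settings(), plans = NULL,
                           keep_results = FALSE) {
  stopifnot(is.data.frame(targets), all(c("x", "y") %in% names(targets)))
  if (nrow(targets) == 0) stop("empty target set", call. = FALSE)
  if (is.character(scenario)) scenario <- scenario_params(scenario)
  ids <- if ("target_id" %in% names(targets)) targets$target_id
         else seq_len(nrow(targets))
  if (is.null(plans)) {
    plans <- lapply(seq_len(nrow(targets)), function(i)
      plan_reach(model, c(targets$x[i], targets$y[i]), settings = settings))
    names(plans) <- as.character(ids)
  }
  results <- lapply(seq_len(nrow(targets)), function(i) {
    simulate_reach(model, scenario, cp, c(targets$x[i], targets$y[i]),
                   settings = settings, plans[[as.character(ids[i])]],
                   keep_series = keep_results)
  })
  out <- targets
  out$target_id <- ids
  out$e_h <- vapply(results, function(r) r$e_h, numeric(1))
  out$e_mv <- vapply(results, function(r) r$e_mv, numeric(1))
  out$coact_shoulder <- vapply(results, function(r) r$coactivation[["shoulder"]], numeric(1))
  out$coact_elbow <- vapply(results, function(r) r$coactivation[["elbow"]], numeric(1))
  out$coact_wrist <- vapply(results, function(r) r$coactivation[["wrist"]], numeric(1))
  out$failure <- vapply(results, function(r) r$failure, character(1))
  out$unstable <- vapply(results, function(r) r$unstable, logical(1))
  out <- tibble::as_tibble(out)
  if (keep_results) attr(out, "results") <- results
  out
}
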