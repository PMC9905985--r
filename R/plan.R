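#' Minimum-jerk position profile
#'
#' The quintic `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5` and its first two
#' derivatives with respect to real time, for `tau = t / T` clamped to
#' `[0, 1]`.  The speed profile is bell-shaped with zero velocity and
#' acceleration at both ends and a peak path speed of `1.875 d / T` over a
#' path of length `d`.
#'
#' @param t Time(s) since movement onset (s).
#' @param T Movement duration (s).
#' @return A list of vectors `s`, `sdot`, `sddot` (path fractions and their
#'   time derivatives).
#' @export
min_jerk_profile <- function(t, T) {
  stopifnot(T > 0)
  tau <- pmin(pmax(t / T, 0), 1)
  list(s = 10 * tau^3 - 15 * tau^4 + 6 * tau^5,
       sdot = (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / T,
       sddot = (60 * tau - 180 * tau^2 + 120 * tau^3) / T^2)
}

# best-effort target configuration: multi-start box-constrained minimization
# of the endpoint error; returns the best posture found and its residual
# endpoint distance (zero residual for reachable targets)
solve_target_posture <- function(model, target, tol = 1e-6, seeds = NULL) {
  g <- model$geometry
  f <- function(q) {
    e <- forward_kinematics(model, q)$endpoint - target
    sum(e * e)
  }
  gr <- function(q) {
    e <- forward_kinematics(model, q)$endpoint - target
    as.numeric(2 * t(endpoint_jacobian(model, q)) %*% e)
  }
  if (is.null(seeds)) {
    seeds <- as.matrix(expand.grid(
      q1 = seq(g$joint_min[1] + 1e-3, g$joint_max[1] - 1e-3, length.out = 5),
      q2 = seq(g$joint_min[2] + 1e-3, g$joint_max[2] - 1e-3, length.out = 4),
      q3 = 0))
  }
  seeds <- matrix(seeds, ncol = 3)
  best <- NULL
  best_val <- Inf
  for (i in seq_len(nrow(seeds))) {
    fit <- try(stats::optim(seeds[i, ], f, gr, method = "L-BFGS-B",
                            lower = g$joint_min, upper = g$joint_max,
                            control = list(maxit = 200)), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$value < best_val) {
      best_val <- fit$value
      best <- fit$par
    }
    if (best_val < tol^2) break
  }
  list(q = as.numeric(best), dist = sqrt(best_val))
}

#' Plan a straight minimum-jerk reach
#'
#' Builds the reference trajectory for one reach: the endpoint follows the
#' straight segment from `start` to `target` with a minimum-jerk speed
#' profile over duration `T`, then holds the target for the homing window.
#' The endpoint reference is converted to reference joint trajectories by
#' closed-loop damped-least-squares inverse kinematics integrated on the
#' control grid, with a null-space attraction towards mid-range joint angles
#' to resolve the arm's redundancy.
#'
#' If `T` is `NULL` it is set by an average-speed rule,
#' `max(t_min, d / v_avg)` rounded up to the control step.  Targets outside
#' the workspace are planned like any others (the reference simply saturates
#' at the reachable boundary); they are flagged downstream, not clamped here.
#'
#' @param model An [arm_model()].
#' @param target Target endpoint, `c(x, y)` in metres.
#' @param start Start endpoint; default the endpoint of the reset posture.
#' @param T Movement duration (s), or `NULL` for the speed rule.
#' @param settings A [sim_settings()].
#' @return An object of class `reach_plan`: sampled reference endpoint and
#'   joint trajectories on the control grid over `T` plus the homing window.
#' @export
plan_reach <- function(model, target, start = NULL, T = NULL,
                       settings = sim_settings()) {
  stop_if_not_finite(target, "target")
  stopifnot(length(target) == 2)
  geom <- model$geometry
  if (is.null(start)) {
    start <- forward_kinematics(model, geom$initial_joint_angles)$endpoint
  }
  d <- sqrt(sum((target - start)^2))
  dt <- settings$dt
  if (is.null(T)) T <- max(settings$t_min, d / settings$v_avg)
  if (T <= 0) stop("`T` must be positive", call. = FALSE)
  T <- ceiling(T / dt) * dt
  horizon <- T + settings$homing
  n <- round(horizon / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  prof <- min_jerk_profile(t, T)
  dir <- if (d > 0) (target - start) / d else c(0, 0)
  p_ref <- cbind(start[1] + d * prof$s * dir[1], start[2] + d * prof$s * dir[2])
  v_ref <- cbind(d * prof$sdot * dir[1], d * prof$sdot * dir[2])

  # closed-loop differential IK along the reference path (compiled)
  a <- model_args(model)
  ik <- cpp_plan_ik(a$geom, a$mus, a$scen, p_ref, v_ref, dt, 4L,
                    settings$k_ik, settings$ik_damping, settings$k_ns)
  refq <- ik$refq
  refqd <- ik$refqd
  ik_fallback <- FALSE
  tail_err <- sqrt(sum((forward_kinematics(model, refq[n, ])$endpoint -
                          target)^2))
  if (tail_err > 1e-3) {
    # the straight-path IK jammed at a joint limit (targets reachable only on
    # another IK branch, e.g. elbow-wrapped postures); if the target is
    # reachable at all, fall back to a joint-space minimum-jerk reference
    # ending on a directly solved target configuration.  The endpoint
    # reference (and hence the movement-error metric) keeps the straight path.
    sol <- solve_target_posture(model, target)
    if (sol$dist < 0.5 * tail_err) {
      profT <- min_jerk_profile(t, T)
      dq <- sol$q - geom$initial_joint_angles
      refq <- outer(profT$s, dq) +
        matrix(geom$initial_joint_angles, n, 3, byrow = TRUE)
      refqd <- outer(profT$sdot, dq)
      ik_fallback <- TRUE
    }
  }
  # reference accelerations by central differences of the reference positions
  refqdd <- matrix(0, n, 3)
  if (n > 2) {
    refqdd[2:(n - 1), ] <- (refq[3:n, ] - 2 * refq[2:(n - 1), ] +
                              refq[1:(n - 2), ]) / dt^2
  }
  structure(
    list(start = start, target = as.numeric(target), T = T, horizon = horizon,
         dt = dt, t = t, p_ref = p_ref, v_ref = v_ref, refq = refq,
         refqd = refqd, refqdd = refqdd,
         ik_endpoint_error = ik$ik_endpoint_error,
         ik_fallback = ik_fallback),
    class = "reach_plan")
}
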