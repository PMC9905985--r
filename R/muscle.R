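#' Hill-type muscle parameters
#'
#' One antagonistic flexor-extensor pair actuates each joint, six muscles in
#' all, ordered shoulder flexor, shoulder extensor, elbow flexor, elbow
#' extensor, wrist flexor, wrist extensor.  Muscle paths are linear in joint
#' angle with constant moment arms, so a flexor shortens as its joint flexes
#' and its extensor lengthens by the same amount.  Every muscle sits exactly
#' at its optimal length (normalized length 1) in the reset posture, and the
#' moment-arm-to-optimal-length ratios are chosen so that the normalized
#' length never exceeds 1.25 anywhere in the feasible joint box.
#'
#' Active force scaling `f_a(lbar, ldot)` is a Gaussian force-length curve
#' times a Hill force-velocity curve (hyperbolic concentric branch, saturating
#' eccentric branch with matched slope at zero velocity), normalized so that
#' `f_a(1, 0) = 1`.  Excitation is converted to activation by a third-order
#' chain of first-order lags.
#'
#' @param fmax Maximum isometric force per muscle (N).
#' @param l0 Optimal muscle length per muscle (m).
#' @param moment_arm Constant moment arm per muscle (m), positive.
#' @param sign +1 for flexors, -1 for extensors.
#' @param joint Joint actuated by each muscle (1 shoulder, 2 elbow, 3 wrist).
#' @param fl_width Width of the Gaussian force-length curve (normalized
#'   length units).
#' @param v_max Maximal shortening velocity (optimal lengths per second).
#' @param fv_curvature Hill curvature constant of the concentric branch.
#' @param fv_flen Eccentric force plateau (multiple of isometric force).
#' @param act_tau Time constants of the three activation stages (s).
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(fmax = c(800, 800, 600, 600, 200, 200),
                          l0 = c(0.15, 0.15, 0.13, 0.13, 0.06, 0.06),
                          moment_arm = 0.25 * l0 /
                            rep(c(80, 75, 45) * pi / 180, each = 2),
                          sign = rep(c(1L, -1L), 3),
                          joint = rep(1:3, each = 2),
                          fl_width = 0.45,
                          v_max = 10,
                          fv_curvature = 0.25,
                          fv_flen = 1.5,
                          act_tau = c(0.015, 0.015, 0.015)) {
  stopifnot(length(fmax) == 6, length(l0) == 6, length(moment_arm) == 6,
            all(fmax > 0), all(l0 > 0), all(moment_arm > 0),
            all(sign %in% c(-1L, 1L)), all(joint %in% 1:3),
            length(act_tau) == 3, all(act_tau > 0), v_max > 0,
            fv_curvature > 0, fv_flen > 1, fl_width > 0)
  structure(
    list(fmax = as.numeric(fmax), l0 = as.numeric(l0),
         moment_arm = as.numeric(moment_arm), sign = as.integer(sign),
         joint = as.integer(joint), fl_width = fl_width, v_max = v_max,
         fv_curvature = fv_curvature, fv_flen = fv_flen,
         act_tau = as.numeric(act_tau)),
    class = "muscle_params")
}

#' Ageing scenarios: passive force-length parameter sets
#'
#' The nine study conditions: a no-passive-force reference and eight ageing
#' scenarios A-H formed by crossing a low and a high value of each passive
#' curve parameter.  In the reference, the slack length (1.3) exceeds the
#' largest normalized length any muscle can attain, so passive force is
#' identically zero.  Scenarios are labelled in increasing order of severity
#' as measured by [elongation_work()].
#'
#' @return A tibble with columns `label`, `s_p`, `r_p`, `l_p`.
#' @export
ageing_scenarios <- function() {
  tibble::tibble(
    label = c("no_passive", LETTERS[1:8]),
    s_p = c(0.05, 0.05, 0.075, 0.05, 0.075, 0.05, 0.075, 0.05, 0.075),
    r_p = c(5, 5, 5, 8, 8, 5, 5, 8, 8),
    l_p = c(1.3, 1.1, 1.1, 1.1, 1.1, 1.0, 1.0, 1.0, 1.0))
}

#' Passive force parameters of one scenario
#'
#' @param label One of `"no_passive"`, `"A"` ... `"H"`, or a numeric vector
#'   `c(s_p, r_p, l_p)` for a custom passive curve.
#' @return A named numeric vector with elements `s_p`, `r_p`, `l_p`.
#' @export
scenario_params <- function(label = "no_passive") {
  if (is.numeric(label)) {
    stopifnot(length(label) == 3)
    p <- setNames(as.numeric(label), c("s_p", "r_p", "l_p"))
  } else {
    tab <- ageing_scenarios()
    i <- match(label, tab$label)
    if (is.na(i)) stop("unknown scenario label: ", label, call. = FALSE)
    p <- c(s_p = tab$s_p[i], r_p = tab$r_p[i], l_p = tab$l_p[i])
  }
  if (p[["s_p"]] < 0 || p[["r_p"]] <= 0 || p[["l_p"]] <= 0) {
    stop("invalid passive force parameters", call. = FALSE)
  }
  p
}

#' Exponential passive force-length curve
#'
#' Dimensionless passive force of a muscle stretched to normalized length
#' `lbar`: zero at or below the slack length `l_p`, and growing as
#' `s_p (exp(r_p (lbar - l_p)) - 1)` above it.  Continuous at the slack point
#' and strictly increasing beyond it.
#'
#' @param params Passive parameters from [scenario_params()].
#' @param lbar Normalized muscle length(s), `l / l0`.
#' @return Dimensionless passive force, same length as `lbar`.
#' @export
passive_force <- function(params, lbar) {
  stopifnot(all(lbar > 0))
  ifelse(lbar > params[["l_p"]],
         params[["s_p"]] * (exp(params[["r_p"]] * (lbar - params[["l_p"]])) - 1),
         0)
}

#' Active force-length-velocity scaling
#'
#' The dimensionless factor `f_a(lbar, ldot)` multiplying activation in the
#' total force equation, normalized so `f_a(1, 0) = 1`.
#'
#' @param muscles A [muscle_params()].
#' @param lbar Normalized muscle length.
#' @param ldot_norm Normalized lengthening velocity in optimal lengths per
#'   second (negative when shortening).
#' @return Dimensionless active scaling factor.
#' @export
active_force_scale <- function(muscles, lbar, ldot_norm = 0) {
  n <- max(length(lbar), length(ldot_norm))
  lbar <- rep_len(lbar, n)
  ldot_norm <- rep_len(ldot_norm, n)
  geom <- arm_geometry()
  vapply(seq_len(n), function(i) {
    cpp_active_fa(geom, muscles, c(0.05, 5, 1.3), lbar[i], ldot_norm[i])
  }, numeric(1))
}

#' Total muscle force
#'
#' Hill-type total force `fmax * (f_a(lbar, ldot) a + f_p(lbar))`: active
#' contribution scaled by activation plus the length-dependent passive term.
#' Muscles pull, never push, so the result is non-negative.
#'
#' @param muscles A [muscle_params()].
#' @param params Passive parameters from [scenario_params()].
#' @param lbar Normalized muscle length.
#' @param ldot Lengthening velocity (m/s).
#' @param a Activation in `[0, 1]`.
#' @param muscle Index 1-6 selecting `fmax` and `l0` (default 1).
#' @return Force in newtons.
#' @export
total_force <- function(muscles, params, lbar, ldot = 0, a = 0, muscle = 1L) {
  stopifnot(a >= 0, a <= 1)
  fa <- active_force_scale(muscles, lbar, ldot / muscles$l0[muscle])
  f <- muscles$fmax[muscle] * (fa * a + passive_force(params, lbar))
  pmax(f, 0)
}

#' Muscle lengths and moment arms at a posture
#'
#' @param model An [arm_model()].
#' @param q Joint angles (rad).
#' @param qdot Joint velocities (rad/s).
#' @return A tibble with one row per muscle: `muscle`, `joint`, `role`,
#'   `l` (m), `lbar`, `ldot` (m/s), `moment_arm` (signed, m).
#' @export
muscle_lengths <- function(model, q, qdot = c(0, 0, 0)) {
  check_q(model, q)
  a <- model_args(model)
  k <- cpp_muscle_kinematics(a$geom, a$mus, a$scen, q, qdot)
  tibble::tibble(
    muscle = seq_len(6),
    joint = c("shoulder", "shoulder", "elbow", "elbow", "wrist", "wrist"),
    role = rep(c("flexor", "extensor"), 3),
    l = as.numeric(k$l), lbar = as.numeric(k$lbar),
    ldot = as.numeric(k$ldot), moment_arm = as.numeric(k$moment_arm))
}

#' Net muscle torques on the joints
#'
#' Sums each muscle's total force times its signed moment arm per joint.
#'
#' @inheritParams muscle_lengths
#' @param activations Six activation states in `[0, 1]`.
#' @param scenario Passive parameters from [scenario_params()].
#' @return A list with `tau` (3 joint torques, N m) and `force` (6 muscle
#'   forces, N).
#' @export
muscle_joint_torques <- function(model, q, qdot = c(0, 0, 0),
                                 activations = rep(0, 6),
                                 scenario = scenario_params("no_passive")) {
  check_q(model, q)
  stopifnot(length(activations) == 6, all(activations >= 0),
            all(activations <= 1))
  a <- model_args(model, scenario)
  r <- cpp_muscle_torques(a$geom, a$mus, a$scen, q, qdot, activations)
  list(tau = as.numeric(r$tau), force = as.numeric(r$force))
}

#' One step of the third-order activation dynamics
#'
#' Advances the three-stage low-pass chain converting an excitation signal
#' into muscle activation.  Activation converges to a constant excitation and
#' stays within `[0, 1]` for admissible excitations.
#'
#' @param muscles A [muscle_params()].
#' @param state Internal state, three values in `[0, 1]` (activation is the
#'   third).
#' @param u Excitation in `[0, 1]`.
#' @param dt Time step (s), positive.
#' @return Updated length-3 state; element 3 is the activation.
#' @export
activation_step <- function(muscles, state = c(0, 0, 0), u, dt) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  stopifnot(u >= 0, u <= 1, length(state) == 3)
  # exact exponential update of each linear stage over dt, sequentially using
  # the sub-stepped RK4 of the full simulator would be overkill here; a
  # sufficiently fine RK4 on the 3-state chain matches the simulator's path
  n <- max(1L, ceiling(dt / 1e-4))
  h <- dt / n
  tau <- muscles$act_tau
  y <- state
  f <- function(y) c((u - y[1]) / tau[1], (y[1] - y[2]) / tau[2],
                     (y[2] - y[3]) / tau[3])
  for (i in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  pmin(pmax(y, 0), 1)
}

#' Work to elongate a muscle along its passive curve
#'
#' Integral of the dimensionless passive force from the slack length to
#' `lbar_max`, in closed form
#' `s_p ((exp(r_p D) - 1) / r_p - D)` with `D = lbar_max - l_p`; zero when the
#' muscle never reaches its slack length.  Used to rank scenario severity.
#'
#' @param params Passive parameters from [scenario_params()].
#' @param lbar_max Maximum normalized length reached by the muscle.
#' @return Dimensionless elongation work.
#' @export
elongation_work <- function(params, lbar_max) {
  d <- lbar_max - params[["l_p"]]
  ifelse(d > 0,
         params[["s_p"]] * ((exp(params[["r_p"]] * d) - 1) / params[["r_p"]] - d),
         0)
}

#' Largest normalized muscle length over the feasible joint box
#'
#' Sweeps all joint-angle combinations on a dense grid and returns the global
#' maximum of `l / l0` over the six muscles.  With the default geometry this
#' is 1.25, below the 1.26 bound at which no muscle generates passive force in
#' any feasible configuration.
#'
#' @param model An [arm_model()].
#' @param n_grid Grid points per joint (all combinations are evaluated).
#' @return The maximum normalized muscle length (dimensionless).
#' @export
max_normalized_length <- function(model, n_grid = 200) {
  a <- model_args(model)
  cpp_max_lbar(a$geom, a$mus, a$scen, as.integer(n_grid))
}
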