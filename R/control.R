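#' Controller parameters
#'
#' The seven scalars of the predictive PD controller: a proportional and a
#' derivative gain per joint, plus the prediction time over which the
#' controller forward-simulates its internal model of the arm before
#' computing the tracking error.  The prediction time is quantized to an
#' integer number of control steps when used.
#'
#' @param kp Proportional gains (N m/rad), shoulder/elbow/wrist.
#' @param kd Derivative gains (N m s/rad).
#' @param t_pred Prediction time (s), non-negative.
#' @return An object of class `control_params`.
#' @export
control_params <- function(kp, kd, t_pred) {
  kp <- as.numeric(kp); kd <- as.numeric(kd)
  stopifnot(length(kp) == 3, length(kd) == 3, length(t_pred) == 1,
            all(kp >= 0), all(kd >= 0), t_pred >= 0)
  structure(list(kp = kp, kd = kd, t_pred = as.numeric(t_pred)),
            class = "control_params")
}

#' @export
format.control_params <- function(x, ...) {
  sprintf("control_params: kp = (%s), kd = (%s), t_pred = %.0f ms",
          paste(signif(x$kp, 4), collapse = ", "),
          paste(signif(x$kd, 4), collapse = ", "), 1000 * x$t_pred)
}

#' @export
print.control_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Tuned controller parameter sets shipped with the package
#'
#' Loads the controller parameters produced by the package's own
#' genetic-algorithm tuning runs (see [optimize_controls()]); provenance
#' (seed, population, generations, objective achieved) is stored alongside in
#' `inst/extdata/control_params.json`.  `"baseline"` control is the set tuned
#' for scenario A; `"reference"` the set tuned with no passive force;
#' `"retuned"` the set tuned for the requested scenario itself.
#'
#' @param scenario Scenario label (`"no_passive"`, `"A"` ... `"H"`).
#' @param control One of `"baseline"`, `"reference"`, `"retuned"`.
#' @return A [control_params()].
#' @export
default_control_params <- function(scenario = "A", control = "retuned") {
  control <- match.arg(control, c("baseline", "reference", "retuned"))
  path <- system.file("extdata", "control_params.csv", package = "reacharm")
  if (!nzchar(path)) {
    stop("no tuned control parameters installed with the package", call. = FALSE)
  }
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lab <- switch(control, baseline = "A", reference = "no_passive", scenario)
  row <- tab[tab$scenario == lab, ]
  if (nrow(row) != 1) {
    stop("no tuned parameters stored for scenario ", lab, call. = FALSE)
  }
  control_params(kp = c(row$kp1, row$kp2, row$kp3),
                 kd = c(row$kd1, row$kd2, row$kd3), t_pred = row$t_pred)
}

#' Predict the arm state ahead of time
#'
#' Forward-simulates the model's own (noise-free) dynamics over the
#' prediction time while holding the current excitations, exactly as the
#' controller's internal forward model does.  With `t_pred = 0` the state is
#' returned unchanged.
#'
#' @param model An [arm_model()].
#' @param state Full state vector: `q` (3), `qdot` (3), then three activation
#'   states per muscle (18).
#' @param excitations Held muscle excitations, length 6.
#' @param t_pred Prediction horizon (s).
#' @param scenario Passive parameters from [scenario_params()].
#' @param dt Internal integration step (s).
#' @return The predicted state vector (length 24).
#' @export
predict_state <- function(model, state, excitations = rep(0, 6), t_pred,
                          scenario = scenario_params("no_passive"),
                          dt = 0.001) {
  stopifnot(t_pred >= 0, length(state) == 24, length(excitations) == 6)
  a <- model_args(model, scenario)
  as.numeric(cpp_predict_state(a$geom, a$mus, a$scen, state, excitations,
                               t_pred, dt))
}

#' Desired joint torques for one control step
#'
#' Inverse-dynamics feedforward along the reference trajectory plus a PD
#' correction on the (predicted) joint-space tracking error:
#' `tau = ID(q_ref, qd_ref, qdd_ref) + Kp (q_ref - q) + Kd (qd_ref - qd)`.
#'
#' @param model An [arm_model()].
#' @param q,qdot Current (typically predicted) joint state.
#' @param q_ref,qd_ref,qdd_ref Reference joint position, velocity and
#'   acceleration at the (predicted) evaluation time.
#' @param cp A [control_params()].
#' @return Desired joint torques (N m), length 3.
#' @export
control_step <- function(model, q, qdot, q_ref, qd_ref, qdd_ref, cp) {
  ff <- inverse_dynamics(model, q_ref, qd_ref, qdd_ref)
  ff + cp$kp * (q_ref - q) + cp$kd * (qd_ref - qdot)
}

#' Convert desired torques to muscle excitations
#'
#' Realizes the desired joint torques under the no-co-excitation rule: at
#' each joint at most one of the flexor/extensor pair receives a non-zero
#' excitation.  The agonist is the muscle whose pull matches the sign of the
#' desired torque; its excitation is the demand divided by its moment arm and
#' active force-scaling at the (predicted) operating point, with a capped
#' first-order lead compensation for the activation lag over the prediction
#' time, clamped to `[0, 1]` (demands beyond capacity saturate at 1).  The
#' inversion models only the active muscle apparatus: passive muscle forces
#' are an unmodeled disturbance that the feedback gains must overcome, which
#' is precisely the pathway by which passive stiffening degrades reaching.
#'
#' @param model An [arm_model()].
#' @param state Full 24-element state vector (see [predict_state()]).
#' @param tau_des Desired joint torques (N m).
#' @param scenario Passive parameters from [scenario_params()].
#' @param t_pred Prediction time used for the lag compensation (s).
#' @return Six excitations in `[0, 1]`, at most one non-zero per joint.
#' @export
torques_to_excitations <- function(model, state, tau_des,
                                   scenario = scenario_params("no_passive"),
                                   t_pred = 0) {
  stop_if_not_finite(tau_des, "tau_des")
  stopifnot(length(state) == 24, length(tau_des) == 3)
  a <- model_args(model, scenario)
  as.numeric(cpp_excitations(a$geom, a$mus, a$scen, state, tau_des, t_pred))
}
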