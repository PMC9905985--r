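#' Arm geometry
#'
#' Physical description of the planar four-segment arm: a stationary upper
#' chest (a bar along the negative x-axis with the shoulder at the origin) and
#' three moving segments (upper arm, forearm, hand) connected by range-limited
#' hinge joints.  All motion is in the horizontal plane, so gravity exerts no
#' joint torque.  Angles are measured counter-clockwise; flexion is positive.
#'
#' Joint limits are enforced in the dynamics by a stiff one-sided penalty
#' torque with damping engaged only beyond the limit, which keeps the
#' equations of motion smooth for the integrator.
#'
#' @param segment_lengths Lengths of upper arm, forearm, hand (m).
#' @param segment_masses Segment masses (kg).
#' @param segment_com_offsets Centre-of-mass distance from the proximal joint
#'   along each segment (m).
#' @param segment_inertias Moments of inertia about each segment's centre of
#'   mass (kg m^2).
#' @param joint_min,joint_max Joint range of motion (rad), shoulder/elbow/wrist.
#' @param initial_joint_angles Reset posture of the arm (rad); every reach
#'   starts here at rest.
#' @param chest_span Extent of the chest bar from the shoulder towards the
#'   contralateral side (m).
#' @param limit_stiffness,limit_damping One-sided joint-limit penalty
#'   stiffness (N m/rad) and damping (N m s/rad).
#'
#' @return An object of class `arm_geometry`.
#' @export
arm_geometry <- function(segment_lengths = c(0.30, 0.25, 0.18),
                         segment_masses = c(2.0, 1.2, 0.5),
                         segment_com_offsets = c(0.135, 0.1125, 0.09),
                         segment_inertias = c(0.015, 0.00625, 0.00135),
                         joint_min = c(-10, 0, -45) * pi / 180,
                         joint_max = c(150, 150, 45) * pi / 180,
                         initial_joint_angles = c(70, 75, 0) * pi / 180,
                         chest_span = 0.44,
                         limit_stiffness = 500,
                         limit_damping = 5) {
  for (nm in c("segment_lengths", "segment_masses", "segment_com_offsets",
               "segment_inertias")) {
    v <- get(nm)
    if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be 3 strictly positive finite values", nm),
           call. = FALSE)
    }
  }
  if (any(joint_min >= joint_max)) {
    stop("`joint_min` must be strictly below `joint_max` for every joint",
         call. = FALSE)
  }
  if (any(initial_joint_angles < joint_min | initial_joint_angles > joint_max)) {
    stop("`initial_joint_angles` must lie within the joint limits",
         call. = FALSE)
  }
  structure(
    list(segment_lengths = as.numeric(segment_lengths),
         segment_masses = as.numeric(segment_masses),
         segment_com_offsets = as.numeric(segment_com_offsets),
         segment_inertias = as.numeric(segment_inertias),
         joint_min = as.numeric(joint_min),
         joint_max = as.numeric(joint_max),
         initial_joint_angles = as.numeric(initial_joint_angles),
         chest_span = chest_span,
         limit_stiffness = limit_stiffness,
         limit_damping = limit_damping),
    class = "arm_geometry")
}

#' Arm model: geometry plus the six-muscle apparatus
#'
#' Bundles the rigid-body geometry with the Hill-type muscle parameters into
#' the single object most package functions take as their first argument.
#'
#' @param geometry An [arm_geometry()].
#' @param muscles A [muscle_params()].
#' @return An object of class `arm_model`.
#' @export
arm_model <- function(geometry = arm_geometry(), muscles = muscle_params()) {
  stopifnot(inherits(geometry, "arm_geometry"), inherits(muscles, "muscle_params"))
  structure(list(geometry = geometry, muscles = muscles), class = "arm_model")
}

# internal: the (geom, mus, scen) triple every C++ entry point takes
model_args <- function(model, scenario = scenario_params("no_passive")) {
  list(geom = model$geometry, mus = model$muscles,
       scen = as.numeric(scenario[c("s_p", "r_p", "l_p")]))
}

check_q <- function(model, q) {
  if (length(q) != 3) stop("`q` must have three joint angles", call. = FALSE)
  stop_if_not_finite(q, "q")
  invisible(q)
}

#' Forward kinematics of the arm
#'
#' Maps joint angles to the planar position of the endpoint (the distal tip of
#' the hand segment) and of each joint.
#'
#' @param model An [arm_model()].
#' @param q Joint angles (rad), length 3.
#' @return A list with `endpoint` (length-2 numeric, m) and `joints`
#'   (4 x 2 matrix: shoulder, elbow, wrist, endpoint).
#' @export
forward_kinematics <- function(model, q) {
  check_q(model, q)
  a <- model_args(model)
  P <- cpp_joint_positions(a$geom, a$mus, a$scen, q)
  list(endpoint = as.numeric(P[4, ]), joints = P)
}

#' Endpoint Jacobian
#'
#' The 2 x 3 matrix mapping joint velocities to endpoint velocity.
#'
#' @inheritParams forward_kinematics
#' @return A 2 x 3 numeric matrix.
#' @export
endpoint_jacobian <- function(model, q) {
  check_q(model, q)
  a <- model_args(model)
  cpp_jacobian(a$geom, a$mus, a$scen, q)
}

#' Forward dynamics of the arm
#'
#' Solves `M(q) qddot + C(q, qdot) qdot = tau` (plus the one-sided joint-limit
#' penalty torques when `limits = TRUE`) for the joint accelerations.  There
#' is no gravity term because the arm moves in the horizontal plane.
#'
#' @inheritParams forward_kinematics
#' @param qdot Joint velocities (rad/s).
#' @param tau Applied joint torques (N m).
#' @param limits Include joint-limit penalty torques?
#' @return Joint accelerations (rad/s^2), length 3.
#' @export
forward_dynamics <- function(model, q, qdot, tau, limits = TRUE) {
  check_q(model, q)
  stop_if_not_finite(qdot, "qdot")
  stop_if_not_finite(tau, "tau")
  a <- model_args(model)
  as.numeric(cpp_forward_dynamics(a$geom, a$mus, a$scen, q, qdot, tau, limits))
}

#' Inverse dynamics of the arm
#'
#' Exact joint torques that produce `qddot` at `(q, qdot)` under the same
#' equations of motion as [forward_dynamics()] (joint-limit torques excluded).
#' Interaction torques between coupled segments are fully accounted for, which
#' is what lets the controller counteract them.
#'
#' @inheritParams forward_dynamics
#' @param qddot Desired joint accelerations (rad/s^2).
#' @return Joint torques (N m), length 3.
#' @export
inverse_dynamics <- function(model, q, qdot, qddot) {
  check_q(model, q)
  stop_if_not_finite(qdot, "qdot")
  stop_if_not_finite(qddot, "qddot")
  a <- model_args(model)
  as.numeric(cpp_inverse_dynamics(a$geom, a$mus, a$scen, q, qdot, qddot))
}

#' Joint-space mass matrix
#'
#' @inheritParams forward_kinematics
#' @return A symmetric positive definite 3 x 3 matrix (kg m^2).
#' @export
mass_matrix <- function(model, q) {
  check_q(model, q)
  a <- model_args(model)
  cpp_mass_matrix(a$geom, a$mus, a$scen, q)
}

#' Kinetic energy of the arm
#'
#' @inheritParams forward_dynamics
#' @return Scalar kinetic energy (J).
#' @export
kinetic_energy <- function(model, q, qdot) {
  a <- model_args(model)
  cpp_kinetic_energy(a$geom, a$mus, a$scen, q, qdot)
}
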