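# Shared fixtures, memoized so expensive objects are built once per test run.
.fixtures <- new.env(parent = emptyenv())

fix_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- arm_model()
  .fixtures$model
}

fix_settings <- function() sim_settings()

fix_boundary <- function() {
  if (is.null(.fixtures$boundary)) {
    .fixtures$boundary <- estimate_workspace(fix_model())
  }
  .fixtures$boundary
}

fix_targets <- function() {
  if (is.null(.fixtures$targets)) {
    .fixtures$targets <- make_target_sets(fix_model(), fix_boundary())
  }
  .fixtures$targets
}

# a conservative hand-set controller, comfortably inside the stable region,
# for tests that must not depend on the shipped tuned parameters
fix_control <- function() {
  control_params(kp = c(60, 12, 1), kd = c(6, 1.2, 0.1), t_pred = 0.03)
}

fix_initial_endpoint <- function() {
  m <- fix_model()
  forward_kinematics(m, m$geometry$initial_joint_angles)$endpoint
}

# random feasible joint configuration
random_q <- function(model = fix_model()) {
  g <- model$geometry
  g$joint_min + runif(3) * (g$joint_max - g$joint_min)
}

# synthetic reach_result carrying only what the metrics need
synthetic_result <- function(t, T, dist = NULL, dev = NULL,
                             activation = NULL, unstable = FALSE) {
  structure(list(t = t, T = T, dist = dist, dev = dev,
                 activation = activation, unstable = unstable),
            class = "reach_result")
}
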