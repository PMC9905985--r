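#' Homing-in error
#'
#' Time-averaged distance (mm) between the endpoint and the target over the
#' homing phase, which lasts from the moment the planned trajectory reaches
#' the target to the end of the simulation.  Besides accuracy, it doubles as
#' a dynamic-stability indicator: oscillating or diverging reaches average a
#' large distance.  Averages use trapezoidal integration so they are robust
#' to the sampling step.
#'
#' @param result A [simulate_reach()] result with its time series.
#' @return Non-negative error in millimetres.
#' @export
homing_in_error <- function(result) {
  i <- which(result$t >= result$T)
  if (length(i) < 1) stop("empty homing phase", call. = FALSE)
  1000 * trapz_mean(result$t[i], result$dist[i])
}

#' Movement error
#'
#' Time-averaged deviation (mm) of the endpoint from the planned reference
#' trajectory over the movement phase `[0, T]` — the tracking accuracy.
#'
#' @inheritParams homing_in_error
#' @return Non-negative error in millimetres.
#' @export
movement_error <- function(result) {
  i <- which(result$t <= result$T)
  if (length(i) < 1) stop("empty movement phase", call. = FALSE)
  1000 * trapz_mean(result$t[i], result$dev[i])
}

#' Per-joint co-activation
#'
#' Time-average of the simultaneous activation of a joint's antagonistic
#' pair, `min(a_flexor, a_extensor)`, over the whole movement.  Co-activation
#' is emergent here: the controller never excites both muscles of a pair at
#' the same time, but activation dynamics let their activations overlap when
#' the desired torque changes direction.
#'
#' @inheritParams homing_in_error
#' @param joint Joint index (1 shoulder, 2 elbow, 3 wrist) or name.
#' @return Co-activation level in `[0, 1]`.
#' @export
co_activation <- function(result, joint = 1L) {
  if (is.character(joint)) {
    joint <- match(joint, c("shoulder", "elbow", "wrist"))
  }
  stopifnot(joint %in% 1:3)
  af <- result$activation[, 2 * joint - 1]
  ae <- result$activation[, 2 * joint]
  trapz_mean(result$t, pmin(af, ae))
}

#' Classify the outcome of a reach
#'
#' Taxonomy of the failure modes: a reach is a `success` when the homing-in
#' error is at or below `success_mm`.  Failed reaches split into `oscillatory`
#' (the endpoint keeps oscillating through or around the target during the
#' homing phase, including chaotic and quasi-steady oscillation and
#' integrator blow-ups) and `stopping_short` (the arm decelerates smoothly
#' and stabilizes at a distance from the target, a static force balance
#' between agonist drive and passive antagonist force).  Oscillation is
#' detected by counting direction reversals of the distance-to-target signal
#' in the homing phase whose peak-to-peak amplitude exceeds `amp_floor_mm`;
#' more than `max_reversals` reversals classifies the reach oscillatory.
#'
#' @inheritParams homing_in_error
#' @param success_mm Success threshold on `e_h` (mm).
#' @param max_reversals Reversal count above which a failure is oscillatory.
#' @param amp_floor_mm Minimum peak-to-peak excursion counted (mm).
#' @return One of `"success"`, `"stopping_short"`, `"oscillatory"`.
#' @export
classify_failure <- function(result, success_mm = 1, max_reversals = 6,
                             amp_floor_mm = 1) {
  e_h <- if (!is.null(result$e_h)) result$e_h else homing_in_error(result)
  if (e_h <= success_mm) return("success")
  if (isTRUE(result$unstable)) return("oscillatory")
  i <- which(result$t >= result$T)
  d <- result$dist[i] * 1000
  # local extrema of the distance signal, then count alternations whose
  # amplitude clears the floor
  dd <- diff(d)
  nz <- which(dd != 0)
  if (length(nz) < 2) return("stopping_short")
  s <- sign(dd[nz])
  turns <- nz[which(diff(s) != 0)] + 1L
  ext <- c(d[1], d[turns], d[length(d)])
  amp <- abs(diff(ext))
  if (sum(amp > amp_floor_mm) > max_reversals) "oscillatory" else "stopping_short"
}

#' Fraction of failed targets on a boundary subset
#'
#' Fraction of in-workspace targets of one boundary side whose homing-in
#' error exceeds a threshold.  The two reporting thresholds, 1 mm and
#' 0.1 mm, are nested: the 0.1 mm fraction is always at least the 1 mm one.
#'
#' @param metrics A metrics tibble from [run_target_set()] with columns
#'   `e_h`, `in_workspace` and `boundary_side`.
#' @param side `"left"`, `"right"`, or `"any"`.
#' @param e_h_threshold Threshold (mm).
#' @return Fraction in `[0, 1]`.
#' @export
failure_fraction <- function(metrics, side = "any", e_h_threshold = 1) {
  stopifnot(is.data.frame(metrics), "e_h" %in% names(metrics))
  keep <- if ("in_workspace" %in% names(metrics)) metrics$in_workspace
          else rep(TRUE, nrow(metrics))
  if (side != "any") {
    stopifnot("boundary_side" %in% names(metrics))
    keep <- keep & metrics$boundary_side == side
  }
  sub <- metrics[keep, ]
  if (nrow(sub) == 0) stop("empty boundary subset", call. = FALSE)
  mean(sub$e_h > e_h_threshold)
}
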