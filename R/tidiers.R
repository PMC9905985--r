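#' Tidy a reach result into its time series
#'
#' @param x A [simulate_reach()] result with its series kept.
#' @param ... Unused.
#' @return A tibble with one row per control step: time, joint state,
#'   endpoint, reference, distance to target, per-muscle activation, force
#'   and excitation.
#' @export
tidy.reach_result <- function(x, ...) {
  if (!"t" %in% names(x)) {
    stop("reach_result was run with `keep_series = FALSE`", call. = FALSE)
  }
  r <- unclass(x)
  mus <- c("sh_flex", "sh_ext", "el_flex", "el_ext", "wr_flex", "wr_ext")
  out <- tibble::tibble(
    t = r$t,
    q1 = r$q[, 1], q2 = r$q[, 2], q3 = r$q[, 3],
    qd1 = r$qdot[, 1], qd2 = r$qdot[, 2], qd3 = r$qdot[, 3],
    x = r$endpoint[, 1], y = r$endpoint[, 2],
    x_ref = r$p_ref[, 1], y_ref = r$p_ref[, 2],
    dist_to_target = r$dist, dev_from_ref = r$dev)
  for (i in seq_along(mus)) {
    out[[paste0("a_", mus[i])]] <- r$activation[, i]
    out[[paste0("f_", mus[i])]] <- r$force[, i]
    out[[paste0("u_", mus[i])]] <- r$excitation[, i]
  }
  out
}

#' One-row summary of a reach
#'
#' @inheritParams tidy.reach_result
#' @return A tibble with the reach metrics: homing-in and movement errors
#'   (mm), per-joint co-activation, failure class and stability flags.
#' @export
glance.reach_result <- function(x, ...) {
  tibble::tibble(
    target_x = x$target[1], target_y = x$target[2], T = x$T,
    e_h = x$e_h, e_mv = x$e_mv,
    coact_shoulder = x$coactivation[["shoulder"]],
    coact_elbow = x$coactivation[["elbow"]],
    coact_wrist = x$coactivation[["wrist"]],
    failure = x$failure, unstable = x$unstable, saturated = x$saturated)
}

#' Per-muscle time-series export
#'
#' Writes one CSV per reach with the per-muscle series (`t`, `lbar`, `a`,
#' `f_tot` for each muscle) plus endpoint and reference columns.
#'
#' @param result A [simulate_reach()] result with series.
#' @param path Output CSV path.
#' @param model The [arm_model()] used (for muscle lengths).
#' @return The path, invisibly.
#' @export
write_reach_csv <- function(result, path, model = arm_model()) {
  ser <- tidy(result)
  lb <- t(apply(result$q, 1, function(qk)
    muscle_lengths(model, qk)$lbar))
  colnames(lb) <- paste0("lbar_", c("sh_flex", "sh_ext", "el_flex", "el_ext",
                                    "wr_flex", "wr_ext"))
  write.csv(cbind(ser, lb), path, row.names = FALSE)
  invisible(path)
}
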