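#' Default full model configuration
#'
#' Nested list of every physical, scenario, controller, integrator and GA
#' setting, in the units used throughout (metres, kilograms, radians,
#' seconds, newtons).  A YAML rendering of this configuration ships at
#' `inst/extdata/default_config.yaml`.
#'
#' @return A named nested list with a `config_version` field.
#' @export
default_config <- function() {
  geom <- arm_geometry()
  mus <- muscle_params()
  st <- sim_settings()
  ga <- ga_settings()
  list(
    config_version = 1L,
    geometry = unclass(geom),
    muscles = unclass(mus),
    scenarios = as.data.frame(ageing_scenarios()),
    settings = unclass(st),
    ga = unclass(ga))
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, fills unspecified blocks from the defaults,
#' and validates values; errors name the offending key.  Unknown top-level
#' or block keys are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- def
  for (blk in names(raw)) {
    if (blk %in% c("config_version")) { cfg[[blk]] <- raw[[blk]]; next }
    if (blk == "scenarios") {
      cfg$scenarios <- do.call(rbind, lapply(raw$scenarios, as.data.frame))
      next
    }
    bad <- setdiff(names(raw[[blk]]), names(def[[blk]]))
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in `%s`: %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    cfg[[blk]][names(raw[[blk]])] <- raw[[blk]]
  }
  # validation with key paths; the constructors re-check invariants
  g <- cfg$geometry
  for (nm in c("segment_lengths", "segment_masses", "segment_inertias",
               "segment_com_offsets")) {
    if (any(unlist(g[[nm]]) <= 0)) {
      stop(sprintf("geometry$%s: values must be strictly positive", nm),
           call. = FALSE)
    }
  }
  if (any(unlist(g$joint_min) >= unlist(g$joint_max))) {
    stop("geometry$joint_min/joint_max: min must be below max", call. = FALSE)
  }
  m <- cfg$muscles
  if (any(unlist(m$fmax) <= 0)) {
    stop("muscles$fmax: values must be strictly positive", call. = FALSE)
  }
  if (any(unlist(m$l0) <= 0)) {
    stop("muscles$l0: values must be strictly positive", call. = FALSE)
  }
  sc <- cfg$scenarios
  if (any(sc$s_p < 0) || any(sc$r_p <= 0) || any(sc$l_p <= 0)) {
    stop("scenarios: require s_p >= 0, r_p > 0, l_p > 0", call. = FALSE)
  }
  if (cfg$settings$dt <= 0) stop("settings$dt: must be positive", call. = FALSE)
  cfg
}

#' Write a configuration to YAML
#'
#' @param config A configuration list (see [default_config()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- config
  cfg$scenarios <- lapply(seq_len(nrow(config$scenarios)), function(i)
    as.list(config$scenarios[i, ]))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Build an arm model from a configuration
#'
#' @param config A configuration list from [load_config()] or
#'   [default_config()].
#' @return An [arm_model()].
#' @export
model_from_config <- function(config) {
  g <- config$geometry
  m <- config$muscles
  arm_model(
    geometry = arm_geometry(
      segment_lengths = unlist(g$segment_lengths),
      segment_masses = unlist(g$segment_masses),
      segment_com_offsets = unlist(g$segment_com_offsets),
      segment_inertias = unlist(g$segment_inertias),
      joint_min = unlist(g$joint_min), joint_max = unlist(g$joint_max),
      initial_joint_angles = unlist(g$initial_joint_angles),
      chest_span = g$chest_span, limit_stiffness = g$limit_stiffness,
      limit_damping = g$limit_damping),
    muscles = muscle_params(
      fmax = unlist(m$fmax), l0 = unlist(m$l0),
      moment_arm = unlist(m$moment_arm), sign = unlist(m$sign),
      joint = unlist(m$joint), fl_width = m$fl_width, v_max = m$v_max,
      fv_curvature = m$fv_curvature, fv_flen = m$fv_flen,
      act_tau = unlist(m$act_tau)))
}

#' Scenario parameters from a configuration
#'
#' @param config A configuration list.
#' @param label Scenario label present in the configuration's scenario table.
#' @return A named `c(s_p, r_p, l_p)` vector.
#' @export
config_scenario <- function(config, label) {
  sc <- config$scenarios
  i <- match(label, sc$label)
  if (is.na(i)) stop("unknown scenario label: ", label, call. = FALSE)
  c(s_p = sc$s_p[i], r_p = sc$r_p[i], l_p = sc$l_p[i])
}
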