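#' Mean homing-in error over a tuning target set
#'
#' The tuning objective: the mean of [homing_in_error()] over the targets,
#' each reach starting from the reset posture.  Unstable reaches contribute
#' their (large) computed error rather than raising.
#'
#' @param cp A [control_params()].
#' @param model An [arm_model()].
#' @param scenario Scenario label or parameters.
#' @param targets Target tibble (normally the four-target `opt_sequence`).
#' @param settings A [sim_settings()].
#' @param plans Optional precomputed plans keyed by `target_id`.
#' @return Mean homing-in error (mm).
#' @export
evaluate_objective <- function(cp, model, scenario, targets,
                               settings = sim_settings(), plans = NULL) {
  res <- run_target_set(targets, model, scenario, cp, settings, plans)
  mean(res$e_h)
}

#' Genetic-algorithm settings
#'
#' @param population Population size.
#' @param generations Number of generations.
#' @param kp_max,kd_max Upper bounds of the proportional / derivative gains.
#' @param t_pred_max Upper bound of the prediction time (s); the gene is an
#'   integer number of control steps.
#' @param elites Individuals copied unchanged each generation.
#' @param tournament Tournament size for parent selection.
#' @param p_mut_real,p_mut_int Per-gene mutation probabilities.
#' @param mut_sd Gaussian mutation standard deviation, as a fraction of each
#'   real gene's range.
#' @return A list of class `ga_settings`.
#' @export
ga_settings <- function(population = 40L, generations = 60L, kp_max = 300,
                        kd_max = 50, t_pred_max = 0.1, elites = 2L,
                        tournament = 3L, p_mut_real = 0.25, p_mut_int = 0.3,
                        mut_sd = 0.1) {
  stopifnot(population >= 4, generations >= 1, kp_max > 0, kd_max > 0,
            t_pred_max >= 0, elites >= 1, elites < population)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations), kp_max = kp_max,
                 kd_max = kd_max, t_pred_max = t_pred_max,
                 elites = as.integer(elites), tournament = as.integer(tournament),
                 p_mut_real = p_mut_real, p_mut_int = p_mut_int,
                 mut_sd = mut_sd),
            class = "ga_settings")
}

genes_to_cp <- function(g, dt) {
  control_params(kp = g[1:3], kd = g[4:6], t_pred = g[7] * dt)
}

cp_to_genes <- function(cp, dt) {
  c(cp$kp, cp$kd, round(cp$t_pred / dt))
}

#' Tune the seven controller parameters with a mixed-integer GA
#'
#' Minimizes the mean homing-in error over the tuning target sequence with a
#' genetic algorithm over six real genes (the PD gains) and one integer gene
#' (the prediction time in control steps): tournament selection, uniform
#' crossover, Gaussian mutation on the real genes, random-walk mutation on
#' the integer gene, and elitism (so the best objective is non-increasing
#' across generations).  Known optima — e.g. the baseline optimum when
#' re-tuning an ageing scenario — can be injected into the initial
#' population.  Deterministic for a fixed `seed`.
#'
#' @param model An [arm_model()].
#' @param scenario Scenario label or parameters.
#' @param targets Tuning target tibble (the four-target `opt_sequence`).
#' @param ga A [ga_settings()].
#' @param settings A [sim_settings()].
#' @param seed Integer RNG seed.
#' @param seeds_in_population Optional list of [control_params()] injected
#'   into the initial population.
#' @return A list of class `control_tuning`: `best` ([control_params()]),
#'   `objective` (mm), `log` (per-generation tibble), and provenance.
#' @export
optimize_controls <- function(model, scenario, targets, ga = ga_settings(),
                              settings = sim_settings(), seed = 1L,
                              seeds_in_population = NULL) {
  if (is.character(scenario)) {
    scenario_label <- scenario
    scenario <- scenario_params(scenario)
  } else scenario_label <- "custom"
  dt <- settings$dt
  n_pred_max <- round(ga$t_pred_max / dt)
  lo <- c(rep(0, 6), 0)
  hi <- c(rep(ga$kp_max, 3), rep(ga$kd_max, 3), n_pred_max)
  plans <- lapply(seq_len(nrow(targets)), function(i)
    plan_reach(model, c(targets$x[i], targets$y[i]), settings = settings))
  names(plans) <- as.character(if ("target_id" %in% names(targets))
    targets$target_id else seq_len(nrow(targets)))
  obj <- function(g) {
    evaluate_objective(genes_to_cp(g, dt), model, scenario, targets,
                       settings, plans)
  }
  withr::local_seed(seed)
  pop <- t(vapply(seq_len(ga$population), function(i)
    c(runif(3, 0, ga$kp_max), runif(3, 0, ga$kd_max),
      sample(0:n_pred_max, 1)), numeric(7)))
  if (!is.null(seeds_in_population)) {
    for (i in seq_along(seeds_in_population)) {
      pop[i, ] <- cp_to_genes(seeds_in_population[[i]], dt)
    }
  }
  fit <- apply(pop, 1, obj)
  log <- vector("list", ga$generations)
  for (gen in seq_len(ga$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(ga$elites)], , drop = FALSE]
    while (nrow(newpop) < ga$population) {
      pick <- function() {
        cand <- sample(ga$population, ga$tournament)
        pop[cand[which.min(fit[cand])], ]
      }
      p1 <- pick(); p2 <- pick()
      mask <- runif(7) < 0.5
      child <- ifelse(mask, p1, p2)
      for (j in 1:6) {
        if (runif(1) < ga$p_mut_real) {
          child[j] <- child[j] + rnorm(1, 0, ga$mut_sd * (hi[j] - lo[j]))
        }
      }
      if (runif(1) < ga$p_mut_int) {
        child[7] <- child[7] + sample(c(-10:-1, 1:10), 1)
      }
      child <- pmin(pmax(child, lo), hi)
      child[7] <- round(child[7])
      newpop <- rbind(newpop, child)
    }
    newfit <- c(fit[ord[seq_len(ga$elites)]],
                apply(newpop[-seq_len(ga$elites), , drop = FALSE], 1, obj))
    pop <- newpop
    fit <- newfit
    log[[gen]] <- tibble::tibble(generation = gen, best = min(fit),
                                 mean = mean(fit))
  }
  best_i <- which.min(fit)
  structure(
    list(best = genes_to_cp(pop[best_i, ], dt), objective = unname(fit[best_i]),
         log = dplyr::bind_rows(log), scenario = scenario_label, seed = seed,
         ga = ga),
    class = "control_tuning")
}

#' @export
print.control_tuning <- function(x, ...) {
  cat(sprintf("control_tuning (%s): objective %.4g mm after %d generations\n",
              x$scenario, x$objective, x$ga$generations))
  print(x$best)
  invisible(x)
}

#' @rdname optimize_controls
#' @param x A `control_tuning` object.
#' @param ... Unused.
#' @export
tidy.control_tuning <- function(x, ...) x$log

#' @rdname optimize_controls
#' @export
glance.control_tuning <- function(x, ...) {
  b <- x$best
  tibble::tibble(scenario = x$scenario, objective = x$objective,
                 kp1 = b$kp[1], kp2 = b$kp[2], kp3 = b$kp[3],
                 kd1 = b$kd[1], kd2 = b$kd[2], kd3 = b$kd[3],
                 t_pred = b$t_pred, seed = x$seed,
                 generations = x$ga$generations,
                 population = x$ga$population)
}
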