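# full rectangular-grid sweeps are expensive; build once and share across
# acceptance checks
fix_grid_plans <- function(grid) {
  if (is.null(.fixtures$grid_plans)) {
    m <- fix_model()
    st <- fix_settings()
    pl <- lapply(seq_len(nrow(grid)), function(i)
      plan_reach(m, c(grid$x[i], grid$y[i]), settings = st))
    names(pl) <- as.character(grid$target_id)
    .fixtures$grid_plans <- pl
  }
  .fixtures$grid_plans
}

fix_sweep <- function(scenario, control) {
  key <- paste0("sweep_", scenario, "_", control)
  if (is.null(.fixtures[[key]])) {
    m <- fix_model()
    ts <- fix_targets()
    grid <- ts[ts$set_id == "rect_grid" & ts$in_workspace, ]
    cp <- default_control_params(scenario, control)
    .fixtures[[key]] <- run_target_set(grid, m, scenario, cp, fix_settings(),
                                       plans = fix_grid_plans(grid))
  }
  .fixtures[[key]]
}
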