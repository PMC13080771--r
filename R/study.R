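#' Parameter grid for a sweep
#'
#' @param forces Normal-force levels in nN (each in (0, 350]).
#' @param E_cyto Cytoplasm stiffness levels in kPa.
#' @param configs Force configurations to run.
#' @param material_model `"elastic"` or `"viscoelastic"` cytoplasm.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(forces = seq(50, 300, by = 50),
                       E_cyto = c(0.8, 1.2, 2.0),
                       configs = c("top", "bottom"),
                       material_model = c("elastic", "viscoelastic")) {
  material_model <- match.arg(material_model)
  stopifnot(length(forces) >= 1, length(E_cyto) >= 1, length(configs) >= 1,
            all(forces > 0), all(forces <= 350), all(E_cyto > 0),
            all(configs %in% c("top", "bottom")))
  g <- list(forces = forces, E_cyto = E_cyto, configs = configs,
            material_model = material_model)
  class(g) <- "sweep_grid"
  g
}

# One solved run of the full cell-on-gel model; viscoelastic runs report the
# state at the end of the loading ramp (the instant the full load is
# attained, matching the applied-load state of the elastic runs).
run_single <- function(mesh, bcs, E_cyto, force, config, material_model,
                       settings, visco_mode = "equilibrium",
                       allow_partial = FALSE) {
  mats <- default_materials(E_cyto = E_cyto, model = material_model,
                            visco_mode = visco_mode)
  lc <- load_case(force, config = config)
  la <- build_load_case(mesh, lc)
  if (material_model == "elastic") {
    solve_quasistatic(mesh, mats, la, bcs, settings, allow_partial)
  } else {
    solve_viscoelastic(mesh, mats, la, bcs, settings)$state_ramp_end
  }
}

#' Run a parameter sweep
#'
#' Solves one model per grid point in a fixed deterministic order and
#' tabulates the outcome metrics, then derives the top-versus-bottom
#' percentage-difference columns at every matched `(force, E_cyto)` point
#' (bottom-applied values are the baseline). Failures are recorded per row,
#' never dropped.
#'
#' @param grid A [sweep_grid()].
#' @param params Geometry parameters.
#' @param resolution Mesh resolution level.
#' @param settings Solver settings.
#' @param verbose Print per-run progress.
#' @param allow_partial Record runs whose equilibrium path ends before full
#'   load at the highest attained load (flagged by `converged = FALSE` and
#'   `load_factor < 1`) instead of as missing rows.
#' @return An object of class `sweep_table`: list with `runs` (one row per
#'   grid point) and `diffs` (percentage differences per matched pair).
#' @export
run_sweep <- function(grid = sweep_grid(), params = geometry_params(),
                      resolution = 1, settings = solver_settings(),
                      verbose = FALSE, allow_partial = TRUE) {
  stopifnot(inherits(grid, "sweep_grid"))
  mesh <- build_domain(params, resolution)
  bcs <- build_bcs(mesh)
  rows <- list()
  for (E in grid$E_cyto) for (F in grid$forces) for (cfg in grid$configs) {
    if (verbose)
      message(sprintf("run: F = %g nN, E_cyto = %g kPa, %s, %s",
                      F, E, cfg, grid$material_model))
    row <- tryCatch({
      st <- run_single(mesh, bcs, E, F, cfg, grid$material_model, settings,
                       allow_partial = allow_partial)
      rs <- result_summary(st, F = F, E_cyto = E, config = cfg,
                           model = grid$material_model)
      rs$converged <- !isTRUE(st$partial)
      rs
    }, error = function(e) {
      data.frame(F = F, E_cyto = E, config = cfg,
                 model = grid$material_model, converged = FALSE,
                 load_factor = NA_real_,
                 indentation_depth = NA_real_,
                 nucleus_total_stress = NA_real_, nucleus_vm_stress = NA_real_,
                 nucleus_peak_total = NA_real_,
                 cytoplasm_total_stress = NA_real_,
                 cytoplasm_vm_stress = NA_real_,
                 gel_transmitted_stress = NA_real_,
                 nucleus_aspect_ratio = NA_real_,
                 avg_effective_strain_cell = NA_real_,
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- row
  }
  runs <- do.call(rbind, rows)
  out <- list(runs = runs, diffs = sweep_diffs(runs))
  class(out) <- "sweep_table"
  if (any(!runs$converged))
    warning(sprintf("%d run(s) failed to converge", sum(!runs$converged)))
  out
}

# Percentage-difference table at matched grid points; defined only where
# both configurations converged.
sweep_diffs <- function(runs) {
  keys <- unique(runs[, c("F", "E_cyto", "model")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    top <- runs[runs$F == k$F & runs$E_cyto == k$E_cyto &
                  runs$model == k$model & runs$config == "top", ]
    bot <- runs[runs$F == k$F & runs$E_cyto == k$E_cyto &
                  runs$model == k$model & runs$config == "bottom", ]
    if (nrow(top) != 1 || nrow(bot) != 1 ||
        !top$converged || !bot$converged) next
    out[[length(out) + 1L]] <- data.frame(
      F = k$F, E_cyto = k$E_cyto, model = k$model,
      pct_diff_indentation = percent_difference(top$indentation_depth,
                                                bot$indentation_depth),
      pct_diff_nucleus_stress = percent_difference(top$nucleus_total_stress,
                                                   bot$nucleus_total_stress),
      pct_diff_cytoplasm_stress =
        percent_difference(top$cytoplasm_total_stress,
                           bot$cytoplasm_total_stress),
      pct_diff_gel_stress = percent_difference(top$gel_transmitted_stress,
                                               bot$gel_transmitted_stress),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(F = numeric(0), E_cyto = numeric(0), model = character(0),
               pct_diff_indentation = numeric(0),
               pct_diff_nucleus_stress = numeric(0),
               pct_diff_cytoplasm_stress = numeric(0),
               pct_diff_gel_stress = numeric(0))
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("Sweep: %d runs (%d converged), %d matched pairs\n",
              nrow(x$runs), sum(x$runs$converged), nrow(x$diffs)))
  invisible(x)
}

#' Mesh convergence study
#'
#' Solves one representative load case at a sequence of uniform refinement
#' levels and reports the tracked outcome metrics per level with their
#' relative change between consecutive levels. The convergence declaration
#' (`converged_level`) follows the primary outcome, indentation depth: the
#' coarsest level whose depth changes by less than `tol` (default 2%)
#' against the next refinement. The other metrics are tabulated for
#' inspection; volume-mean signed stresses converge more slowly at small
#' loads because they are near-cancelling integrals.
#'
#' @param params Geometry parameters.
#' @param lc Representative [load_case()].
#' @param materials Region materials (elastic).
#' @param refinements Integer vector of uniform subdivision factors applied
#'   to the base mesh (at least two levels).
#' @param resolution Base mesh resolution.
#' @param settings Solver settings.
#' @param tol Convergence threshold on the relative change (default 0.02).
#' @return List of class `convergence_report` with the per-level metric
#'   table, the per-transition relative changes, and `converged_level` (NA
#'   if the criterion is never met).
#' @export
mesh_convergence_study <- function(params = geometry_params(),
                                   lc = load_case(300, "top"),
                                   materials = default_materials(),
                                   refinements = c(1, 2),
                                   resolution = 1,
                                   settings = solver_settings(),
                                   tol = 0.02) {
  stopifnot(length(refinements) >= 2)
  base <- build_domain(params, resolution)
  metr <- list()
  for (f in refinements) {
    mesh <- refine_mesh(base, f)
    bcs <- build_bcs(mesh)
    la <- build_load_case(mesh, lc)
    st <- solve_quasistatic(mesh, materials, la, bcs, settings)
    metr[[length(metr) + 1L]] <- data.frame(
      refinement = f,
      n_elements = nrow(mesh$tri6),
      indentation_depth = indentation_depth(st),
      nucleus_total_stress = region_stress_aggregate(st, "nucleus", "total"),
      nucleus_vm_stress = region_stress_aggregate(st, "nucleus", "von_mises"),
      gel_transmitted_stress = gel_transmitted_stress(st),
      avg_effective_strain_cell = average_effective_strain(st, "cell"))
  }
  tab <- do.call(rbind, metr)
  tracked <- c("indentation_depth", "nucleus_total_stress",
               "nucleus_vm_stress", "gel_transmitted_stress",
               "avg_effective_strain_cell")
  changes <- list()
  converged_level <- NA
  for (i in seq_len(nrow(tab) - 1)) {
    rel <- abs(tab[i + 1, tracked] - tab[i, tracked]) /
      abs(tab[i + 1, tracked])
    changes[[i]] <- data.frame(from = tab$refinement[i],
                               to = tab$refinement[i + 1], rel)
    if (is.na(converged_level) && rel[["indentation_depth"]] < tol)
      converged_level <- tab$refinement[i]
  }
  rep <- list(metrics = tab, changes = do.call(rbind, changes),
              converged_level = converged_level, tol = tol)
  class(rep) <- "convergence_report"
  rep
}

#' @export
print.convergence_report <- function(x, ...) {
  print(x$metrics, row.names = FALSE)
  if (is.na(x$converged_level)) {
    cat(sprintf("depth criterion (<%g%% change on refinement) NOT met\n",
                100 * x$tol))
  } else {
    cat(sprintf("depth criterion (<%g%% change) met at refinement level %s\n",
                100 * x$tol, x$converged_level))
  }
  invisible(x)
}

#' Compare elastic and viscoelastic cytoplasm models
#'
#' Runs both configurations with two cytoplasm material models at matched
#' grid points and tabulates the paired comparison: viscoelastic-to-elastic
#' nuclear-stress ratios, the relative reduction of peak nuclear stress, and
#' the top-versus-bottom percentage differences under each model.
#' Viscoelastic metrics are evaluated at the end of the loading ramp.
#'
#' @param forces Force levels (nN).
#' @param E_cyto Cytoplasm stiffness (kPa).
#' @param params,resolution,settings Model discretisation controls.
#' @param models Character vector of length 2 naming the baseline and
#'   comparison cytoplasm models (each `"elastic"` or `"viscoelastic"`).
#' @return List with `runs` (per-run metrics) and `comparison` (one row per
#'   force level).
#' @export
compare_material_models <- function(forces = 300, E_cyto = 0.8,
                                    params = geometry_params(),
                                    resolution = 1,
                                    settings = solver_settings(),
                                    models = c("elastic", "viscoelastic")) {
  stopifnot(length(models) == 2, all(models %in% c("elastic", "viscoelastic")))
  mesh <- build_domain(params, resolution)
  bcs <- build_bcs(mesh)
  rows <- list()
  for (mi in 1:2) for (F in forces) for (cfg in c("top", "bottom")) {
    st <- run_single(mesh, bcs, E_cyto, F, cfg, models[mi], settings)
    rs <- result_summary(st, F = F, E_cyto = E_cyto, config = cfg,
                         model = models[mi])
    rs$slot <- c("baseline", "comparison")[mi]
    rows[[length(rows) + 1L]] <- rs
  }
  runs <- do.call(rbind, rows)
  comp <- list()
  for (F in forces) {
    g <- function(slot, cfg, col)
      runs[runs$slot == slot & runs$config == cfg & runs$F == F, col]
    if (any(lengths(list(g("baseline", "top", "F"),
                         g("comparison", "top", "F"))) == 0))
      stop(sprintf("missing model pair at force %g nN", F))
    comp[[length(comp) + 1L]] <- data.frame(
      F = F, E_cyto = E_cyto,
      nucleus_stress_ratio_top =
        g("comparison", "top", "nucleus_total_stress") /
        g("baseline", "top", "nucleus_total_stress"),
      peak_nucleus_reduction_pct =
        100 * (abs(g("baseline", "top", "nucleus_peak_total")) -
                 abs(g("comparison", "top", "nucleus_peak_total"))) /
        abs(g("baseline", "top", "nucleus_peak_total")),
      pct_diff_nucleus_baseline =
        percent_difference(g("baseline", "top", "nucleus_total_stress"),
                           g("baseline", "bottom", "nucleus_total_stress")),
      pct_diff_nucleus_comparison =
        percent_difference(g("comparison", "top", "nucleus_total_stress"),
                           g("comparison", "bottom", "nucleus_total_stress")),
      pct_diff_indent_baseline =
        percent_difference(g("baseline", "top", "indentation_depth"),
                           g("baseline", "bottom", "indentation_depth")),
      pct_diff_indent_comparison =
        percent_difference(g("comparison", "top", "indentation_depth"),
                           g("comparison", "bottom", "indentation_depth")))
  }
  list(runs = runs, comparison = do.call(rbind, comp))
}
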