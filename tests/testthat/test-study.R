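test_that("sweep_grid validates its inputs", {
  g <- sweep_grid()
  expect_s3_class(g, "sweep_grid")
  expect_equal(g$forces, seq(50, 300, by = 50))
  expect_identical(g$material_model, "elastic")
  expect_error(sweep_grid(forces = -10))
  expect_error(sweep_grid(forces = 400))
  expect_error(sweep_grid(configs = "sideways"))
})

test_that("run_sweep tabulates runs and matched-pair differences", {
  g <- sweep_grid(forces = c(5, 10), E_cyto = 1.2)
  tab <- run_sweep(g, settings = solver_settings(n_load_steps = 2))
  expect_s3_class(tab, "sweep_table")
  expect_identical(nrow(tab$runs), 4L)
  expect_true(all(tab$runs$converged))
  expect_identical(nrow(tab$diffs), 2L)
  # depth grows with force in both configurations
  for (cfg in c("top", "bottom")) {
    d <- tab$runs$indentation_depth[tab$runs$config == cfg]
    expect_true(all(diff(d[order(tab$runs$F[tab$runs$config == cfg])]) > 0))
  }
  expect_true(all(is.finite(tab$diffs$pct_diff_indentation)))
  # deterministic ordering of rows: E_cyto, then force, then config
  expect_identical(tab$runs$F, c(5, 5, 10, 10))
  expect_identical(tab$runs$config, rep(c("top", "bottom"), 2))
})

test_that("sweep_diffs skips pairs with a non-converged member", {
  runs <- data.frame(
    F = c(10, 10, 20, 20), E_cyto = 1, model = "elastic",
    config = rep(c("top", "bottom"), 2),
    converged = c(TRUE, TRUE, TRUE, FALSE),
    indentation_depth = c(1, 2, 3, 4),
    nucleus_total_stress = c(-1, -2, -3, -4),
    cytoplasm_total_stress = c(-1, -2, -3, -4),
    gel_transmitted_stress = c(1, 2, 3, 4),
    stringsAsFactors = FALSE)
  d <- axicell:::sweep_diffs(runs)
  expect_identical(nrow(d), 1L)
  expect_equal(d$F, 10)
  expect_equal(d$pct_diff_indentation, -50)
  # empty table keeps the schema
  d0 <- axicell:::sweep_diffs(runs[runs$converged == FALSE, ])
  expect_identical(nrow(d0), 0L)
  expect_true("pct_diff_gel_stress" %in% names(d0))
})

test_that("mesh refinement leaves a small-load solution nearly unchanged", {
  # reduced gel keeps this structural test fast; the production-geometry
  # convergence check lives in the acceptance suite
  rep <- mesh_convergence_study(params = geometry_params(gel_radius = 100,
                                                         gel_thickness = 120),
                                lc = load_case(10, "top"),
                                materials = default_materials(E_cyto = 1.2),
                                refinements = c(1, 2),
                                settings = solver_settings(n_load_steps = 1),
                                tol = 0.02)
  expect_s3_class(rep, "convergence_report")
  expect_identical(nrow(rep$metrics), 2L)
  expect_equal(rep$metrics$n_elements[2], 4 * rep$metrics$n_elements[1])
  expect_identical(rep$converged_level, 1)
})

test_that("compare_material_models pairs both models at each force", {
  cmp <- compare_material_models(forces = 20, E_cyto = 1.2,
                                 settings = solver_settings(
                                   n_load_steps = 2, dt = 0.25))
  expect_identical(nrow(cmp$runs), 4L)
  expect_identical(nrow(cmp$comparison), 1L)
  expect_true(all(c("nucleus_stress_ratio_top",
                    "peak_nucleus_reduction_pct",
                    "pct_diff_indent_baseline",
                    "pct_diff_indent_comparison") %in%
                    names(cmp$comparison)))
  expect_true(all(is.finite(unlist(cmp$comparison))))
  expect_gt(cmp$comparison$nucleus_stress_ratio_top, 0)
  # the ramp-end viscoelastic response is stiffer than the equilibrium
  # elastic one, so it indents less
  d <- cmp$runs
  expect_lt(d$indentation_depth[d$model == "viscoelastic" &
                                  d$config == "top"],
            d$indentation_depth[d$model == "elastic" & d$config == "top"])
})
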