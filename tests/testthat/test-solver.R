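test_that("zero load yields the zero state", {
  m <- tiny_patch()
  st <- solve_quasistatic(m, list(gel = material_spec("neo_hookean", E = 1,
                                                      nu = 0.3)),
                          NULL, build_bcs(m))
  expect_true(st$converged)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(indentation_depth(st), 0)
})

test_that("reactions balance the applied load on random patches", {
  cases <- randomized_property_cases(seed = 20240301, n = 4)
  for (fx in cases) {
    st <- solve_quasistatic(fx$mesh, fx$materials, fx$loads, fx$bcs,
                            solver_settings(n_load_steps = 2,
                                            newton_tol = 1e-10))
    rs <- reaction_sums(st, fx$bcs)
    expect_equal(rs[["Fz"]], fx$expected$reaction_z$value,
                 tolerance = 1e-8)
  }
})

test_that("randomized fixtures are deterministic in the seed", {
  a <- randomized_property_cases(seed = 99, n = 3)
  b <- randomized_property_cases(seed = 99, n = 3)
  expect_identical(lapply(a, function(f) f$mesh$nodes),
                   lapply(b, function(f) f$mesh$nodes))
  expect_identical(lapply(a, function(f) f$loads),
                   lapply(b, function(f) f$loads))
  c1 <- randomized_property_cases(seed = 100, n = 3)
  expect_false(identical(a[[1]]$loads, c1[[1]]$loads))
})

test_that("solution scales linearly at small load", {
  fx <- randomized_property_cases(seed = 5, n = 1)[[1]]
  s1 <- solve_quasistatic(fx$mesh, fx$materials, fx$loads * 1e-3, fx$bcs,
                          solver_settings(n_load_steps = 1))
  s2 <- solve_quasistatic(fx$mesh, fx$materials, fx$loads * 2e-3, fx$bcs,
                          solver_settings(n_load_steps = 1))
  expect_equal(max(abs(s2$u - 2 * s1$u)) / max(abs(s2$u)), 0,
               tolerance = 0.01)
})

test_that("solver is deterministic", {
  fx <- randomized_property_cases(seed = 8, n = 1)[[1]]
  s1 <- solve_quasistatic(fx$mesh, fx$materials, fx$loads, fx$bcs)
  s2 <- solve_quasistatic(fx$mesh, fx$materials, fx$loads, fx$bcs)
  expect_identical(s1$u, s2$u)
})

test_that("viscoelastic long-time limit matches the equilibrium elastic solve", {
  fx <- randomized_property_cases(seed = 3, n = 1)[[1]]
  E <- fx$materials$gel$E
  nu <- fx$materials$gel$nu
  mats_v <- list(gel = material_spec("viscoelastic_prony", E = E, nu = nu,
                                     prony = prony_constants(),
                                     visco_mode = "equilibrium"))
  mats_e <- list(gel = material_spec("neo_hookean", E = E, nu = nu))
  st_e <- solve_quasistatic(fx$mesh, mats_e, fx$loads, fx$bcs)
  # creep toward equilibrium is governed by the retardation times
  # tau_i * (E_inst / E_relax), an order of magnitude beyond the relaxation
  # times, so the hold must be several hundred seconds
  hist <- solve_viscoelastic(fx$mesh, mats_v, fx$loads, fx$bcs,
                             solver_settings(dt = 0.25, dt_max = 2,
                                             steady_state_tol = 1e-8),
                             ramp_time = 0.01, hold_time = 600)
  uf <- hist$state_final$u
  expect_lt(max(abs(uf - st_e$u)) / max(abs(st_e$u)), 0.02)
  # the unrelaxed (ramp-end) response is stiffer than the equilibrium one
  expect_lt(max(abs(hist$state_ramp_end$u)), max(abs(st_e$u)))
})

test_that("viscoelastic response is time-step converged", {
  fx <- randomized_property_cases(seed = 13, n = 1)[[1]]
  mats_v <- list(gel = material_spec("viscoelastic_prony",
                                     E = fx$materials$gel$E,
                                     nu = fx$materials$gel$nu))
  run <- function(dt) {
    solve_viscoelastic(fx$mesh, mats_v, fx$loads, fx$bcs,
                       solver_settings(dt = dt, dt_growth = 1,
                                       steady_state_tol = 1e-9))
  }
  h1 <- run(0.2)
  h2 <- run(0.1)
  d1 <- h1$depths[length(h1$depths)]
  d2 <- h2$depths[length(h2$depths)]
  expect_lt(abs(d1 - d2) / abs(d2), 0.005)
})

test_that("viscoelastic zero load stays identically zero", {
  fx <- randomized_property_cases(seed = 4, n = 1)[[1]]
  mats_v <- list(gel = material_spec("viscoelastic_prony", E = 1, nu = 0.3))
  h <- solve_viscoelastic(fx$mesh, mats_v, NULL, fx$bcs,
                          solver_settings(dt = 0.5))
  expect_equal(max(abs(h$state_final$u)), 0)
})

test_that("material/solver misuse is caught", {
  fx <- randomized_property_cases(seed = 6, n = 1)[[1]]
  mats_v <- list(gel = material_spec("viscoelastic_prony", E = 1, nu = 0.3))
  expect_error(solve_quasistatic(fx$mesh, mats_v, fx$loads, fx$bcs),
               "solve_viscoelastic")
  expect_error(solve_viscoelastic(fx$mesh, fx$materials, fx$loads, fx$bcs),
               "solve_quasistatic")
  expect_error(
    solve_quasistatic(fx$mesh, list(), fx$loads, fx$bcs), "material")
})
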