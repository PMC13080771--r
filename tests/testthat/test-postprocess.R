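uniform_mats <- function(E = 1, nu = 0.3) {
  sp <- material_spec("neo_hookean", E = E, nu = nu)
  list(nucleus = sp, cytoplasm = sp, gel = sp)
}

test_that("homogeneous dilation reproduces the closed-form aggregates", {
  m <- small_cell_mesh()
  mats <- uniform_mats()
  g <- 1.04
  st <- affine_state(m, mats, diag(c(g - 1, g - 1)))
  lm <- axicell:::lame_from_E_nu(1, 0.3)
  sig <- neo_hookean_stress(diag(g, 3), lm[["lambda"]], lm[["mu"]])
  tr <- sum(diag(sig))
  for (rg in c("nucleus", "cytoplasm", "gel", "cell")) {
    expect_equal(region_stress_aggregate(st, rg, "total"), tr,
                 tolerance = 1e-10)
    expect_equal(region_stress_aggregate(st, rg, "total", "max"), tr,
                 tolerance = 1e-10)
    expect_equal(region_stress_aggregate(st, rg, "von_mises"), 0,
                 tolerance = 1e-10)
  }
  # volume integral = pointwise value x deformed volume
  expect_equal(region_stress_aggregate(st, "nucleus", "total", "volume_sum"),
               tr * g^3 * region_measure(m, "nucleus"), tolerance = 1e-6)
  # pure dilation has zero deviatoric (effective) strain
  expect_equal(average_effective_strain(st, "cell"), 0, tolerance = 1e-12)
  # all gel-stress modes agree on a homogeneous state
  expect_equal(gel_transmitted_stress(st, "near_cell"), 0, tolerance = 1e-10)
  expect_equal(gel_transmitted_stress(st, "whole_gel"), 0, tolerance = 1e-10)
  # uniform scaling about the origin preserves the nucleus aspect ratio;
  # the reference is the meshed (nodal) ratio, which differs from the
  # continuum 8/6 at the coordinate-snap level
  st0 <- affine_state(m, mats, diag(c(0, 0)))
  expect_equal(nucleus_aspect_ratio(st), nucleus_aspect_ratio(st0),
               tolerance = 1e-9)
  expect_equal(nucleus_aspect_ratio(st0), 4 / 3, tolerance = 1e-3)
})

test_that("homogeneous biaxial state matches principal-stress formulas", {
  m <- small_cell_mesh()
  mats <- uniform_mats(E = 2, nu = 0.4)
  c1 <- 0.03
  c2 <- -0.05
  st <- affine_state(m, mats, diag(c(c1, c2)))
  lm <- axicell:::lame_from_E_nu(2, 0.4)
  sig <- neo_hookean_stress(diag(c(1 + c1, 1 + c2, 1 + c1)),
                            lm[["lambda"]], lm[["mu"]])
  s <- diag(sig)
  vm <- sqrt(0.5 * ((s[1] - s[2])^2 + (s[2] - s[3])^2 + (s[3] - s[1])^2))
  expect_equal(region_stress_aggregate(st, "cell", "total"), sum(s),
               tolerance = 1e-10)
  expect_equal(region_stress_aggregate(st, "gel", "von_mises"), vm,
               tolerance = 1e-10)
  expect_equal(gel_transmitted_stress(st, "peak"), vm, tolerance = 1e-10)
  # Hencky effective strain of diag(a, b, a): 2|a - b| / 3
  a <- log(1 + c1)
  b <- log(1 + c2)
  expect_equal(average_effective_strain(st, "cell"), 2 * abs(a - b) / 3,
               tolerance = 1e-12)
})

test_that("percent_difference is signed and guards the zero baseline", {
  expect_equal(percent_difference(3, 2), 50)
  expect_equal(percent_difference(1, 4), -75)
  expect_error(percent_difference(1, 0), "zero baseline")
})

test_that("misuse of post-processing is rejected", {
  m <- small_cell_mesh()
  st <- affine_state(m, uniform_mats(), diag(c(0.01, 0.01)))
  expect_error(region_stress_aggregate(st, "membrane"), "region")
  bad <- st
  bad$converged <- FALSE
  expect_error(indentation_depth(bad), "not converged")
  expect_error(region_stress_aggregate(bad, "gel"), "not converged")
})

test_that("result_summary tabulates a real solve consistently", {
  m <- small_cell_mesh()
  mats <- default_materials(E_cyto = 1.2)
  la <- build_load_case(m, load_case(20, "top"))
  st <- solve_quasistatic(m, mats, la, build_bcs(m),
                          solver_settings(n_load_steps = 2))
  rs <- result_summary(st, F = 20, E_cyto = 1.2, config = "top",
                       model = "elastic")
  expect_s3_class(rs, "data.frame")
  expect_identical(nrow(rs), 1L)
  expect_identical(rs$config, "top")
  expect_true(rs$converged)
  expect_equal(rs$load_factor, 1)
  expect_equal(rs$indentation_depth, indentation_depth(st))
  expect_gt(rs$indentation_depth, 0)
  # a downward push compresses: mean total stress in the nucleus is negative
  expect_lt(rs$nucleus_total_stress, 0)
  expect_gt(rs$nucleus_vm_stress, 0)
  expect_gt(rs$gel_transmitted_stress, 0)
  expect_true(is.finite(rs$avg_effective_strain_cell))
})
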