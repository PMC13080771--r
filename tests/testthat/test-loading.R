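test_that("perimeter force decomposition follows the 50-degree geometry", {
  d <- decompose_perimeter_force(300, 50)
  expect_equal(d[["F_up"]], 300)
  expect_equal(d[["F_traction"]], 300 / tan(50 * pi / 180), tolerance = 1e-12)
  expect_equal(d[["F_traction"]], 251.73, tolerance = 1e-4)
  expect_equal(d[["F_total"]], 300 / sin(50 * pi / 180), tolerance = 1e-12)
  expect_equal(d[["F_total"]], 391.62, tolerance = 1e-4)
  expect_equal(decompose_perimeter_force(100, 50)[["F_traction"]], 83.91,
               tolerance = 1e-4)
  # nearly vertical pull: traction vanishes
  expect_lt(decompose_perimeter_force(100, 90 - 1e-6)[["F_traction"]], 1e-5)
  expect_error(decompose_perimeter_force(100, 90), "angle")
  expect_error(decompose_perimeter_force(100, 0), "angle")
})

test_that("assembled load cases are exactly self-equilibrated", {
  m <- small_cell_mesh()
  for (cfg in c("top", "bottom")) for (F in c(50, 300)) {
    la <- build_load_case(m, load_case(F, cfg))
    fz <- sum(la$fext[seq(2, length(la$fext), 2)])
    expect_lt(abs(fz), 1e-9 * F)
    fr <- sum(la$fext[seq(1, length(la$fext), 2)])
    expect_equal(fr, -decompose_perimeter_force(F)[["F_traction"]],
                 tolerance = 1e-10)
  }
})

test_that("top and bottom configurations differ only in the central force", {
  m <- small_cell_mesh()
  lt <- build_load_case(m, load_case(300, "top"))
  lb <- build_load_case(m, load_case(300, "bottom"))
  diffdof <- which(abs(lt$fext - lb$fext) > 1e-12)
  nodes_diff <- unique((diffdof + 1) %/% 2)
  top_nodes <- unique(as.vector(
    m$tri6[m$element_sets$nucleus_top_third, ]))
  bot_nodes <- unique(as.vector(
    m$tri6[m$element_sets$nucleus_bottom_third, ]))
  expect_true(all(nodes_diff %in% union(top_nodes, bot_nodes)))
  expect_identical(lt$third_set, "nucleus_top_third")
  expect_identical(lb$third_set, "nucleus_bottom_third")
})

test_that("load assembly is linear in the force magnitude", {
  m <- small_cell_mesh()
  l1 <- build_load_case(m, load_case(100, "top"))
  l2 <- build_load_case(m, load_case(200, "top"))
  expect_equal(l2$fext, 2 * l1$fext, tolerance = 1e-12)
})

test_that("boundary conditions fix gel bottom/lateral and the axis only", {
  m <- small_cell_mesh()
  bc <- build_bcs(m)
  ss <- m$surface_sets
  free_surface <- setdiff(ss$gel_top_free, c(ss$gel_lateral, ss$axis))
  expect_length(intersect(c(2 * free_surface - 1, 2 * free_surface),
                          bc$fixed_dofs), 0)
  expect_true(all(c(2 * ss$gel_bottom - 1, 2 * ss$gel_bottom) %in%
                    bc$fixed_dofs))
  expect_gt(length(ss$axis), 0)
  expect_true(all((2 * ss$axis - 1) %in% bc$fixed_dofs))
  expect_false(any(setdiff(2 * ss$axis, 2 * ss$gel_bottom) %in% bc$fixed_dofs))
})

test_that("missing element sets are reported as configuration errors", {
  m <- tiny_patch()
  expect_error(build_load_case(m, load_case(100, "top")), "perimeter_band")
})
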