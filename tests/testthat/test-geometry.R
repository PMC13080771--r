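test_that("revolved region volumes match the closed forms within 2%", {
  m <- small_cell_mesh()
  expect_lt(abs(region_measure(m, "nucleus") - vol_nucleus()) / vol_nucleus(),
            0.02)
  cell <- region_measure(m, "nucleus") + region_measure(m, "cytoplasm")
  expect_lt(abs(cell - vol_hemisphere()) / vol_hemisphere(), 0.02)
  expect_lt(abs(region_measure(m, "cytoplasm") -
                  (vol_hemisphere() - vol_nucleus())) /
              (vol_hemisphere() - vol_nucleus()), 0.02)
  expect_lt(abs(region_measure(m, "gel") - vol_gel()) / vol_gel(), 0.02)
})

test_that("mesh is conforming with valid axisymmetric structure", {
  m <- small_cell_mesh()
  expect_true(all(m$nodes[, 1] >= -1e-9))
  expect_gt(length(m$surface_sets$axis), 0)
  # tied interfaces by construction: cell-base nodes are gel-top nodes
  cyt <- m$region == "cytoplasm"
  cyt_nodes <- unique(as.vector(m$tri6[cyt, ]))
  base_nodes <- cyt_nodes[abs(m$nodes[cyt_nodes, 2]) < 1e-6 &
                            m$nodes[cyt_nodes, 1] <= 10 + 1e-6]
  expect_true(all(base_nodes %in% m$surface_sets$gel_top_free))
  # every element belongs to exactly one region
  expect_true(all(m$region %in% c("nucleus", "cytoplasm", "gel")))
  expect_equal(length(m$region), nrow(m$tri6))
  # nucleus thirds partition by z-extent and do not overlap
  expect_length(intersect(m$element_sets$nucleus_top_third,
                          m$element_sets$nucleus_bottom_third), 0)
})

test_that("invalid geometries are rejected", {
  expect_error(geometry_params(nucleus_diam_vertical = 25), "fit")
  expect_error(geometry_params(cell_diameter = -2), "positive")
  expect_error(geometry_params(contact_disc_diameter = 9), "disc")
  expect_error(geometry_params(gel_radius = 50), "10x")
  expect_error(region_measure(small_cell_mesh(), "organelle"), "region")
})

test_that("refinement scales element count, preserves volumes and sets", {
  m <- tiny_patch()
  m2 <- refine_mesh(m, 2)
  expect_equal(nrow(m2$tri3), 4 * nrow(m$tri3))
  expect_identical(refine_mesh(m, 1), m)
  # straight-sided subdivision preserves the polygonal volume exactly
  expect_equal(region_measure(m2, "gel"), region_measure(m, "gel"),
               tolerance = 1e-10)
  mc <- small_cell_mesh()
  mc2 <- refine_mesh(mc, 2)
  expect_equal(nrow(mc2$tri3), 4 * nrow(mc$tri3))
  for (rg in c("nucleus", "cytoplasm", "gel"))
    # midside nodes are snapped to a 1e-6 coordinate grid, so the match is
    # exact only to that resolution
    expect_equal(region_measure(mc2, rg), region_measure(mc, rg),
                 tolerance = 1e-7)
  expect_gt(nrow(mc2$surface_sets$perimeter_band),
            nrow(mc$surface_sets$perimeter_band))
  expect_gt(length(mc2$element_sets$nucleus_top_third),
            length(mc$element_sets$nucleus_top_third))
})

test_that("gel-only fixtures have no nucleus region", {
  m <- tiny_patch()
  expect_error(region_measure(m, "nucleus"), "region")
})
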