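#' Export a mesh (and optionally a solution) to legacy VTK
#'
#' Writes the axisymmetric mesh as a VTK legacy ASCII unstructured grid of
#' quadratic triangles in the (r, z) plane, with the region tag as cell data
#' and, when a state is supplied, nodal displacements and per-element mean
#' von Mises / total Cauchy stress as point/cell data.
#'
#' @param mesh An `axi_mesh`.
#' @param file Output path (`.vtk`).
#' @param state Optional converged `fe_state` from the same mesh.
#' @return The file path, invisibly.
#' @export
write_vtk <- function(mesh, file, state = NULL) {
  stopifnot(inherits(mesh, "axi_mesh"))
  nd <- mesh$nodes
  nel <- nrow(mesh$tri6)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("axisymmetric cell-on-gel mesh (r, z plane)")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nrow(nd))
  writeLines(paste(nd[, 1], nd[, 2], 0), con)
  w("CELLS %d %d", nel, nel * 7L)
  writeLines(paste(6L, mesh$tri6[, 1] - 1L, mesh$tri6[, 2] - 1L,
                   mesh$tri6[, 3] - 1L, mesh$tri6[, 4] - 1L,
                   mesh$tri6[, 5] - 1L, mesh$tri6[, 6] - 1L), con)
  w("CELL_TYPES %d", nel)
  writeLines(rep("22", nel), con) # VTK_QUADRATIC_TRIANGLE
  w("CELL_DATA %d", nel)
  w("SCALARS region int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(match(mesh$region,
                                c("nucleus", "cytoplasm", "gel"))), con)
  if (!is.null(state)) {
    nq <- 6L
    vm <- qp_measure(state, "von_mises")
    tot <- qp_measure(state, "total")
    el_mean <- function(x) colMeans(matrix(x, nrow = nq))
    w("SCALARS von_mises_kPa double 1")
    w("LOOKUP_TABLE default")
    writeLines(as.character(el_mean(vm)), con)
    w("SCALARS total_stress_kPa double 1")
    w("LOOKUP_TABLE default")
    writeLines(as.character(el_mean(tot)), con)
    w("POINT_DATA %d", nrow(nd))
    w("VECTORS displacement_um double")
    writeLines(paste(state$u[seq(1, length(state$u), 2)],
                     state$u[seq(2, length(state$u), 2)], 0), con)
  }
  invisible(file)
}
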