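#' Define a self-equilibrated load case
#'
#' The cell pushes a downward central force through the top or bottom third
#' of the nucleus while pulling upward and inward at its base perimeter, with
#' the perimeter force resultant angled at `angle` degrees to the gel surface.
#' The vertical resultants cancel exactly, so the cell as a whole applies
#' zero net force (and, by axisymmetry, zero net moment).
#'
#' @param F_normal Magnitude of the downward central force, equal to the
#'   upward perimeter normal resultant (nN).
#' @param config `"top"` or `"bottom"`: which nucleus third carries the
#'   central force.
#' @param angle Angle of the total perimeter force relative to the gel
#'   surface, in degrees (default 50).
#' @param ramp_time,hold_time Loading protocol for viscoelastic runs (s):
#'   the load is ramped linearly over `ramp_time` and then held.
#' @return An object of class `load_case`.
#' @export
load_case <- function(F_normal, config = c("top", "bottom"), angle = 50,
                      ramp_time = 1, hold_time = 10) {
  config <- match.arg(config)
  if (!is.finite(F_normal) || F_normal <= 0) stop("F_normal must be positive")
  if (angle <= 0 || angle >= 90) stop("angle must lie strictly in (0, 90)")
  if (ramp_time < 0 || hold_time < 0) stop("protocol times must be >= 0")
  lc <- list(F_normal = F_normal, config = config, angle = angle,
             ramp_time = ramp_time, hold_time = hold_time)
  class(lc) <- "load_case"
  lc
}

#' @export
print.load_case <- function(x, ...) {
  d <- decompose_perimeter_force(x$F_normal, x$angle)
  cat(sprintf(
    "Load case: %g nN central force through nucleus %s third;\n  perimeter pull %g nN up + %.3g nN inward (total %.4g nN at %g deg)\n",
    x$F_normal, x$config, x$F_normal, d[["F_traction"]], d[["F_total"]],
    x$angle))
  invisible(x)
}

#' Decompose the angled perimeter force
#'
#' The total perimeter force is angled at `angle` degrees to the gel surface;
#' its vertical component balances the central force, so
#' `F_up = F_normal`, `F_traction = F_normal / tan(angle)` (inward radial)
#' and `F_total = F_normal / sin(angle)`.
#'
#' @param F_normal Vertical perimeter resultant (nN).
#' @param angle Angle to the gel surface in degrees, strictly inside (0, 90).
#' @return Named vector `c(F_up, F_traction, F_total)` in nN.
#' @export
decompose_perimeter_force <- function(F_normal, angle = 50) {
  if (angle <= 0 || angle >= 90)
    stop("degenerate decomposition: angle must lie strictly in (0, 90)")
  a <- angle * pi / 180
  c(F_up = F_normal, F_traction = F_normal / tan(a),
    F_total = F_normal / sin(a))
}

#' Displacement boundary conditions
#'
#' Fixes both displacement components on the gel bottom and lateral faces and
#' the radial component on the symmetry axis; the gel top surface and all
#' cell surfaces remain free.
#'
#' @param mesh An `axi_mesh`.
#' @return An object of class `bc_set` with the constrained node sets and the
#'   global constrained dof indices.
#' @export
build_bcs <- function(mesh) {
  stopifnot(inherits(mesh, "axi_mesh"))
  ss <- mesh$surface_sets
  fixed_both <- sort(union(ss$gel_bottom, ss$gel_lateral))
  axis_only <- setdiff(ss$axis, fixed_both)
  fixed_dofs <- sort(c(2 * fixed_both - 1, 2 * fixed_both, 2 * axis_only - 1))
  bc <- list(fixed_both = fixed_both, axis_ur = sort(ss$axis),
             fixed_dofs = fixed_dofs)
  class(bc) <- "bc_set"
  bc
}

#' Assemble the nodal force vector of a load case
#'
#' Perimeter tractions (upward + inward, uniform per revolved area) are
#' integrated consistently over the perimeter band edges; the central
#' downward force is applied as a uniform body-force density over the
#' elements of the selected nucleus third. Both are dead loads, so the
#' assignment is exactly self-equilibrated (vertical force sum zero to
#' machine precision) at every deformation level.
#'
#' @param mesh An `axi_mesh` built with a cell (perimeter band and nucleus
#'   element sets present).
#' @param lc A [load_case()].
#' @return List of class `load_assignment` with `fext` (global nodal force
#'   vector, length `2 * n_nodes`), the load case, and bookkeeping values
#'   (band area, loaded nucleus-third volume).
#' @export
build_load_case <- function(mesh, lc) {
  stopifnot(inherits(mesh, "axi_mesh"), inherits(lc, "load_case"))
  band <- mesh$surface_sets$perimeter_band
  if (is.null(band) || nrow(band) == 0)
    stop("configuration error: mesh has no perimeter_band surface set")
  set_name <- paste0("nucleus_", lc$config, "_third")
  els <- mesh$element_sets[[set_name]]
  if (is.null(els) || length(els) == 0)
    stop(sprintf("configuration error: mesh has no element set '%s'", set_name))

  nd <- mesh$nodes
  ndof <- 2L * nrow(nd)
  fext <- numeric(ndof)
  dec <- decompose_perimeter_force(lc$F_normal, lc$angle)

  ## perimeter band: consistent P2 edge integration of a uniform traction
  r1 <- nd[band[, 1], 1]; r2 <- nd[band[, 2], 1]
  z1 <- nd[band[, 1], 2]; z2 <- nd[band[, 2], 2]
  len <- sqrt((r2 - r1)^2 + (z2 - z1)^2)
  gx <- c(0.5 - sqrt(0.15), 0.5, 0.5 + sqrt(0.15))
  gw <- c(5, 8, 5) / 18
  # integral of N_a(xi) * R(xi) over the edge, per edge
  intN <- matrix(0, nrow(band), 3)
  for (g in 1:3) {
    xi <- gx[g]
    N <- c((1 - xi) * (1 - 2 * xi), xi * (2 * xi - 1), 4 * xi * (1 - xi))
    Rg_ <- r1 + (r2 - r1) * xi
    for (a in 1:3) intN[, a] <- intN[, a] + gw[g] * N[a] * Rg_
  }
  intN <- intN * (2 * pi * len)
  band_area <- sum(intN)
  tz <- lc$F_normal / band_area      # upward
  tr <- -dec[["F_traction"]] / band_area # inward
  for (a in 1:3) {
    ids <- band[, a]
    fext[2 * ids - 1] <- fext[2 * ids - 1] + tr * intN[, a]
    fext[2 * ids] <- fext[2 * ids] + tz * intN[, a]
  }

  ## central force: uniform body-force density over the nucleus third
  qd <- mesh_quadrature(mesh, elements = els)
  V_third <- sum(qd$wq)
  dens <- -lc$F_normal / V_third
  conn <- mesh$tri6[els, , drop = FALSE]
  for (a in 1:6) {
    contrib <- rowsum(as.vector(qd$wq * qd$Nmat[, a]),
                      group = rep(conn[, a], each = qd$nq))
    ids <- as.integer(rownames(contrib))
    fext[2 * ids] <- fext[2 * ids] + dens * contrib[, 1]
  }

  out <- list(fext = fext, lc = lc, band_area = band_area,
              V_third = V_third, third_set = set_name)
  class(out) <- "load_assignment"
  out
}
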