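# Shared small fixtures for the unit suite. Meshes here are deliberately
# coarse: unit tests exercise correctness, not production accuracy.

small_cell_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_domain(geometry_params(), 1)
    cache
  }
})

tiny_patch <- function(h = 1.5, R = 3, H = 3) {
  axicell:::gel_only_mesh(R, H, fine_to = R, h = h)
}

# analytic revolved volumes from the default geometry
vol_hemisphere <- function(Rc = 10) 2 / 3 * pi * Rc^3
vol_nucleus <- function(a = 3, b = 4) 4 / 3 * pi * a^2 * b
vol_gel <- function(R = 225, H = 300) pi * R^2 * H

# homogeneous state injected into a mesh: u = A %*% x for an affine map,
# solved-state fields recomputed through the package assembly
affine_state <- function(mesh, materials, A) {
  nd <- mesh$nodes
  u <- numeric(2 * nrow(nd))
  u[seq(1, length(u), 2)] <- A[1, 1] * nd[, 1] + A[1, 2] * nd[, 2]
  u[seq(2, length(u), 2)] <- A[2, 1] * nd[, 1] + A[2, 2] * nd[, 2]
  ctx <- axicell:::solver_context(mesh, materials, build_bcs(mesh))
  axicell:::make_state(u, ctx, mesh, materials, numeric(length(u)),
                       rep(1, ctx$qd$nel), matrix(0, ctx$nqp, 4), 0)
}
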