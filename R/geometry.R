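#' Geometry parameters for the cell-on-gel model
#'
#' Collects and validates the geometric parameters of the axisymmetric model:
#' a hemispherical cell resting on a large gel cylinder, with an embedded
#' ellipsoidal nucleus. All lengths are in micrometres.
#'
#' @param cell_diameter Cell (hemisphere) diameter; also the diameter of the
#'   cell-gel contact area.
#' @param nucleus_diam_planar Planar (horizontal) diameter of the ellipsoidal
#'   nucleus.
#' @param nucleus_diam_vertical Vertical diameter of the nucleus.
#' @param gel_radius Radius of the gel cylinder.
#' @param gel_thickness Height of the gel cylinder.
#' @param contact_disc_diameter Diameter of the central contact disc at the
#'   cell base through which the nuclear force is routed to the gel.
#' @param nucleus_center_height Height of the nucleus centre above the gel
#'   surface. Defaults to mid-height of the hemisphere.
#' @param band_width Width of the annular perimeter band at the cell base over
#'   which the push-pull tractions are applied.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(cell_diameter = 20,
                            nucleus_diam_planar = 6,
                            nucleus_diam_vertical = 8,
                            gel_radius = 225,
                            gel_thickness = 300,
                            contact_disc_diameter = 6,
                            nucleus_center_height = cell_diameter / 4,
                            band_width = 1) {
  p <- list(cell_diameter = cell_diameter,
            nucleus_diam_planar = nucleus_diam_planar,
            nucleus_diam_vertical = nucleus_diam_vertical,
            gel_radius = gel_radius,
            gel_thickness = gel_thickness,
            contact_disc_diameter = contact_disc_diameter,
            nucleus_center_height = nucleus_center_height,
            band_width = band_width)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be positive and finite")
  Rc <- cell_diameter / 2
  a_n <- nucleus_diam_planar / 2
  b_n <- nucleus_diam_vertical / 2
  zc <- nucleus_center_height
  if (b_n >= Rc)
    stop("nucleus does not fit inside the cell: vertical semi-axis >= cell radius")
  # nucleus must lie strictly inside the hemisphere r^2 + z^2 <= Rc^2, z > 0
  th <- seq(0, pi, length.out = 181)
  er <- a_n * sin(th)
  ez <- zc + b_n * cos(th)
  if (any(ez <= 1e-9) || any(er^2 + ez^2 >= Rc^2 - 1e-9))
    stop("nucleus does not fit strictly inside the cell")
  if (contact_disc_diameter > nucleus_diam_planar + 1e-9)
    stop("contact disc must not exceed the nucleus planar diameter")
  if (gel_radius < 10 * Rc)
    stop("gel radius must be at least 10x the cell radius")
  if (band_width >= Rc)
    stop("perimeter band wider than the cell radius")
  class(p) <- "geometry_params"
  p
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Cell-on-gel geometry (um):\n")
  cat(sprintf("  cell diameter %g, nucleus %g x %g (centre at z = %g)\n",
              x$cell_diameter, x$nucleus_diam_planar, x$nucleus_diam_vertical,
              x$nucleus_center_height))
  cat(sprintf("  gel %g (radius) x %g (thickness); contact disc %g, band %g\n",
              x$gel_radius, x$gel_thickness, x$contact_disc_diameter,
              x$band_width))
  invisible(x)
}

## ---- internal node store with coordinate de-duplication -------------------

new_node_store <- function() {
  st <- new.env(parent = emptyenv())
  st$map <- new.env(hash = TRUE, parent = emptyenv())
  st$r <- numeric(0)
  st$z <- numeric(0)
  st$n <- 0L
  st
}

snap_coord <- function(x) {
  x <- round(x, 6)
  x[x == 0] <- 0 # avoid -0
  x
}

store_add <- function(st, pts) {
  r <- snap_coord(pts[, 1])
  z <- snap_coord(pts[, 2])
  keys <- paste(sprintf("%.6f", r), sprintf("%.6f", z), sep = "|")
  idx <- integer(length(keys))
  for (i in seq_along(keys)) {
    v <- st$map[[keys[i]]]
    if (is.null(v)) {
      st$n <- st$n + 1L
      v <- st$n
      st$map[[keys[i]]] <- v
      st$r[v] <- r[i]
      st$z[v] <- z[i]
    }
    idx[i] <- v
  }
  idx
}

store_nodes <- function(st) cbind(r = st$r, z = st$z)

## ---- P2 elevation ---------------------------------------------------------

# Insert midside nodes (at straight-edge midpoints) into a linear triangle
# mesh. Returns list(nodes, tri6) with P1 nodes first, midside nodes appended.
p2_elevate <- function(nodes, tri3) {
  nel <- nrow(tri3)
  ea <- rbind(tri3[, c(1, 2)], tri3[, c(2, 3)], tri3[, c(3, 1)])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]), sep = "_")
  uk <- unique(key)
  mid_id <- match(key, uk) + nrow(nodes)
  ue <- ea[!duplicated(key), , drop = FALSE]
  midpts <- (nodes[ue[, 1], , drop = FALSE] + nodes[ue[, 2], , drop = FALSE]) / 2
  tri6 <- cbind(tri3,
                mid_id[seq_len(nel)],
                mid_id[nel + seq_len(nel)],
                mid_id[2 * nel + seq_len(nel)])
  colnames(tri6) <- NULL
  list(nodes = rbind(nodes, midpts), tri6 = tri6)
}

## ---- graded 1-d spacing ---------------------------------------------------

# Geometric sequence of k intervals from 0 to L, first interval ~ d0, ratio g;
# rescaled so the last point lands exactly on L.
graded_seq <- function(L, d0, g) {
  if (L <= d0 * 1.5) return(c(0, L))
  k <- max(2L, ceiling(log(1 + L * (g - 1) / d0) / log(g)))
  raw <- cumsum(d0 * g^(0:(k - 1)))
  c(0, raw * (L / raw[k]))
}

## ---- domain construction --------------------------------------------------

#' Build the axisymmetric computational mesh
#'
#' Constructs a conforming (node-shared) triangulation of the gel cylinder,
#' hemispherical cytoplasm and ellipsoidal nucleus in the (r, z) half-plane.
#' Node sharing across the cell-gel and nucleus-cytoplasm interfaces realises
#' tied (no-slip, no-separation) contact by construction. The mesh carries
#' named surface sets (`gel_top_free`, `gel_bottom`, `gel_lateral`, `axis`,
#' `perimeter_band`) and element sets (`nucleus_top_third`,
#' `nucleus_bottom_third`, `center_contact_disc`) used by the load and
#' boundary-condition builders.
#'
#' Elements are 6-node (quadratic) triangles with straight edges; the target
#' edge length near the cell-gel contact is `0.5 / resolution` micrometres,
#' coarsening geometrically toward the far gel boundaries.
#'
#' @param params A [geometry_params()] object.
#' @param resolution Integer refinement level (>= 1); 1 is the production
#'   default.
#' @return An object of class `axi_mesh`.
#' @export
build_domain <- function(params = geometry_params(), resolution = 1) {
  stopifnot(inherits(params, "geometry_params"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 1) stop("resolution must be >= 1")

  Rc <- params$cell_diameter / 2
  a_n <- params$nucleus_diam_planar / 2
  b_n <- params$nucleus_diam_vertical / 2
  zc <- params$nucleus_center_height
  Rg <- params$gel_radius
  Tg <- params$gel_thickness
  h <- 0.5 / resolution

  st <- new_node_store()
  tris <- list()
  regs <- list()
  add_tris <- function(t3, region) {
    tris[[length(tris) + 1L]] <<- t3
    regs[[length(regs) + 1L]] <<- rep(region, nrow(t3))
  }

  # quad grid (given as index matrix id[n1, n2]) -> triangles, split along the
  # shorter diagonal (deterministic tie-break: diagonal 1-3)
  quads_to_tris <- function(id, nodes_r, nodes_z) {
    n1 <- nrow(id) - 1L
    n2 <- ncol(id) - 1L
    out <- matrix(0L, 2L * n1 * n2, 3)
    k <- 0L
    for (j in seq_len(n2)) {
      for (i in seq_len(n1)) {
        a <- id[i, j]; b <- id[i + 1, j]; cc <- id[i + 1, j + 1]; d <- id[i, j + 1]
        d13 <- (nodes_r[a] - nodes_r[cc])^2 + (nodes_z[a] - nodes_z[cc])^2
        d24 <- (nodes_r[b] - nodes_r[d])^2 + (nodes_z[b] - nodes_z[d])^2
        if (d13 <= d24) {
          out[k + 1L, ] <- c(a, b, cc)
          out[k + 2L, ] <- c(a, cc, d)
        } else {
          out[k + 1L, ] <- c(a, b, d)
          out[k + 2L, ] <- c(b, cc, d)
        }
        k <- k + 2L
      }
    }
    out[seq_len(k), , drop = FALSE]
  }

  ## --- ray system around the nucleus centre (0, zc) ---
  # phi = 0 points straight down, phi = pi straight up; the cell outer
  # boundary (base disc + hemispherical arc) is star-shaped about (0, zc).
  n_base <- max(4L, round(Rc / h))
  r_base <- seq(0, Rc, length.out = n_base + 1)
  phi_base <- atan(r_base / zc)
  arclen <- (pi / 2) * Rc
  n_arc <- max(6L, round(arclen / h))
  alpha <- seq(pi / 2, 0, length.out = n_arc + 1)[-1] # exclude corner
  arc_r <- Rc * sin(alpha)
  arc_z <- Rc * cos(alpha)
  phi_arc <- atan2(arc_r, zc - arc_z)
  phi <- c(phi_base, phi_arc)
  out_r <- c(r_base, arc_r)
  out_z <- c(rep(0, n_base + 1), arc_z)
  nray <- length(phi)
  sphi <- sin(phi)
  cphi <- cos(phi)
  t_in <- 1 / sqrt((sphi / a_n)^2 + (cphi / b_n)^2)
  t_out <- sqrt(out_r^2 + (out_z - zc)^2)

  ## --- cytoplasm: transfinite grid between ellipse and outer boundary ---
  n_rad <- max(3L, round(4 / h))
  s <- seq(0, 1, length.out = n_rad + 1)
  cy_id <- matrix(0L, nray, n_rad + 1)
  for (i in seq_along(s)) {
    t <- t_in + s[i] * (t_out - t_in)
    pr <- t * sphi
    pz <- zc - t * cphi
    if (i == length(s)) { pr <- out_r; pz <- out_z }
    cy_id[, i] <- store_add(st, cbind(pr, pz))
  }
  add_tris(quads_to_tris(cy_id, st$r, st$z), "cytoplasm")

  ## --- nucleus: polar rings down to a centre fan ---
  n_ring <- max(2L, round(min(a_n, b_n) / h))
  rho <- seq(0, 1, length.out = n_ring + 1)
  nu_id <- matrix(0L, nray, n_ring + 1)
  ctr <- store_add(st, cbind(0, zc))
  nu_id[, 1] <- ctr
  for (m in 2:(n_ring + 1)) {
    t <- rho[m] * t_in
    nu_id[, m] <- store_add(st, cbind(t * sphi, zc - t * cphi))
  }
  # fan at the centre
  fan <- cbind(rep(ctr, nray - 1), nu_id[-nray, 2], nu_id[-1, 2])
  add_tris(fan, "nucleus")
  add_tris(quads_to_tris(nu_id[, -1, drop = FALSE], st$r, st$z), "nucleus")

  ## --- gel: tensor grid; top radii conform to the cell base nodes ---
  r_gel <- c(r_base, Rc + graded_seq(Rg - Rc, h, 1.35)[-1])
  z_gel <- -graded_seq(Tg, h, 1.4)
  gid <- matrix(0L, length(r_gel), length(z_gel))
  for (j in seq_along(z_gel))
    gid[, j] <- store_add(st, cbind(r_gel, rep(z_gel[j], length(r_gel))))
  add_tris(quads_to_tris(gid, st$r, st$z), "gel")

  nodes <- store_nodes(st)
  tri3 <- do.call(rbind, tris)
  region <- unlist(regs, use.names = FALSE)

  geom <- list(params = params, Rc = Rc, a_n = a_n, b_n = b_n, zc = zc,
               Rg = Rg, Tg = Tg, band_width = params$band_width,
               disc_r = params$contact_disc_diameter / 2, has_cell = TRUE)
  mesh_finalize(nodes, tri3, region, geom, resolution)
}

# Gel-only cylinder mesh for verification fixtures (flat punch). `fine_radii`
# are top-surface radii that must appear as mesh lines (e.g. the punch edge).
gel_only_mesh <- function(gel_radius, gel_thickness, fine_to, h = 0.25,
                          fine_radii = numeric(0)) {
  st <- new_node_store()
  r_fine <- seq(0, fine_to, by = h)
  if (abs(r_fine[length(r_fine)] - fine_to) > 1e-9) r_fine <- c(r_fine, fine_to)
  r_fine <- sort(unique(snap_coord(c(r_fine, fine_radii))))
  r_tail <- if (gel_radius - fine_to > 1e-9)
    fine_to + graded_seq(gel_radius - fine_to, h, 1.35)[-1] else numeric(0)
  r_gel <- c(r_fine, r_tail)
  z_gel <- -graded_seq(gel_thickness, h, 1.4)
  gid <- matrix(0L, length(r_gel), length(z_gel))
  for (j in seq_along(z_gel))
    gid[, j] <- store_add(st, cbind(r_gel, rep(z_gel[j], length(r_gel))))
  n1 <- length(r_gel) - 1L
  n2 <- length(z_gel) - 1L
  tri3 <- matrix(0L, 2L * n1 * n2, 3)
  k <- 0L
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    a <- gid[i, j]; b <- gid[i + 1, j]; cc <- gid[i + 1, j + 1]; d <- gid[i, j + 1]
    tri3[k + 1L, ] <- c(a, b, cc)
    tri3[k + 2L, ] <- c(a, cc, d)
    k <- k + 2L
  }
  geom <- list(params = NULL, Rc = NA_real_, Rg = gel_radius,
               Tg = gel_thickness, has_cell = FALSE)
  mesh_finalize(store_nodes(st), tri3, rep("gel", nrow(tri3)), geom, 1L)
}

# Orient triangles positively, elevate to P2, and (re)derive all named sets
# from the stored geometry. Shared by build_domain(), refine_mesh() and the
# fixture meshes.
mesh_finalize <- function(nodes, tri3, region, geom, resolution) {
  r1 <- nodes[tri3[, 1], 1]; z1 <- nodes[tri3[, 1], 2]
  r2 <- nodes[tri3[, 2], 1]; z2 <- nodes[tri3[, 2], 2]
  r3 <- nodes[tri3[, 3], 1]; z3 <- nodes[tri3[, 3], 2]
  area2 <- (r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1)
  flip <- area2 < 0
  if (any(flip)) {
    tmp <- tri3[flip, 2]
    tri3[flip, 2] <- tri3[flip, 3]
    tri3[flip, 3] <- tmp
    area2[flip] <- -area2[flip]
  }
  if (any(area2 <= 1e-12))
    stop("meshing error: degenerate element(s) produced")
  if (any(nodes[, 1] < -1e-9))
    stop("meshing error: node with negative radius")

  p2 <- p2_elevate(nodes, tri3)
  nodes6 <- p2$nodes
  tri6 <- p2$tri6
  tol <- 1e-5

  on_z0 <- abs(nodes6[, 2]) < tol
  gel_el <- which(region == "gel")
  gel_nodes <- unique(as.vector(tri6[gel_el, , drop = FALSE]))
  surface_sets <- list(
    gel_top_free = sort(intersect(which(on_z0), gel_nodes)),
    gel_bottom = which(abs(nodes6[, 2] + geom$Tg) < tol),
    gel_lateral = which(abs(nodes6[, 1] - geom$Rg) < tol),
    axis = which(abs(nodes6[, 1]) < tol)
  )

  element_sets <- list()
  if (isTRUE(geom$has_cell)) {
    # perimeter band: cell-base edges with midpoint radius inside the band
    cyt <- which(region == "cytoplasm")
    eset <- integer(0); e1 <- integer(0); e2 <- integer(0); em <- integer(0)
    for (k in 1:3) {
      a <- tri6[cyt, k]
      b <- tri6[cyt, (k %% 3) + 1]
      m <- tri6[cyt, 3 + k]
      sel <- abs(nodes6[a, 2]) < tol & abs(nodes6[b, 2]) < tol
      rm_ <- (nodes6[a, 1] + nodes6[b, 1]) / 2
      band <- sel & rm_ > geom$Rc - geom$band_width - tol & rm_ < geom$Rc + tol
      e1 <- c(e1, a[band]); e2 <- c(e2, b[band]); em <- c(em, m[band])
      disc <- sel & rm_ < geom$disc_r + tol
      eset <- c(eset, cyt[disc])
    }
    surface_sets$perimeter_band <- cbind(n1 = e1, n2 = e2, mid = em)
    element_sets$center_contact_disc <- sort(unique(eset))

    nuc <- which(region == "nucleus")
    nz <- nodes6[tri6[nuc, 1:3], 2]
    dim(nz) <- c(length(nuc), 3)
    zc_el <- rowMeans(nz)
    nzall <- nodes6[unique(as.vector(tri6[nuc, 1:3])), 2]
    zmin <- min(nzall); zmax <- max(nzall)
    third <- (zmax - zmin) / 3
    element_sets$nucleus_top_third <- nuc[zc_el >= zmax - third]
    element_sets$nucleus_bottom_third <- nuc[zc_el <= zmin + third]
  }

  mesh <- list(nodes = nodes6, tri6 = tri6,
               nodes_p1 = nodes, tri3 = tri3,
               region = region,
               surface_sets = surface_sets,
               element_sets = element_sets,
               geom = geom, resolution = resolution)
  class(mesh) <- "axi_mesh"
  mesh
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf("Axisymmetric P2 mesh: %d nodes, %d elements\n",
              nrow(x$nodes), nrow(x$tri6)))
  tb <- table(x$region)
  cat("  regions:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' Uniformly refine a mesh
#'
#' Subdivides every triangle into `factor^2` congruent triangles and rebuilds
#' the quadratic nodes and all named sets. `factor = 1` returns the mesh
#' unchanged. Straight-edged subdivision preserves the polygonal region
#' geometry (and hence revolved volumes) exactly.
#'
#' @param mesh An `axi_mesh`.
#' @param factor Integer subdivision factor (>= 1).
#' @return The refined `axi_mesh`.
#' @export
refine_mesh <- function(mesh, factor = 2) {
  stopifnot(inherits(mesh, "axi_mesh"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer")
  if (factor == 1L) return(mesh)

  nodes <- mesh$nodes_p1
  tri3 <- mesh$tri3
  nel <- nrow(tri3)
  k <- factor
  # barycentric lattice indices for one parent triangle
  ij <- expand.grid(i = 0:k, j = 0:k)
  ij <- ij[ij$i + ij$j <= k, ]
  ij <- ij[order(ij$j, ij$i), ]
  lat_id <- function(i, j) match(paste(i, j), paste(ij$i, ij$j))
  upA <- list(); upB <- list(); upC <- list()
  dnA <- list(); dnB <- list(); dnC <- list()
  for (j in 0:(k - 1)) for (i in 0:(k - 1 - j)) {
    upA[[length(upA) + 1]] <- lat_id(i, j)
    upB[[length(upB) + 1]] <- lat_id(i + 1, j)
    upC[[length(upC) + 1]] <- lat_id(i, j + 1)
    if (i + j <= k - 2) {
      dnA[[length(dnA) + 1]] <- lat_id(i + 1, j)
      dnB[[length(dnB) + 1]] <- lat_id(i + 1, j + 1)
      dnC[[length(dnC) + 1]] <- lat_id(i, j + 1)
    }
  }
  upA <- unlist(upA); upB <- unlist(upB); upC <- unlist(upC)
  dnA <- unlist(dnA); dnB <- unlist(dnB); dnC <- unlist(dnC)

  st <- new_node_store()
  new_tris <- vector("list", nel)
  new_regs <- vector("list", nel)
  wi <- ij$i / k
  wj <- ij$j / k
  for (e in seq_len(nel)) {
    v1 <- nodes[tri3[e, 1], ]
    v2 <- nodes[tri3[e, 2], ]
    v3 <- nodes[tri3[e, 3], ]
    pr <- v1[1] + wi * (v2[1] - v1[1]) + wj * (v3[1] - v1[1])
    pz <- v1[2] + wi * (v2[2] - v1[2]) + wj * (v3[2] - v1[2])
    ids <- store_add(st, cbind(pr, pz))
    t3 <- rbind(cbind(ids[upA], ids[upB], ids[upC]),
                cbind(ids[dnA], ids[dnB], ids[dnC]))
    new_tris[[e]] <- t3
    new_regs[[e]] <- rep(mesh$region[e], nrow(t3))
  }
  mesh_finalize(store_nodes(st), do.call(rbind, new_tris),
                unlist(new_regs, use.names = FALSE), mesh$geom,
                mesh$resolution)
}

#' Revolved volume of a mesh region
#'
#' Computes the volume `2 * pi * integral(r dA)` of all elements carrying the
#' given region tag, i.e. the volume of the revolved solid.
#'
#' @param mesh An `axi_mesh`.
#' @param region Region tag: `"nucleus"`, `"cytoplasm"` or `"gel"`.
#' @return Volume in cubic micrometres.
#' @export
region_measure <- function(mesh, region) {
  stopifnot(inherits(mesh, "axi_mesh"))
  sel <- mesh$region == region
  if (!any(sel)) stop(sprintf("unknown or empty region '%s'", region))
  t3 <- mesh$tri3[sel, , drop = FALSE]
  nd <- mesh$nodes_p1
  r1 <- nd[t3[, 1], 1]; z1 <- nd[t3[, 1], 2]
  r2 <- nd[t3[, 2], 1]; z2 <- nd[t3[, 2], 2]
  r3 <- nd[t3[, 3], 1]; z3 <- nd[t3[, 3], 2]
  area <- 0.5 * ((r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1))
  rc <- (r1 + r2 + r3) / 3
  2 * pi * sum(area * rc)
}
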