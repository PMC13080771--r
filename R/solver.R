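## Quadrature precomputation and the Newton solver for the axisymmetric
## total-Lagrangian problem. The per-element hot loop lives in src/assembly.cpp.

# 6-point, degree-4 triangle rule (barycentric orbits)
tri_rule6 <- function() {
  a <- 0.445948490915965
  b <- 0.091576213509771
  wa <- 0.111690794839005
  wb <- 0.054975871827661
  L <- rbind(c(1 - 2 * a, a, a), c(a, 1 - 2 * a, a), c(a, a, 1 - 2 * a),
             c(1 - 2 * b, b, b), c(b, 1 - 2 * b, b), c(b, b, 1 - 2 * b))
  list(L = L, w = c(wa, wa, wa, wb, wb, wb))
}

p2_shape <- function(L1, L2, L3) {
  N <- c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
         4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1)
  dxi <- c(-(4 * L1 - 1), 4 * L2 - 1, 0, 4 * (L1 - L2), 4 * L3, -4 * L3)
  deta <- c(-(4 * L1 - 1), 0, 4 * L3 - 1, -4 * L2, 4 * L2, 4 * (L1 - L3))
  list(N = N, dxi = dxi, deta = deta)
}

# Reference-configuration quadrature data for (a subset of) the elements:
# global shape-function derivatives, radii and total weights
# w = w_ref * detJ * 2 * pi * R at each of the 6 points per element.
mesh_quadrature <- function(mesh, elements = NULL) {
  tri6 <- mesh$tri6
  if (!is.null(elements)) tri6 <- tri6[elements, , drop = FALSE]
  nel <- nrow(tri6)
  nd <- mesh$nodes
  rule <- tri_rule6()
  nq <- 6L
  v1r <- nd[tri6[, 1], 1]; v1z <- nd[tri6[, 1], 2]
  a <- nd[tri6[, 2], 1] - v1r; cc <- nd[tri6[, 2], 2] - v1z
  b <- nd[tri6[, 3], 1] - v1r; d <- nd[tri6[, 3], 2] - v1z
  det <- a * d - b * cc
  nrow_tot <- nel * nq
  dNdR <- matrix(0, nrow_tot, 6)
  dNdZ <- matrix(0, nrow_tot, 6)
  Nmat <- matrix(0, nrow_tot, 6)
  Rq <- numeric(nrow_tot)
  wq <- numeric(nrow_tot)
  rows_q <- function(q) seq.int(q, by = nq, length.out = nel)
  for (q in seq_len(nq)) {
    sh <- p2_shape(rule$L[q, 1], rule$L[q, 2], rule$L[q, 3])
    rows <- rows_q(q)
    Rq[rows] <- rule$L[q, 1] * v1r + rule$L[q, 2] * nd[tri6[, 2], 1] +
      rule$L[q, 3] * nd[tri6[, 3], 1]
    wq[rows] <- rule$w[q] * det * 2 * pi * Rq[rows]
    for (aa in 1:6) {
      dNdR[rows, aa] <- (sh$dxi[aa] * d - sh$deta[aa] * cc) / det
      dNdZ[rows, aa] <- (-sh$dxi[aa] * b + sh$deta[aa] * a) / det
      Nmat[rows, aa] <- sh$N[aa]
    }
  }
  list(dNdR = dNdR, dNdZ = dNdZ, Nmat = Nmat, Rq = Rq, wq = wq, nq = nq,
       nel = nel)
}

#' Solver settings
#'
#' @param n_load_steps Number of load increments for the quasi-static solve.
#' @param newton_tol Relative residual tolerance of the Newton iteration.
#' @param max_newton_iters Maximum Newton iterations per increment.
#' @param line_search Use backtracking line search (recommended).
#' @param dt Base time step for viscoelastic runs (s).
#' @param dt_growth Growth factor applied to the time step during the hold
#'   phase of viscoelastic runs (1 keeps `dt` fixed).
#' @param dt_max Cap on the grown time step (s).
#' @param steady_state_tol Relative indentation-depth change per step below
#'   which a viscoelastic hold is declared steady.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(n_load_steps = 10, newton_tol = 1e-6,
                            max_newton_iters = 25, line_search = TRUE,
                            dt = 0.1, dt_growth = 1.5, dt_max = 2,
                            steady_state_tol = 1e-4) {
  stopifnot(n_load_steps >= 1, newton_tol > 0, newton_tol < 1,
            max_newton_iters >= 1, dt > 0, dt_growth >= 1,
            steady_state_tol > 0)
  s <- list(n_load_steps = n_load_steps, newton_tol = newton_tol,
            max_newton_iters = max_newton_iters, line_search = line_search,
            dt = dt, dt_growth = dt_growth, dt_max = dt_max,
            steady_state_tol = steady_state_tol)
  class(s) <- "solver_settings"
  s
}

# Per-element material arrays. Viscoelastic materials contribute their
# instantaneous Lame parameters; `visc` flags the elements whose stress is
# convolved with the reduced relaxation function.
material_arrays <- function(mesh, materials) {
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop("no material specified for region(s): ", paste(missing, collapse = ", "))
  nel <- nrow(mesh$tri6)
  law_e <- integer(nel)
  lam_e <- numeric(nel)
  mu_e <- numeric(nel)
  visc_e <- logical(nel)
  prony <- NULL
  for (rg in regions) {
    m <- materials[[rg]]
    stopifnot(inherits(m, "material_spec"))
    sel <- mesh$region == rg
    law_e[sel] <- if (m$law == "linear_elastic") 1L else 0L
    lm <- instantaneous_lame(m)
    lam_e[sel] <- lm[["lambda"]]
    mu_e[sel] <- lm[["mu"]]
    if (m$law == "viscoelastic_prony") {
      visc_e[sel] <- TRUE
      prony <- m$prony
    }
  }
  list(law_e = law_e, lam_e = lam_e, mu_e = mu_e, visc_e = visc_e,
       prony = prony)
}

#' Assemble residual and tangent of the equilibrium system
#'
#' Assembles the internal force vector and (optionally) the consistent
#' tangent stiffness at a given displacement state. The residual is
#' `internal force - external force`.
#'
#' @param mesh An `axi_mesh`.
#' @param materials Named list of [material_spec()] per region.
#' @param u Global displacement vector (length `2 * n_nodes`), micrometres.
#' @param fext External nodal force vector (or `NULL` for zero load).
#' @param want_K Assemble the tangent matrix as well.
#' @return List with `residual`, `minJ` (minimum quadrature determinant of
#'   the deformation gradient) and, if requested, the sparse tangent `K`.
#' @export
assemble_system <- function(mesh, materials, u, fext = NULL, want_K = TRUE) {
  qd <- mesh_quadrature(mesh)
  ma <- material_arrays(mesh, materials)
  nqp <- qd$nel * qd$nq
  ndof <- 2L * nrow(mesh$nodes)
  if (is.null(fext)) fext <- numeric(ndof)
  res <- asm_core(mesh$tri6 - 1L, u, qd$dNdR, qd$dNdZ, qd$Nmat, qd$Rq, qd$wq,
                  ma$law_e, ma$lam_e, ma$mu_e, rep(1, qd$nel),
                  matrix(0, nqp, 4), want_K, FALSE)
  if (!isTRUE(res$ok))
    stop(sprintf("assembly error: element inversion (min J = %g)", res$minJ))
  out <- list(residual = res$fint - fext, minJ = res$minJ)
  if (want_K) {
    pat <- triplet_pattern(mesh$tri6)
    out$K <- Matrix::sparseMatrix(i = pat$Ti, j = pat$Tj, x = res$Kx,
                                  dims = c(ndof, ndof))
  }
  out
}

# global dof triplet indices of the element tangent blocks, in the exact
# order asm_core emits values (element-major; row-major within each 12x12)
triplet_pattern <- function(conn) {
  dofs <- matrix(0L, nrow(conn), 12)
  dofs[, seq(1, 12, 2)] <- 2L * conn - 1L
  dofs[, seq(2, 12, 2)] <- 2L * conn
  list(Ti = as.integer(t(dofs[, rep(1:12, each = 12)])),
       Tj = as.integer(t(dofs[, rep(1:12, times = 12)])))
}

# Factorise the equilibrated reduced tangent with a simplicial LDL
# factorisation, reusing the cached symbolic analysis across iterations.
# Simplicial (non-supernodal) LDL handles indefinite tangents at strongly
# deformed states without the dense-block pivot grind of the supernodal
# path, and is faster than sparse LU in every regime measured here. LU
# remains as a fallback if the numeric factorisation fails outright.
tangent_solver <- function(ctx, Ks) {
  sym <- Matrix::forceSymmetric(Ks)
  fac <- tryCatch({
    if (is.null(ctx$cache$chol)) {
      ctx$cache$chol <- Matrix::Cholesky(sym, LDL = TRUE, super = FALSE)
      ctx$cache$chol
    } else {
      Matrix::update(ctx$cache$chol, sym)
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fac))
    return(function(b) as.numeric(Matrix::solve(fac, b)))
  luK <- Matrix::lu(Ks)
  function(b) as.numeric(Matrix::solve(luK, b))
}

# Assemble the reduced (free-dof) tangent using the cached sparsity pattern:
# the triplet -> compressed-column mapping is precomputed once per solve, so
# each Newton iteration only aggregates values.
reduced_tangent <- function(ctx, Kx) {
  kp <- ctx$kpat
  xs <- Kx[kp$keep][kp$ord]
  K <- kp$Ktmpl
  K@x <- as.numeric(rowsum(xs, kp$grp, reorder = FALSE))
  K
}

# Newton iteration at fixed external load and fixed viscoelastic state.
# Returns list(u, converged, rnorm, iters).
newton_solve <- function(u, ctx, fext, geff_e, Sconst, settings) {
  free <- ctx$free
  fref <- max(sqrt(sum(fext[free]^2)), 1e-8)
  tol <- settings$newton_tol * fref
  asm <- function(uu, wk) {
    asm_core(ctx$conn0, uu, ctx$qd$dNdR, ctx$qd$dNdZ, ctx$qd$Nmat,
             ctx$qd$Rq, ctx$qd$wq, ctx$ma$law_e, ctx$ma$lam_e, ctx$ma$mu_e,
             geff_e, Sconst, wk, FALSE)
  }
  res <- asm(u, TRUE)
  if (!isTRUE(res$ok)) return(list(u = u, converged = FALSE, rnorm = Inf,
                                   iters = 0L))
  r <- res$fint - fext
  rn <- sqrt(sum(r[free]^2))
  rn0 <- rn
  iters <- 0L
  slv <- NULL
  dsc <- NULL
  while (rn > tol && iters < settings$max_newton_iters) {
    # Jacobi-equilibrated symmetric factorisation with one iterative
    # refinement pass: keeps the achievable residual well below the Newton
    # tolerance on badly conditioned meshes (high-aspect far-field
    # elements, near incompressibility).
    Kf <- reduced_tangent(ctx, res$Kx)
    dsc <- 1 / sqrt(pmax(abs(Matrix::diag(Kf)), 1e-300))
    Dm <- Matrix::Diagonal(x = dsc)
    Ks <- Dm %*% Kf %*% Dm
    slv <- tangent_solver(ctx, Ks)
    rs <- dsc * r[free]
    y <- slv(rs)
    y <- y + slv(rs - as.numeric(Ks %*% y))
    du <- numeric(ctx$ndof)
    du[free] <- -dsc * y
    alpha <- 1
    repeat {
      u_try <- u + alpha * du
      res_try <- asm(u_try, FALSE) # residual-only trial
      rn_try <- if (isTRUE(res_try$ok)) {
        sqrt(sum((res_try$fint - fext)[free]^2))
      } else Inf
      if (rn_try < rn || !settings$line_search) break
      alpha <- alpha / 2
      if (alpha < 1e-4) break
    }
    if (!is.finite(rn_try) ||
        (settings$line_search && rn_try >= rn && rn > tol))
      return(list(u = u, converged = FALSE, rnorm = rn, iters = iters,
                  slv = slv, dsc = dsc))
    u <- u_try
    rn <- rn_try
    iters <- iters + 1L
    if (rn > tol) {
      res <- asm(u, TRUE)
      if (!isTRUE(res$ok))
        return(list(u = u, converged = FALSE, rnorm = rn, iters = iters,
                    slv = slv, dsc = dsc))
      r <- res$fint - fext
      rn <- sqrt(sum(r[free]^2))
    }
  }
  list(u = u, converged = rn <= tol, rnorm = rn, iters = iters,
       slv = slv, dsc = dsc)
}

# First-order continuation predictor: du ~ K^-1 (d_lambda * fext) using the
# factorisation from the last accepted Newton iteration.
predict_step <- function(ctx, ns, dfext) {
  if (is.null(ns$slv)) return(numeric(ctx$ndof))
  rs <- ns$dsc * dfext[ctx$free]
  du <- numeric(ctx$ndof)
  du[ctx$free] <- ns$dsc * ns$slv(rs)
  du
}

solver_context <- function(mesh, materials, bcs) {
  qd <- mesh_quadrature(mesh)
  ma <- material_arrays(mesh, materials)
  ndof <- 2L * nrow(mesh$nodes)
  free <- setdiff(seq_len(ndof), bcs$fixed_dofs)
  nf <- length(free)
  # constant triplet pattern of the element tangents (matches the C++
  # scatter order: element-major, then row-major within the 12x12 block)
  conn <- mesh$tri6
  dofs <- matrix(0L, nrow(conn), 12)
  dofs[, seq(1, 12, 2)] <- 2L * conn - 1L
  dofs[, seq(2, 12, 2)] <- 2L * conn
  Ti <- as.integer(t(dofs[, rep(1:12, each = 12)]))
  Tj <- as.integer(t(dofs[, rep(1:12, times = 12)]))
  fmap <- integer(ndof)
  fmap[free] <- seq_len(nf)
  ri <- fmap[Ti]
  rj <- fmap[Tj]
  keep <- which(ri > 0L & rj > 0L)
  ri <- ri[keep]
  rj <- rj[keep]
  key <- (as.numeric(rj) - 1) * nf + ri
  ord <- order(key)
  ks <- key[ord]
  newgrp <- c(TRUE, diff(ks) > 0)
  grp <- cumsum(newgrp)
  ui <- ri[ord][newgrp]
  uj <- rj[ord][newgrp]
  Ktmpl <- Matrix::sparseMatrix(i = ui, j = uj, x = double(length(ui)),
                                dims = c(nf, nf))
  kpat <- list(keep = keep, ord = ord, grp = grp, Ktmpl = Ktmpl)
  list(conn0 = mesh$tri6 - 1L, qd = qd, ma = ma, ndof = ndof, free = free,
       nqp = qd$nel * qd$nq, kpat = kpat,
       cache = new.env(parent = emptyenv()))
}

# Full state extraction at a converged displacement: deformation gradients,
# second Piola-Kirchhoff and Cauchy stresses at every quadrature point.
make_state <- function(u, ctx, mesh, materials, fext, geff_e, Sconst,
                       rnorm, time = NA_real_, load_factor = 1) {
  res <- asm_core(ctx$conn0, u, ctx$qd$dNdR, ctx$qd$dNdZ, ctx$qd$Nmat,
                  ctx$qd$Rq, ctx$qd$wq, ctx$ma$law_e, ctx$ma$lam_e,
                  ctx$ma$mu_e, geff_e, Sconst, FALSE, TRUE)
  Fq <- res$Fq
  Sq <- res$Sq
  J2 <- Fq[, 1] * Fq[, 4] - Fq[, 2] * Fq[, 3]
  J <- J2 * Fq[, 5]
  sig <- cbind(
    rr = (Fq[, 1]^2 * Sq[, 1] + 2 * Fq[, 1] * Fq[, 2] * Sq[, 4] +
            Fq[, 2]^2 * Sq[, 2]) / J,
    zz = (Fq[, 3]^2 * Sq[, 1] + 2 * Fq[, 3] * Fq[, 4] * Sq[, 4] +
            Fq[, 4]^2 * Sq[, 2]) / J,
    tt = Fq[, 5]^2 * Sq[, 3] / J,
    rz = (Fq[, 1] * Fq[, 3] * Sq[, 1] +
            (Fq[, 1] * Fq[, 4] + Fq[, 2] * Fq[, 3]) * Sq[, 4] +
            Fq[, 2] * Fq[, 4] * Sq[, 2]) / J
  )
  st <- list(u = u, Fq = Fq, Sq = Sq, Seq = res$Seq, sigma = sig, Jq = J,
             wq_ref = ctx$qd$wq, Rq_qp = ctx$qd$Rq,
             region_qp = rep(mesh$region, each = ctx$qd$nq),
             fint = res$fint, fext = fext, mesh = mesh, materials = materials,
             converged = TRUE, residual_norm = rnorm, time = time,
             load_factor = load_factor)
  class(st) <- "fe_state"
  st
}

#' @export
print.fe_state <- function(x, ...) {
  cat(sprintf(
    "FE state: %d dofs, %s, |residual| = %.3g, max |u| = %.4g um\n",
    length(x$u), if (x$converged) "converged" else "NOT converged",
    x$residual_norm, max(abs(x$u))))
  invisible(x)
}

#' Quasi-static nonlinear solve
#'
#' Solves the equilibrium boundary-value problem by Newton iteration with
#' incremental loading and automatic step halving. All materials must be
#' elastic (`neo_hookean` or `linear_elastic`); use [solve_viscoelastic()]
#' for a Prony-series cytoplasm. The solve is fully deterministic.
#'
#' @param mesh An `axi_mesh`.
#' @param materials Named list of [material_spec()] per region.
#' @param load A `load_assignment` from [build_load_case()], a raw external
#'   force vector, or `NULL` for zero load.
#' @param bcs A [build_bcs()] result.
#' @param settings [solver_settings()].
#' @param allow_partial If `TRUE` and the continuation stalls before full
#'   load (the equilibrium path ends, e.g. the cell is crushed beyond what
#'   the mesh can follow), return the converged state at the highest
#'   attained load factor instead of raising; the state carries
#'   `load_factor < 1` and `partial = TRUE`.
#' @return An `fe_state` with nodal displacements and quadrature-point
#'   deformation gradients and Cauchy stresses.
#' @export
solve_quasistatic <- function(mesh, materials, load, bcs,
                              settings = solver_settings(),
                              allow_partial = FALSE) {
  ctx <- solver_context(mesh, materials, bcs)
  if (any(ctx$ma$visc_e))
    stop("viscoelastic material present: use solve_viscoelastic()")
  fext <- extract_fext(load, ctx$ndof)
  geff_e <- rep(1, ctx$qd$nel)
  Sconst <- matrix(0, ctx$nqp, 4)

  # incremental loading with adaptive step control: halve on Newton failure,
  # grow gently after success
  u <- numeric(ctx$ndof)
  lam_done <- 0
  dl0 <- 1 / settings$n_load_steps
  dl <- dl0
  ns <- newton_solve(u, ctx, fext * 0, geff_e, Sconst, settings)
  while (lam_done < 1 - 1e-12) {
    lam_to <- min(lam_done + dl, 1)
    pred <- predict_step(ctx, ns, fext * (lam_to - lam_done))
    trial <- newton_solve(u + pred, ctx, fext * lam_to, geff_e, Sconst,
                          settings)
    if (!trial$converged && any(pred != 0))
      trial <- newton_solve(u, ctx, fext * lam_to, geff_e, Sconst, settings)
    if (trial$converged) {
      ns <- trial
      u <- ns$u
      lam_done <- lam_to
      dl <- min(dl * 1.3, 2 * dl0)
    } else {
      dl <- dl / 2
      if (dl < dl0 / 256) {
        if (allow_partial && lam_done > 0) break
        stop(sprintf(
          "Newton divergence: no convergence at load factor %.4g (|r| = %.3g)",
          lam_to, trial$rnorm))
      }
    }
  }
  st <- make_state(ns$u, ctx, mesh, materials, fext * lam_done, geff_e,
                   Sconst, ns$rnorm, load_factor = lam_done)
  st$partial <- lam_done < 1 - 1e-12
  st
}

extract_fext <- function(load, ndof) {
  if (is.null(load)) return(numeric(ndof))
  if (inherits(load, "load_assignment")) return(load$fext)
  stopifnot(is.numeric(load), length(load) == ndof)
  load
}

#' Time-stepped solve with a viscoelastic cytoplasm
#'
#' Ramps the load linearly over the case's `ramp_time`, then holds it,
#' advancing the quasi-linear viscoelastic state of the cytoplasm with the
#' exponential-integrator recurrence at every step. The hold terminates when
#' the relative indentation-depth change per step drops below
#' `steady_state_tol` or `hold_time` is exhausted. Every step satisfies the
#' quasi-static residual contract.
#'
#' @inheritParams solve_quasistatic
#' @param ramp_time,hold_time Optional protocol overrides; by default taken
#'   from the load case (1 s ramp, 10 s hold when the load is a raw vector).
#' @param allow_partial If `TRUE` and a ramp step fails to converge even
#'   after the time step is refined to its floor (the quasi-static
#'   equilibrium path ends below full load), return the history up to the
#'   highest attained load instead of raising; the final state carries
#'   `load_factor < 1` and `partial = TRUE`.
#' @return An object of class `fe_history`: time series of indentation depth
#'   plus the full states at the end of the ramp (`state_ramp_end`) and at
#'   the final time (`state_final`).
#' @export
solve_viscoelastic <- function(mesh, materials, load, bcs,
                               settings = solver_settings(),
                               ramp_time = NULL, hold_time = NULL,
                               allow_partial = FALSE) {
  ctx <- solver_context(mesh, materials, bcs)
  if (!any(ctx$ma$visc_e))
    stop("no viscoelastic material: use solve_quasistatic()")
  prony <- ctx$ma$prony
  lc <- if (inherits(load, "load_assignment")) load$lc else NULL
  ramp <- if (!is.null(ramp_time)) ramp_time else
    if (!is.null(lc)) lc$ramp_time else 1
  hold <- if (!is.null(hold_time)) hold_time else
    if (!is.null(lc)) lc$hold_time else 10
  fext <- extract_fext(load, ctx$ndof)

  Gsum <- prony$G_inf + prony$G_1 + prony$G_2
  gam_inf <- prony$G_inf / Gsum
  gam <- c(prony$G_1, prony$G_2) / Gsum
  tau <- c(prony$tau_1, prony$tau_2)
  visc_qp <- rep(ctx$ma$visc_e, each = ctx$qd$nq)

  Se_prev <- matrix(0, ctx$nqp, 4)
  h1 <- matrix(0, ctx$nqp, 4)
  h2 <- matrix(0, ctx$nqp, 4)
  u <- numeric(ctx$ndof)

  n_ramp <- if (ramp > 0) max(1L, ceiling(ramp / settings$dt)) else 0L
  dt_ramp <- if (n_ramp > 0) ramp / n_ramp else settings$dt

  times <- numeric(0)
  depths <- numeric(0)
  state_ramp_end <- NULL
  state_final <- NULL
  t_now <- 0
  step <- 0L
  dt_cur <- dt_ramp
  dt_hold <- settings$dt
  prev_depth <- NA_real_
  partial <- FALSE

  repeat {
    step <- step + 1L
    in_ramp <- ramp > 0 && t_now < ramp - 1e-12
    dt <- if (in_ramp) min(dt_cur, ramp - t_now) else dt_hold
    t_next <- t_now + dt
    lamf <- if (ramp > 0) min(t_next / ramp, 1) else 1

    ex <- exp(-dt / tau)
    beta <- (1 - ex) / (dt / tau)
    geff_val <- gam_inf + sum(gam * beta)
    geff_e <- ifelse(ctx$ma$visc_e, geff_val, 1)
    Sconst <- matrix(0, ctx$nqp, 4)
    Sconst[visc_qp, ] <- ex[1] * h1[visc_qp, , drop = FALSE] +
      ex[2] * h2[visc_qp, , drop = FALSE] -
      sum(gam * beta) * Se_prev[visc_qp, , drop = FALSE]

    ns <- newton_solve(u, ctx, fext * lamf, geff_e, Sconst, settings)
    if (!ns$converged) {
      # refine the time step (and hence the load increment) before giving up
      if (in_ramp && dt_cur > dt_ramp / 64) {
        dt_cur <- dt_cur / 2
        step <- step - 1L
        next
      }
      if (allow_partial && in_ramp && !is.null(state_final)) {
        partial <- TRUE
        if (is.null(state_ramp_end)) state_ramp_end <- state_final
        break
      }
      stop(sprintf("viscoelastic step %d (t = %.3g s) failed to converge",
                   step, t_next))
    }
    u <- ns$u
    st <- make_state(u, ctx, mesh, materials, fext * lamf, geff_e, Sconst,
                     ns$rnorm, time = t_next, load_factor = lamf)
    # advance the convolution state
    dSe <- st$Seq - Se_prev
    h1[visc_qp, ] <- ex[1] * h1[visc_qp, , drop = FALSE] +
      gam[1] * beta[1] * dSe[visc_qp, , drop = FALSE]
    h2[visc_qp, ] <- ex[2] * h2[visc_qp, , drop = FALSE] +
      gam[2] * beta[2] * dSe[visc_qp, , drop = FALSE]
    Se_prev <- st$Seq

    t_now <- t_next
    d <- indentation_depth(st)
    times <- c(times, t_now)
    depths <- c(depths, d)
    if ((in_ramp && t_now >= ramp - 1e-12) || (n_ramp == 0L && step == 1L))
      state_ramp_end <- st
    state_final <- st

    if (!in_ramp) {
      if (!is.na(prev_depth) &&
          abs(d - prev_depth) / max(abs(d), 1e-12) < settings$steady_state_tol)
        break
      prev_depth <- d
      dt_hold <- min(dt_hold * settings$dt_growth, settings$dt_max)
      if (t_now >= ramp + hold - 1e-12) break
    } else {
      prev_depth <- d
      dt_cur <- min(dt_cur * settings$dt_growth, dt_ramp)
      if (t_now >= ramp - 1e-12 && hold <= 0) break
    }
  }

  state_final$partial <- partial
  if (!is.null(state_ramp_end)) state_ramp_end$partial <- partial
  out <- list(times = times, depths = depths,
              state_ramp_end = state_ramp_end, state_final = state_final,
              converged = !partial, settings = settings, load_case = lc)
  class(out) <- "fe_history"
  out
}

#' @export
print.fe_history <- function(x, ...) {
  cat(sprintf(
    "Viscoelastic history: %d steps to t = %.3g s; depth %.4g um (ramp end %.4g um)\n",
    length(x$times), max(x$times), x$depths[length(x$depths)],
    if (!is.null(x$state_ramp_end)) indentation_depth(x$state_ramp_end)
    else NA_real_))
  invisible(x)
}

#' Reaction resultants at the constrained boundary
#'
#' Sums the reaction forces (internal minus external nodal force) over the
#' constrained dofs of a converged state. For a self-equilibrated load case
#' the vertical reaction resultant vanishes.
#'
#' @param state An `fe_state`.
#' @param bcs The [build_bcs()] set used for the solve.
#' @return Named vector with the radial and vertical reaction sums (nN).
#' @export
reaction_sums <- function(state, bcs) {
  r <- state$fint - state$fext
  fd <- bcs$fixed_dofs
  c(Fr = sum(r[fd[fd %% 2 == 1]]), Fz = sum(r[fd[fd %% 2 == 0]]))
}
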