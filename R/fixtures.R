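## Self-contained verification fixtures with closed-form expected values.
## Every expected value is computed from its formula at construction time,
## so fixtures cannot drift from the analytic solutions they encode.

new_fixture <- function(mesh, materials, loads, bcs, expected, note) {
  f <- list(mesh = mesh, materials = materials, loads = loads, bcs = bcs,
            expected = expected, note = note)
  class(f) <- "fe_fixture"
  f
}

#' @export
print.fe_fixture <- function(x, ...) {
  cat("Verification fixture:", x$note, "\n")
  for (nm in names(x$expected))
    cat(sprintf("  expected %s = %s (tol %g)\n", nm,
                paste(signif(x$expected[[nm]]$value, 6), collapse = ", "),
                x$expected[[nm]]$tol))
  invisible(x)
}

#' Rigid flat-punch indentation fixture
#'
#' Boussinesq's rigid flat circular punch on an elastic half-space: a total
#' force `F` through a rigid disc of radius `a` produces the uniform
#' displacement `d = F (1 - nu^2) / (2 a E)` under the disc. The fixture
#' applies the punch's exact contact-pressure distribution
#' `p(r) = F / (2 pi a sqrt(a^2 - r^2))` as consistent nodal loads on a
#' gel-only cylinder with the production gel dimensions (so it doubles as a
#' far-boundary check of the half-space approximation).
#'
#' @param a Punch radius (um).
#' @param E,nu Gel elastic constants (kPa, -).
#' @param F Total punch force (nN); keep small enough for the linear regime.
#' @param resolution Mesh fineness (edge length `0.25 / resolution` um near
#'   the punch).
#' @param gel_radius,gel_thickness Domain dimensions (um).
#' @return An `fe_fixture`; `expected$depth` holds the closed-form depth.
#' @export
flat_punch_fixture <- function(a = 3, E = 2.4, nu = 0.48, F = 10,
                               resolution = 1, gel_radius = 225,
                               gel_thickness = 300) {
  h <- 0.25 / resolution
  mesh <- gel_only_mesh(gel_radius, gel_thickness, fine_to = 4 * a, h = h,
                        fine_radii = a)
  bcs <- build_bcs(mesh)
  nd <- mesh$nodes
  ndof <- 2L * nrow(nd)
  fext <- numeric(ndof)
  # surface edges inside the punch: endpoints on z = 0 with r <= a
  tol <- 1e-6
  e1 <- integer(0); e2 <- integer(0); em <- integer(0)
  for (k in 1:3) {
    aa <- mesh$tri6[, k]
    bb <- mesh$tri6[, (k %% 3) + 1]
    mm <- mesh$tri6[, 3 + k]
    sel <- abs(nd[aa, 2]) < tol & abs(nd[bb, 2]) < tol &
      nd[aa, 1] <= a + tol & nd[bb, 1] <= a + tol
    e1 <- c(e1, aa[sel]); e2 <- c(e2, bb[sel]); em <- c(em, mm[sel])
  }
  # integrate p(r) N_a(r) 2 pi r dr exactly via u = sqrt(a^2 - r^2):
  # the integrand becomes (F/a) N(r(u)), smooth in u; 4-pt Gauss per edge.
  gx <- c(-0.861136311594053, -0.339981043584856,
          0.339981043584856, 0.861136311594053)
  gw <- c(0.347854845137454, 0.652145154862546,
          0.652145154862546, 0.347854845137454)
  for (i in seq_along(e1)) {
    r1 <- nd[e1[i], 1]; r2 <- nd[e2[i], 1]
    u1 <- sqrt(max(a^2 - r1^2, 0)); u2 <- sqrt(max(a^2 - r2^2, 0))
    for (g in 1:4) {
      u <- (u1 + u2) / 2 + gx[g] * (u2 - u1) / 2
      w <- gw[g] * abs(u2 - u1) / 2 * (F / a)
      r <- sqrt(max(a^2 - u^2, 0))
      xi <- (r - r1) / (r2 - r1)
      N <- c((1 - xi) * (1 - 2 * xi), xi * (2 * xi - 1), 4 * xi * (1 - xi))
      ids <- c(e1[i], e2[i], em[i])
      fext[2 * ids] <- fext[2 * ids] - w * N
    }
  }
  materials <- list(gel = material_spec("neo_hookean", E = E, nu = nu))
  expected <- list(depth = list(value = F * (1 - nu^2) / (2 * a * E),
                                tol = 0.05,
                                formula = "F (1 - nu^2) / (2 a E)"))
  new_fixture(mesh, materials, fext, bcs, expected,
              sprintf("Boussinesq flat punch a = %g um, F = %g nN", a, F))
}

# Lateral stretch of a uniaxial-stress state (free lateral faces) for the
# given law, found from the closed-form lateral-stress condition.
uniaxial_lateral_stretch <- function(law, lambda, mu, stretch) {
  sig_lat <- function(ll) {
    if (law == "neo_hookean") {
      J <- stretch * ll^2
      (mu / J) * (ll^2 - 1) + (lambda / J) * log(J)
    } else {
      # Saint Venant-Kirchhoff lateral second PK stress (zero iff lateral
      # Cauchy stress is zero for diagonal F)
      Ea <- (stretch^2 - 1) / 2
      El <- (ll^2 - 1) / 2
      lambda * (Ea + 2 * El) + 2 * mu * El
    }
  }
  stats::uniroot(sig_lat, c(0.05, 20), tol = 1e-14)$root
}

#' Homogeneous uniaxial-stress patch fixture
#'
#' A homogeneous uniaxial-stress deformation state at a prescribed axial
#' stretch: the lateral stretch is found from the condition of vanishing
#' lateral stress and the expected axial Cauchy stress follows from the
#' constitutive closed form. The fixture carries the deformation gradient
#' and the expected stress tensor; at small stretch the axial stress tends
#' to `E * (stretch - 1)`.
#'
#' @param law `"neo_hookean"` or `"linear_elastic"`.
#' @param E,nu Elastic constants.
#' @param stretch Axial stretch (> 0); 1 gives the stress-free state.
#' @return An `fe_fixture` with `F_grad` and `expected$sigma_axial`.
#' @export
uniaxial_patch_fixture <- function(law = "neo_hookean", E = 1, nu = 0.3,
                                   stretch = 1.0001) {
  stopifnot(stretch > 0)
  lm <- lame_from_E_nu(E, nu)
  ll <- if (abs(stretch - 1) < 1e-14) 1 else
    uniaxial_lateral_stretch(law, lm[["lambda"]], lm[["mu"]], stretch)
  F_grad <- diag(c(ll, stretch, ll))
  sig <- if (law == "neo_hookean") {
    neo_hookean_stress(F_grad, lm[["lambda"]], lm[["mu"]])
  } else {
    Emat <- (t(F_grad) %*% F_grad - diag(3)) / 2
    S <- lm[["lambda"]] * sum(diag(Emat)) * diag(3) + 2 * lm[["mu"]] * Emat
    F_grad %*% S %*% t(F_grad) / det(F_grad)
  }
  expected <- list(sigma_axial = list(value = sig[2, 2], tol = 1e-10,
                                      formula = "constitutive closed form at uniaxial stress"),
                   sigma_lateral = list(value = 0, tol = 1e-8,
                                        formula = "free lateral faces"))
  f <- new_fixture(mesh = NULL, materials = list(patch =
                     material_spec(law, E = E, nu = nu)),
                   loads = NULL, bcs = NULL, expected = expected,
                   note = sprintf("uniaxial patch, %s, stretch %g", law,
                                  stretch))
  f$F_grad <- F_grad
  f
}

#' Step-strain relaxation fixture
#'
#' A single material point subjected to a step in elastic stress at `t = 0`
#' and held: the convolved stress ratio follows the reduced relaxation
#' function `g(t)` exactly. Expected values are computed from the Prony
#' closed form on a sampling grid over the hold.
#'
#' @param prony Prony constants.
#' @param hold Hold duration (s), positive.
#' @param n_samples Number of sample times.
#' @return An `fe_fixture` with `times` and `expected$ratio`.
#' @export
relaxation_fixture <- function(prony = prony_constants(), hold = 30,
                               n_samples = 60) {
  stopifnot(hold > 0)
  times <- seq(0, hold, length.out = n_samples + 1)[-1]
  expected <- list(ratio = list(value = reduced_relaxation(times, prony),
                                tol = 0.01,
                                formula = "g(t) = (Ginf + G1 e^(-t/tau1) + G2 e^(-t/tau2)) / sum(G)"),
                   ratio_inf = list(
                     value = prony$G_inf / (prony$G_inf + prony$G_1 + prony$G_2),
                     tol = 1e-12, formula = "g(Inf) = Ginf / sum(G)"))
  f <- new_fixture(mesh = NULL,
                   materials = list(point = material_spec(
                     "viscoelastic_prony", E = 1, nu = 0.3, prony = prony)),
                   loads = NULL, bcs = NULL, expected = expected,
                   note = sprintf("step-strain relaxation over %g s", hold))
  f$times <- times
  f$prony <- prony
  f
}

#' Reproducible randomised property-test fixtures
#'
#' Generates `n` small axisymmetric patch problems (gel-only cylinders with
#' random dimensions, random elastic materials and a random uniform surface
#' pressure on the top face) for property tests: global equilibrium of the
#' reactions, tangent consistency, and mesh invariants. Generation is pure:
#' the same seed yields identical fixtures.
#'
#' @param seed Integer RNG seed.
#' @param n Number of fixtures (>= 1).
#' @return List of `fe_fixture` objects; each expects the vertical reaction
#'   sum to balance the applied load.
#' @export
randomized_property_cases <- function(seed = 20240301, n = 5) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    Rg <- round(stats::runif(1, 2, 5), 2)
    Tg <- round(stats::runif(1, 1.5, 4), 2)
    h <- Rg / sample(2:4, 1)
    law <- sample(c("neo_hookean", "linear_elastic"), 1)
    E <- round(stats::runif(1, 0.5, 3), 3)
    nu <- round(stats::runif(1, 0, 0.45), 3)
    q <- round(stats::runif(1, 0.01, 0.05) * E, 5)
    mesh <- gel_only_mesh(Rg, Tg, fine_to = Rg, h = h)
    bcs <- build_bcs(mesh)
    # uniform downward pressure on the whole top face, consistent P2 loads
    nd <- mesh$nodes
    fext <- numeric(2L * nrow(nd))
    tol <- 1e-6
    for (k in 1:3) {
      aa <- mesh$tri6[, k]
      bb <- mesh$tri6[, (k %% 3) + 1]
      mm <- mesh$tri6[, 3 + k]
      sel <- abs(nd[aa, 2]) < tol & abs(nd[bb, 2]) < tol
      if (!any(sel)) next
      r1 <- nd[aa[sel], 1]; r2 <- nd[bb[sel], 1]
      len <- abs(r2 - r1)
      gx <- c(0.5 - sqrt(0.15), 0.5, 0.5 + sqrt(0.15))
      gw <- c(5, 8, 5) / 18
      intN <- matrix(0, sum(sel), 3)
      for (g in 1:3) {
        xi <- gx[g]
        N <- c((1 - xi) * (1 - 2 * xi), xi * (2 * xi - 1), 4 * xi * (1 - xi))
        Rm <- r1 + (r2 - r1) * xi
        for (a2 in 1:3) intN[, a2] <- intN[, a2] + gw[g] * N[a2] * Rm
      }
      intN <- intN * (2 * pi * len)
      idm <- cbind(aa[sel], bb[sel], mm[sel])
      for (a2 in 1:3)
        fext[2 * idm[, a2]] <- fext[2 * idm[, a2]] - q * intN[, a2]
    }
    total_fz <- sum(fext[seq(2, length(fext), by = 2)])
    out[[i]] <- new_fixture(
      mesh,
      list(gel = material_spec(law, E = E, nu = nu)),
      fext, bcs,
      expected = list(reaction_z = list(
        value = -total_fz, tol = 1e-8,
        formula = "reactions balance the applied resultant")),
      note = sprintf("random patch %d: %s, E = %g, nu = %g, q = %g",
                     i, law, E, nu, q))
  }
  out
}
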