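#' Prony relaxation constants for the viscoelastic cytoplasm
#'
#' Two-branch Prony series used for the quasi-linear viscoelastic cytoplasm:
#' a long-time weight `G_inf` and two decaying branches `(G_1, tau_1)`,
#' `(G_2, tau_2)`. The defaults are the literature constants adopted for
#' cytoplasm rheology (weights in kPa, times in seconds). Internally the
#' weights are normalised by their sum, giving the reduced relaxation
#' function `g(t)`.
#'
#' @param G_inf,G_1,G_2 Prony weights (kPa).
#' @param tau_1,tau_2 Relaxation times (s).
#' @return A list of class `prony`.
#' @export
prony_constants <- function(G_inf = 4.05, G_1 = 34, G_2 = 20.2,
                            tau_1 = 0.58, tau_2 = 5.47) {
  p <- list(G_inf = G_inf, G_1 = G_1, G_2 = G_2, tau_1 = tau_1, tau_2 = tau_2)
  if (any(unlist(p) <= 0)) stop("all Prony constants must be positive")
  class(p) <- "prony"
  p
}

#' Material specification
#'
#' @param law One of `"neo_hookean"` (compressible hyperelastic),
#'   `"linear_elastic"` (Hookean in Green strain, i.e. Saint Venant-Kirchhoff,
#'   assembled in the geometrically nonlinear framework) or
#'   `"viscoelastic_prony"` (quasi-linear viscoelastic Neo-Hookean).
#' @param E Young's modulus (kPa).
#' @param nu Poisson ratio; must be strictly below 0.5.
#' @param prony Prony constants (required for `viscoelastic_prony`), see
#'   [prony_constants()].
#' @param visco_mode How the Prony weights relate to `E`:
#'   `"equilibrium"` (default) treats them as normalised relaxation weights
#'   and anchors the long-time modulus at `E`, so a fully relaxed
#'   viscoelastic run matches the elastic run with the same `E`;
#'   `"literal"` reads the weights as shear moduli in kPa, with instantaneous
#'   shear modulus `G_inf + G_1 + G_2`.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(law = c("neo_hookean", "linear_elastic",
                                  "viscoelastic_prony"),
                          E, nu, prony = NULL,
                          visco_mode = c("equilibrium", "literal")) {
  law <- match.arg(law)
  visco_mode <- match.arg(visco_mode)
  if (!is.finite(E) || E <= 0) stop("E must be positive")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("nu must satisfy 0 <= nu < 0.5 (fully incompressible not supported)")
  if (law == "viscoelastic_prony") {
    if (is.null(prony)) prony <- prony_constants()
    stopifnot(inherits(prony, "prony"))
  }
  m <- list(law = law, E = E, nu = nu, prony = prony, visco_mode = visco_mode)
  class(m) <- "material_spec"
  m
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("%s: E = %g kPa, nu = %g", x$law, x$E, x$nu))
  if (!is.null(x$prony))
    cat(sprintf("; Prony G = (%g, %g, %g) kPa, tau = (%g, %g) s [%s mode]",
                x$prony$G_inf, x$prony$G_1, x$prony$G_2,
                x$prony$tau_1, x$prony$tau_2, x$visco_mode))
  cat("\n")
  invisible(x)
}

#' Default region materials for the cell-on-gel model
#'
#' Nucleus: Neo-Hookean, 2 kPa, nu 0.49. Cytoplasm: Neo-Hookean (or
#' quasi-linear viscoelastic) with adjustable stiffness, nu 0.49.
#' Gel: linear elastic, 2.4 kPa, nu 0.48.
#'
#' @param E_cyto Cytoplasm Young's modulus (kPa).
#' @param model `"elastic"` or `"viscoelastic"` cytoplasm.
#' @param visco_mode See [material_spec()].
#' @param prony Prony constants for the viscoelastic cytoplasm.
#' @param gel_law Constitutive law for the gel. The gel responds linearly
#'   over its working strain range; the default `"neo_hookean"` realises
#'   that linear behaviour with a finite-strain law that remains stable
#'   under the strong local compression beneath the cell (the Green-strain
#'   Hookean law, available as `"linear_elastic"`, loses ellipticity there).
#' @return Named list of [material_spec()] objects (nucleus, cytoplasm, gel).
#' @export
default_materials <- function(E_cyto = 0.8,
                              model = c("elastic", "viscoelastic"),
                              visco_mode = c("equilibrium", "literal"),
                              prony = prony_constants(),
                              gel_law = "neo_hookean") {
  model <- match.arg(model)
  visco_mode <- match.arg(visco_mode)
  cyto <- if (model == "elastic") {
    material_spec("neo_hookean", E = E_cyto, nu = 0.49)
  } else {
    material_spec("viscoelastic_prony", E = E_cyto, nu = 0.49,
                  prony = prony, visco_mode = visco_mode)
  }
  list(nucleus = material_spec("neo_hookean", E = 2, nu = 0.49),
       cytoplasm = cyto,
       gel = material_spec(gel_law, E = 2.4, nu = 0.48))
}

#' Lame parameters from Young's modulus and Poisson ratio
#'
#' @param E Young's modulus (kPa).
#' @param nu Poisson ratio (must be < 0.5).
#' @return Named numeric vector `c(lambda, mu)` in kPa.
#' @export
lame_from_E_nu <- function(E, nu) {
  if (any(E <= 0)) stop("E must be positive")
  if (any(nu >= 0.5)) stop("nu must be < 0.5: incompressible limit excluded")
  if (any(nu < 0)) stop("nu must be >= 0")
  mu <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  c(lambda = lambda, mu = mu)
}

as_tensor3 <- function(sigma) {
  if (is.matrix(sigma)) {
    stopifnot(nrow(sigma) == 3, ncol(sigma) == 3)
    return(sigma)
  }
  stopifnot(length(sigma) == 4)
  # axisymmetric storage (s_rr, s_zz, s_tt, s_rz)
  matrix(c(sigma[1], sigma[4], 0,
           sigma[4], sigma[2], 0,
           0, 0, sigma[3]), 3, 3)
}

#' Cauchy stress of the compressible Neo-Hookean law
#'
#' Evaluates `sigma = (mu/J)(B - I) + (lambda/J) ln(J) I` with `B = F F^T`
#' and `J = det F`, the stress of the stored energy
#' `W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2`.
#'
#' @param F_grad Deformation gradient, a 3x3 matrix with positive determinant.
#' @param lambda,mu Lame parameters (kPa).
#' @return 3x3 Cauchy stress matrix (kPa).
#' @export
neo_hookean_stress <- function(F_grad, lambda, mu) {
  stopifnot(is.matrix(F_grad), all(dim(F_grad) == c(3, 3)))
  J <- det(F_grad)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  B <- F_grad %*% t(F_grad)
  (mu / J) * (B - diag(3)) + (lambda / J) * log(J) * diag(3)
}

#' Reduced relaxation function of the Prony series
#'
#' `g(t) = (G_inf + G_1 exp(-t/tau_1) + G_2 exp(-t/tau_2)) / (G_inf+G_1+G_2)`,
#' normalised so `g(0) = 1` and monotonically decaying to
#' `G_inf / (G_inf + G_1 + G_2)`.
#'
#' @param t Time(s) in seconds, non-negative (vectorised).
#' @param prony Prony constants, see [prony_constants()].
#' @return Dimensionless relaxation value(s).
#' @export
reduced_relaxation <- function(t, prony = prony_constants()) {
  stopifnot(inherits(prony, "prony"))
  if (any(t < 0)) stop("t must be non-negative")
  Gsum <- prony$G_inf + prony$G_1 + prony$G_2
  (prony$G_inf + prony$G_1 * exp(-t / prony$tau_1) +
      prony$G_2 * exp(-t / prony$tau_2)) / Gsum
}

#' One step of the quasi-linear viscoelastic stress recurrence
#'
#' Advances the convolution `sigma(t) = integral g(t - s) d sigma_e(s)` by one
#' time step using the standard exponential-integrator recurrence per Prony
#' branch. The internal state is one tensorial variable per branch plus the
#' previous elastic stress.
#'
#' @param history State from the previous step, or `NULL` to initialise at
#'   `t = 0` with zero stress.
#' @param dt Time step (s), positive.
#' @param elastic_stress_new Elastic (instantaneous-law) stress at the end of
#'   the step; 3x3 matrix or axisymmetric 4-vector.
#' @param prony Prony constants.
#' @return List with `stress` (3x3 matrix, the convolved stress) and
#'   `history` (the updated state).
#' @export
viscoelastic_stress_update <- function(history, dt, elastic_stress_new,
                                       prony = prony_constants()) {
  if (dt <= 0) stop("dt must be positive")
  Se <- as_tensor3(elastic_stress_new)
  if (is.null(history))
    history <- list(t = 0, Se_prev = matrix(0, 3, 3),
                    h = list(matrix(0, 3, 3), matrix(0, 3, 3)))
  Gsum <- prony$G_inf + prony$G_1 + prony$G_2
  gam <- c(prony$G_1, prony$G_2) / Gsum
  tau <- c(prony$tau_1, prony$tau_2)
  dSe <- Se - history$Se_prev
  h <- history$h
  for (i in 1:2) {
    x <- dt / tau[i]
    beta <- (1 - exp(-x)) / x
    h[[i]] <- exp(-x) * h[[i]] + gam[i] * beta * dSe
  }
  stress <- (prony$G_inf / Gsum) * Se + h[[1]] + h[[2]]
  list(stress = stress,
       history = list(t = history$t + dt, Se_prev = Se, h = h))
}

#' von Mises (effective) stress
#'
#' `sqrt(3/2 dev(sigma) : dev(sigma))`, the scalar deviatoric invariant used
#' as the effective stress measure.
#'
#' @param sigma 3x3 symmetric stress matrix, or axisymmetric 4-vector
#'   `(s_rr, s_zz, s_tt, s_rz)`.
#' @return Non-negative scalar (kPa).
#' @export
von_mises <- function(sigma) {
  s <- as_tensor3(sigma)
  d <- s - diag(3) * sum(diag(s)) / 3
  sqrt(1.5 * sum(d * d))
}

#' Total (trace) stress
#'
#' Sum of the three directional (normal) stress components,
#' `s_rr + s_zz + s_tt`. Signed: negative under net compression.
#'
#' @inheritParams von_mises
#' @return Scalar (kPa).
#' @export
total_stress <- function(sigma) {
  s <- as_tensor3(sigma)
  sum(diag(s))
}

# Instantaneous Lame parameters of a material, honouring the viscoelastic
# anchoring mode. For "equilibrium" the elastic-law stress is scaled so that
# g(Inf) * S_inst equals the elastic stress at modulus E; for "literal" the
# Prony weights are shear moduli and E is ignored for the instantaneous value.
instantaneous_lame <- function(mat) {
  lm <- lame_from_E_nu(mat$E, mat$nu)
  if (mat$law != "viscoelastic_prony") return(lm)
  p <- mat$prony
  Gsum <- p$G_inf + p$G_1 + p$G_2
  if (mat$visco_mode == "equilibrium") {
    lm / (p$G_inf / Gsum)
  } else {
    E_inst <- 2 * (1 + mat$nu) * Gsum
    lame_from_E_nu(E_inst, mat$nu)
  }
}
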