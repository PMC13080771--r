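test_that("Lame conversion matches the closed form", {
  lm <- lame_from_E_nu(2.4, 0.48)
  expect_equal(lm[["mu"]], 2.4 / (2 * 1.48), tolerance = 1e-12)
  expect_equal(lm[["lambda"]], 2.4 * 0.48 / (1.48 * 0.04), tolerance = 1e-12)
  expect_equal(unname(lame_from_E_nu(2.0, 0.49)),
               c(2 * 0.49 / (1.49 * 0.02), 2 / (2 * 1.49)), tolerance = 1e-12)
  expect_equal(unname(lame_from_E_nu(1, 0)), c(0, 0.5))
  expect_error(lame_from_E_nu(1, 0.5), "incompressible")
  expect_error(lame_from_E_nu(-1, 0.3), "positive")
})

test_that("Neo-Hookean stress: reference state, linear and bulk limits", {
  lm <- lame_from_E_nu(1.7, 0.35)
  expect_equal(neo_hookean_stress(diag(3), lm[["lambda"]], lm[["mu"]]),
               matrix(0, 3, 3))
  # uniaxial-stress small strain: sigma_axial / eps -> E
  eps <- 1e-4
  fx <- uniaxial_patch_fixture("neo_hookean", E = 1.7, nu = 0.35,
                               stretch = 1 + eps)
  expect_equal(fx$expected$sigma_axial$value / eps, 1.7, tolerance = 1e-3)
  # volumetric: pressure/dilatation -> bulk modulus
  dl <- 1e-4
  s <- neo_hookean_stress(diag(3) * (1 + dl), lm[["lambda"]], lm[["mu"]])
  K <- 1.7 / (3 * (1 - 2 * 0.35))
  expect_equal(sum(diag(s)) / 3 / (3 * dl), K, tolerance = 1e-3)
  expect_error(neo_hookean_stress(diag(c(-1, 1, 1)), 1, 1), "inversion")
})

test_that("Neo-Hookean stress is frame-indifferent", {
  set.seed(7)
  lm <- lame_from_E_nu(2, 0.3)
  for (k in 1:5) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.15), 3, 3)
    if (det(F) <= 0.1) next
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, pi)
    Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                 3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
    s1 <- neo_hookean_stress(R %*% F, lm[["lambda"]], lm[["mu"]])
    s2 <- R %*% neo_hookean_stress(F, lm[["lambda"]], lm[["mu"]]) %*% t(R)
    expect_equal(s1, s2, tolerance = 1e-10)
  }
})

test_that("reduced relaxation function has the Prony limits and monotonicity", {
  p <- prony_constants()
  expect_equal(reduced_relaxation(0, p), 1)
  ginf <- 4.05 / (4.05 + 34 + 20.2)
  expect_equal(reduced_relaxation(1e6, p), ginf, tolerance = 1e-10)
  tgrid <- seq(0, 40, by = 0.05)
  g <- reduced_relaxation(tgrid, p)
  expect_true(all(diff(g) < 0))
  expect_true(all(g >= ginf - 1e-12 & g <= 1 + 1e-12))
  g058 <- reduced_relaxation(0.58, p)
  expect_true(g058 < 1 && g058 > ginf)
  expect_error(reduced_relaxation(-1, p), "non-negative")
})

test_that("viscoelastic recurrence reproduces closed-form relaxation", {
  p <- prony_constants()
  # step elastic stress held constant: sigma(t)/sigma_e = g(t)
  Se <- diag(c(2, 1, -0.5))
  h <- NULL
  dt <- 0.01
  t <- 0
  while (t < 60 - 1e-9) {
    up <- viscoelastic_stress_update(h, dt, Se, p)
    h <- up$history
    t <- t + dt
  }
  expect_equal(up$stress[1, 1] / 2, reduced_relaxation(60, p),
               tolerance = 0.01)
  # by 60 s (~ 11 tau_2) both branches have decayed to the long-time modulus
  expect_equal(up$stress[1, 1] / 2, 4.05 / 58.25, tolerance = 0.01)
  # zero input stays zero
  up0 <- viscoelastic_stress_update(NULL, 1, matrix(0, 3, 3), p)
  expect_equal(up0$stress, matrix(0, 3, 3))
  # single-branch closed form on a grid
  p1 <- prony_constants(G_inf = 3, G_1 = 5, G_2 = 1e-12, tau_1 = 0.7,
                        tau_2 = 1)
  h <- NULL
  Se1 <- diag(3)
  tt <- 0
  dt <- 0.002
  for (k in 1:2500) {
    up <- viscoelastic_stress_update(h, dt, Se1, p1)
    h <- up$history
    tt <- tt + dt
    if (k %% 500 == 0) {
      expected <- (3 + 5 * exp(-tt / 0.7)) / 8
      expect_equal(up$stress[1, 1], expected, tolerance = 1e-3)
    }
  }
  expect_error(viscoelastic_stress_update(NULL, -0.1, Se, p), "positive")
})

test_that("von Mises and total stress invariants", {
  expect_equal(von_mises(diag(c(5, 5, 5))), 0)
  expect_equal(von_mises(diag(c(3, 0, 0))), 3)
  s <- matrix(0, 3, 3); s[1, 2] <- s[2, 1] <- 2
  expect_equal(von_mises(s), sqrt(3) * 2)
  expect_equal(von_mises(c(0, 0, 0, 2)), sqrt(3) * 2) # axisym 4-vector
  expect_equal(total_stress(diag(c(1, 2, 3))), 6)
  expect_equal(total_stress(s), 0)
  expect_equal(total_stress(diag(3) * -1.5), -4.5)
})

test_that("assembled tangent is consistent with the residual (FD oracle)", {
  set.seed(11)
  m <- tiny_patch()
  ndof <- 2 * nrow(m$nodes)
  u <- rnorm(ndof, sd = 0.02)
  du <- rnorm(ndof)
  eps <- 1e-6
  for (law in c("neo_hookean", "linear_elastic")) {
    mats <- list(gel = material_spec(law, E = 2, nu = 0.45))
    a0 <- assemble_system(m, mats, u)
    fd <- (assemble_system(m, mats, u + eps * du, want_K = FALSE)$residual -
             assemble_system(m, mats, u - eps * du,
                             want_K = FALSE)$residual) / (2 * eps)
    an <- as.numeric(a0$K %*% du)
    expect_lt(max(abs(fd - an)) / max(abs(fd)), 1e-5)
  }
})

test_that("axisymmetric assembly matches the 3x3 constitutive closed form", {
  # homogeneous affine state: quadrature stresses must equal the pointwise law
  m <- tiny_patch()
  mats <- list(gel = material_spec("neo_hookean", E = 1.3, nu = 0.31))
  # u_r must be proportional to r (no z-dependence) so the hoop stretch
  # 1 + u_r/r is homogeneous
  A <- matrix(c(0.05, 0.02, 0, -0.04), 2, 2)
  st <- affine_state(m, mats, A)
  F3 <- diag(3)
  F3[1, 1] <- 1 + A[1, 1]; F3[1, 2] <- A[1, 2]
  F3[2, 1] <- A[2, 1]; F3[2, 2] <- 1 + A[2, 2]
  F3[3, 3] <- 1 + A[1, 1] # hoop stretch = 1 + ur/r for linear-in-r ur
  lm <- lame_from_E_nu(1.3, 0.31)
  sref <- neo_hookean_stress(F3, lm[["lambda"]], lm[["mu"]])
  expect_equal(max(abs(st$sigma[, "rr"] - sref[1, 1])), 0, tolerance = 1e-9)
  expect_equal(max(abs(st$sigma[, "zz"] - sref[2, 2])), 0, tolerance = 1e-9)
  expect_equal(max(abs(st$sigma[, "tt"] - sref[3, 3])), 0, tolerance = 1e-9)
  expect_equal(max(abs(st$sigma[, "rz"] - sref[1, 2])), 0, tolerance = 1e-9)
})
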