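test_that("fiber invariants match direct quadratic forms", {
  # undeformed and equibiaxial special cases
  expect_equal(unname(fiber_invariants(diag(3), 0.79)), c(1, 1))
  lam <- 1.3
  C <- diag(c(lam^2, lam^2, 1 / lam^4))
  for (a in c(0, 0.4, 0.79, 1.4)) {
    I <- fiber_invariants(C, a)
    expect_equal(unname(I), c(lam^2, lam^2))
  }
  # random SPD draws against the matrix arithmetic oracle
  set.seed(11)
  for (k in 1:20) {
    A <- matrix(rnorm(9), 3)
    C <- t(A) %*% A + 0.5 * diag(3)
    a <- runif(1, 0, pi / 2)
    m4 <- c(cos(a), sin(a), 0)
    m6 <- c(cos(a), -sin(a), 0)
    I <- fiber_invariants(C, a)
    expect_equal(I[["I4"]], drop(t(m4) %*% C %*% m4))
    expect_equal(I[["I6"]], drop(t(m6) %*% C %*% m6))
  }
  expect_error(fiber_invariants(diag(c(1, 1, -1)), 0.5), "positive definite")
})

test_that("constituent strain energies follow their defining forms", {
  mat <- medial_material()
  # reference state and tension-only switch
  expect_equal(unname(constituent_strain_energy(mat, 3, 1, 1)), c(0, 0))
  expect_equal(constituent_strain_energy(mat, 3, 0.81, 1)[["psi_c"]], 0)
  # independent evaluation at I1 = 3.2, I4 = I6 = 1.21 (hand arithmetic)
  psi <- constituent_strain_energy(mat, 3.2, 1.21, 1.21)
  expect_equal(psi[["psi_e"]], (0.015 / 0.46) * (3.2 - 3), tolerance = 1e-12)
  expect_equal(psi[["psi_c"]],
               (0.12 / 0.27) / (2 * 6.9) * 2 * (exp(6.9 * 0.21^2) - 1),
               tolerance = 1e-12)
  expect_error(constituent_strain_energy(mat, 3, 200, 1), "overflow")
})

test_that("fiber Cauchy stress matches a finite-difference of the energy", {
  mat <- medial_material()
  expect_equal(fiber_cauchy_stress(1, mat), 0)
  expect_equal(fiber_cauchy_stress(0.95, mat), 0)
  # sigma = lambda dpsi_f/dlambda for an incompressible uniaxial fiber;
  # central finite difference of the single-family energy as oracle
  psi_f <- function(l) {
    I4 <- max(l^2, 1)
    (mat$k1 / mat$rho0_c) / (2 * mat$k2) * (exp(mat$k2 * (I4 - 1)^2) - 1)
  }
  h <- 1e-6
  for (lam in c(1.05, 1.1, 1.2)) {
    fd <- lam * (psi_f(lam + h) - psi_f(lam - h)) / (2 * h)
    expect_equal(fiber_cauchy_stress(lam, mat), fd, tolerance = 1e-7)
  }
  # C0 continuity at the slack limit
  expect_lt(fiber_cauchy_stress(1 + 1e-8, mat), 1e-6)
})

test_that("homeostatic stress is the 10% deposition-strain stress and is linear in k1", {
  matM <- medial_material()
  expect_equal(homeostatic_fiber_stress(matM),
               fiber_cauchy_stress(1.10, matM))
  expect_gt(homeostatic_fiber_stress(matM), 0)
  zero_k1 <- layer_material(0.015, 0, 6.9, 0.79, 1, 0)
  expect_equal(homeostatic_fiber_stress(zero_k1), 0)
  # scaling k1 alone at fixed k2 scales sigma_h by the same factor
  scaled <- layer_material(0.015, 1.17 * matM$k1, 6.9, 0.79,
                           matM$rho0_e, matM$rho0_c)
  expect_equal(homeostatic_fiber_stress(scaled) / homeostatic_fiber_stress(matM),
               1.17, tolerance = 1e-12)
})

test_that("adventitia is coupled to the media by the published area-fraction ratios", {
  m <- medial_material()
  a <- adventitial_material()
  expect_equal(a$c10, 0.34 * m$c10)
  expect_equal(a$k1, 1.17 * m$k1)
  expect_equal(a$k2, m$k2)
  # layer composition closes: elastin + two collagen families
  expect_equal(m$rho0_e + 2 * m$rho0_c, 1)
  expect_equal(a$rho0_e + 2 * a$rho0_c, 1)
})

test_that("mixture stress equals the finite-difference of the mixture energy", {
  set.seed(21)
  mats <- default_materials()
  for (k in 1:100) {
    mat <- if (k %% 2) mats$media else mats$adventitia
    # random admissible state: moderate stretch + inelastic maps
    F <- diag(3) + 0.15 * matrix(rnorm(9), 3)
    if (det(F) < 0.4) next
    a <- mat$alpha
    lam_r <- runif(1, 0.85, 1.15)
    g <- runif(1, 0.8, 1.25)
    Gc <- solve(remodeling_tensor(lam_r, c(cos(a), sin(a), 0)) %*%
                  growth_tensor(g, 1))
    Ge <- solve(growth_tensor(g, 1)) %*% diag(c(1.15, 1.1, 1 / (1.15 * 1.1)))
    cons <- list(
      list(rho = runif(1, 0.2, 0.6), type = "elastin", mat = mat, H = Ge),
      list(rho = runif(1, 0.1, 0.5), type = "collagen", mat = mat,
           H = Gc, M = c(cos(a), sin(a), 0)),
      list(rho = runif(1, 0.1, 0.5), type = "collagen", mat = mat,
           H = Gc, M = c(cos(a), -sin(a), 0))
    )
    sig <- mixture_cauchy_stress(F, cons)
    # finite-difference oracle: sigma = J^-1 (dPsi/dF) F^T
    h <- 1e-6
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fm <- F
      Fp[i, j] <- Fp[i, j] + h
      Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (mixture_energy(Fp, cons) - mixture_energy(Fm, cons)) / (2 * h)
    }
    sig_fd <- (P %*% t(F)) / det(F)
    sig_fd <- (sig_fd + t(sig_fd)) / 2
    scale <- max(abs(sig), 1e-8)
    expect_lt(max(abs(sig - sig_fd)) / scale, 1e-6)
  }
})

test_that("mixture stress degenerate cases", {
  mat <- medial_material()
  cons0 <- list(list(rho = 0, type = "elastin", mat = mat, H = diag(3)))
  sig <- mixture_cauchy_stress(diag(3), cons0, p = 0.3)
  expect_equal(sig, -0.3 * diag(3))
  expect_error(
    mixture_cauchy_stress(diag(3),
                          list(list(rho = -1, type = "elastin", mat = mat,
                                    H = diag(3)))),
    "negative density")
  # single family along theta at stretch 1.1 reproduces the scalar fiber law
  lam <- 1.1
  F <- diag(c(lam, 1, 1 / lam))
  cons <- list(list(rho = 1, type = "collagen", mat = mat, H = diag(3),
                    M = c(1, 0, 0)))
  sig <- mixture_cauchy_stress(F, cons)
  expect_equal(sig[1, 1], fiber_cauchy_stress(lam, mat), tolerance = 1e-12)
})

test_that("fiber stress inversion is exact on the tensile branch", {
  mat <- medial_material()
  for (lam in c(1.0001, 1.02, 1.1, 1.3, 1.49)) {
    s <- fiber_cauchy_stress(lam, mat)
    expect_equal(fiber_stress_inverse(s, mat), lam, tolerance = 1e-9)
  }
  expect_equal(fiber_stress_inverse(0, mat), 1)
  # very large targets stay finite and bracketed
  lam_big <- fiber_stress_inverse(1e5, mat)
  expect_true(is.finite(lam_big) && lam_big > 1)
  expect_equal(fiber_cauchy_stress(lam_big, mat), 1e5, tolerance = 1e-6)
})
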