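test_that("turnover rates follow the published kinetic laws", {
  params <- growth_parameters(0.42, 5, 4, 0.0707, 0.198, 1.24)
  sh <- 0.3
  # at homeostatic stress without inflammation: production = rho/T
  expect_equal(collagen_production_rate(0.27, sh, sh, 0, params), 0.27 / 101)
  # released membrane, sigma = 0, k_sigma = 0.42
  expect_equal(collagen_production_rate(0.27, 0, sh, 0, params),
               0.27 / 101 * (1 - 0.42))
  # inflammation symmetry: equal gains at homeostatic stress cancel
  p_eq <- growth_parameters(0.42, 7, 7, 0, 0.198, 1.24)
  expect_equal(collagen_production_rate(0.27, sh, sh, 1, p_eq),
               -collagen_degradation_rate(0.27, 1, p_eq))
  # degradation: direct substitution and trivial cases
  expect_equal(collagen_degradation_rate(0.27, 0, params), -0.27 / 101)
  expect_equal(collagen_degradation_rate(0, 0.5, params), 0)
  p_deg <- growth_parameters(0, 0, 20.7, 0, 0.198, 1.24)
  expect_equal(collagen_degradation_rate(0.27, 0.5, p_deg),
               -0.27 / 101 * (1 + 20.7 * 0.5))
  # elastin: degrades only under inflammation, with the 1/3 per-step factor
  expect_equal(elastin_degradation_rate(0.46, 0, params), 0)
  expect_equal(elastin_degradation_rate(0.46, 1, params),
               -(1 / 3) * 0.46 * 0.0707)
  p0 <- growth_parameters(0.1, 5, 4, 0, 0.198, 1.24)
  expect_equal(elastin_degradation_rate(0.46, 1, p0), 0)
  # production floor: the bracket cannot push production negative
  p_floor <- growth_parameters(0.42, 0, 0, 0, 0.198, 1.24)
  expect_gte(collagen_production_rate(0.27, -10 * sh, sh, 0, p_floor), 0)
})

test_that("net collagen rate vanishes iff stress deviation balances the gain difference", {
  set.seed(31)
  for (k in 1:50) {
    params <- growth_parameters(runif(1, 0.01, 0.42), runif(1, 1.74, 24.9),
                                runif(1, 1.41, 20.7), 0, 0.198, 1.24)
    G <- runif(1)
    sh <- runif(1, 0.1, 0.5)
    rho <- runif(1, 0.05, 0.6)
    # algebra of the two laws: net = 0 when k_sigma * dev = (k_G- - k_G+) G
    dev <- (params$k_gminus_c - params$k_gplus_c) * G / params$k_sigma
    sigma <- sh * (1 + dev)
    net <- collagen_production_rate(rho, sigma, sh, G, params) +
      collagen_degradation_rate(rho, G, params)
    if (sigma >= 0) {
      expect_equal(net, 0, tolerance = 1e-12)
    }
    # and is nonzero off the balance point
    net2 <- collagen_production_rate(rho, sigma + 0.1 * sh, sh, G, params) +
      collagen_degradation_rate(rho, G, params)
    expect_gt(net2, 0)
  }
})

test_that("growth tensor acts radially with det equal to the density ratio", {
  expect_equal(growth_tensor(1, 1), diag(3))
  expect_equal(growth_tensor(1.2, 1), diag(c(1, 1, 1.2)))
  set.seed(41)
  for (r in runif(50, 0.3, 3)) {
    Fg <- growth_tensor(r, 1)
    expect_equal(det(Fg), r, tolerance = 1e-12)
    expect_equal(Fg[1:2, 1:2], diag(2))
  }
  expect_error(growth_tensor(0, 1), "ratio")
  expect_error(growth_tensor(1, 0), "initial density")
})

test_that("remodeling tensor is volume-preserving with the rank-one structure", {
  expect_equal(remodeling_tensor(1, c(1, 0, 0)), diag(3))
  Fr <- remodeling_tensor(1.21, c(1, 0, 0))
  expect_equal(Fr, diag(c(1.21, 1 / 1.1, 1 / 1.1)))
  set.seed(42)
  for (lr in runif(50, 0.5, 2)) {
    a <- runif(1, 0, pi / 2)
    Fr <- remodeling_tensor(lr, c(cos(a), sin(a), 0))
    expect_equal(det(Fr), 1, tolerance = 1e-12)
  }
  expect_error(remodeling_tensor(0, c(1, 0, 0)), "lambda_r")
})

test_that("remodeling is stationary at homeostatic stress and shortens slack fibers", {
  mat <- medial_material()
  # fiber exactly at the deposition stretch: no remodeling
  up <- update_remodeling_stretch(1, 1, mat, turnover_rate = 2 / 101, dt = 1)
  expect_equal(up$lam_r, 1, tolerance = 1e-9)
  expect_equal(up$sigma_f, homeostatic_fiber_stress(mat), tolerance = 1e-9)
  # released membrane (slack fiber): lam_r decreases, stress rises toward
  # homeostatic
  up2 <- update_remodeling_stretch(1, 0.9, mat, turnover_rate = 2 / 101, dt = 1)
  expect_lt(up2$lam_r, 1)
  expect_gt(up2$sigma_f, 0)
  expect_lt(up2$sigma_f, homeostatic_fiber_stress(mat))
  # overstressed fiber: lam_r grows, stress relaxes downward
  up3 <- update_remodeling_stretch(1, 1.1, mat, turnover_rate = 2 / 101, dt = 1)
  expect_gt(up3$lam_r, 1)
  expect_lt(up3$sigma_f, fiber_cauchy_stress(1.1 * 1.1, mat))
  expect_gt(up3$sigma_f, homeostatic_fiber_stress(mat))
})

test_that("material-point kinetics agree with a 1000x-refined integration", {
  mat <- medial_material()
  params <- example_params()
  pat <- inflammation_pattern("transient", "local")
  burden <- function(a, b) gamma_burden_average(pat, a, b, params$delta,
                                                params$beta)
  pt0 <- list(rho_e = 0.46, rho_c = 0.27, lam_r = 1)
  for (lfa in c(0.9, 1.05)) {
    coarse <- integrate_gr_point(pt0, mat, params, burden, days = 90,
                                 substeps_per_day = 1, lam_fib_add = lfa)
    fine <- integrate_gr_point(pt0, mat, params, burden, days = 90,
                               substeps_per_day = 1000, lam_fib_add = lfa)
    tc <- attr(coarse, "trajectory")
    tf <- attr(fine, "trajectory")
    at <- match(tc$time, round(tf$time, 9))
    expect_lt(max(abs(tc$lam_r - tf$lam_r[at])), 1e-4)
  }
})

test_that("forward-Euler density integration converges at first order", {
  mat <- medial_material()
  params <- example_params()
  pat <- inflammation_pattern("transient", "local")
  burden <- function(a, b) gamma_burden_average(pat, a, b, params$delta,
                                                params$beta)
  pt0 <- list(rho_e = 0.46, rho_c = 0.27, lam_r = 1)
  rho_at <- function(spd) {
    integrate_gr_point(pt0, mat, params, burden, days = 30,
                       substeps_per_day = spd, lam_fib_add = 0.9)$rho_c
  }
  ref <- rho_at(100)   # 100x-refined oracle
  e1 <- abs(rho_at(1) - ref)
  e2 <- abs(rho_at(2) - ref)
  e4 <- abs(rho_at(4) - ref)
  expect_gt(e1 / e2, 1.7); expect_lt(e1 / e2, 2.4)
  expect_gt(e2 / e4, 1.7); expect_lt(e2 / e4, 2.4)
})

test_that("stress-only kinetics keep densities exactly constant at homeostasis", {
  # k_sigma arbitrary, Gamma = 0 everywhere, sigma = sigma_h: production and
  # degradation cancel identically
  mat <- medial_material()
  params <- stress_only_params(0.3)
  burden0 <- function(a, b) 0
  out <- integrate_gr_point(list(rho_e = 0.46, rho_c = 0.27, lam_r = 1),
                            mat, params, burden0, days = 90,
                            substeps_per_day = 1, lam_fib_add = 1)
  expect_equal(out$rho_c, 0.27, tolerance = 1e-12)
  expect_equal(out$rho_e, 0.46, tolerance = 1e-12)
  expect_equal(out$lam_r, 1, tolerance = 1e-9)
})

test_that("growth parameters validate their domain", {
  expect_error(growth_parameters(-0.1, 1, 1, 0, 0.1), "finite and >= 0")
  expect_error(growth_parameters(0.1, 1, 1, 0, 0), "delta and T_c")
  expect_error(growth_parameters(0.1, 1, 1, 0, 0.1, beta = 1), "beta")
})
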