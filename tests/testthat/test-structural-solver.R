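test_that("schedule validates report days against the step grid", {
  s <- schedule_spec()
  expect_equal(s$n_steps, 30L)
  expect_equal(s$report_days, c(0, 15, 42, 90))
  expect_error(schedule_spec(report_days = c(0, 14)), "step grid")
  expect_error(schedule_spec(n_steps = 0), "n_steps")
})

test_that("every equilibrium solve closes the force balance to 1e-8", {
  d <- dissected_state()
  for (sec in c("dissected", "intact")) {
    prof <- wall_stress_profile(d, sec)
    P_ri <- attr(prof, "P_ri")
    expect_lt(abs(attr(prof, "int_hoop") - P_ri) / P_ri, 1e-8)
  }
  # and after growth steps with strong turnover
  st <- d
  params <- example_params()
  pat <- inflammation_pattern("transient", "local")
  for (k in 1:5) st <- step_gr(st, params, pat, step_index = k)
  expect_true(st$status$ok)
  for (sec in c("dissected", "intact")) {
    prof <- wall_stress_profile(st, sec)
    P_ri <- attr(prof, "P_ri")
    expect_lt(abs(attr(prof, "int_hoop") - P_ri) / P_ri, 1e-8)
  }
})

test_that("thin-walled isotropic limit recovers the Laplace hoop stress", {
  mat <- elastin_only_material(c10 = 0.1)
  gs <- geometry_spec(inner_diameter = 200, wall_thickness = 1,
                      media_fraction = 0.5, membrane_depth_fraction = 0.5,
                      false_lumen_angle = 245, axial_length = 1)
  dep <- deposition_spec(1, 1, 5e-4, 1)
  h <- solve_healthy_invivo_state(build_reference_geometry(gs),
                                  list(media = mat,
                                       adventitia = elastin_only_material(0.1, "adventitia")),
                                  dep)
  prof <- wall_stress_profile(h, "wall")
  laplace <- 5e-4 * 100 / 1   # P r / t
  expect_lt(abs(mean(prof$sigma_tt) - laplace) / laplace, 0.02)
})

test_that("membrane thickness tracks growth and recoil kinematics", {
  d <- dissected_state()
  t_ref <- diff(d$membrane$region$ref_r)
  expect_equal(d$membrane$thickness,
               t_ref * d$membrane$region$g / d$membrane$lam_theta)
  # pure growth: scaling all densities by 1.1 at fixed elastic state scales
  # the thickness by 1.1 through the growth factor
  st <- d
  st$membrane$region$rho_e <- 1.1 * st$membrane$region$rho_e
  st$membrane$region$rho_c <- 1.1 * st$membrane$region$rho_c
  st$membrane$region$g <- with(st$membrane$region,
                               (rho_e + 2 * rho_c) / rho_tot0)
  st <- equilibrate_membrane(st)
  expect_true(st$status$ok)
  # recoil changes only marginally; growth factor accounts for the volume
  expect_equal(st$membrane$region$g, 1.1, tolerance = 1e-12)
  expect_equal(st$membrane$thickness,
               t_ref * 1.1 / st$membrane$lam_theta)
})

test_that("lumen diameter identity holds at every snapshot", {
  res <- example_result()
  expect_true(res$converged)
  for (day in names(res$snapshots)) {
    dm <- diameters(res$snapshots[[day]])
    expect_equal(dm[["D_TL"]] + dm[["D_FL"]], dm[["D_tot"]])
  }
  # mass-thickness consistency: membrane thickness ratio = growth factor
  # (volume) / circumferential stretch at every snapshot
  t0 <- diff(res$snapshots[["0"]]$membrane$region$ref_r)
  for (day in names(res$snapshots)) {
    m <- res$snapshots[[day]]$membrane
    expect_equal(m$thickness / t0, m$region$g / m$lam_theta,
                 tolerance = 1e-12)
  }
})

test_that("simulations are deterministic and failures are recorded, not raised", {
  params <- example_params()
  pat <- inflammation_pattern("transient", "local")
  r1 <- run_simulation(params, pat)
  r2 <- run_simulation(params, pat)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(outcome_record(r1), outcome_record(r2))
  # a strongly unbalanced permanent sample fails by the growth-factor bound
  bad <- growth_parameters(0.1, 24.9, 1.41, 0.02, 5)
  res <- expect_no_error(run_simulation(bad, inflammation_pattern("permanent", "full")))
  expect_false(res$converged)
  expect_match(res$status$reason, "growth_factor_bounds|fiber_stretch|equilibrium_solve|density_floor")
  expect_true(res$n_steps_completed < 30)
  oc <- outcome_record(res)
  expect_false(oc$in_clinical_range)
  expect_true(is.na(oc$R_T_chronic_mm_per_year))
})

test_that("healthy simulation without dissection stays at day-0 within 0.1%", {
  params <- stress_only_params()
  res <- run_simulation(params, inflammation_pattern("transient", "full"),
                        dissected = FALSE)
  expect_true(res$converged)
  ts <- res$timeseries
  expect_lt(max(abs(ts$D_tot_mm / ts$D_tot_mm[1] - 1)), 1e-3)
  expect_lt(max(abs(ts$wall_sigma_f_MPa / ts$wall_sigma_f_MPa[1] - 1)), 1e-3)
})

test_that("net inflammatory production thickens the membrane by day 90", {
  params <- growth_parameters(0.130, 8, 2, 0.02, 0.198, 1.24)  # k_G+ >> k_G-
  res <- run_simulation(params, inflammation_pattern("transient", "full"))
  expect_true(res$converged)
  oc <- outcome_record(res)
  expect_gt(oc$T_DM_day90_mm, oc$T_DM_day0_mm)
  expect_gt(oc$membrane_volume_ratio_day90, 1)
})
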