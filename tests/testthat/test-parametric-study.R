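test_that("Latin hypercube stratification is exact in every marginal", {
  # n = 2: one sample per half-range
  s2 <- latin_hypercube(2, "transient", seed = 3,
                        ranges = list(x = c(0, 1)))
  expect_equal(sum(s2$x < 0.5), 1L)
  # n = 1000, 6 dims: exactly one sample per width-0.001 stratum
  s <- latin_hypercube(1000, "transient", seed = 17)
  rng <- attr(s, "ranges")
  expect_equal(nrow(s), 1000L)
  for (nm in names(rng)) {
    u <- (s[[nm]] - rng[[nm]][1]) / (rng[[nm]][2] - rng[[nm]][1])
    expect_true(all(u >= 0 & u <= 1))
    stratum <- floor(u * 1000)
    expect_equal(sort(stratum), 0:999)
  }
})

test_that("permanent table has 5 dimensions with the permanent delta range", {
  s <- latin_hypercube(50, "permanent", seed = 5)
  expect_false("beta" %in% names(s))
  expect_setequal(setdiff(names(s), "sample"),
                  c("k_sigma", "k_gplus_c", "k_gminus_c", "k_gminus_e",
                    "delta"))
  expect_true(all(s$delta >= 2.77 & s$delta <= 17.0))
  st <- latin_hypercube(50, "transient", seed = 5)
  expect_true(all(st$delta >= 0.0151 & st$delta <= 0.478))
  expect_true(all(st$beta >= 1.10 & st$beta <= 4.64))
})

test_that("sampling is reproducible under a fixed seed and validates ranges", {
  a <- latin_hypercube(20, "transient", seed = 99)
  b <- latin_hypercube(20, "transient", seed = 99)
  expect_identical(a, b)
  c <- latin_hypercube(20, "transient", seed = 100)
  expect_false(identical(a, c))
  expect_error(latin_hypercube(10, "transient",
                               ranges = list(x = c(1, 1))), "min < max")
  expect_error(latin_hypercube(0, "transient"), "n must be")
})

test_that("parameter-space reduction is the product of relative widths", {
  rng <- list(a = c(0, 1), b = c(0, 10))
  # full-range subset: widths at the sampled extremes, <= 1
  sub <- data.frame(a = c(0, 1), b = c(0, 10))
  red <- parameter_space_reduction(sub, rng)
  expect_equal(unname(red$relative_widths), c(1, 1))
  expect_equal(red$product, 1)
  # single sample: all widths zero
  red1 <- parameter_space_reduction(data.frame(a = 0.3, b = 2), rng)
  expect_equal(red1$product, 0)
  # two samples at the extremes of one parameter, identical elsewhere
  red2 <- parameter_space_reduction(data.frame(a = c(0, 1), b = c(5, 5)), rng)
  expect_equal(unname(red2$relative_widths), c(1, 0))
  # empty subset is reported as undefined
  red0 <- parameter_space_reduction(data.frame(a = numeric(), b = numeric()),
                                    rng)
  expect_true(is.na(red0$product))
  expect_equal(red0$n, 0L)
})

test_that("study aggregation: success rate definition and subset reductions", {
  samples <- latin_hypercube(12, "transient", seed = 23)
  st <- run_study(samples, "local")
  expect_equal(st$success_rate, st$n_converged / nrow(samples))
  expect_true(st$n_clinical <= st$n_converged)
  # clinical subset is nested in the converged subset: per-parameter widths
  # cannot exceed the converged ones
  if (st$n_clinical > 0) {
    expect_true(all(st$reduction_clinical$relative_widths <=
                      st$reduction_converged$relative_widths + 1e-12))
    expect_lte(st$reduction_clinical$product,
               st$reduction_converged$product + 1e-12)
  }
  # sample order permutation leaves the aggregates unchanged
  perm <- samples[rev(seq_len(nrow(samples))), ]
  attr(perm, "seed") <- attr(samples, "seed")
  attr(perm, "duration") <- attr(samples, "duration")
  attr(perm, "ranges") <- attr(samples, "ranges")
  st2 <- run_study(perm, "local")
  expect_equal(st2$success_rate, st$success_rate)
  expect_equal(st2$reduction_converged$product,
               st$reduction_converged$product)
  expect_setequal(st2$outcomes$sample[st2$outcomes$converged],
                  st$outcomes$sample[st$outcomes$converged])
})

test_that("healthy-wall degenerate study: every sample converges", {
  # inflammation disabled through zero gains: homeostatic wall for any
  # k_sigma, so all samples must converge
  samples <- latin_hypercube(4, "transient", seed = 31)
  samples$k_gplus_c <- 0
  samples$k_gminus_c <- 0
  samples$k_gminus_e <- 0
  for (i in seq_len(nrow(samples))) {
    params <- growth_parameters(samples$k_sigma[i], 0, 0, 0,
                                samples$delta[i], samples$beta[i])
    res <- run_simulation(params, inflammation_pattern("transient", "full"),
                          dissected = FALSE)
    expect_true(res$converged)
  }
})
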