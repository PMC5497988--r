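test_that("parameter validation enforces the model invariants", {
  expect_s3_class(t2_params(), "cml_params")
  expect_error(t2_params(theta_s2 = -5), "strictly positive")
  expect_error(cml_params("A", alpha = c(1, 1), delta = c(1, 1),
    a = c(1, 1), d = c(1, 1), theta_s = c(1, 1), theta_d = 1,
    omega = matrix(c(-1, 0, 0, 1), 2, 2)), "diagonal")
  expect_error(cml_params("A", alpha = c(1, 1, 1), delta = c(1, 1, 1),
    a = rep(1, 3), d = rep(1, 3), theta_s = rep(1, 3), theta_d = 1,
    omega = diag(3), nu2 = 0.6, nu3 = 0.5), "nu2")
  expect_error(t2_params(model_kind = "B"), "nu_q1")
  expect_error(t2_params(model_kind = "C", nu_q1 = 0.1), "nu_c1")
  expect_error(t2_params(model_kind = "C", nu_q1 = 0.1, nu_c1 = 1),
               "theta_q1")
  # model C with deactivation off needs no threshold
  expect_s3_class(t2_params(model_kind = "C", nu_q1 = 0.1, nu_c1 = 0),
                  "cml_params")
  expect_error(cml_state(c(1, 2), c(1, -2)), "non-negative")
})

test_that("stem growth factor matches its closed form and boundaries", {
  p <- t2_params()
  # empty niche: identity
  expect_identical(stem_growth_factor(1, c(0, 0, 0), p), 1)
  # direct evaluation at the test-simulation state
  expect_equal(stem_growth_factor(1, c(100, 5, 1), p), exp(-1.06),
               tolerance = 1e-12)
  expect_equal(stem_growth_factor(2, c(100, 5, 1), p), exp(-0.56),
               tolerance = 1e-12)
  expect_equal(exp(-1.06), 0.34646, tolerance = 1e-4)
  expect_equal(exp(-0.56), 0.57121, tolerance = 1e-4)
  # negative weights enhance growth: factor above 1
  pn <- p; pn$omega[1, 2] <- -2
  expect_gt(stem_growth_factor(1, c(0, 10, 0), pn), 1)
  expect_error(stem_growth_factor(4, c(1, 1, 1), p), "out of range")
  expect_error(stem_growth_factor(1, c(1, 1), p), "length")
})

test_that("differentiation growth factor handles shared and per-clone thresholds", {
  p <- t2_params()
  expect_identical(diff_growth_factor(NULL, c(0, 0, 0), p), 1)
  # e-folding threshold by definition
  expect_equal(diff_growth_factor(NULL, c(5e9, 4e9, 1e9), p), exp(-1),
               tolerance = 1e-12)
  expect_equal(diff_growth_factor(NULL, c(7e7, 0, 0), p), exp(-0.007),
               tolerance = 1e-12)
  pc <- p; pc$theta_d <- c(1e10, 5e9, 1e10)
  expect_equal(diff_growth_factor(2, c(5e9, 0, 0), pc), exp(-1),
               tolerance = 1e-12)
  expect_error(diff_growth_factor(NULL, c(1, 1, 1), pc), "clone index")
  expect_error(diff_growth_factor(1, c(1, 1), p), "length")
})

test_that("quiescence switch implements step and sigmoid variants", {
  pC <- t2_params(model_kind = "C", nu_q1 = 0.01, nu_c1 = 1,
                  theta_q1 = 1.5e7)
  expect_identical(quiescence_switch(0.5 * 1.5e7, pC), 0)
  expect_identical(quiescence_switch(2 * 1.5e7, pC), 1)
  # step is off exactly at the threshold
  expect_identical(quiescence_switch(1.5e7, pC), 0)
  pS <- t2_params(model_kind = "C", nu_q1 = 0.01, nu_c1 = 1,
                  theta_q1 = 1.5e7, switch_kind = "sigmoid")
  expect_equal(quiescence_switch(1.5e7, pS), 0.5, tolerance = 1e-12)
  expect_equal(quiescence_switch(2 * 1.5e7, pS), 1, tolerance = 1e-12)
  expect_error(quiescence_switch(1, t2_params()), "model C")
})

test_that("mutation influx originates from clone 1 only", {
  p <- t2_params()
  expect_identical(mutation_influx(2, c(100, 5, 1), p), 0)
  expect_identical(mutation_influx(3, c(100, 5, 1), p), 0)
  pm <- p; pm$nu3 <- 3e-10
  expect_equal(mutation_influx(3, c(100, 5, 1), pm),
               3e-10 * exp(-1.06) * 100, tolerance = 1e-12)
  expect_gt(mutation_influx(3, c(100, 5, 1), pm), 0)
  expect_identical(mutation_influx(3, c(0, 5, 1), pm), 0)
  expect_error(mutation_influx(1, c(1, 1, 1), p), "clones 2 and 3")
})

test_that("right-hand side reproduces known fixed points and decay laws", {
  # single-clone fixed point: zeta * alpha = delta at xs = theta ln(alpha/delta)
  p1 <- cml_params("A", alpha = c(1.25, 1), delta = c(1, 1),
    a = c(1e6, 1e6), d = c(1, 1), theta_s = c(100, 100), theta_d = 1e10,
    omega = diag(2))
  xs_star <- 100 * log(1.25)
  d <- cml_rhs(0, cml_state(c(xs_star, 0), c(0, 0)), p1)[[1]]
  expect_equal(d[1], 0, tolerance = 1e-12)
  # model B: pure linear decay of the quiescent pool
  pB <- t2_params(model_kind = "B", nu_q1 = 0.01)
  dB <- cml_rhs(0, t2_state(xq1 = 100), pB)[[1]]
  expect_equal(dB[7], -1, tolerance = 1e-12)
  expect_error(cml_rhs(0, t2_state(), pB), "length")
})

test_that("clone-1 transfer terms cancel in model C pool accounting", {
  pC <- t2_params(model_kind = "C", nu_q1 = 0.01, nu_c1 = 0.5,
                  theta_q1 = 1.5e7)
  pB <- t2_params(model_kind = "B", nu_q1 = 0.01)
  set.seed(11)
  for (k in 1:20) {
    st <- rand_state(pC)
    dC <- cml_rhs(0, st, pC)[[1]]
    dB <- cml_rhs(0, st, pB)[[1]]
    # d(xs1 + xq1)/dt identical with and without the transfer terms
    expect_equal(dC[1] + dC[7], dB[1] + dB[7], tolerance = 1e-12)
  }
})

test_that("model C with nu_c1 = 0 equals model B; model B with xq1 = 0 equals model A", {
  pA <- t2_params()
  pB <- t2_params(model_kind = "B", nu_q1 = 0.01)
  pC0 <- t2_params(model_kind = "C", nu_q1 = 0.01, nu_c1 = 0)
  set.seed(21)
  for (k in 1:20) {
    st <- rand_state(pB)
    expect_identical(cml_rhs(0, st, pC0)[[1]], cml_rhs(0, st, pB)[[1]])
    st0 <- st; st0["xq1"] <- 0
    dB <- cml_rhs(0, st0, pB)[[1]]
    dA <- cml_rhs(0, st0[1:6], pA)[[1]]
    expect_identical(dB[1:6], dA)
    expect_identical(dB[7], 0)
  }
})

test_that("derivatives at zero populations are non-negative (influx only)", {
  pm <- t2_params(model_kind = "C", nu_q1 = 0.05, nu_c1 = 0.5,
                  theta_q1 = 1.5e7)
  pm$nu2 <- 1e-9; pm$nu3 <- 3e-10
  set.seed(31)
  for (k in 1:20) {
    st <- rand_state(pm)
    for (i in seq_along(st)) {
      st_i <- st; st_i[i] <- 0
      expect_gte(cml_rhs(0, st_i, pm)[[1]][i], 0)
    }
  }
})

test_that("growth factors are positive, bounded by 1 and monotone for positive weights", {
  p <- t2_params()
  set.seed(41)
  for (k in 1:20) {
    xs <- runif(3, 0, 500); xd <- runif(3, 0, 5e10)
    z <- vapply(1:3, function(i) stem_growth_factor(i, xs, p), numeric(1))
    expect_true(all(z > 0 & z <= 1))
    expect_true(diff_growth_factor(NULL, xd, p) > 0)
    expect_lte(diff_growth_factor(NULL, xd, p), 1)
    # monotone non-increasing in every component
    bump <- xs + c(10, 0, 0)
    expect_lte(stem_growth_factor(1, bump, p), z[1])
  }
})
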