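test_that("allometric individual parameters follow the covariate model", {
  pop <- published_model()
  # typical 70-kg individual reproduces the published typical values
  p <- individual_parameters(pop, 70)
  expect_equal(p$cl, 14.7)
  expect_equal(p$v1, 26.0)
  expect_equal(p$q, 2.25)
  expect_equal(p$v2, 9.93)
  # exponential random effect on clearance doubles it, leaves the rest
  p2 <- individual_parameters(pop, 70, c(cl = log(2), v1 = 0, q = 0))
  expect_equal(p2$cl, 29.4)
  expect_equal(p2$v1, 26.0)
  # half the reference weight: Cl scales with 0.5^0.75, volumes with 0.5,
  # Q is not weight-scaled in the final model
  p3 <- individual_parameters(pop, 35)
  expect_equal(p3$cl, 14.7 * 0.5^0.75, tolerance = 1e-12)
  expect_equal(p3$cl, 8.740672, tolerance = 1e-6)
  expect_equal(p3$v1, 13.0)
  expect_equal(p3$v2, 4.965)
  expect_equal(p3$q, 2.25)
  expect_error(individual_parameters(pop, -1), "bodyweight")
  expect_error(individual_parameters(pop, 0), "bodyweight")
})

test_that("micro constants and disposition exponents satisfy Vieta", {
  mc <- micro_constants(typical_params())
  expect_equal(mc$k10, 0.5653846154, tolerance = 1e-9)
  expect_equal(mc$k12, 0.0865384615, tolerance = 1e-9)
  expect_equal(mc$k21, 0.2265861027, tolerance = 1e-9)
  expect_equal(mc$alpha, 0.6938843174, tolerance = 1e-9)
  expect_equal(mc$beta, 0.1846248623, tolerance = 1e-9)
  # one-compartment degenerate limit
  mc0 <- micro_constants(pk_parameters(14.7, 26, 0, 9.93))
  expect_equal(mc0$k12, 0)
  expect_equal(mc0$k21, 0)
  expect_equal(mc0$alpha, mc0$k10)
  expect_equal(mc0$beta, 0)
  # Vieta identities across a random parameter sweep
  set.seed(42)
  for (i in 1:25) {
    p <- pk_parameters(runif(1, 1, 30), runif(1, 5, 60), runif(1, 0.1, 10),
                       runif(1, 2, 40))
    m <- micro_constants(p)
    expect_equal(m$alpha * m$beta, m$k10 * m$k21, tolerance = 1e-12)
    expect_equal(m$alpha + m$beta, m$k10 + m$k12 + m$k21, tolerance = 1e-12)
    expect_true(m$alpha >= m$beta && m$beta > 0)
  }
})

test_that("infusion concentration: start, continuity, one-compartment limit", {
  p <- typical_params()
  expect_equal(concentration(p, ref_dose(), 2, 0), 0)
  expect_error(concentration(p, ref_dose(), 2, -0.1), "negative time")
  # one-compartment closed form at end of a 1-h infusion
  p1 <- pk_parameters(14.7, 26.0, 0, 9.93)
  expect_equal(concentration(p1, 22200, 1, 1), 652.194335, tolerance = 1e-6)
  # continuity at end of infusion
  eps <- 1e-9
  expect_equal(concentration(p, ref_dose(), 2, 2 - eps),
               concentration(p, ref_dose(), 2, 2 + eps), tolerance = 1e-6)
  # monotone decay after end of infusion
  tt <- seq(2, 24, by = 0.25)
  cc <- concentration(p, ref_dose(), 2, tt)
  expect_true(all(diff(cc) < 0))
  # dose linearity (superposition)
  expect_equal(concentration(p, 2 * ref_dose(), 2, c(1, 3, 7)),
               2 * concentration(p, ref_dose(), 2, c(1, 3, 7)),
               tolerance = 1e-12)
})

test_that("analytic concentration matches an ODE integrator oracle", {
  skip_if_not_installed("deSolve")
  ode_conc <- function(p, dose, t_inf, times) {
    mc <- micro_constants(p)
    rhs <- function(t, y, parms) {
      inp <- if (t <= t_inf) dose / t_inf else 0
      list(c(inp - (mc$k10 + mc$k12) * y[1] + mc$k21 * y[2],
             mc$k12 * y[1] - mc$k21 * y[2]))
    }
    out <- deSolve::lsoda(c(0, 0), c(0, times), rhs, NULL,
                          rtol = 1e-10, atol = 1e-10)
    out[-1, 2] / p$v1
  }
  set.seed(7)
  for (i in 1:12) {
    p <- pk_parameters(runif(1, 2, 25), runif(1, 5, 50), runif(1, 0.2, 8),
                       runif(1, 2, 30))
    t_inf <- sample(c(1, 2), 1)
    tt <- sort(runif(8, 0.1, 14))
    a <- concentration(p, 20000, t_inf, tt)
    b <- ode_conc(p, 20000, t_inf, tt)
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("AUC from clearance equals dose/Cl and the quadrature integral", {
  expect_equal(auc_from_clearance(0, 14.7), 0)
  expect_equal(auc_from_clearance(22200, 14.7), 1510.204082,
               tolerance = 1e-8)
  expect_error(auc_from_clearance(100, 0), "clearance")
  expect_error(auc_from_clearance(100, -2), "clearance")
  set.seed(11)
  for (i in 1:5) {
    p <- pk_parameters(runif(1, 3, 25), runif(1, 8, 50), runif(1, 0.3, 6),
                       runif(1, 3, 30))
    q <- stats::integrate(function(t) concentration(p, 20000, 2, t), 0, Inf,
                          rel.tol = 1e-9, subdivisions = 400)
    expect_equal(q$value, auc_from_clearance(20000, p$cl), tolerance = 1e-4)
  }
})

test_that("residual error model is proportional with the published SD", {
  pop <- published_model()
  expect_equal(as.numeric(apply_residual_error(c(100, 50), pop,
                                               eps1 = c(0, 0))), c(100, 50))
  expect_equal(as.numeric(apply_residual_error(100, pop, eps1 = 0.188)),
               118.8)
  # Monte-Carlo check of the variance: SD of observations at c_pred = 100
  set.seed(99)
  obs <- apply_residual_error(rep(100, 1e5), pop)
  expect_equal(sd(obs), 18.8, tolerance = 0.3 / 18.8)
  # truncation flags negatives
  low <- apply_residual_error(10, pop, eps1 = -1.5)
  expect_equal(as.numeric(low), 0)
  expect_equal(attr(low, "n_truncated"), 1L)
})

test_that("random effects reproduce the configured IIV covariance", {
  pop <- published_model()
  z <- sample_random_effects(population_model(typical_params(),
                                              omega = c(cl = 0, v1 = 0,
                                                        q = 0),
                                              corr_cl_v1 = 0),
                             10, seed = 1)
  expect_true(all(z == 0))
  eta <- sample_random_effects(pop, 1e5, seed = 2)
  expect_equal(sd(eta[, "cl"]), 0.255, tolerance = 0.005 / 0.255)
  expect_equal(sd(eta[, "v1"]), 0.514, tolerance = 0.01 / 0.514)
  expect_equal(cor(eta[, "cl"], eta[, "v1"]), 0.714, tolerance = 0.02 / 0.714)
  expect_equal(cor(eta[, "cl"], eta[, "q"]), 0, tolerance = 0.02)
  # reproducibility
  expect_identical(sample_random_effects(pop, 10, seed = 5),
                   sample_random_effects(pop, 10, seed = 5))
})

test_that("invalid model configurations are rejected", {
  th <- typical_params()
  expect_error(population_model(th, corr_cl_v1 = 1.2), "corr")
  expect_error(population_model(th, omega = c(cl = -0.1, v1 = 0.5,
                                              q = 0.4)), "omega")
  expect_error(pk_parameters(-1, 26, 2.25, 9.93))
  expect_error(pk_parameters(14.7, 26, 2.25, 0))
})
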