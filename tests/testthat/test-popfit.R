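test_that("marginal likelihood reduces to the closed Gaussian form without IIV", {
  pop0 <- population_model(typical_params(),
                           omega = c(cl = 0, v1 = 0, q = 0),
                           corr_cl_v1 = 0, prop_error_b = 0.188)
  ds <- simulate_group(pop0, 12, 2, n = 4, seed = 13)
  m2 <- marginal_minus2ll(pop0, ds, method = "laplace")
  # oracle: sum of Gaussian log densities at the typical predictions
  rec <- ds$records
  ll <- 0
  for (i in ds$subjects$id) {
    s <- ds$subjects[ds$subjects$id == i, ]
    r <- rec[rec$id == i, ]
    f <- concentration(individual_parameters(pop0, s$bodyweight),
                       s$total_dose, s$t_inf, r$time)
    ll <- ll + sum(stats::dnorm(r$conc, f, 0.188 * f, log = TRUE))
  }
  expect_equal(m2, -2 * ll, tolerance = 1e-8)
})

test_that("Laplace and importance sampling match 1-D adaptive quadrature", {
  # IIV on clearance only: the marginal integral is one-dimensional
  pop1 <- population_model(typical_params(),
                           omega = c(cl = 0.3, v1 = 0, q = 0),
                           corr_cl_v1 = 0, prop_error_b = 0.188)
  ds <- simulate_group(pop1, 12, 2, n = 1, times = c(2, 6), seed = 3)
  s <- ds$subjects[1, ]
  r <- ds$records
  lik <- function(eta) {
    vapply(eta, function(e) {
      p <- individual_parameters(pop1, s$bodyweight, c(cl = e, v1 = 0,
                                                       q = 0))
      f <- concentration(p, s$total_dose, s$t_inf, r$time)
      prod(stats::dnorm(r$conc, f, 0.188 * f)) * stats::dnorm(e, 0, 0.3)
    }, numeric(1))
  }
  oracle <- -2 * log(stats::integrate(lik, -3, 3, rel.tol = 1e-10)$value)
  # the Laplace value carries genuine approximation error (a non-Gaussian
  # posterior with 2 observations); importance sampling corrects it below
  lap <- marginal_minus2ll(pop1, ds, method = "laplace")
  expect_lt(abs(lap - oracle), 0.1)
  is1 <- marginal_minus2ll(pop1, ds, method = "importance", n_is = 2000,
                           seed = 5)
  expect_lt(abs(as.numeric(is1) - oracle), 3 * attr(is1, "mc_se") + 1e-3)
  # deterministic under a fixed seed, consistent as samples double
  is2 <- marginal_minus2ll(pop1, ds, method = "importance", n_is = 2000,
                           seed = 5)
  expect_identical(as.numeric(is1), as.numeric(is2))
  is4 <- marginal_minus2ll(pop1, ds, method = "importance", n_is = 4000,
                           seed = 6)
  expect_lt(abs(as.numeric(is4) - as.numeric(is1)),
            3 * (attr(is1, "mc_se") + attr(is4, "mc_se")) + 1e-3)
})

test_that("batched Laplace evaluator matches the per-subject reference", {
  pop <- final_model()
  ds <- simulate_group(pop, 12, 2, n = 12, seed = 3)
  p <- list(cl = 14.7, v1 = 26, q = 2.25, v2 = 9.93, q3 = 0, v3 = 1,
            om_cl = 0.255, om_v1 = 0.514, om_q = 0.386, corr = 0.714,
            b = 0.188)
  om <- treopk:::omega_active(p, c("cl", "v1", "q"))
  om_inv <- solve(om)
  ldo <- determinant(2 * pi * om)$modulus[1]
  bc <- treopk:::batch_constants(ds)
  bl <- treopk:::batch_laplace_m2ll(bc, p, om_inv, ldo, matrix(0, 12, 3))
  ref <- marginal_minus2ll(pop, ds, method = "laplace")
  expect_equal(bl$m2ll, ref, tolerance = 1e-6)
  # batched prediction equals the scalar concentration model
  E <- sample_random_effects(pop, 12, seed = 9)
  f <- treopk:::batch_predict(bc, p, E)
  for (i in c(1, 5, 12)) {
    s <- ds$subjects[i, ]
    pi_ <- individual_parameters(pop, s$bodyweight, E[i, ])
    r <- ds$records[ds$records$id == s$id, ]
    expect_equal(f[i, seq_len(nrow(r))],
                 concentration(pi_, s$total_dose, s$t_inf, r$time),
                 tolerance = 1e-10)
  }
})

test_that("three-compartment option degenerates to the analytic model", {
  p <- typical_params()
  tt <- c(0.5, 1, 2, 3, 6, 10)
  c3 <- treopk:::conc_mammillary(p$cl, p$v1, p$q, p$v2, 1e-9, 1,
                                 ref_dose(), 2, tt)
  expect_equal(c3, concentration(p, ref_dose(), 2, tt), tolerance = 1e-6)
})

test_that("model comparison applies the 10.8 and 6.67 MOFV rules", {
  f_red <- list(minus2ll = 1012, aic = 1024, bic = 1030, npar = 6,
                structure = treopk:::fit_structure(1))
  f_full <- list(minus2ll = 1000, aic = 1018, bic = 1026, npar = 9,
                 structure = treopk:::fit_structure(2))
  cmp <- compare_models(f_red, f_full)
  expect_true(cmp$nested)
  expect_equal(cmp$delta_mofv, 12)
  expect_true(cmp$significant_forward)
  expect_true(cmp$significant_backward)
  f_red$minus2ll <- 1005
  cmp2 <- compare_models(f_red, f_full)
  expect_false(cmp2$significant_forward)
  expect_false(cmp2$significant_backward)
  # decision thresholds sit at the chi-square(1) quantiles (printed to 2 dp)
  expect_equal(stats::qchisq(0.999, 1), 10.83, tolerance = 1e-3)
  expect_equal(stats::qchisq(0.99, 1), 6.63, tolerance = 1e-3)
  expect_warning(compare_models(f_full, f_red), "not nested")
})

test_that("eta-shrinkage closed cases: 0%, 100%, and 19% at 0.9 omega", {
  set.seed(2)
  om <- 0.5
  eta <- matrix(rnorm(4000, 0, om), ncol = 1)
  eta <- (eta - mean(eta)) / sd(eta) * om  # exact sample SD = omega
  expect_equal(eta_shrinkage(eta, om)[1], 0, tolerance = 1e-10)
  expect_equal(eta_shrinkage(matrix(0.3, 10, 1), om)[1], 100)
  eta9 <- eta * 0.9
  expect_equal(eta_shrinkage(eta9, om)[1], 19, tolerance = 1e-10)
  expect_error(eta_shrinkage(eta, 0), "positive")
})

test_that("population fitting recovers the generating model on a small cohort", {
  pop <- final_model()
  ds <- simulate_group(pop, 12, 2, n = 15, seed = 7)
  fit <- fit_population(ds, seed = 1)
  expect_equal(fit$convergence, 0)
  expect_equal(fit$estimates$theta$cl, 14.7, tolerance = 0.2)
  expect_equal(fit$estimates$theta$v1, 26.0, tolerance = 0.3)
  expect_equal(fit$estimates$prop_error_b, 0.188, tolerance = 0.2)
  # information-criterion identities
  expect_equal(fit$aic, fit$minus2ll + 2 * fit$npar, tolerance = 1e-12)
  expect_equal(fit$bic, fit$minus2ll + fit$npar * log(fit$n_subjects),
               tolerance = 1e-12)
  # shrinkage is a percentage below 100 for every random effect
  expect_true(all(fit$shrinkage_pct < 100))
})

test_that("bootstrap summarises replicate fits by median and 5-95 percentiles", {
  pop <- final_model()
  ds <- simulate_group(pop, 12, 2, n = 8, times = c(1, 2, 4, 6, 8, 12),
                       seed = 19)
  bs <- bootstrap_population(ds, n_reps = 3, seed = 2, max_iter = 60)
  expect_lte(bs$n_failed, 1)
  est <- bs$estimates
  # sort-based percentile oracle
  for (j in seq_len(ncol(est))) {
    expect_equal(bs$summary$median[j],
                 stats::median(est[, j]), tolerance = 1e-12)
    expect_equal(bs$summary$p5[j],
                 unname(stats::quantile(est[, j], 0.05)), tolerance = 1e-12)
  }
  # single replicate: interval collapses onto that replicate's estimate
  bs1 <- bootstrap_population(ds, n_reps = 1, seed = 3, max_iter = 60)
  expect_equal(bs1$summary$p5, bs1$summary$median, tolerance = 1e-12)
  expect_equal(bs1$summary$p95, bs1$summary$median, tolerance = 1e-12)
})

test_that("pcVPC is self-consistent on data simulated from the same model", {
  pop <- final_model()
  ds <- simulate_group(pop, 12, 2, n = 30, seed = 23)
  v <- pcvpc(ds, pop, n_sim = 150, seed = 4)
  b <- v$bins
  # band ordering within every bin and percentile
  for (p in c("p5", "p50", "p95")) {
    expect_true(all(b[[paste0("sim_", p, "_lo95")]] <=
                      b[[paste0("sim_", p, "_med")]]))
    expect_true(all(b[[paste0("sim_", p, "_med")]] <=
                      b[[paste0("sim_", p, "_hi95")]]))
  }
  # observed percentiles fall inside the 95% simulated bands in >= 90% of
  # bin-percentile combinations
  inside <- 0; total <- 0
  for (p in c("p5", "p50", "p95")) {
    o <- b[[paste0("obs_", p)]]
    inside <- inside + sum(o >= b[[paste0("sim_", p, "_lo95")]] &
                             o <= b[[paste0("sim_", p, "_hi95")]])
    total <- total + nrow(b)
  }
  expect_gte(inside / total, 0.9)
})

test_that("prediction correction is inert for a homogeneous design", {
  pop <- final_model()
  ds <- simulate_group(pop, 12, 2, n = 25, seed = 29,
                       weight_args = list(sd = 0))
  v <- pcvpc(ds, pop, n_sim = 120, seed = 5)
  rec <- ds$records
  for (k in seq_len(nrow(v$bins))) {
    raw <- rec$conc[rec$time == v$bins$time[k]]
    expect_equal(v$bins$obs_p50[k],
                 unname(stats::quantile(raw, 0.5)), tolerance = 1e-9)
  }
})
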