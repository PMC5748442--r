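test_that("MAP objective matches an independent recomputation on a grid", {
  pop <- final_model()
  bw <- 25; dose <- 11000; t_inf <- 2
  p_true <- individual_parameters(pop, bw, c(cl = 0.2, v1 = -0.1, q = 0.1))
  tt <- c(2, 6)
  yy <- concentration(p_true, dose, t_inf, tt)
  om_inv <- solve(omega_matrix(pop))
  b <- pop$prop_error_b
  oracle <- function(eta) {
    p <- individual_parameters(pop, bw, c(cl = eta[1], v1 = eta[2],
                                          q = eta[3]))
    cp <- concentration(p, dose, t_inf, tt)
    sum((yy - cp)^2 / (b * cp)^2 + 2 * log(b * cp)) +
      drop(t(eta) %*% om_inv %*% eta)
  }
  grid <- seq(-0.5, 0.5, length.out = 11)
  for (e1 in grid[c(1, 4, 8, 11)]) for (e2 in grid[c(2, 6, 10)]) {
    eta <- c(e1, e2, 0.05)
    expect_equal(map_objective(pop, bw, dose, t_inf, tt, yy, eta),
                 oracle(eta), tolerance = 1e-10)
  }
  expect_error(map_objective(pop, bw, dose, t_inf, numeric(0), numeric(0),
                             c(0, 0, 0)), "observation")
})

test_that("MAP estimation recovers random effects from rich noiseless data", {
  pop <- final_model()
  eta_true <- c(cl = 0.25, v1 = -0.3, q = 0.15)
  bw <- 30; dose <- 12000; t_inf <- 2
  p <- individual_parameters(pop, bw, eta_true)
  tt <- candidate_times()
  yy <- concentration(p, dose, t_inf, tt)
  est <- estimate_individual(pop, bw, dose, t_inf, tt, yy, seed = 1)
  # noise-free rich data: the data term dominates, but the prior (and the
  # log-variance part of the proportional-error likelihood) still pulls the
  # mode slightly off the generating value
  expect_lt(max(abs(est$eta_hat - eta_true)), 0.1)
  expect_equal(est$auc_hat, dose / p$cl, tolerance = 0.05)
  expect_equal(est$auc_hat, dose / est$params_hat$cl, tolerance = 1e-12)
  # the MAP objective is genuinely lower at the mode than at the truth
  expect_lte(est$objective_value,
             map_objective(pop, bw, dose, t_inf, tt, yy, eta_true))
})

test_that("MAP minimiser agrees with a dense grid search on a sparse subject", {
  pop <- final_model()
  bw <- 20; dose <- 9000; t_inf <- 1
  p_true <- individual_parameters(pop, bw, c(cl = -0.2, v1 = 0.2, q = 0))
  tt <- c(1, 6)
  yy <- concentration(p_true, dose, t_inf, tt) * c(1.1, 0.95)
  est <- estimate_individual(pop, bw, dose, t_inf, tt, yy, seed = 2)
  g <- seq(-0.8, 0.8, length.out = 41)
  best <- c(Inf, 0, 0, 0)
  for (e1 in g) for (e2 in g) for (e3 in g) {
    v <- map_objective(pop, bw, dose, t_inf, tt, yy, c(e1, e2, e3))
    if (v < best[1]) best <- c(v, e1, e2, e3)
  }
  step <- g[2] - g[1]
  expect_lte(est$objective_value, best[1] + 1e-9)
  expect_lt(max(abs(est$eta_hat - best[2:4])), step * 1.5)
})

test_that("sparse-data MAP estimates shrink toward the population mean", {
  pop <- final_model()
  ds <- simulate_group(pop, 12, 2, n = 100, seed = 41,
                       residual_error = FALSE)
  eta_true <- as.matrix(ds$subjects[, c("eta_cl", "eta_v1", "eta_q")])
  rec <- ds$records
  eta_hat <- t(vapply(seq_len(100), function(i) {
    s <- ds$subjects[i, ]
    r <- rec[rec$id == s$id & rec$time %in% c(2, 6), ]
    estimate_individual(pop, s$bodyweight, s$total_dose, s$t_inf,
                        r$time, r$conc, n_starts = 2, seed = i)$eta_hat
  }, numeric(3)))
  expect_lt(mean(abs(eta_hat)), mean(abs(eta_true)))
})

test_that("posterior-mean estimate agrees with MAP in the Gaussian regime", {
  pop <- final_model()
  bw <- 28; dose <- 11500; t_inf <- 2
  p_true <- individual_parameters(pop, bw, c(cl = 0.1, v1 = 0.1, q = -0.1))
  tt <- c(2, 4, 6, 8)
  yy <- concentration(p_true, dose, t_inf, tt)
  map <- estimate_individual(pop, bw, dose, t_inf, tt, yy, seed = 3)
  cm <- conditional_mean_estimate(pop, bw, dose, t_inf, tt, yy,
                                  n_mcmc = 4000, burn_in = 1000, seed = 4)
  expect_lt(max(abs(cm$eta_hat - map$eta_hat)), 0.08)
  expect_gt(attr(cm, "acceptance_rate"), 0.05)
  # chain reproducibility
  cm2 <- conditional_mean_estimate(pop, bw, dose, t_inf, tt, yy,
                                   n_mcmc = 500, burn_in = 100, seed = 11)
  cm3 <- conditional_mean_estimate(pop, bw, dose, t_inf, tt, yy,
                                   n_mcmc = 500, burn_in = 100, seed = 11)
  expect_identical(cm2$eta_hat, cm3$eta_hat)
})
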