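test_that("learning/validation split is disjoint, exhaustive and balanced", {
  ds <- toy_dataset(n = 100, seed = 1)
  sp <- split_learning_validation(ds, 0.5, seed = 2)
  expect_equal(nrow(sp$learning$subjects), 50L)
  expect_equal(nrow(sp$validation$subjects), 50L)
  expect_length(intersect(sp$learning$subjects$id,
                          sp$validation$subjects$id), 0)
  expect_setequal(c(sp$learning$subjects$id, sp$validation$subjects$id),
                  ds$subjects$id)
  ds5 <- toy_dataset(n = 5, seed = 1)
  sp5 <- split_learning_validation(ds5, 0.5, seed = 1)
  expect_true(abs(nrow(sp5$learning$subjects) -
                    nrow(sp5$validation$subjects)) <= 1)
  expect_identical(split_learning_validation(ds, 0.5, seed = 9)$learning$subjects$id,
                   split_learning_validation(ds, 0.5, seed = 9)$learning$subjects$id)
  expect_error(split_learning_validation(ds, 1.2), "fraction")
  expect_error(split_learning_validation(toy_dataset(n = 3, seed = 1)),
               "at least 4")
})

test_that("candidate subsets exclude in-infusion draws and the 12-h sample", {
  s2 <- candidate_subsets(candidate_times(), 2, t_inf = 2)
  expect_length(s2, choose(6, 2))   # {2, 2.5, 3, 4, 6, 8}
  expect_true(all(vapply(s2, function(x) all(x >= 2 & x != 12), logical(1))))
  s2_1h <- candidate_subsets(candidate_times(), 2, t_inf = 1)
  expect_length(s2_1h, choose(8, 2))
  expect_false(any(vapply(s2_1h, function(x) 12 %in% x, logical(1))))
  s3 <- candidate_subsets(candidate_times(), 3, t_inf = 1)
  expect_length(s3, choose(8, 3))
  expect_error(candidate_subsets(candidate_times(), 4, 1), "k must be")
})

test_that("regression fitting matches the normal-equations oracle", {
  ds <- toy_dataset(n = 12, seed = 21)
  auc <- nca_dataset(ds)
  m <- fit_lss(ds, c(2, 6), auc)
  ct <- conc_table(ds, c(2, 6))
  x <- cbind(1, as.matrix(ct[, -1]))
  y <- auc$auc_obs[match(ct$id, auc$id)]
  beta_oracle <- solve(t(x) %*% x, t(x) %*% y)
  expect_equal(unname(c(m$intercept, m$coefficients)),
               unname(drop(beta_oracle)), tolerance = 1e-8)
  # exact linear relation -> perfect fit
  auc_lin <- data.frame(id = ct$id, auc_obs = 3 * ct$C_6h)
  m_lin <- suppressWarnings(fit_lss(ds, c(2, 6), auc_lin))
  expect_equal(m_lin$coefficients, c(0, 3), tolerance = 1e-8)
  expect_equal(m_lin$intercept, 0, tolerance = 1e-6)
  expect_equal(m_lin$adj_r2, 1, tolerance = 1e-10)
})

test_that("strategy ranking is an exhaustive adjusted-R2 sort", {
  ds <- toy_dataset(n = 40, seed = 33)
  auc <- nca_dataset(ds)
  subsets <- candidate_subsets(candidate_times(), 2, t_inf = 2)
  ranked <- rank_strategies(ds, subsets, auc)
  r2 <- vapply(ranked, `[[`, numeric(1), "adj_r2")
  expect_true(all(diff(r2) <= 1e-12))
  # brute-force re-sort oracle
  fits <- lapply(subsets, function(tt) fit_lss(ds, tt, auc))
  expect_equal(max(vapply(fits, `[[`, numeric(1), "adj_r2")), r2[1])
  # invariant to subject ordering
  perm <- rev(ds$subjects$id)
  ds_perm <- subset_dataset(ds, perm)
  ds_perm$subjects <- ds_perm$subjects[order(match(ds_perm$subjects$id,
                                                   perm)), ]
  ranked2 <- rank_strategies(ds_perm, subsets, auc)
  expect_equal(ranked[[1]]$times, ranked2[[1]]$times)
  expect_equal(ranked[[1]]$adj_r2, ranked2[[1]]$adj_r2, tolerance = 1e-12)
})

test_that("prediction applies the linear equation and is unbiased in-sample", {
  m <- structure(list(times = c(2, 6), intercept = 1,
                      coefficients = c(2, 7), mode = "regression"),
                 class = "lss_model")
  expect_equal(predict_auc(m, c(10, 5)), 56)
  m0 <- structure(list(times = c(2, 6), intercept = 42,
                       coefficients = c(0, 0), mode = "regression"),
                  class = "lss_model")
  expect_equal(predict_auc(m0, c(10, 5)), 42)
  # OLS with intercept: mean in-sample prediction error is zero
  ds <- toy_dataset(n = 30, seed = 55)
  auc <- nca_dataset(ds)
  fit <- fit_lss(ds, c(2, 6), auc)
  rep <- evaluate_lss(fit, ds, auc)
  expect_equal(mean(attr(rep, "predictions")$auc_pred - auc$auc_obs), 0,
               tolerance = 1e-8)
})

test_that("three-point winners never trail two-point winners", {
  pop <- final_model()
  for (g in study_groups()[1:2]) {
    ds <- simulate_group(pop, g$dose_per_bsa, g$t_inf, 40,
                         seed = child_seed(8, g$name),
                         residual_error = FALSE)
    auc <- nca_dataset(ds)
    best2 <- rank_strategies(ds, candidate_subsets(candidate_times(), 2,
                                                   g$t_inf), auc)[[1]]
    best3 <- rank_strategies(ds, candidate_subsets(candidate_times(), 3,
                                                   g$t_inf), auc)[[1]]
    expect_gte(best3$adj_r2, best2$adj_r2)
  }
})
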