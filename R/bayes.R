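#' MAP objective for individual random effects
#'
#' Minus twice the log joint density of a subject's observations and random
#' effects under the fixed population model (up to an additive constant):
#' the proportional-error data term
#' `sum[(c_obs - c_pred)^2 / (b c_pred)^2 + 2 log(b c_pred)]` plus the
#' log-normal prior term `eta' Omega^{-1} eta`, with `Omega` the IIV
#' covariance of (Cl, V1, Q) including the Cl-V1 correlation.
#'
#' @param pop a [population_model()] (estimates fixed).
#' @param bodyweight subject bodyweight, kg.
#' @param dose total dose, mg.
#' @param t_inf infusion duration, h.
#' @param time observation times, h (>= 1 non-BLQ record).
#' @param conc observed concentrations, mg/L.
#' @param eta random-effect vector `c(cl, v1, q)`.
#' @return the scalar objective (smaller is better).
#' @export
map_objective <- function(pop, bodyweight, dose, t_inf, time, conc, eta) {
  if (length(time) < 1) stop("need at least one observation")
  eta <- as.numeric(eta)
  p <- individual_parameters(pop, bodyweight,
                             c(cl = eta[1], v1 = eta[2], q = eta[3]))
  cp <- concentration(p, dose, t_inf, time)
  if (any(cp <= 0)) stop("predicted concentration is zero at an observation time")
  b <- pop$prop_error_b
  data_term <- sum((conc - cp)^2 / (b * cp)^2 + 2 * log(b * cp))
  om_inv <- solve(omega_matrix(pop))
  data_term + drop(t(eta) %*% om_inv %*% eta)
}

#' MAP estimate of an individual's parameters and exposure
#'
#' Minimises [map_objective()] over the random effects by quasi-Newton
#' optimisation with multiple starts drawn from the prior (plus the zero
#' start), then maps the winning `eta` to individual parameters and to
#' `AUC0-inf = dose / Cl`.
#'
#' @inheritParams map_objective
#' @param time,conc the subject's retained (sparse) records.
#' @param n_starts number of prior-drawn starts in addition to `eta = 0`.
#' @param seed RNG seed for the starts.
#' @return object of class `individual_estimate`: `eta_hat`, `params_hat`
#'   ([pk_parameters()]), `auc_hat` (mg*h/L), `objective_value`,
#'   `convergence` (0 = ok).
#' @export
estimate_individual <- function(pop, bodyweight, dose, t_inf, time, conc,
                                n_starts = 5, seed = NULL) {
  if (length(time) < 1) stop("no records at the requested times")
  # robust wrapper: extreme trial steps (prediction underflow) get a large
  # finite value instead of aborting the line search
  obj <- function(eta) {
    v <- tryCatch(map_objective(pop, bodyweight, dose, t_inf, time, conc,
                                eta),
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- rbind(c(0, 0, 0),
                  if (n_starts > 0)
                    sample_random_effects(pop, n_starts, seed = seed))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[i, ], obj, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("individual estimation failed to converge from any start")
  }
  eta_hat <- stats::setNames(best$par, c("cl", "v1", "q"))
  params <- individual_parameters(pop, bodyweight, eta_hat)
  structure(list(eta_hat = eta_hat, params_hat = params,
                 auc_hat = auc_from_clearance(dose, params$cl),
                 objective_value = best$value,
                 convergence = best$convergence),
            class = "individual_estimate")
}

#' @export
print.individual_estimate <- function(x, ...) {
  cat(sprintf(
    "Individual estimate: Cl %.4g L/h, AUC0-inf %.4g mg*h/L (objective %.4g)\n",
    x$params_hat$cl, x$auc_hat, x$objective_value))
  invisible(x)
}

#' Posterior-mean individual estimate by MCMC
#'
#' Samples the same posterior as [map_objective()] with a random-walk
#' Metropolis-within-Gibbs scheme (one component of `eta` updated at a
#' time) and returns the posterior mean of `eta` after burn-in.  Provided as
#' the conditional-mean alternative to the MAP mode; in the near-Gaussian
#' posteriors typical of this model the two agree closely.
#'
#' @inheritParams estimate_individual
#' @param n_mcmc number of MCMC iterations after burn-in.
#' @param burn_in discarded initial iterations.
#' @param proposal_sd random-walk SD per component; defaults to half the
#'   prior SDs.
#' @param seed RNG seed.
#' @return an `individual_estimate` whose `eta_hat` is the posterior mean;
#'   `objective_value` is the MAP objective evaluated at the posterior mean,
#'   with acceptance rate attached as attribute `"acceptance_rate"`.
#' @export
conditional_mean_estimate <- function(pop, bodyweight, dose, t_inf, time,
                                      conc, n_mcmc = 2000,
                                      burn_in = 500, proposal_sd = NULL,
                                      seed = NULL) {
  if (length(time) < 1) stop("no records at the requested times")
  if (is.null(proposal_sd)) proposal_sd <- pmax(pop$omega / 2, 0.05)
  obj <- function(eta) map_objective(pop, bodyweight, dose, t_inf,
                                     time, conc, eta)
  with_seed(seed, function() {
    eta <- c(0, 0, 0)
    cur <- obj(eta)
    keep <- matrix(NA_real_, n_mcmc, 3)
    n_acc <- 0L
    n_tot <- 0L
    for (it in seq_len(burn_in + n_mcmc)) {
      for (j in 1:3) {
        cand <- eta
        cand[j] <- cand[j] + stats::rnorm(1, 0, proposal_sd[j])
        val <- try(obj(cand), silent = TRUE)
        n_tot <- n_tot + 1L
        # accept with probability exp(-(val - cur)/2): obj is -2 log posterior
        if (!inherits(val, "try-error") &&
            log(stats::runif(1)) < (cur - val) / 2) {
          eta <- cand
          cur <- val
          n_acc <- n_acc + 1L
        }
      }
      if (it > burn_in) keep[it - burn_in, ] <- eta
    }
    eta_mean <- stats::setNames(colMeans(keep), c("cl", "v1", "q"))
    params <- individual_parameters(pop, bodyweight, eta_mean)
    out <- structure(list(eta_hat = eta_mean, params_hat = params,
                          auc_hat = auc_from_clearance(dose, params$cl),
                          objective_value = obj(eta_mean),
                          convergence = 0L),
                     class = "individual_estimate")
    attr(out, "acceptance_rate") <- n_acc / n_tot
    out
  })
}
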