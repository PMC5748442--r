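#' Individual structural pharmacokinetic parameters
#'
#' Container for the four structural parameters of the two-compartment
#' disposition model: clearance `cl` (L/h), central volume `v1` (L),
#' intercompartmental clearance `q` (L/h) and peripheral volume `v2` (L).
#' All must be strictly positive.
#'
#' @param cl clearance, L/h.
#' @param v1 central compartment volume, L.
#' @param q intercompartmental clearance, L/h (0 allowed as the
#'   one-compartment limit).
#' @param v2 peripheral compartment volume, L.
#' @return an object of class `pk_parameters`.
#' @examples
#' pk_parameters(cl = 14.7, v1 = 26.0, q = 2.25, v2 = 9.93)
#' @export
pk_parameters <- function(cl, v1, q, v2) {
  vals <- c(cl = cl, v1 = v1, q = q, v2 = v2)
  if (any(!is.finite(vals))) stop("pk_parameters must be finite")
  if (cl <= 0 || v1 <= 0 || v2 <= 0 || q < 0) {
    stop("pk_parameters: cl, v1, v2 must be > 0 and q >= 0")
  }
  structure(as.list(vals), class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("PK parameters: Cl %.4g L/h, V1 %.4g L, Q %.4g L/h, V2 %.4g L\n",
              x$cl, x$v1, x$q, x$v2))
  invisible(x)
}

#' Population pharmacokinetic model
#'
#' Typical parameter values referenced to a 70-kg individual, allometric
#' bodyweight exponents, log-scale interindividual variability (IIV) standard
#' deviations, the correlation between the clearance and central-volume
#' random effects, and the residual-error magnitudes.  In the final model the
#' clearance exponent is 0.75, the volume exponents are 1, intercompartmental
#' clearance carries IIV but no bodyweight covariate, the peripheral volume
#' carries no IIV, and the residual error is purely proportional.
#'
#' @param theta [pk_parameters()] of typical values at `ref_weight`.
#' @param beta named numeric of allometric exponents for `cl`, `v1`, `q`,
#'   `v2`; an exponent of 0 means the parameter is not weight-scaled.
#' @param ref_weight reference bodyweight, kg (70).
#' @param omega named numeric of IIV standard deviations (log scale) for
#'   `cl`, `v1`, `q`; the peripheral-volume random effect is fixed at 0.
#' @param corr_cl_v1 correlation between the clearance and central-volume
#'   random effects, in `[-1, 1]`.
#' @param prop_error_b proportional residual-error standard deviation
#'   (dimensionless).
#' @param add_error additive residual-error standard deviation, mg/L
#'   (0 in the final model).
#' @return an object of class `population_model`.
#' @examples
#' final_model()
#' @export
population_model <- function(theta,
                             beta = c(cl = 0.75, v1 = 1, q = 0, v2 = 1),
                             ref_weight = 70,
                             omega = c(cl = 0.255, v1 = 0.514, q = 0.386),
                             corr_cl_v1 = 0.714,
                             prop_error_b = 0.188,
                             add_error = 0) {
  stopifnot(inherits(theta, "pk_parameters"))
  beta <- beta[c("cl", "v1", "q", "v2")]
  omega <- omega[c("cl", "v1", "q")]
  if (any(is.na(beta)) || any(!is.finite(beta))) {
    stop("beta must provide finite exponents for cl, v1, q, v2")
  }
  if (any(is.na(omega)) || any(omega < 0)) {
    stop("omega must provide non-negative SDs for cl, v1, q")
  }
  if (abs(corr_cl_v1) > 1) stop("corr_cl_v1 must lie in [-1, 1]")
  if (prop_error_b < 0 || add_error < 0) {
    stop("residual error SDs must be non-negative")
  }
  if (ref_weight <= 0) stop("ref_weight must be positive")
  structure(list(theta = theta, beta = beta, ref_weight = ref_weight,
                 omega = omega, corr_cl_v1 = corr_cl_v1,
                 prop_error_b = prop_error_b, add_error = add_error),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "Population PK model (ref %g kg):\n  Cl %.4g L/h (beta %.3g, omega %.3g)\n  V1 %.4g L   (beta %.3g, omega %.3g)\n  Q  %.4g L/h (beta %.3g, omega %.3g)\n  V2 %.4g L   (beta %.3g, no IIV)\n  corr(eta_Cl, eta_V1) %.3g; proportional error %.3g; additive %.3g mg/L\n",
    x$ref_weight,
    x$theta$cl, x$beta["cl"], x$omega["cl"],
    x$theta$v1, x$beta["v1"], x$omega["v1"],
    x$theta$q,  x$beta["q"],  x$omega["q"],
    x$theta$v2, x$beta["v2"],
    x$corr_cl_v1, x$prop_error_b, x$add_error))
  invisible(x)
}

#' IIV covariance matrix of a population model
#'
#' The 3x3 covariance of the random effects carrying interindividual
#' variability (clearance, central volume, intercompartmental clearance),
#' with the configured clearance/central-volume correlation and zero
#' correlation with the intercompartmental-clearance effect.
#'
#' @param pop a [population_model()].
#' @return a 3x3 positive semi-definite matrix with dimnames
#'   `c("cl","v1","q")`.
#' @export
omega_matrix <- function(pop) {
  sd <- pop$omega
  m <- diag(sd^2)
  dimnames(m) <- list(names(sd), names(sd))
  m["cl", "v1"] <- m["v1", "cl"] <- pop$corr_cl_v1 * sd["cl"] * sd["v1"]
  m
}

#' Individual parameters from typical values, bodyweight and random effects
#'
#' Applies the allometric covariate model
#' `theta_i = theta * (BW / ref)^beta * exp(eta)` parameter by parameter.
#' The peripheral-volume random effect is fixed at zero and
#' intercompartmental clearance is not weight-scaled in the final model.
#'
#' @param pop a [population_model()].
#' @param bodyweight bodyweight, kg; must be positive.
#' @param eta named numeric of random effects for `cl`, `v1`, `q`
#'   (log scale); defaults to zero (the typical individual).
#' @return a [pk_parameters()] object.
#' @examples
#' individual_parameters(final_model(), bodyweight = 35)
#' @export
individual_parameters <- function(pop, bodyweight,
                                  eta = c(cl = 0, v1 = 0, q = 0)) {
  if (!is.finite(bodyweight) || bodyweight <= 0) {
    stop("bodyweight must be a positive number (kg)")
  }
  eta4 <- c(eta[c("cl", "v1", "q")], v2 = 0)
  if (any(is.na(eta4)) || any(!is.finite(eta4))) {
    stop("eta must provide finite values for cl, v1, q")
  }
  w <- (bodyweight / pop$ref_weight)^pop$beta
  th <- unlist(pop$theta)[c("cl", "v1", "q", "v2")]
  p <- th * w * exp(eta4)
  pk_parameters(cl = unname(p["cl"]), v1 = unname(p["v1"]),
                q = unname(p["q"]), v2 = unname(p["v2"]))
}

#' Micro rate constants and disposition exponents
#'
#' Standard reparameterization of the two-compartment model:
#' `k10 = Cl/V1`, `k12 = Q/V1`, `k21 = Q/V2`; `alpha` and `beta` are the
#' roots of `s^2 - (k10 + k12 + k21) s + k10 k21`, with
#' `alpha >= beta >= 0`.  With `Q = 0` the model degenerates to one
#' compartment (`alpha = k10`, `beta = 0`).
#'
#' @param p a [pk_parameters()].
#' @return list with `k10`, `k12`, `k21`, `alpha`, `beta` (all 1/h).
#' @examples
#' micro_constants(pk_parameters(14.7, 26.0, 2.25, 9.93))
#' @export
micro_constants <- function(p) {
  stopifnot(inherits(p, "pk_parameters"))
  k10 <- p$cl / p$v1
  k12 <- p$q / p$v1
  k21 <- p$q / p$v2
  s <- k10 + k12 + k21
  # discriminant is always >= 0 for real positive rate constants
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Plasma concentration during and after a zero-order intravenous infusion
#'
#' Closed-form bi-exponential solution of the two-compartment disposition
#' model with constant-rate input `dose / t_inf` into the central compartment
#' over `[0, t_inf]`.  The solution is continuous at the end of infusion,
#' starts at zero and decays to zero.  With `q = 0` the one-compartment
#' closed form is used.
#'
#' @param p a [pk_parameters()].
#' @param dose total dose, mg (>= 0).
#' @param t_inf infusion duration, h (> 0).
#' @param t time after infusion start, h; vectorised, all values must be
#'   >= 0.
#' @return central-compartment concentration, mg/L, same length as `t`.
#' @examples
#' p <- pk_parameters(14.7, 26.0, 2.25, 9.93)
#' concentration(p, dose = 22200, t_inf = 2, t = c(0, 1, 2, 4, 8, 12))
#' @export
concentration <- function(p, dose, t_inf, t) {
  stopifnot(inherits(p, "pk_parameters"))
  if (dose < 0) stop("dose must be non-negative")
  if (t_inf <= 0) stop("t_inf must be positive")
  if (any(t < 0)) stop("negative time")
  if (dose == 0) return(rep(0, length(t)))
  r0 <- dose / t_inf
  mc <- micro_constants(p)
  t1 <- pmin(t, t_inf)           # elapsed infusion time
  t2 <- pmax(t - t_inf, 0)       # time since end of infusion
  if (mc$beta < 1e-12) {
    # one-compartment limit (q = 0): beta-phase vanishes
    k <- mc$alpha
    return((r0 / p$cl) * (1 - exp(-k * t1)) * exp(-k * t2))
  }
  a <- (mc$k21 - mc$alpha) / (mc$alpha * (mc$beta - mc$alpha))
  b <- (mc$k21 - mc$beta) / (mc$beta * (mc$alpha - mc$beta))
  (r0 / p$v1) * (a * (1 - exp(-mc$alpha * t1)) * exp(-mc$alpha * t2) +
                 b * (1 - exp(-mc$beta  * t1)) * exp(-mc$beta  * t2))
}

#' Total exposure from dose and clearance
#'
#' For a linear system the area under the concentration-time curve from dose
#' start to infinity equals dose divided by clearance.
#'
#' @param dose total dose, mg.
#' @param cl clearance, L/h; must be positive.
#' @return AUC0-inf, mg*h/L.
#' @examples
#' auc_from_clearance(22200, 14.7)
#' @export
auc_from_clearance <- function(dose, cl) {
  if (!is.finite(cl) || cl <= 0) stop("clearance must be positive")
  if (any(dose < 0)) stop("dose must be non-negative")
  dose / cl
}

#' Apply the residual-error model to noise-free predictions
#'
#' Observation model `C_obs = C_pred * (1 + eps1) + eps2` with
#' `eps1 ~ N(0, b^2)` proportional and `eps2 ~ N(0, a^2)` additive; the
#' final model is purely proportional (`a = 0`).  Negative results (rare at
#' the final error magnitude) are truncated at zero; the count of truncated
#' values is attached as attribute `"n_truncated"`.
#'
#' @param c_pred noise-free predicted concentrations, mg/L (>= 0).
#' @param pop a [population_model()] supplying `prop_error_b` and
#'   `add_error`.
#' @param eps1 optional vector of proportional-error draws (standardised by
#'   `b` already applied, i.e. the actual relative deviations); drawn
#'   internally when `NULL`.
#' @param eps2 optional additive-error draws, mg/L.
#' @param seed optional seed used when draws are generated internally.
#' @return observed concentrations, mg/L.
#' @examples
#' apply_residual_error(c(100, 50), final_model(), eps1 = c(0.188, 0))
#' @export
apply_residual_error <- function(c_pred, pop, eps1 = NULL, eps2 = NULL,
                                 seed = NULL) {
  if (any(c_pred < 0)) stop("c_pred must be non-negative")
  n <- length(c_pred)
  with_seed(seed, function() {
    if (is.null(eps1)) {
      eps1 <<- stats::rnorm(n, 0, pop$prop_error_b)
    }
    if (is.null(eps2)) {
      eps2 <<- if (pop$add_error > 0) stats::rnorm(n, 0, pop$add_error) else
        rep(0, n)
    }
    NULL
  })
  obs <- c_pred * (1 + eps1) + eps2
  n_trunc <- sum(obs < 0)
  obs <- pmax(obs, 0)
  attr(obs, "n_truncated") <- n_trunc
  obs
}

#' Draw interindividual random effects
#'
#' Samples `eta` vectors from the multivariate normal with standard
#' deviations `pop$omega` and the configured clearance/central-volume
#' correlation.  Reproducible under a fixed seed.
#'
#' @param pop a [population_model()].
#' @param n number of individuals.
#' @param seed optional RNG seed.
#' @return an `n` x 3 matrix with columns `cl`, `v1`, `q`.
#' @examples
#' sample_random_effects(final_model(), 5, seed = 1)
#' @export
sample_random_effects <- function(pop, n, seed = NULL) {
  stopifnot(n >= 0)
  sigma <- omega_matrix(pop)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("IIV covariance is not positive semi-definite")
  }
  # matrix square root via eigen handles the zero-variance edge cases
  ed <- eigen(sigma, symmetric = TRUE)
  root <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), 3) %*% t(ed$vectors)
  with_seed(seed, function() {
    z <- matrix(stats::rnorm(3 * n), nrow = n, ncol = 3)
    eta <- z %*% root
    colnames(eta) <- colnames(sigma)
    eta
  })
}
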