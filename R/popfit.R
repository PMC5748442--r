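# Nonlinear mixed-effects estimation of the population model.
#
# The marginal likelihood integrates the subject-level random effects out of
# the joint density.  The integral is approximated per subject by the Laplace
# method around the MAP random effects (inner damped-Newton solver with warm
# starts), and, for final model comparison, recomputed by importance sampling
# with the Laplace Gaussian as proposal.  The outer maximization runs
# quasi-Newton on log/atanh-transformed parameters.

LOG2PI <- log(2 * pi)

# ---- structures -----------------------------------------------------------

# A structure fixes which parameters are free and which random effects are
# active.  1-cpt: Cl, V1 (+ IIV on both, correlated); 2-cpt adds Q, V2 and
# IIV on Q; 3-cpt adds a second peripheral compartment (Q3, V3, no IIV).
fit_structure <- function(n_compartments = 2,
                          error = "proportional") {
  stopifnot(n_compartments %in% 1:3, error == "proportional")
  free <- switch(as.character(n_compartments),
    "1" = c("lcl", "lv1", "lom_cl", "lom_v1", "zcorr", "lb"),
    "2" = c("lcl", "lv1", "lq", "lv2", "lom_cl", "lom_v1", "lom_q",
            "zcorr", "lb"),
    "3" = c("lcl", "lv1", "lq", "lv2", "lq3", "lv3", "lom_cl", "lom_v1",
            "lom_q", "zcorr", "lb"))
  eta_names <- if (n_compartments == 1) c("cl", "v1") else c("cl", "v1", "q")
  list(n_compartments = n_compartments, error = error, free = free,
       eta_names = eta_names, npar = length(free))
}

# decode transformed parameter vector into a named natural-scale list
decode_pars <- function(par, structure) {
  names(par) <- structure$free
  g <- function(nm, default = 0) if (nm %in% structure$free)
    exp(par[[nm]]) else default
  list(cl = g("lcl"), v1 = g("lv1"),
       q = g("lq"), v2 = g("lv2", 1),
       q3 = g("lq3"), v3 = g("lv3", 1),
       om_cl = g("lom_cl"), om_v1 = g("lom_v1"), om_q = g("lom_q"),
       corr = if ("zcorr" %in% structure$free) tanh(par[["zcorr"]]) else 0,
       b = g("lb"))
}

encode_pars <- function(p, structure) {
  full <- c(lcl = log(p$cl), lv1 = log(p$v1),
            lq = if (p$q > 0) log(p$q) else NA,
            lv2 = log(p$v2),
            lq3 = if (p$q3 > 0) log(p$q3) else NA,
            lv3 = if (p$v3 > 0) log(p$v3) else NA,
            lom_cl = log(p$om_cl), lom_v1 = log(p$om_v1),
            lom_q = if (p$om_q > 0) log(p$om_q) else NA,
            zcorr = atanh(min(max(p$corr, -0.99), 0.99)),
            lb = log(p$b))
  full[structure$free]
}

# active-eta IIV covariance
omega_active <- function(p, eta_names) {
  sd <- c(cl = p$om_cl, v1 = p$om_v1, q = p$om_q)[eta_names]
  m <- diag(sd^2, length(sd))
  dimnames(m) <- list(eta_names, eta_names)
  if (all(c("cl", "v1") %in% eta_names)) {
    m["cl", "v1"] <- m["v1", "cl"] <- p$corr * sd["cl"] * sd["v1"]
  }
  m
}

# ---- per-subject constants and fast prediction ----------------------------

# Precompute everything that does not change during optimisation.
subject_constants <- function(dataset, ref_weight = 70,
                              beta = c(cl = 0.75, v1 = 1, q = 0, v2 = 1)) {
  subj <- dataset$subjects
  rec <- dataset$records[!dataset$records$blq, , drop = FALSE]
  lapply(seq_len(nrow(subj)), function(i) {
    r <- rec[rec$id == subj$id[i], , drop = FALSE]
    w <- subj$bodyweight[i] / ref_weight
    list(id = subj$id[i],
         time = r$time, y = r$conc, n = nrow(r),
         dose = subj$total_dose[i], t_inf = subj$t_inf[i],
         r0 = subj$total_dose[i] / subj$t_inf[i],
         t1 = pmin(r$time, subj$t_inf[i]),
         t2 = pmax(r$time - subj$t_inf[i], 0),
         wcl = w^beta[["cl"]], wv1 = w^beta[["v1"]],
         wq = w^beta[["q"]], wv2 = w^beta[["v2"]])
  })
}

# fast two/three-compartment infusion prediction for one subject; eta may
# cover a leading subset of (cl, v1, q) when some IIV terms are fixed at 0
predict_subject <- function(cst, p, eta) {
  cl <- p$cl * cst$wcl * exp(eta[1])
  v1 <- p$v1 * cst$wv1 * (if (length(eta) >= 2) exp(eta[2]) else 1)
  q <- if (length(eta) >= 3) p$q * cst$wq * exp(eta[3]) else p$q * cst$wq
  v2 <- p$v2 * cst$wv2
  if (p$q3 > 0) {
    return(conc_mammillary(cl, v1, q, v2, p$q3, p$v3 * cst$wv2,
                           cst$dose, cst$t_inf, cst$time))
  }
  if (q <= 0) {
    k <- cl / v1
    return((cst$r0 / cl) * (1 - exp(-k * cst$t1)) * exp(-k * cst$t2))
  }
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  al <- (s + disc) / 2; be <- (s - disc) / 2
  a <- (k21 - al) / (al * (be - al))
  b2 <- (k21 - be) / (be * (al - be))
  (cst$r0 / v1) * (a * (1 - exp(-al * cst$t1)) * exp(-al * cst$t2) +
                   b2 * (1 - exp(-be * cst$t1)) * exp(-be * cst$t2))
}

# three-compartment mammillary infusion model via eigendecomposition
conc_mammillary <- function(cl, v1, q2, v2, q3, v3, dose, t_inf, t) {
  k10 <- cl / v1; k12 <- q2 / v1; k21 <- q2 / v2
  k13 <- q3 / v1; k31 <- q3 / v3
  a_mat <- matrix(c(-(k10 + k12 + k13), k21, k31,
                    k12, -k21, 0,
                    k13, 0, -k31), 3, 3, byrow = TRUE)
  r <- c(dose / t_inf, 0, 0)
  ed <- eigen(a_mat)
  vinv <- solve(ed$vectors)
  a_ss <- -solve(a_mat, r)
  # a(t) = a_ss - V e^{Lambda t} V^{-1} a_ss during infusion,
  # then decays from a(t_inf)
  amt1 <- function(tt) {
    e <- ed$vectors %*% (exp(ed$values * tt) * (vinv %*% a_ss))
    Re(a_ss[1] - e[1])
  }
  a_end <- vapply(1:3, function(j) {
    e <- ed$vectors %*% (exp(ed$values * t_inf) * (vinv %*% a_ss))
    Re(a_ss[j] - e[j])
  }, numeric(1))
  w_end <- vinv %*% a_end
  vapply(t, function(tt) {
    if (tt <= t_inf) amt1(tt) else {
      Re((ed$vectors %*% (exp(ed$values * (tt - t_inf)) * w_end))[1])
    }
  }, numeric(1)) / v1
}

# joint -2 log density of (y, eta) for one subject, all constants included
g_joint <- function(eta, cst, p, om_inv, log_det_2pi_om) {
  # out-of-range or degenerate points get a penalty that still grows with
  # |eta|, so the surface never attracts iterates outward
  penalty <- function() 1e10 + sum(pmin(abs(eta[is.finite(eta)]), 1e6)^2)
  if (any(!is.finite(eta)) || any(abs(eta) > 20)) return(penalty())
  f <- predict_subject(cst, p, eta)
  if (any(f <= 0) || any(!is.finite(f))) return(penalty())
  s2 <- (p$b * f)^2
  v <- sum((cst$y - f)^2 / s2 + log(s2)) + cst$n * LOG2PI +
    drop(t(eta) %*% om_inv %*% eta) + log_det_2pi_om
  if (!is.finite(v)) penalty() else v
}

num_grad <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- rep(0, length(x)); e[j] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

num_hess <- function(fn, x, h = 1e-4) {
  d <- length(x)
  hmat <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    ei <- rep(0, d); ei[i] <- h
    hmat[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < d) for (j in (i + 1):d) {
      ej <- rep(0, d); ej[j] <- h
      hmat[i, j] <- hmat[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * h^2)
    }
  }
  hmat
}

# inner MAP solver: damped Newton with finite-difference derivatives,
# falling back to BFGS if Newton stalls
inner_map <- function(cst, p, om_inv, log_det_2pi_om, eta0, tol = 1e-8,
                      max_iter = 40) {
  fn <- function(e) g_joint(e, cst, p, om_inv, log_det_2pi_om)
  eta <- eta0
  val <- fn(eta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    gr <- num_grad(fn, eta)
    if (sqrt(sum(gr^2)) < tol) { converged <- TRUE; break }
    hs <- num_hess(fn, eta)
    step <- tryCatch(solve(hs + diag(1e-8, length(eta)), gr),
                     error = function(e) gr)
    lambda <- 1
    improved <- FALSE
    for (ls in 1:8) {
      cand <- eta - lambda * step
      vc <- fn(cand)
      if (is.finite(vc) && vc < val - 1e-12) {
        eta <- cand; val <- vc; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  if (!converged) {
    # Newton stalled (indefinite curvature or a line-search dead end):
    # polish with quasi-Newton and keep the better point
    o <- tryCatch(stats::optim(eta, fn, method = "BFGS",
                               control = list(maxit = 300,
                                              reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < val) { eta <- o$par; val <- o$value }
    gr <- num_grad(fn, eta)
    if (sqrt(sum(gr^2)) > tol * 10) {
      for (it in seq_len(10)) {
        gr <- num_grad(fn, eta)
        if (sqrt(sum(gr^2)) < tol) break
        hs <- num_hess(fn, eta)
        step <- tryCatch(solve(hs + diag(1e-8, length(eta)), gr),
                         error = function(e) gr)
        lambda <- 1
        repeat {
          cand <- eta - lambda * step
          vc <- fn(cand)
          if (is.finite(vc) && vc < val) { eta <- cand; val <- vc; break }
          lambda <- lambda / 2
          if (lambda < 1e-6) break
        }
      }
    }
  }
  hs <- num_hess(fn, eta)
  list(eta = eta, value = val, hess = hs)
}

# Laplace -2 log marginal likelihood contribution of one subject
laplace_m2ll_subject <- function(cst, p, om_inv, log_det_2pi_om, eta0) {
  m <- inner_map(cst, p, om_inv, log_det_2pi_om, eta0)
  d <- length(m$eta)
  half_h <- m$hess / 2          # Hessian of -log p(y, eta)
  det_h <- det(half_h)
  if (!is.finite(det_h) || det_h <= 0) {
    # non-PD curvature: fall back to the joint density at the mode
    return(list(m2ll = m$value, eta = m$eta, hess = m$hess))
  }
  list(m2ll = m$value - d * LOG2PI + log(det_h), eta = m$eta,
       hess = m$hess)
}

# ---- exported operations --------------------------------------------------

#' Marginal -2 log-likelihood of a population model on a dataset
#'
#' Integrates the subject-level random effects out of the joint likelihood,
#' per subject, either by the Laplace approximation around the MAP random
#' effects or by importance sampling with the Laplace Gaussian as proposal
#' (the method used for final model comparison; its Monte-Carlo standard
#' error is attached as attribute `"mc_se"`).  Random effects with zero
#' `omega` are fixed at 0.  BLQ records are excluded.
#'
#' @param pop a [population_model()].
#' @param dataset a `treo_dataset`.
#' @param method `"laplace"` or `"importance"`.
#' @param n_is importance samples per subject.
#' @param seed RNG seed for importance sampling (deterministic given seed).
#' @return the scalar -2 log marginal likelihood (MOFV scale).
#' @export
marginal_minus2ll <- function(pop, dataset,
                              method = c("laplace", "importance"),
                              n_is = 300, seed = 1) {
  method <- match.arg(method)
  if (nrow(dataset$records[!dataset$records$blq, ]) == 0) {
    stop("dataset has no quantifiable records")
  }
  p <- list(cl = pop$theta$cl, v1 = pop$theta$v1, q = pop$theta$q,
            v2 = pop$theta$v2, q3 = 0, v3 = 1,
            om_cl = pop$omega[["cl"]], om_v1 = pop$omega[["v1"]],
            om_q = pop$omega[["q"]], corr = pop$corr_cl_v1,
            b = pop$prop_error_b)
  csts <- subject_constants(dataset, pop$ref_weight, pop$beta)
  eta_all <- c("cl", "v1", "q")
  active <- eta_all[c(p$om_cl, p$om_v1, p$om_q) > 0]
  if (length(active) == 0) {
    # no random effects: closed-form Gaussian residual likelihood
    tot <- sum(vapply(csts, function(cst) {
      f <- predict_subject(cst, p, c(0, 0, 0))
      s2 <- (p$b * f)^2
      sum((cst$y - f)^2 / s2 + log(s2)) + cst$n * LOG2PI
    }, numeric(1)))
    return(tot)
  }
  if (!identical(active, eta_all[seq_along(active)])) {
    stop("active random effects must be a leading subset (cl, v1, q)")
  }
  om <- omega_active(p, active)
  om_inv <- solve(om)
  ldo <- determinant(2 * pi * om)$modulus[1]
  d <- length(active)
  total <- 0
  mc_var <- 0
  with_seed(if (method == "importance") seed else NULL, function() {
    for (cst in csts) {
      lap <- laplace_m2ll_subject(cst, p, om_inv, ldo, rep(0, d))
      if (method == "laplace") {
        total <<- total + lap$m2ll
      } else {
        prec <- lap$hess / 2
        covp <- tryCatch(solve(prec), error = function(e) diag(d) * 0.1)
        ed <- eigen(covp, symmetric = TRUE)
        root <- ed$vectors %*% diag(sqrt(pmax(ed$values, 1e-12)), d) %*%
          t(ed$vectors)
        z <- matrix(stats::rnorm(n_is * d), n_is, d)
        etas <- sweep(z %*% root, 2, lap$eta, `+`)
        ldq <- determinant(2 * pi * covp)$modulus[1]
        lw <- vapply(seq_len(n_is), function(k) {
          e <- etas[k, ]
          gj <- g_joint(e, cst, p, om_inv, ldo)
          dq <- -0.5 * (ldq + drop(t(e - lap$eta) %*% prec %*% (e - lap$eta)))
          -gj / 2 - dq
        }, numeric(1))
        mx <- max(lw)
        w <- exp(lw - mx)
        li_log <- mx + log(mean(w))
        total <<- total - 2 * li_log
        mc_var <<- mc_var + 4 * stats::var(w) / (n_is * mean(w)^2)
      }
    }
    NULL
  })
  out <- total
  if (method == "importance") attr(out, "mc_se") <- sqrt(mc_var)
  out
}

crude_init <- function(dataset, structure) {
  nca <- try(nca_dataset(dataset), silent = TRUE)
  subj <- dataset$subjects
  cl0 <- if (!inherits(nca, "try-error")) {
    cl_i <- subj$total_dose / nca$auc_obs
    stats::median(cl_i / (subj$bodyweight / 70)^0.75)
  } else 10
  list(cl = cl0, v1 = cl0 * 1.8, q = cl0 * 0.15, v2 = cl0 * 0.7,
       q3 = if (structure$n_compartments == 3) cl0 * 0.02 else 0,
       v3 = if (structure$n_compartments == 3) cl0 * 0.3 else 1,
       om_cl = 0.3, om_v1 = 0.4, om_q = 0.3, corr = 0.3, b = 0.2)
}

#' Fit the population pharmacokinetic model to a dataset
#'
#' Maximum-likelihood estimation of the population model (typical values,
#' IIV standard deviations, clearance/central-volume correlation and
#' proportional residual error) by direct maximization of the
#' Laplace-approximated marginal likelihood: an inner damped-Newton solver
#' finds each subject's MAP random effects (warm-started across outer
#' iterations) and an outer quasi-Newton run optimizes the transformed
#' population parameters.  Standard errors come from the numerically
#' differentiated observed information; the reported MOFV is recomputed by
#' importance sampling at the final estimates.  Allometric exponents are
#' fixed at 0.75 (clearance) and 1 (volumes), with intercompartmental
#' clearance unscaled, unless `beta` overrides them.
#'
#' @param dataset a `treo_dataset` with at least 5 subjects.
#' @param n_compartments structural model: 1, 2 or 3.
#' @param beta allometric exponents, named as in [population_model()].
#' @param init optional list of natural-scale starting values (fields as
#'   [decode_pars] names: `cl`, `v1`, `q`, `v2`, `om_cl`, `om_v1`, `om_q`,
#'   `corr`, `b`); a crude data-driven heuristic otherwise.
#' @param mofv_method method for the reported final MOFV (`"importance"` or
#'   `"laplace"`).
#' @param n_is importance samples per subject for the final MOFV.
#' @param seed seed for the importance-sampled MOFV.
#' @param max_iter outer iteration cap.
#' @return object of class `fit_result`: `estimates` (a
#'   [population_model()]; for 3 compartments the extra `q3`, `v3` are in
#'   `extra`), `se` and `rse_pct` per free parameter, `minus2ll` (MOFV),
#'   `minus2ll_laplace`, `aic`, `bic`, `shrinkage_pct`, `eta_hat` (matrix of
#'   MAP random effects), `convergence`, `structure`, `npar`,
#'   `n_subjects`, `n_obs`.
#' @export
fit_population <- function(dataset, n_compartments = 2,
                           beta = c(cl = 0.75, v1 = 1, q = 0, v2 = 1),
                           init = NULL,
                           mofv_method = c("importance", "laplace"),
                           n_is = 300, seed = 1, max_iter = 150) {
  mofv_method <- match.arg(mofv_method)
  if (nrow(dataset$subjects) < 5) stop("need at least 5 subjects")
  structure_cfg <- fit_structure(n_compartments)
  csts <- subject_constants(dataset, ref_weight = 70, beta = beta)
  n_obs <- sum(vapply(csts, `[[`, numeric(1), "n"))
  p0 <- utils::modifyList(crude_init(dataset, structure_cfg),
                          if (is.null(init)) list() else init)
  par0 <- encode_pars(p0, structure_cfg)
  d <- length(structure_cfg$eta_names)
  n_subj <- length(csts)
  warm <- matrix(0, n_subj, d)
  # two-compartment (and its one-compartment reduction) run through the
  # batched Laplace evaluator; the three-compartment harness uses the
  # per-subject reference path
  batched <- n_compartments <= 2
  bc <- if (batched) batch_constants(dataset, ref_weight = 70, beta = beta)

  outer_obj <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 20)) return(1e10)
    p <- decode_pars(par, structure_cfg)
    om <- omega_active(p, structure_cfg$eta_names)
    om_inv <- tryCatch(solve(om), error = function(e) NULL)
    if (is.null(om_inv)) return(1e10)
    ldo <- determinant(2 * pi * om)$modulus[1]
    if (batched) {
      bl <- batch_laplace_m2ll(bc, p, om_inv, ldo, warm)
      warm <<- bl$E
      tot <- bl$m2ll
    } else {
      tot <- 0
      for (i in seq_len(n_subj)) {
        lap <- laplace_m2ll_subject(csts[[i]], p, om_inv, ldo, warm[i, ])
        warm[i, ] <<- lap$eta
        tot <- tot + lap$m2ll
      }
    }
    if (!is.finite(tot)) 1e10 else tot
  }

  # forward differences: half the cost of central, and the O(h) truncation
  # error (h = 1e-4) is well below the scale the optimizer needs
  outer_grad <- function(par) {
    f0 <- outer_obj(par)
    h <- 1e-4
    vapply(seq_along(par), function(j) {
      e <- rep(0, length(par)); e[j] <- h
      (outer_obj(par + e) - f0) / h
    }, numeric(1))
  }
  # box bounds keep the search away from the degenerate-parameter plateau;
  # a restart with a fresh state guards against stalls on the flat
  # variance-parameter directions
  ctrl <- list(iter.max = max_iter, eval.max = 3 * max_iter,
               rel.tol = 1e-10)
  opt <- stats::nlminb(par0, outer_obj, gradient = outer_grad,
                       lower = -12, upper = 12, control = ctrl)
  opt2 <- stats::nlminb(opt$par, outer_obj, gradient = outer_grad,
                        lower = -12, upper = 12, control = ctrl)
  if (opt2$objective <= opt$objective) opt <- opt2
  opt$value <- opt$objective
  par_hat <- opt$par

  # observed information on the transformed scale
  hess <- num_hess(outer_obj, par_hat, h = 0.01)

  # Newton polish: nlminb regularly stops with "false convergence" when
  # finite-difference noise dominates; a couple of full Newton steps with
  # the observed information clean up the flat variance directions
  f_cur <- opt$objective
  gr <- outer_grad(par_hat)
  for (np in 1:3) {
    step <- tryCatch(solve(hess + diag(1e-6, nrow(hess)), gr),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    moved <- FALSE
    for (ls in 1:6) {
      cand <- pmin(pmax(par_hat - lambda * step, -12), 12)
      fc <- outer_obj(cand)
      if (is.finite(fc) && fc < f_cur - 1e-10) {
        par_hat <- cand; f_cur <- fc; moved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!moved) break
    gr <- outer_grad(par_hat)
  }
  opt$objective <- opt$value <- f_cur
  # convergence by Newton decrement: predicted remaining improvement of
  # the objective below half an MOFV unit counts as converged
  if (opt$convergence != 0) {
    dec <- tryCatch(drop(t(gr) %*% solve(hess + diag(1e-6, nrow(hess)),
                                         gr)) / 2,
                    error = function(e) Inf)
    if (is.finite(dec) && dec < 0.5) {
      opt$convergence <- 0L
      opt$message <- paste0(opt$message,
                            sprintf(" (accepted: Newton decrement %.3g)",
                                    dec))
    }
  }
  p_hat <- decode_pars(par_hat, structure_cfg)
  cov_t <- tryCatch(2 * solve(hess), error = function(e)
    matrix(NA_real_, length(par_hat), length(par_hat)))
  se_t <- sqrt(pmax(diag(cov_t), 0))
  names(se_t) <- structure_cfg$free

  # MAP random effects and shrinkage at the final estimates
  om <- omega_active(p_hat, structure_cfg$eta_names)
  om_inv <- solve(om)
  ldo <- determinant(2 * pi * om)$modulus[1]
  eta_hat <- if (batched) {
    batch_inner_map(bc, p_hat, om_inv, ldo, matrix(0, n_subj, d))$E
  } else {
    t(vapply(seq_len(n_subj), function(i) {
      inner_map(csts[[i]], p_hat, om_inv, ldo, rep(0, d))$eta
    }, numeric(d)))
  }
  colnames(eta_hat) <- structure_cfg$eta_names
  omega_sd <- sqrt(diag(om))
  shrink <- eta_shrinkage(eta_hat, omega_sd)

  est <- population_model(
    theta = pk_parameters(cl = p_hat$cl, v1 = p_hat$v1,
                          q = max(p_hat$q, 0), v2 = p_hat$v2),
    beta = beta, ref_weight = 70,
    omega = c(cl = p_hat$om_cl, v1 = p_hat$om_v1, q = p_hat$om_q),
    corr_cl_v1 = p_hat$corr, prop_error_b = p_hat$b, add_error = 0)

  m2ll_lap <- opt$objective
  m2ll <- if (mofv_method == "importance") {
    as.numeric(marginal_minus2ll(est, dataset, method = "importance",
                                 n_is = n_is, seed = seed))
  } else m2ll_lap

  npar <- structure_cfg$npar
  # natural-scale SEs by the delta method (log- and atanh-transforms)
  nat <- unlist(p_hat[c("cl", "v1", "q", "v2", "q3", "v3", "om_cl",
                        "om_v1", "om_q", "corr", "b")])
  se_nat <- se_t
  for (nm in names(se_t)) {
    se_nat[nm] <- if (nm == "zcorr") {
      (1 - p_hat$corr^2) * se_t[nm]
    } else {
      exp(par_hat[[match(nm, structure_cfg$free)]]) * se_t[nm]
    }
  }
  structure(list(estimates = est,
                 extra = if (n_compartments == 3)
                   c(q3 = p_hat$q3, v3 = p_hat$v3) else NULL,
                 se = se_nat, rse_pct = 100 * se_t,
                 minus2ll = m2ll, minus2ll_laplace = m2ll_lap,
                 aic = m2ll + 2 * npar,
                 bic = m2ll + npar * log(n_subj),
                 shrinkage_pct = shrink,
                 eta_hat = eta_hat,
                 convergence = opt$convergence,
                 message = opt$message,
                 structure = structure_cfg, npar = npar,
                 n_subjects = n_subj, n_obs = n_obs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Population fit (%d-compartment, %d subjects, %d obs): MOFV %.2f, AIC %.2f, BIC %.2f\n",
    x$structure$n_compartments, x$n_subjects, x$n_obs, x$minus2ll, x$aic,
    x$bic))
  print(x$estimates)
  cat("eta-shrinkage [%]:",
      paste(sprintf("%s %.1f", names(x$shrinkage_pct), x$shrinkage_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio comparison of two nested fits
#'
#' Reports the MOFV difference with the decision thresholds used in model
#' building: a drop of more than 10.8 (chi-square, 1 df, p < 0.001) for
#' forward/structural inclusion and more than 6.67 (p < 0.01) for backward
#' retention, together with AIC/BIC differences.  Refuses the LRT for
#' non-nested structures and then reports information criteria only.
#'
#' @param fit_reduced,fit_full `fit_result`s of the reduced and richer
#'   model; nesting requires the reduced free-parameter set to be a subset.
#' @return list with `delta_mofv` (reduced minus full), `df`,
#'   `significant_forward` (10.8 rule), `significant_backward` (6.67 rule),
#'   `delta_aic`, `delta_bic`, `nested`.
#' @export
compare_models <- function(fit_reduced, fit_full) {
  nested <- all(fit_reduced$structure$free %in% fit_full$structure$free) &&
    fit_reduced$npar < fit_full$npar
  out <- list(delta_aic = fit_reduced$aic - fit_full$aic,
              delta_bic = fit_reduced$bic - fit_full$bic,
              nested = nested)
  if (!nested) {
    out$delta_mofv <- NA_real_
    warning("models are not nested; reporting AIC/BIC only")
    return(out)
  }
  delta <- fit_reduced$minus2ll - fit_full$minus2ll
  out$delta_mofv <- delta
  out$df <- fit_full$npar - fit_reduced$npar
  out$significant_forward <- delta > 10.8
  out$significant_backward <- delta > 6.67
  out
}

#' Eta-shrinkage
#'
#' `100 * (1 - Var(eta_hat) / omega^2)` per random effect: near 0% when the
#' data support individual estimates spanning the population variability,
#' near 100% when sparse data collapse all individuals onto the typical
#' subject.
#'
#' @param eta_hats matrix of empirical Bayes (MAP) random effects, one row
#'   per subject.
#' @param omega vector of estimated IIV standard deviations, one per column.
#' @return shrinkage per random effect, %.
#' @export
eta_shrinkage <- function(eta_hats, omega) {
  eta_hats <- as.matrix(eta_hats)
  if (nrow(eta_hats) < 2) stop("need at least 2 subjects")
  if (any(omega <= 0)) stop("omega must be positive")
  v <- apply(eta_hats, 2, stats::var)
  100 * (1 - v / omega^2)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits each replicate and summarises
#' every estimated parameter by its median and 5th-95th percentile interval.
#' Failed or non-converged replicates are dropped and counted; more than
#' 50% failures aborts.
#'
#' @param dataset a `treo_dataset`.
#' @param n_reps number of bootstrap replicates.
#' @param seed RNG seed.
#' @param ... further arguments passed to [fit_population()].
#' @return object of class `bootstrap_result`: `summary` (data.frame with
#'   `parameter`, `median`, `p5`, `p95`), `estimates` (replicate x
#'   parameter matrix), `n_failed`.
#' @export
bootstrap_population <- function(dataset, n_reps = 200, seed = 1, ...) {
  stopifnot(n_reps >= 1)
  ids <- dataset$subjects$id
  draws <- with_seed(seed, function() {
    lapply(seq_len(n_reps), function(r) sample(ids, length(ids),
                                               replace = TRUE))
  })
  rows <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    bd <- resample_dataset(dataset, draws[[r]])
    fit <- try(fit_population(bd, ...), silent = TRUE)
    if (inherits(fit, "try-error") || fit$convergence != 0) {
      n_failed <- n_failed + 1L
      next
    }
    e <- fit$estimates
    rows[[length(rows) + 1]] <-
      c(cl = e$theta$cl, v1 = e$theta$v1, q = e$theta$q, v2 = e$theta$v2,
        om_cl = e$omega[["cl"]], om_v1 = e$omega[["v1"]],
        om_q = e$omega[["q"]], corr = e$corr_cl_v1, b = e$prop_error_b)
  }
  if (n_failed > n_reps / 2) {
    stop(sprintf("bootstrap aborted: %d of %d replicates failed", n_failed,
                 n_reps))
  }
  est <- do.call(rbind, rows)
  summ <- data.frame(parameter = colnames(est),
                     median = apply(est, 2, stats::median),
                     p5 = apply(est, 2, stats::quantile, 0.05),
                     p95 = apply(est, 2, stats::quantile, 0.95),
                     row.names = NULL)
  structure(list(summary = summ, estimates = est, n_failed = n_failed),
            class = "bootstrap_result")
}

# rebuild a dataset from a resampled id vector (duplicates get fresh ids)
resample_dataset <- function(dataset, ids) {
  subj <- dataset$subjects
  rec <- dataset$records
  new_subj <- do.call(rbind, lapply(seq_along(ids), function(k) {
    s <- subj[subj$id == ids[k], , drop = FALSE]
    s$id <- k
    s
  }))
  new_rec <- do.call(rbind, lapply(seq_along(ids), function(k) {
    r <- rec[rec$id == ids[k], , drop = FALSE]
    r$id <- k
    r
  }))
  new_treo_dataset(new_subj, new_rec, dataset$provenance)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model simulations are normalised by the ratio of the
#' bin-median typical prediction to each record's own typical prediction
#' (prediction correction), which removes the spread caused by different
#' bodyweights and doses.  Per time bin the 5th/50th/95th percentiles of the
#' corrected observations are compared with the 50% and 95% intervals of
#' the same percentiles across `n_sim` full-design simulation replicates.
#'
#' @param dataset a `treo_dataset` (the "observed" data).
#' @param pop the [population_model()] to simulate from.
#' @param n_sim number of simulation replicates (>= 100).
#' @param bins optional numeric vector of bin edges (h); by default each
#'   distinct design time is its own bin (bins with fewer than 2 records are
#'   merged with their neighbour).
#' @param seed RNG seed.
#' @return object of class `vpc_summary`: data.frame `bins` with, per bin,
#'   the median time, record count, observed percentiles (`obs_p5`,
#'   `obs_p50`, `obs_p95`) and simulated bands
#'   (`sim_<p>_lo95/lo50/med/hi50/hi95` for each percentile), plus `n_sim`.
#' @export
pcvpc <- function(dataset, pop, n_sim = 1000, bins = NULL, seed = 1) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  rec <- dataset$records[!dataset$records$blq, , drop = FALSE]
  subj <- dataset$subjects
  # typical (eta = 0) prediction per record
  pred_typ <- vapply(seq_len(nrow(rec)), function(j) {
    i <- match(rec$id[j], subj$id)
    p <- individual_parameters(pop, subj$bodyweight[i])
    concentration(p, subj$total_dose[i], subj$t_inf[i], rec$time[j])
  }, numeric(1))

  if (is.null(bins)) {
    ut <- sort(unique(rec$time))
    cnt <- vapply(ut, function(tt) sum(rec$time == tt), numeric(1))
    while (any(cnt < 2) && length(ut) > 1) {
      k <- which(cnt < 2)[1]
      j <- if (k == 1) 2 else k - 1
      ut <- ut[-k]
      cnt <- vapply(ut, function(tt) numeric(1), numeric(1))
      bin_id_tmp <- vapply(rec$time, function(tt)
        which.min(abs(ut - tt)), numeric(1))
      cnt <- vapply(seq_along(ut), function(k2) sum(bin_id_tmp == k2),
                    numeric(1))
    }
    centers <- ut
  } else {
    centers <- bins
  }
  bin_id <- vapply(rec$time, function(tt) which.min(abs(centers - tt)),
                   numeric(1))
  n_bins <- length(centers)

  pred_bin_med <- vapply(seq_len(n_bins), function(k)
    stats::median(pred_typ[bin_id == k]), numeric(1))
  pc_obs <- rec$conc * pred_bin_med[bin_id] / pred_typ
  qs <- c(0.05, 0.5, 0.95)
  obs_q <- t(vapply(seq_len(n_bins), function(k)
    stats::quantile(pc_obs[bin_id == k], qs, names = FALSE), numeric(3)))

  # simulate replicates on the same design
  noise_free <- function(eta_mat) {
    vapply(seq_len(nrow(rec)), function(j) {
      i <- match(rec$id[j], subj$id)
      p <- individual_parameters(pop, subj$bodyweight[i], eta_mat[i, ])
      concentration(p, subj$total_dose[i], subj$t_inf[i], rec$time[j])
    }, numeric(1))
  }
  sim_q <- array(NA_real_, c(n_sim, n_bins, 3))
  with_seed(seed, function() {
    for (s in seq_len(n_sim)) {
      eta <- sample_random_effects(pop, nrow(subj))
      f <- noise_free(eta)
      eps <- stats::rnorm(length(f), 0, pop$prop_error_b)
      y <- pmax(f * (1 + eps), 0)
      pc_sim <- y * pred_bin_med[bin_id] / pred_typ
      for (k in seq_len(n_bins)) {
        sim_q[s, k, ] <<- stats::quantile(pc_sim[bin_id == k], qs,
                                          names = FALSE)
      }
    }
    NULL
  })
  band <- function(k, j) {
    stats::quantile(sim_q[, k, j], c(0.025, 0.25, 0.5, 0.75, 0.975),
                    names = FALSE)
  }
  out <- data.frame(bin = seq_len(n_bins), time = centers,
                    n_obs = vapply(seq_len(n_bins), function(k)
                      sum(bin_id == k), numeric(1)),
                    obs_p5 = obs_q[, 1], obs_p50 = obs_q[, 2],
                    obs_p95 = obs_q[, 3])
  lab <- c("p5", "p50", "p95")
  for (j in 1:3) {
    bb <- t(vapply(seq_len(n_bins), function(k) band(k, j), numeric(5)))
    out[[paste0("sim_", lab[j], "_lo95")]] <- bb[, 1]
    out[[paste0("sim_", lab[j], "_lo50")]] <- bb[, 2]
    out[[paste0("sim_", lab[j], "_med")]] <- bb[, 3]
    out[[paste0("sim_", lab[j], "_hi50")]] <- bb[, 4]
    out[[paste0("sim_", lab[j], "_hi95")]] <- bb[, 5]
  }
  structure(list(bins = out, n_sim = n_sim), class = "vpc_summary")
}

#' @export
print.vpc_summary <- function(x, ...) {
  cat(sprintf("pcVPC over %d bins, %d simulation replicates\n",
              nrow(x$bins), x$n_sim))
  print(x$bins[, c("bin", "time", "n_obs", "obs_p5", "obs_p50", "obs_p95")])
  invisible(x)
}
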