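# Batched Laplace machinery: evaluates the joint density, its
# finite-difference derivatives in eta, and the per-subject Newton updates
# for ALL subjects simultaneously with matrix arithmetic.  This is the hot
# path of the NLME engine; the per-subject reference implementation in
# popfit.R (g_joint/inner_map) remains the readable specification and the
# two are cross-checked in the tests.

# pack a dataset into padded matrices: TIME/T1/T2/Y are n x m with mask W
batch_constants <- function(dataset, ref_weight = 70,
                            beta = c(cl = 0.75, v1 = 1, q = 0, v2 = 1)) {
  subj <- dataset$subjects
  rec <- dataset$records[!dataset$records$blq, , drop = FALSE]
  n <- nrow(subj)
  counts <- vapply(subj$id, function(i) sum(rec$id == i), numeric(1))
  m <- max(counts)
  TIME <- matrix(1, n, m); Y <- matrix(1, n, m); W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    r <- rec[rec$id == subj$id[i], , drop = FALSE]
    k <- nrow(r)
    if (k > 0) {
      TIME[i, seq_len(k)] <- r$time
      Y[i, seq_len(k)] <- r$conc
      W[i, seq_len(k)] <- 1
    }
  }
  w <- subj$bodyweight / ref_weight
  list(n = n, m = m, counts = counts,
       TIME = TIME, Y = Y, W = W,
       T1 = pmin(TIME, subj$t_inf), T2 = pmax(TIME - subj$t_inf, 0),
       r0 = subj$total_dose / subj$t_inf,
       dose = subj$total_dose, t_inf = subj$t_inf,
       wcl = w^beta[["cl"]], wv1 = w^beta[["v1"]],
       wq = w^beta[["q"]], wv2 = w^beta[["v2"]])
}

# batched two-compartment (or one-compartment when q = 0) prediction;
# E is n x d (d = 2: cl, v1; d = 3: cl, v1, q)
batch_predict <- function(bc, p, E) {
  cl <- p$cl * bc$wcl * exp(E[, 1])
  v1 <- p$v1 * bc$wv1 * exp(E[, 2])
  if (ncol(E) >= 3) {
    q <- p$q * bc$wq * exp(E[, 3])
  } else {
    q <- rep(p$q, bc$n) * bc$wq
  }
  if (all(q <= 0)) {
    k <- cl / v1
    return((bc$r0 / cl) * (1 - exp(-k * bc$T1)) * exp(-k * bc$T2))
  }
  v2 <- p$v2 * bc$wv2
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
  al <- (s + disc) / 2
  be <- pmax((s - disc) / 2, 1e-12)
  A <- (k21 - al) / (al * (be - al))
  B <- (k21 - be) / (be * (al - be))
  # column recycling: length-n vectors multiply down the n x m matrices
  (bc$r0 / v1) * (A * (1 - exp(-al * bc$T1)) * exp(-al * bc$T2) +
                  B * (1 - exp(-be * bc$T1)) * exp(-be * bc$T2))
}

# batched joint -2 log density: returns length-n vector
batch_g <- function(bc, p, E, om_inv, log_det_2pi_om) {
  d <- ncol(E)
  bad_eta <- !is.finite(rowSums(E)) | apply(abs(E) > 20, 1, any)
  E_safe <- E
  E_safe[!is.finite(E_safe)] <- 0
  E_safe[E_safe > 20] <- 20; E_safe[E_safe < -20] <- -20
  f <- batch_predict(bc, p, E_safe)
  bad_f <- rowSums(bc$W * (!is.finite(f) | f <= 0)) > 0
  f[!is.finite(f) | f <= 0] <- 1
  s2 <- (p$b * f)^2
  data_term <- rowSums(bc$W * ((bc$Y - f)^2 / s2 + log(s2))) +
    bc$counts * LOG2PI
  quad <- rowSums((E_safe %*% om_inv) * E_safe)
  g <- data_term + quad + log_det_2pi_om
  bad <- bad_eta | bad_f | !is.finite(g)
  pen_quad <- rowSums(pmin(abs(E_safe), 1e6)^2)
  g[bad] <- 1e10 + pen_quad[bad]
  g
}

# batched gradient and Hessian of batch_g in eta by central differences;
# returns list(grad = n x d, hess = n x d x d)
batch_derivs <- function(bc, p, E, om_inv, ldo, h = 1e-4) {
  n <- nrow(E); d <- ncol(E)
  g0 <- batch_g(bc, p, E, om_inv, ldo)
  gp <- gm <- matrix(0, n, d)
  grad <- matrix(0, n, d)
  for (j in seq_len(d)) {
    Ep <- E; Ep[, j] <- Ep[, j] + h
    Em <- E; Em[, j] <- Em[, j] - h
    gp[, j] <- batch_g(bc, p, Ep, om_inv, ldo)
    gm[, j] <- batch_g(bc, p, Em, om_inv, ldo)
    grad[, j] <- (gp[, j] - gm[, j]) / (2 * h)
  }
  hess <- array(0, c(n, d, d))
  for (j in seq_len(d)) {
    hess[, j, j] <- (gp[, j] - 2 * g0 + gm[, j]) / h^2
  }
  if (d >= 2) {
    for (j in 1:(d - 1)) for (k in (j + 1):d) {
      Epp <- E; Epp[, j] <- Epp[, j] + h; Epp[, k] <- Epp[, k] + h
      Epm <- E; Epm[, j] <- Epm[, j] + h; Epm[, k] <- Epm[, k] - h
      Emp <- E; Emp[, j] <- Emp[, j] - h; Emp[, k] <- Emp[, k] + h
      Emm <- E; Emm[, j] <- Emm[, j] - h; Emm[, k] <- Emm[, k] - h
      hess[, j, k] <- hess[, k, j] <-
        (batch_g(bc, p, Epp, om_inv, ldo) - batch_g(bc, p, Epm, om_inv, ldo) -
           batch_g(bc, p, Emp, om_inv, ldo) +
           batch_g(bc, p, Emm, om_inv, ldo)) / (4 * h^2)
    }
  }
  list(g0 = g0, grad = grad, hess = hess)
}

# closed-form solve of n simultaneous symmetric d x d systems H x = b,
# with a ridge added to keep the step defined near singular curvature
batch_solve <- function(hess, b, ridge = 1e-8) {
  n <- dim(hess)[1]; d <- dim(hess)[2]
  if (d == 2) {
    a11 <- hess[, 1, 1] + ridge; a12 <- hess[, 1, 2]
    a22 <- hess[, 2, 2] + ridge
    det <- a11 * a22 - a12^2
    det[abs(det) < 1e-300] <- 1e-300
    cbind((a22 * b[, 1] - a12 * b[, 2]) / det,
          (a11 * b[, 2] - a12 * b[, 1]) / det)
  } else {
    a11 <- hess[, 1, 1] + ridge; a22 <- hess[, 2, 2] + ridge
    a33 <- hess[, 3, 3] + ridge
    a12 <- hess[, 1, 2]; a13 <- hess[, 1, 3]; a23 <- hess[, 2, 3]
    c11 <- a22 * a33 - a23^2
    c12 <- a13 * a23 - a12 * a33
    c13 <- a12 * a23 - a13 * a22
    c22 <- a11 * a33 - a13^2
    c23 <- a12 * a13 - a11 * a23
    c33 <- a11 * a22 - a12^2
    det <- a11 * c11 + a12 * c12 + a13 * c13
    det[abs(det) < 1e-300] <- 1e-300
    cbind((c11 * b[, 1] + c12 * b[, 2] + c13 * b[, 3]) / det,
          (c12 * b[, 1] + c22 * b[, 2] + c23 * b[, 3]) / det,
          (c13 * b[, 1] + c23 * b[, 2] + c33 * b[, 3]) / det)
  }
}

batch_logdet <- function(hess) {
  d <- dim(hess)[2]
  if (d == 2) {
    det <- hess[, 1, 1] * hess[, 2, 2] - hess[, 1, 2]^2
  } else {
    a11 <- hess[, 1, 1]; a22 <- hess[, 2, 2]; a33 <- hess[, 3, 3]
    a12 <- hess[, 1, 2]; a13 <- hess[, 1, 3]; a23 <- hess[, 2, 3]
    det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a13 * a23) +
      a13 * (a12 * a23 - a13 * a22)
  }
  list(det = det, log = log(pmax(det, 1e-300)))
}

# batched inner MAP: damped Newton for all subjects at once
batch_inner_map <- function(bc, p, om_inv, ldo, E0, tol = 1e-6,
                            max_iter = 40) {
  E <- E0
  val <- batch_g(bc, p, E, om_inv, ldo)
  n <- nrow(E)
  active <- rep(TRUE, n)
  dv <- NULL
  for (it in seq_len(max_iter)) {
    dv <- batch_derivs(bc, p, E, om_inv, ldo)
    val <- dv$g0
    gnorm <- sqrt(rowSums(dv$grad^2))
    active <- gnorm >= tol
    if (!any(active)) break
    step <- batch_solve(dv$hess, dv$grad)
    # fall back to (scaled) gradient direction where the Newton step is
    # not a descent direction or not finite
    desc <- rowSums(step * dv$grad)
    badstep <- !is.finite(desc) | desc <= 0
    step[badstep, ] <- dv$grad[badstep, , drop = FALSE] * 0.1
    lambda <- rep(1, n)
    improved <- rep(FALSE, n)
    for (ls in 1:10) {
      todo <- active & !improved
      if (!any(todo)) break
      cand <- E - step * lambda
      vc <- batch_g(bc, p, cand, om_inv, ldo)
      ok <- todo & is.finite(vc) & (vc < val - 1e-12)
      E[ok, ] <- cand[ok, , drop = FALSE]
      val[ok] <- vc[ok]
      improved <- improved | ok
      lambda[todo & !ok] <- lambda[todo & !ok] / 2
    }
    if (!any(improved)) break
  }
  dv <- batch_derivs(bc, p, E, om_inv, ldo)
  list(E = E, val = dv$g0, grad = dv$grad, hess = dv$hess)
}

# total Laplace -2 log marginal likelihood over all subjects
batch_laplace_m2ll <- function(bc, p, om_inv, ldo, E0) {
  mp <- batch_inner_map(bc, p, om_inv, ldo, E0)
  d <- ncol(mp$E)
  ld <- batch_logdet(mp$hess / 2)
  contrib <- ifelse(ld$det > 0,
                    mp$val - d * LOG2PI + ld$log,
                    mp$val)
  list(m2ll = sum(contrib), E = mp$E, hess = mp$hess, val = mp$val)
}
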