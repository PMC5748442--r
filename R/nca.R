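#' Partial AUC of one segment by the linear-up/log-down rule
#'
#' Rising or flat segments (`c2 >= c1`) use the linear trapezoid
#' `(c1 + c2)(t2 - t1)/2`; falling segments with both concentrations
#' positive use the log trapezoid `(c1 - c2)(t2 - t1)/log(c1/c2)`; segments
#' touching zero fall back to the linear rule.
#'
#' @param t1,c1 earlier time (h) and concentration (mg/L).
#' @param t2,c2 later time and concentration; `t2 > t1` required.
#' @return the partial area, mg*h/L.
#' @examples
#' auc_segment(0, 100, 1, 50)   # log-down: 50 / log(2)
#' auc_segment(0, 50, 1, 100)   # linear-up: 75
#' @export
auc_segment <- function(t1, c1, t2, c2) {
  if (t2 <= t1) stop("auc_segment: t2 must exceed t1")
  if (c1 < 0 || c2 < 0) stop("auc_segment: negative concentration")
  dt <- t2 - t1
  if (c2 >= c1 || c1 == 0 || c2 == 0) {
    (c1 + c2) * dt / 2
  } else {
    (c1 - c2) * dt / log(c1 / c2)
  }
}

#' Terminal elimination rate constant
#'
#' Log-linear regression on the terminal concentrations.  Candidate windows
#' are the last `k` points for `k = 3, ..., n`, never including the peak
#' concentration (or anything before it); the window with the best adjusted
#' R-squared is selected — the usual automatic terminal-phase rule.  The
#' fitted slope must be negative.
#'
#' @param time sampling times, h.
#' @param conc concentrations, mg/L; BLQ records must be removed beforehand.
#' @return list with `lambda_z` (1/h), `n_points`, `adj_r2`, `intercept`
#'   (log scale).
#' @examples
#' t <- c(4, 6, 8, 12)
#' lambda_z(t, 10 * exp(-0.3 * t))
#' @export
lambda_z <- function(time, conc) {
  stopifnot(length(time) == length(conc))
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  keep <- conc > 0
  time <- time[keep]; conc <- conc[keep]
  n <- length(time)
  i_peak <- which.max(conc)
  n_tail <- n - i_peak           # points strictly after the peak
  if (n_tail < 3) stop("lambda_z: need at least 3 positive post-peak records")
  best <- NULL
  for (k in 3:n_tail) {
    idx <- (n - k + 1):n
    fit <- stats::lm.fit(cbind(1, time[idx]), log(conc[idx]))
    slope <- fit$coefficients[2]
    rss <- sum(fit$residuals^2)
    tss <- sum((log(conc[idx]) - mean(log(conc[idx])))^2)
    adj <- if (tss == 0) -Inf else 1 - (rss / (k - 2)) / (tss / (k - 1))
    if (is.finite(slope) && slope < -1e-12 &&
        (is.null(best) || adj > best$adj_r2)) {
      best <- list(lambda_z = unname(-slope), n_points = k,
                   adj_r2 = unname(adj),
                   intercept = unname(fit$coefficients[1]))
    }
  }
  if (is.null(best)) stop("lambda_z: no terminal window with negative slope")
  best
}

#' Non-compartmental AUC from time 0 to infinity
#'
#' Sums linear-up/log-down segments from the infusion-start anchor `(0, 0)`
#' (inserted when the first record is at `t > 0`) through the last
#' quantifiable concentration, then extrapolates the tail as
#' `C_last / lambda_z`.
#'
#' @param time sampling times, h after infusion start.
#' @param conc concentrations, mg/L (BLQ removed).
#' @return object of class `nca_result`: `auc_last`, `auc_inf` (mg*h/L),
#'   `lambda_z` (1/h), `extrapolated_fraction`, `n_points_lambda_z`.
#' @examples
#' t <- candidate_times()
#' p <- pk_parameters(14.7, 26.0, 2.25, 9.93)
#' nca_auc_inf(t, concentration(p, 22200, 2, t))
#' @export
nca_auc_inf <- function(time, conc) {
  stopifnot(length(time) == length(conc), length(time) >= 3)
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]
  if (any(duplicated(time))) stop("duplicate sampling times")
  if (time[1] > 0) {
    time <- c(0, time)
    conc <- c(0, conc)
  }
  lz <- lambda_z(time, conc)
  n <- length(time)
  auc_last <- 0
  for (i in seq_len(n - 1)) {
    auc_last <- auc_last + auc_segment(time[i], conc[i], time[i + 1],
                                       conc[i + 1])
  }
  tail_area <- conc[n] / lz$lambda_z
  auc_inf <- auc_last + tail_area
  structure(list(auc_last = auc_last, auc_inf = auc_inf,
                 lambda_z = lz$lambda_z,
                 extrapolated_fraction = tail_area / auc_inf,
                 n_points_lambda_z = lz$n_points,
                 lambda_z_adj_r2 = lz$adj_r2),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "NCA: AUC0-last %.4g, AUC0-inf %.4g mg*h/L (%.2f%% extrapolated), lambda_z %.4g 1/h (%d pts)\n",
    x$auc_last, x$auc_inf, 100 * x$extrapolated_fraction, x$lambda_z,
    x$n_points_lambda_z))
  invisible(x)
}

#' NCA AUC0-inf for every subject of a dataset
#'
#' BLQ records are removed before analysis; the `(0, 0)` anchor is added per
#' subject.
#'
#' @param dataset a `treo_dataset`.
#' @return data.frame with `id`, `auc_obs` (mg*h/L), `lambda_z`,
#'   `extrapolated_fraction`.
#' @export
nca_dataset <- function(dataset) {
  rec <- dataset$records[!dataset$records$blq, , drop = FALSE]
  ids <- dataset$subjects$id
  res <- lapply(ids, function(i) {
    r <- rec[rec$id == i, ]
    nca_auc_inf(r$time, r$conc)
  })
  data.frame(id = ids,
             auc_obs = vapply(res, `[[`, numeric(1), "auc_inf"),
             lambda_z = vapply(res, `[[`, numeric(1), "lambda_z"),
             extrapolated_fraction =
               vapply(res, `[[`, numeric(1), "extrapolated_fraction"))
}
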