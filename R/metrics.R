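#' Sheiner-Beal prediction-performance metrics
#'
#' Relative prediction error per subject
#' `PE_i = (AUCpred_i - AUCobs_i) / AUCobs_i * 100` and its summaries: mean
#' (MPE, bias), mean absolute (MAPE, accuracy) and root mean square (RMSE,
#' precision), all in percent, plus counts of predictions beyond the +/-20%
#' boundary used for clinical acceptability.
#'
#' @param pred predicted AUC0-inf values, mg*h/L.
#' @param obs observed (reference) AUC0-inf values; all strictly positive.
#' @return object of class `performance_report`: `pe` (vector, %), `mpe`,
#'   `mape`, `rmse` (%), `n_above_20`, `n_below_m20`, `n`.
#' @examples
#' lss_performance(c(110, 90), c(100, 100))
#' @export
lss_performance <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 1) {
    stop("pred and obs must be equal-length, non-empty")
  }
  if (any(!is.finite(obs)) || any(obs <= 0)) {
    stop("observed AUC must be positive")
  }
  pe <- (pred - obs) / obs * 100
  structure(list(pe = pe,
                 mpe = mean(pe),
                 mape = mean(abs(pe)),
                 rmse = sqrt(mean(pe^2)),
                 n_above_20 = sum(pe > 20),
                 n_below_m20 = sum(pe < -20),
                 n = length(pe)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "Prediction performance (n = %d): MPE %.2f%%, MAPE %.2f%%, RMSE %.2f%%; PE > +20%%: %d, PE < -20%%: %d\n",
    x$n, x$mpe, x$mape, x$rmse, x$n_above_20, x$n_below_m20))
  invisible(x)
}

#' Symmetry and range check of the prediction-error distribution
#'
#' @param pe vector of relative prediction errors, %; length >= 3.
#' @return list with sample `skewness` (third standardised moment), `min`,
#'   `max`, and `sign_test_p`, the exact binomial two-sided p-value for a
#'   zero median (zeros dropped).
#' @examples
#' error_distribution_check(c(-5, 0, 5))
#' @export
error_distribution_check <- function(pe) {
  if (length(pe) < 3) stop("need at least 3 errors")
  m <- mean(pe)
  s2 <- mean((pe - m)^2)
  skew <- if (s2 == 0) 0 else mean((pe - m)^3) / s2^1.5
  nz <- pe[pe != 0]
  p <- if (length(nz) == 0) 1 else
    stats::binom.test(sum(nz > 0), length(nz), 0.5)$p.value
  list(skewness = skew, min = min(pe), max = max(pe), sign_test_p = p)
}
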