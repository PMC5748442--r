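#' Split a dataset into learning and validation subgroups
#'
#' Random subject-level split; the two parts are disjoint and exhaustive,
#' and at fraction 0.5 their sizes differ by at most one.
#'
#' @param dataset a `treo_dataset` with at least 4 subjects.
#' @param fraction learning fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `learning` and `validation` datasets.
#' @export
split_learning_validation <- function(dataset, fraction = 0.5, seed = NULL) {
  n <- nrow(dataset$subjects)
  if (n < 4) stop("need at least 4 subjects to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n_learn <- round(fraction * n)
  n_learn <- min(max(n_learn, 1), n - 1)
  ids <- dataset$subjects$id
  learn_ids <- with_seed(seed, function() sort(sample(ids, n_learn)))
  list(learning = subset_dataset(dataset, learn_ids),
       validation = subset_dataset(dataset, setdiff(ids, learn_ids)))
}

#' Subset a dataset by subject id
#'
#' @param dataset a `treo_dataset`.
#' @param ids subject ids to keep.
#' @return the restricted `treo_dataset`.
#' @export
subset_dataset <- function(dataset, ids) {
  dataset$subjects <- dataset$subjects[dataset$subjects$id %in% ids, ,
                                       drop = FALSE]
  dataset$records <- dataset$records[dataset$records$id %in% ids, ,
                                     drop = FALSE]
  dataset
}

#' Enumerate admissible sampling-time subsets
#'
#' All `k`-subsets of the candidate grid whose times lie at or after the end
#' of infusion and exclude 12 h: draws during the infusion are impractical
#' on a clinical ward (strictly before end-of-infusion is excluded; the
#' end-of-infusion time itself is allowed) and the 12-h sample is too late
#' for same-day dose adjustment.
#'
#' @param times candidate grid, h.
#' @param k subset size, 2 or 3.
#' @param t_inf infusion duration, h.
#' @return list of sorted numeric time vectors.
#' @examples
#' length(candidate_subsets(candidate_times(), 2, t_inf = 2))  # 15
#' @export
candidate_subsets <- function(times = candidate_times(), k, t_inf) {
  if (!k %in% c(2, 3)) stop("k must be 2 or 3")
  ok <- times[times >= t_inf & times != 12]
  if (length(ok) < k) return(list())
  cmb <- utils::combn(sort(ok), k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Fit a regression limited-sampling model
#'
#' Ordinary least squares of the reference AUC0-inf on the concentrations at
#' the selected times, over the learning subjects.
#'
#' @param learning a `treo_dataset` (learning subgroup).
#' @param times sampling times of the strategy, h.
#' @param auc_ref data.frame with `id` and `auc_obs`: the reference
#'   (observed) AUC per subject, normally from [nca_dataset()].
#' @return object of class `lss_model`: `times`, `intercept` (mg*h/L),
#'   `coefficients` (h, one per time), `adj_r2`, `r2`, `mode`
#'   (`"regression"`), `n_learning`.
#' @export
fit_lss <- function(learning, times, auc_ref) {
  times <- sort(times)
  if (nrow(learning$subjects) <= length(times) + 1) {
    stop("learning set too small for the number of sampling times")
  }
  ct <- conc_table(learning, times)
  y <- auc_ref$auc_obs[match(ct$id, auc_ref$id)]
  if (any(is.na(y))) stop("missing reference AUC for some learning subjects")
  x <- as.matrix(ct[, -1, drop = FALSE])
  if (qr(cbind(1, x))$rank < ncol(x) + 1) {
    stop("singular design: duplicated or collinear time columns")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(times = times,
                 intercept = unname(stats::coef(fit)[1]),
                 coefficients = unname(stats::coef(fit)[-1]),
                 adj_r2 = sm$adj.r.squared,
                 r2 = sm$r.squared,
                 mode = "regression",
                 n_learning = nrow(ct)),
            class = "lss_model")
}

#' @export
print.lss_model <- function(x, ...) {
  if (x$mode == "regression") {
    terms <- paste(sprintf("%.3g*C_%gh", x$coefficients, x$times),
                   collapse = " + ")
    cat(sprintf("LSS (regression): AUCpred = %s %+.3g  [adj R2 = %.4f]\n",
                terms, x$intercept, x$adj_r2))
  } else {
    cat(sprintf("LSS (Bayesian) from samples at %s h\n",
                paste(x$times, collapse = ", ")))
  }
  invisible(x)
}

#' Bayesian-mode limited-sampling strategy
#'
#' A marker object carrying only the sampling times; prediction goes through
#' MAP estimation of the individual parameters with the population model
#' fixed ([estimate_individual()]).
#'
#' @param times sampling times, h.
#' @return an `lss_model` with `mode = "bayesian"`.
#' @export
bayesian_lss <- function(times) {
  structure(list(times = sort(times), intercept = NA_real_,
                 coefficients = NULL, adj_r2 = NA_real_,
                 mode = "bayesian"),
            class = "lss_model")
}

#' Rank candidate strategies by adjusted R-squared
#'
#' Fits every candidate time subset on the learning subgroup and orders the
#' fitted models by decreasing adjusted R-squared.  Ties are broken
#' deterministically by earliest sampling times, then by fewer samples.
#'
#' @param learning learning `treo_dataset`.
#' @param subsets list of time vectors, e.g. from [candidate_subsets()].
#' @param auc_ref reference AUC table (see [fit_lss()]).
#' @return list of `lss_model`s, best first.
#' @export
rank_strategies <- function(learning, subsets, auc_ref) {
  models <- lapply(subsets, function(tt) fit_lss(learning, tt, auc_ref))
  key_time <- vapply(models, function(m) {
    sum(m$times * 100^(rev(seq_along(m$times)) - 1)) +
      length(m$times) * 1e-3
  }, numeric(1))
  ord <- order(-vapply(models, `[[`, numeric(1), "adj_r2"), key_time)
  models[ord]
}

#' Predict AUC0-inf from a fitted regression strategy
#'
#' @param lss an `lss_model` with `mode = "regression"`.
#' @param conc concentrations at `lss$times` (mg/L): a numeric vector for
#'   one subject or a matrix/data.frame with one column per time.
#' @return predicted AUC0-inf, mg*h/L.
#' @examples
#' m <- structure(list(times = c(2, 6), intercept = 2.94,
#'                     coefficients = c(2.10, 7.73), mode = "regression"),
#'                class = "lss_model")
#' predict_auc(m, c(300, 30))
#' @export
predict_auc <- function(lss, conc) {
  stopifnot(inherits(lss, "lss_model"))
  if (lss$mode != "regression") {
    stop("predict_auc applies to regression strategies; use estimate_individual for Bayesian mode")
  }
  if (is.null(dim(conc))) conc <- matrix(conc, nrow = 1)
  conc <- as.matrix(conc)
  if (ncol(conc) != length(lss$times)) {
    stop("concentrations must match the strategy's sampling times")
  }
  drop(lss$intercept + conc %*% lss$coefficients)
}

#' Evaluate a strategy on a validation subgroup
#'
#' Regression strategies predict from the concentrations at the strategy
#' times; Bayesian strategies re-estimate each subject's parameters by MAP
#' from the reduced dataset and use `dose / Cl_hat`.  Predictions are scored
#' against the observed (NCA) AUC with the Sheiner-Beal metrics.
#'
#' @param lss an `lss_model`.
#' @param validation validation `treo_dataset`.
#' @param auc_ref reference AUC table for the validation subjects.
#' @param pop population model; required for Bayesian mode.
#' @return a `performance_report` (see [lss_performance()]) with the
#'   per-subject predictions attached as attribute `"predictions"`.
#' @export
evaluate_lss <- function(lss, validation, auc_ref, pop = NULL) {
  obs <- auc_ref$auc_obs[match(validation$subjects$id, auc_ref$id)]
  if (lss$mode == "regression") {
    ct <- conc_table(validation, lss$times)
    pred <- predict_auc(lss, as.matrix(ct[, -1, drop = FALSE]))
  } else {
    if (is.null(pop)) stop("Bayesian evaluation needs the population model")
    subj <- validation$subjects
    rec <- validation$records[!validation$records$blq, , drop = FALSE]
    pred <- vapply(seq_len(nrow(subj)), function(i) {
      r <- rec[rec$id == subj$id[i] &
                 rec$time %in% lss$times, , drop = FALSE]
      est <- estimate_individual(pop, bodyweight = subj$bodyweight[i],
                                 dose = subj$total_dose[i],
                                 t_inf = subj$t_inf[i],
                                 time = r$time, conc = r$conc)
      est$auc_hat
    }, numeric(1))
  }
  rep <- lss_performance(pred, obs)
  attr(rep, "predictions") <- data.frame(id = validation$subjects$id,
                                         auc_pred = pred, auc_obs = obs)
  rep
}
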