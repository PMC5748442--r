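#' Candidate sampling-time grid
#'
#' The ten candidate blood-sampling times (hours after infusion start)
#' inspected when developing limited sampling strategies.
#'
#' @return numeric vector of times, h.
#' @export
candidate_times <- function() c(0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 12)

#' Default lower limit of quantification
#'
#' 0.2 micromol/L of treosulfan (molar mass 278.3 g/mol) expressed in mg/L.
#'
#' @return LOQ in mg/L.
#' @export
default_loq <- function() 0.0556

#' Sample bodyweights from a truncated normal
#'
#' Draws i.i.d. bodyweights from a normal distribution truncated to
#' `[lower, upper]`, emulating the bodyweight distribution of the study
#' population (mean 26.9 kg, SD 15.7 kg; realised range in the study
#' 7.7-52 kg).  Sampling uses inverse-CDF transformation, so a fixed seed
#' reproduces the draws exactly.
#'
#' @param n number of subjects.
#' @param mean,sd mean and SD of the untruncated normal, kg.
#' @param lower,upper truncation bounds, kg.
#' @param seed optional RNG seed.
#' @return numeric vector of `n` bodyweights in `[lower, upper]`.
#' @examples
#' sample_bodyweights(5, seed = 1)
#' @export
sample_bodyweights <- function(n, mean = 26.9, sd = 15.7,
                               lower = 5, upper = 55, seed = NULL) {
  stopifnot(n >= 1)
  if (!(lower > 0 && lower < upper)) stop("need 0 < lower < upper")
  if (mean < lower || mean > upper) {
    stop("mean must lie inside the truncation bounds")
  }
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  with_seed(seed, function() {
    u <- stats::runif(n, plo, phi)
    stats::qnorm(u, mean, sd)
  })
}

#' Body surface area from bodyweight
#'
#' Weight-only BSA formula for children:
#' `BSA[cm^2] = 4.688 * BW[g]^(0.8168 - 0.0154 * log10(BW[g]))`,
#' returned in m^2.
#'
#' @param bodyweight bodyweight, kg; vectorised, all positive.
#' @return body surface area, m^2.
#' @examples
#' bsa_from_weight(c(10, 26.9, 70))
#' @export
bsa_from_weight <- function(bodyweight) {
  if (any(!is.finite(bodyweight)) || any(bodyweight <= 0)) {
    stop("bodyweight must be positive (kg)")
  }
  bw_g <- bodyweight * 1000
  bsa_cm2 <- 4.688 * bw_g^(0.8168 - 0.0154 * log10(bw_g))
  bsa_cm2 / 1e4
}

#' Assemble a dosing regimen
#'
#' Total dose is the BSA-normalised dose times the subject's body surface
#' area: `total_dose[mg] = dose_per_bsa[g/m^2] * bsa[m^2] * 1000`.
#'
#' @param dose_per_bsa dose level, g/m^2 (10, 12 or 14 in the study).
#' @param t_inf infusion duration, h (1 or 2 in the study).
#' @param bsa body surface area, m^2.
#' @return list with `dose_per_bsa`, `t_inf`, `total_dose` (mg).
#' @export
dose_regimen <- function(dose_per_bsa, t_inf, bsa) {
  stopifnot(dose_per_bsa > 0, t_inf > 0, bsa > 0)
  list(dose_per_bsa = dose_per_bsa, t_inf = t_inf,
       total_dose = dose_per_bsa * bsa * 1000)
}

new_treo_dataset <- function(subjects, records, provenance = list()) {
  structure(list(subjects = subjects, records = records,
                 provenance = provenance),
            class = "treo_dataset")
}

#' @export
print.treo_dataset <- function(x, ...) {
  cat(sprintf("treo_dataset: %d subjects, %d concentration records (%d BLQ)\n",
              nrow(x$subjects), nrow(x$records), sum(x$records$blq)))
  if (!is.null(x$provenance$design)) {
    cat("  design:", x$provenance$design, "\n")
  }
  invisible(x)
}

simulate_subjects <- function(pop, ids, bodyweight, dose_per_bsa, t_inf,
                              design_times, loq, seed,
                              residual_error = TRUE) {
  n <- length(ids)
  bsa <- bsa_from_weight(bodyweight)
  total_dose <- dose_per_bsa * bsa * 1000
  eta <- sample_random_effects(pop, n, seed = child_seed(seed, "eta"))
  subj <- data.frame(id = ids, bodyweight = bodyweight, bsa = bsa,
                     dose_per_bsa = dose_per_bsa, t_inf = t_inf,
                     total_dose = total_dose,
                     eta_cl = eta[, "cl"], eta_v1 = eta[, "v1"],
                     eta_q = eta[, "q"])
  pars <- lapply(seq_len(n), function(i) {
    individual_parameters(pop, bodyweight[i], eta[i, ])
  })
  subj$cl <- vapply(pars, `[[`, numeric(1), "cl")
  subj$v1 <- vapply(pars, `[[`, numeric(1), "v1")
  subj$q  <- vapply(pars, `[[`, numeric(1), "q")
  subj$v2 <- vapply(pars, `[[`, numeric(1), "v2")
  subj$true_auc <- subj$total_dose / subj$cl

  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    tms <- sort(design_times[[i]])
    cp <- concentration(pars[[i]], total_dose[i], t_inf[i], tms)
    data.frame(id = ids[i], time = tms, conc = cp)
  }))
  if (residual_error) {
    obs <- apply_residual_error(rec$conc, pop,
                                seed = child_seed(seed, "residual"))
    rec$conc <- as.numeric(obs)
  }
  rec$blq <- rec$conc < loq
  new_treo_dataset(subj, rec)
}

#' Simulate a virtual dosing group
#'
#' Generates `n` virtual pediatric subjects for one dosing group: bodyweights
#' from the truncated-normal covariate model, BSA-scaled total dose, random
#' effects from the population IIV model, noise-free two-compartment
#' profiles at the design times, proportional residual error, and flagging
#' of records below the limit of quantification.  Each subject's true
#' exposure `dose / Cl_i` is stored alongside.
#'
#' @param pop a [population_model()].
#' @param dose_per_bsa dose level, g/m^2.
#' @param t_inf infusion duration, h.
#' @param n number of subjects.
#' @param times sampling design, h after infusion start (non-empty, within
#'   0-24 h); default the candidate grid.
#' @param loq limit of quantification, mg/L; records below it are flagged
#'   BLQ and excluded from downstream analysis.
#' @param seed RNG seed (master for this group).
#' @param weight_args optional list overriding [sample_bodyweights()]
#'   arguments (`mean`, `sd`, `lower`, `upper`).
#' @param residual_error apply the proportional residual-error model to the
#'   simulated concentrations (`TRUE`); `FALSE` yields noise-free profiles
#'   carrying interindividual variability only, as used for
#'   limited-sampling-strategy development (see [lss_develop()]).
#' @return a `treo_dataset` with elements `subjects` (one row per subject:
#'   covariates, regimen, random effects, true parameters, true AUC) and
#'   `records` (id, time, conc, blq).
#' @examples
#' ds <- simulate_group(final_model(), 12, 2, n = 10, seed = 1)
#' ds
#' @export
simulate_group <- function(pop, dose_per_bsa, t_inf, n,
                           times = candidate_times(), loq = default_loq(),
                           seed = NULL, weight_args = list(),
                           residual_error = TRUE) {
  if (length(times) == 0) stop("sampling design must be non-empty")
  if (any(times < 0 | times > 24)) stop("design times must lie in [0, 24] h")
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  wa <- utils::modifyList(
    list(n = n, mean = 26.9, sd = 15.7, lower = 5, upper = 55,
         seed = child_seed(seed, "weights")), weight_args)
  bw <- do.call(sample_bodyweights, wa)
  ds <- simulate_subjects(pop, ids = seq_len(n), bodyweight = bw,
                          dose_per_bsa = rep(dose_per_bsa, n),
                          t_inf = rep(t_inf, n),
                          design_times = rep(list(times), n),
                          loq = loq, seed = seed,
                          residual_error = residual_error)
  ds$provenance <- list(seed = seed, loq = loq,
                        residual_error = residual_error,
                        design = sprintf("%gg/m2-%gh x %d", dose_per_bsa,
                                         t_inf, n))
  ds
}

#' Emulate the original 15-patient study dataset
#'
#' Builds a 15-subject dataset with the study's mixed regimens (one subject
#' at 10 g/m^2 over 1 h, four at 12 g/m^2 over 1 h, four at 12 g/m^2 over
#' 2 h, six at 14 g/m^2 over 2 h) and its two sampling schedules: seven
#' subjects sampled at 0.5, 1, 3, 4, 6 and 8 h and eight subjects at 0.5, 1,
#' 1.5, 2, 2.5, 3, 4, 5, 8 and 12 h after infusion start.  Intended for
#' exercising the population-fitting machinery on study-like sparsity.
#'
#' @param pop a [population_model()].
#' @param seed RNG seed.
#' @param loq limit of quantification, mg/L.
#' @return a `treo_dataset` with 15 subjects and 102 records (before BLQ
#'   filtering).
#' @export
emulate_study_dataset <- function(pop, seed = NULL, loq = default_loq()) {
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  dose <- c(10, rep(12, 8), rep(14, 6))
  tinf <- c(1, rep(1, 4), rep(2, 4), rep(2, 6))
  sched_sparse <- c(0.5, 1, 3, 4, 6, 8)
  sched_dense <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 8, 12)
  design <- c(rep(list(sched_sparse), 7), rep(list(sched_dense), 8))
  bw <- sample_bodyweights(15, seed = child_seed(seed, "weights"))
  ds <- simulate_subjects(pop, ids = 1:15, bodyweight = bw,
                          dose_per_bsa = dose, t_inf = tinf,
                          design_times = design, loq = loq, seed = seed)
  ds$provenance <- list(seed = seed, loq = loq, design = "study-emulation")
  ds
}

#' Drop BLQ records from a dataset
#'
#' @param dataset a `treo_dataset`.
#' @return the dataset with records below the limit of quantification
#'   removed (never imputed).
#' @export
drop_blq <- function(dataset) {
  dataset$records <- dataset$records[!dataset$records$blq, , drop = FALSE]
  dataset
}

#' Wide concentration table at selected times
#'
#' @param dataset a `treo_dataset`.
#' @param times times to extract, h; must be present for every subject.
#' @return data.frame with column `id` and one `C_<time>h` column per time.
#' @export
conc_table <- function(dataset, times) {
  rec <- dataset$records
  out <- data.frame(id = dataset$subjects$id)
  for (tt in times) {
    m <- rec[abs(rec$time - tt) < 1e-9, c("id", "conc")]
    col <- m$conc[match(out$id, m$id)]
    if (any(is.na(col))) {
      stop(sprintf("missing concentration at t = %g h for some subjects", tt))
    }
    out[[sprintf("C_%gh", tt)]] <- col
  }
  out
}
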