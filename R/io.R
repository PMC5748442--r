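#' The packaged final population model
#'
#' Loads the final-model configuration shipped with the package (typical
#' values referenced to 70 kg: Cl 14.7 L/h, V1 26.0 L, Q 2.25 L/h, V2
#' 9.93 L; allometric exponents 0.75 for clearance and 1 for volumes, Q
#' unscaled; IIV SDs 0.255/0.514/0.386 for Cl/V1/Q with Cl-V1 correlation
#' 0.714; proportional residual error 0.188).  This model is the default
#' simulation truth throughout the package.
#'
#' @return a [population_model()].
#' @examples
#' final_model()
#' @export
final_model <- function() {
  read_model_config(system.file("extdata", "final_model.yaml",
                                package = "treopk", mustWork = TRUE))
}

#' Read a population-model configuration
#'
#' YAML document whose fields mirror [population_model()]: `theta` (cl, v1,
#' q, v2), `beta`, `ref_weight`, `omega` (cl, v1, q), `corr_cl_v1`,
#' `prop_error_b`, `add_error`.
#'
#' @param path configuration file path.
#' @return a [population_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("theta", "omega", "corr_cl_v1", "prop_error_b")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("model config is missing fields: ", paste(miss, collapse = ", "))
  }
  population_model(
    theta = pk_parameters(cl = cfg$theta$cl, v1 = cfg$theta$v1,
                          q = cfg$theta$q, v2 = cfg$theta$v2),
    beta = unlist(cfg$beta %||% list(cl = 0.75, v1 = 1, q = 0, v2 = 1)),
    ref_weight = cfg$ref_weight %||% 70,
    omega = unlist(cfg$omega),
    corr_cl_v1 = cfg$corr_cl_v1,
    prop_error_b = cfg$prop_error_b,
    add_error = cfg$add_error %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a population model as a YAML configuration
#'
#' @param pop a [population_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(pop, path) {
  yaml::write_yaml(list(
    theta = pop$theta[c("cl", "v1", "q", "v2")],
    beta = as.list(pop$beta),
    ref_weight = pop$ref_weight,
    omega = as.list(pop$omega),
    corr_cl_v1 = pop$corr_cl_v1,
    prop_error_b = pop$prop_error_b,
    add_error = pop$add_error), path)
  invisible(path)
}

#' Write a dataset as a NONMEM-style CSV
#'
#' One dosing row per subject (`EVID = 1`, `AMT` total dose in mg, `RATE`
#' in mg/h, `TIME = 0`) followed by observation rows (`EVID = 0`, `DV` in
#' mg/L, `BLQ` flag).  `BW` (kg) is carried on every row.
#'
#' @param dataset a `treo_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  subj <- dataset$subjects
  rows <- lapply(seq_len(nrow(subj)), function(i) {
    dose_row <- data.frame(ID = subj$id[i], TIME = 0,
                           AMT = subj$total_dose[i],
                           RATE = subj$total_dose[i] / subj$t_inf[i],
                           DV = NA_real_, BW = subj$bodyweight[i],
                           BLQ = 0L, EVID = 1L)
    r <- dataset$records[dataset$records$id == subj$id[i], , drop = FALSE]
    obs <- data.frame(ID = subj$id[i], TIME = r$time, AMT = 0, RATE = 0,
                      DV = r$conc, BW = subj$bodyweight[i],
                      BLQ = as.integer(r$blq), EVID = 0L)
    rbind(dose_row, obs)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = ".")
  invisible(path)
}

#' Read a NONMEM-style CSV dataset
#'
#' Expects columns `ID, TIME, AMT, RATE, DV, BW, BLQ, EVID`; dosing rows
#' (`EVID = 1`) define each subject's total dose and infusion duration
#' (`AMT / RATE`), observation rows carry concentrations.  Validates that
#' observation times are strictly increasing within subject and that no
#' concentration is negative.
#'
#' @param path CSV file path.
#' @return a `treo_dataset`; `true_*` fields are absent for read data.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = c(".", "NA"))
  need <- c("ID", "TIME", "AMT", "RATE", "DV", "BW", "BLQ", "EVID")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  obs <- df[df$EVID == 0, , drop = FALSE]
  if (any(!is.na(obs$DV) & obs$DV < 0)) {
    stop("validation error: negative DV")
  }
  dosing <- df[df$EVID == 1, , drop = FALSE]
  if (any(duplicated(dosing$ID))) stop("multiple dosing rows per subject")
  ids <- unique(df$ID)
  if (!all(ids %in% dosing$ID)) stop("subject without dosing row")
  for (i in ids) {
    tt <- obs$TIME[obs$ID == i]
    if (any(diff(tt) <= 0)) {
      stop(sprintf("validation error: non-monotone times for subject %s", i))
    }
  }
  subj <- data.frame(id = dosing$ID, bodyweight = dosing$BW,
                     bsa = bsa_from_weight(dosing$BW),
                     total_dose = dosing$AMT,
                     t_inf = dosing$AMT / dosing$RATE)
  subj$dose_per_bsa <- subj$total_dose / subj$bsa / 1000
  rec <- data.frame(id = obs$ID, time = obs$TIME, conc = obs$DV,
                    blq = obs$BLQ == 1)
  new_treo_dataset(subj[order(subj$id), ], rec,
                   provenance = list(source = path))
}

# ---- high-level pipeline --------------------------------------------------

#' Default dosing groups of the simulation study
#'
#' @return list of lists with `dose_per_bsa` (g/m^2), `t_inf` (h) and a
#'   `name` label for the three dosing groups.
#' @export
study_groups <- function() {
  list(list(name = "12g-1h", dose_per_bsa = 12, t_inf = 1),
       list(name = "12g-2h", dose_per_bsa = 12, t_inf = 2),
       list(name = "14g-2h", dose_per_bsa = 14, t_inf = 2))
}

#' Develop and validate limited sampling strategies
#'
#' Runs the complete simulation-based LSS workflow: for each dosing group,
#' simulate `n` virtual patients on the candidate grid, compute each
#' subject's observed AUC0-inf by NCA, split into learning and validation
#' halves, exhaustively rank all admissible 2- and 3-point regression
#' strategies on the learning half by adjusted R-squared, validate the best
#' of each size on the validation half, and score Bayesian MAP estimation
#' restricted to the same winning time sets on the full group.
#'
#' @param pop a [population_model()]; the packaged final model by default.
#' @param n subjects per dosing group.
#' @param seed master seed (spawns per-group child seeds).
#' @param groups list of dosing groups (see [study_groups()]).
#' @param modes estimation modes to evaluate: `"regression"`,
#'   `"bayesian"`, or both.
#' @param loq limit of quantification, mg/L.
#' @param residual_error whether to add proportional residual noise to the
#'   simulated profiles; the development workflow uses noise-free profiles
#'   (interindividual variability only) by default, mirroring the
#'   simulation design the strategies were derived under.  Bayesian MAP
#'   estimation still assumes the population residual-error magnitude in
#'   its objective.
#' @return object of class `lss_development`: `results` (one row per group
#'   x size x mode with the fitted equation, adjusted R-squared, and
#'   validation MPE/MAPE/RMSE and exceedance counts), `models`,
#'   `reports`, and `datasets` (per-group simulated `treo_dataset`s).
#' @examples
#' \donttest{
#' dev <- lss_develop(final_model(), n = 40, seed = 1, modes = "regression")
#' dev$results
#' }
#' @export
lss_develop <- function(pop = final_model(), n = 100, seed = 1,
                        groups = study_groups(),
                        modes = c("regression", "bayesian"),
                        loq = default_loq(), residual_error = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  results <- list()
  models <- list()
  reports <- list()
  datasets <- list()
  for (g in groups) {
    gseed <- child_seed(seed, g$name)
    ds <- simulate_group(pop, g$dose_per_bsa, g$t_inf, n, loq = loq,
                         seed = gseed, residual_error = residual_error)
    datasets[[g$name]] <- ds
    auc_ref <- nca_dataset(ds)
    sp <- split_learning_validation(ds, 0.5,
                                    seed = child_seed(gseed, "split"))
    for (k in c(2, 3)) {
      subsets <- candidate_subsets(candidate_times(), k, g$t_inf)
      ranked <- rank_strategies(sp$learning, subsets, auc_ref)
      best <- ranked[[1]]
      key <- sprintf("%s/%dpt", g$name, k)
      models[[paste0(key, "/regression")]] <- best
      if ("regression" %in% modes) {
        rep <- evaluate_lss(best, sp$validation, auc_ref)
        reports[[paste0(key, "/regression")]] <- rep
        results[[length(results) + 1]] <- data.frame(
          group = g$name, k = k, mode = "regression",
          times = paste(best$times, collapse = ","),
          equation = paste0(
            paste(sprintf("%.3g*C%gh", best$coefficients, best$times),
                  collapse = " + "), sprintf(" %+.3g", best$intercept)),
          adj_r2 = best$adj_r2, mpe = rep$mpe, mape = rep$mape,
          rmse = rep$rmse, n_above_20 = rep$n_above_20,
          n_below_m20 = rep$n_below_m20, n = rep$n)
      }
      if ("bayesian" %in% modes) {
        bl <- bayesian_lss(best$times)
        rep <- evaluate_lss(bl, ds, auc_ref, pop = pop)
        models[[paste0(key, "/bayesian")]] <- bl
        reports[[paste0(key, "/bayesian")]] <- rep
        results[[length(results) + 1]] <- data.frame(
          group = g$name, k = k, mode = "bayesian",
          times = paste(bl$times, collapse = ","),
          equation = NA_character_,
          adj_r2 = NA_real_, mpe = rep$mpe, mape = rep$mape,
          rmse = rep$rmse, n_above_20 = rep$n_above_20,
          n_below_m20 = rep$n_below_m20, n = rep$n)
      }
    }
  }
  structure(list(results = do.call(rbind, results), models = models,
                 reports = reports, datasets = datasets,
                 provenance = list(seed = seed, n = n)),
            class = "lss_development")
}

#' @export
print.lss_development <- function(x, ...) {
  cat("LSS development (", x$provenance$n, " subjects/group, seed ",
      x$provenance$seed, "):\n", sep = "")
  print(x$results[, c("group", "k", "mode", "times", "adj_r2", "mpe",
                      "mape", "rmse")], digits = 4)
  invisible(x)
}

#' Evaluate externally specified strategies on a simulated group
#'
#' Fits regression coefficients for the given time sets on the learning
#' half and scores them (and optionally Bayesian MAP estimation at the same
#' times) exactly as [lss_develop()] does for the search winners.  Useful
#' for validating published sampling schedules on fresh virtual cohorts.
#'
#' @param pop a [population_model()].
#' @param group one element of [study_groups()] (or a compatible list).
#' @param time_sets list of numeric time vectors to evaluate.
#' @param n subjects in the simulated group.
#' @param seed RNG seed.
#' @param modes `"regression"`, `"bayesian"`, or both.
#' @param loq limit of quantification, mg/L.
#' @param residual_error add proportional residual noise to the simulated
#'   profiles (see [lss_develop()]).
#' @return data.frame with one row per time set x mode, carrying the fitted
#'   equation (regression), adjusted R-squared and validation metrics.
#' @export
lss_evaluate <- function(pop, group, time_sets, n = 100, seed = 1,
                         modes = c("regression", "bayesian"),
                         loq = default_loq(), residual_error = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  gseed <- child_seed(seed, group$name)
  ds <- simulate_group(pop, group$dose_per_bsa, group$t_inf, n, loq = loq,
                       seed = gseed, residual_error = residual_error)
  auc_ref <- nca_dataset(ds)
  sp <- split_learning_validation(ds, 0.5, seed = child_seed(gseed, "split"))
  out <- list()
  for (tt in time_sets) {
    fitted <- fit_lss(sp$learning, tt, auc_ref)
    if ("regression" %in% modes) {
      rep <- evaluate_lss(fitted, sp$validation, auc_ref)
      out[[length(out) + 1]] <- data.frame(
        group = group$name, times = paste(sort(tt), collapse = ","),
        mode = "regression", adj_r2 = fitted$adj_r2,
        intercept = fitted$intercept,
        coefficients = paste(sprintf("%.4g", fitted$coefficients),
                             collapse = ","),
        mpe = rep$mpe, mape = rep$mape, rmse = rep$rmse,
        n_above_20 = rep$n_above_20, n_below_m20 = rep$n_below_m20)
    }
    if ("bayesian" %in% modes) {
      rep <- evaluate_lss(bayesian_lss(tt), ds, auc_ref, pop = pop)
      out[[length(out) + 1]] <- data.frame(
        group = group$name, times = paste(sort(tt), collapse = ","),
        mode = "bayesian", adj_r2 = NA_real_, intercept = NA_real_,
        coefficients = NA_character_,
        mpe = rep$mpe, mape = rep$mape, rmse = rep$rmse,
        n_above_20 = rep$n_above_20, n_below_m20 = rep$n_below_m20)
    }
  }
  do.call(rbind, out)
}
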