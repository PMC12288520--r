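# Replication experiments: simulation studies that exercise the whole stack
# under known ground truth. Used by the test suite and the acceptance script.

#' Case-cohort recovery experiment
#'
#' Simulates cohorts whose mortality hazard carries a known log-hazard per
#' SD of latent acceleration, draws a Prentice case-cohort sample from each,
#' fits the stratified weighted Cox model with the (SD-scaled) acceleration
#' as exposure, and reports the mean estimated hazard ratio and the coverage
#' of the robust 95% CIs.
#'
#' @param n_reps replicates.
#' @param n subjects per cohort.
#' @param subcohort_fraction sampling fraction.
#' @param hr_per_sd true hazard ratio per SD of the exposure.
#' @param sigma_accel SD (years) of the latent acceleration.
#' @param seed master seed.
#' @return list: `mean_hr`, `coverage` (count of CIs containing the truth),
#'   `estimates` (per-replicate HRs), `n_reps`.
#' @export
experiment_casecohort_recovery <- function(n_reps = 20, n = 8000,
                                           subcohort_fraction = 0.3,
                                           hr_per_sd = 1.4, sigma_accel = 3,
                                           seed = 1L) {
  true_log <- log(hr_per_sd)
  hrs <- numeric(n_reps); covered <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(
      n_subjects = n, n_proteins = 0, n_organs = 0,
      sigma_accel = sigma_accel, lifestyle_effects = c(none = 0),
      gompertz = list(makeham_c = 1e-4, scale_a = 1e-5, rate_b = 0.1,
                      gamma = true_log / sigma_accel),
      seed = derive_seed(seed, 2L * r))
    s <- simulate_cohort(cfg)
    ev <- simulate_survival(s$cohort, s$latent, cfg,
                            seed = derive_seed(seed, 2L * r + 1L))
    cc <- sample_case_cohort(ev, subcohort_fraction,
                             seed = derive_seed(seed, 1000L + r))
    cc <- merge(cc, s$cohort[, c("subject_id", "sex", "center")],
                by = "subject_id")
    cc$accel_z <- s$latent$accel_global[match(cc$subject_id,
                                              s$latent$subject_id)] / sigma_accel
    cc$stratum <- make_strata(cc)
    fit <- fit_stratified_cox(prentice_weights(cc), "accel_z")
    hrs[r] <- fit$hr
    if (fit$ci_low <= hr_per_sd && hr_per_sd <= fit$ci_high)
      covered <- covered + 1L
  }
  list(mean_hr = mean(hrs), coverage = covered, estimates = hrs,
       n_reps = n_reps)
}

#' Lasso selection recovery experiment
#'
#' Each replicate simulates organ-specific accelerations for
#' `n_candidates` organs, of which the first `n_true` drive the hazard, then
#' runs [lasso_cox_select()] on the Prentice-weighted case-cohort sample
#' with all candidate gap z-scores and counts true and false selections.
#'
#' @param n_reps replicates.
#' @param n subjects.
#' @param n_true truly hazardous organ gaps.
#' @param n_candidates candidate organ gaps.
#' @param hr_per_sd hazard ratio per SD of each true gap.
#' @param subcohort_fraction sampling fraction.
#' @param seed master seed.
#' @return list: `full_recovery` (replicates selecting all true gaps),
#'   `mean_false` (average false selections), per-replicate details.
#' @export
experiment_lasso_recovery <- function(n_reps = 20, n = 8000, n_true = 3,
                                      n_candidates = 11, hr_per_sd = 1.3,
                                      subcohort_fraction = 0.3, seed = 1L) {
  sigma_organ <- 3
  gamma <- log(hr_per_sd) / sigma_organ
  n_full <- 0L; n_false <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(
      n_subjects = n, n_proteins = 0, n_organs = n_candidates,
      sigma_accel = 0, sigma_organ = sigma_organ,
      lifestyle_effects = c(none = 0),
      gompertz = list(makeham_c = 1e-4, scale_a = 1e-5, rate_b = 0.1,
                      gamma = gamma),
      seed = derive_seed(seed, 3L * r))
    s <- simulate_cohort(cfg)
    organs <- paste0("accel_organ", seq_len(n_candidates))
    risk <- rowSums(s$latent[, organs[seq_len(n_true)], drop = FALSE])
    ev <- simulate_survival(s$cohort, s$latent, cfg, risk = risk,
                            seed = derive_seed(seed, 3L * r + 1L))
    cc <- sample_case_cohort(ev, subcohort_fraction,
                             seed = derive_seed(seed, 2000L + r))
    cc <- merge(cc, s$cohort[, c("subject_id", "sex", "center")],
                by = "subject_id")
    gaps <- s$latent[match(cc$subject_id, s$latent$subject_id), organs] /
      sigma_organ
    names(gaps) <- paste0("g", seq_len(n_candidates))
    cc <- cbind(cc, gaps)
    cc$stratum <- cc$sex   # only sex structures this simulation
    sel <- suppressWarnings(
      lasso_cox_select(prentice_weights(cc), paste0("g", seq_len(n_candidates)),
                       seed = derive_seed(seed, 3000L + r),
                       nlambda = 30, lambda.min.ratio = 0.05))
    true_set <- paste0("g", seq_len(n_true))
    if (all(true_set %in% sel$selected)) n_full <- n_full + 1L
    n_false[r] <- length(setdiff(sel$selected, true_set))
  }
  list(full_recovery = n_full, mean_false = mean(n_false),
       n_false = n_false, n_reps = n_reps)
}

#' Ensemble dominance experiment
#'
#' Replicates the shared-signal / independent-noise structure behind the
#' Global clock: five clock gaps, each the common signal (SD 2 years) plus
#' independent noise (SD 2 years). Counts the replicates in which the
#' ensemble gap correlates more strongly with the signal than every single
#' clock does (in expectation sqrt(5/6) = 0.913 vs 1/sqrt(2) = 0.707).
#'
#' @param n_reps replicates.
#' @param n subjects per replicate.
#' @param seed master seed.
#' @return list: `wins`, `n_reps`, mean ensemble and individual correlations.
#' @export
experiment_ensemble_dominance <- function(n_reps = 50, n = 1000, seed = 1L) {
  wins <- 0L; cg <- numeric(n_reps); ci <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, 500L + r))
    signal <- stats::rnorm(n, 0, 2)
    ids <- sprintf("S%05d", seq_len(n))
    gaps <- lapply(1:5, function(k)
      stats::setNames(signal + stats::rnorm(n, 0, 2), ids))
    names(gaps) <- paste0("clock", 1:5)
    gg <- global_gap(gaps)
    cors <- vapply(gaps, function(g) stats::cor(g, signal), numeric(1))
    cg[r] <- stats::cor(gg$gap, signal)
    ci[r] <- max(cors)
    if (cg[r] > ci[r]) wins <- wins + 1L
  }
  list(wins = wins, n_reps = n_reps, mean_cor_global = mean(cg),
       mean_cor_best_individual = mean(ci))
}

#' Smoking-contrast recovery experiment
#'
#' Simulates a cohort in which current smoking adds one year of latent
#' acceleration, builds an age-gap with total SD 3 years (acceleration plus
#' independent clock error), z-scores it, and regresses it on smoking
#' category within the cohort. The never-vs-heavy-smoker contrast should
#' recover about -1/3 SD.
#'
#' @param n subjects.
#' @param accel_diff_years acceleration difference (years) between smokers
#'   and never-smokers.
#' @param gap_sd total SD of the age gap (years).
#' @param seed master seed.
#' @return list: `contrast` (never vs heavy smokers, SD units), `se`,
#'   `expected` (-accel_diff_years / gap_sd), `n`.
#' @export
experiment_smoker_contrast <- function(n = 6000, accel_diff_years = 1,
                                       gap_sd = 3, seed = 1L) {
  cfg <- sim_config(
    n_subjects = n, n_proteins = 0, n_organs = 0, sigma_accel = 2.5,
    lifestyle_effects = c(smoking_current = accel_diff_years),
    seed = derive_seed(seed, 600L))
  s <- simulate_cohort(cfg)
  d <- s$cohort
  accel <- s$latent$accel_global
  set.seed(derive_seed(seed, 601L))
  noise_var <- max(gap_sd^2 - stats::var(accel), 0)
  gap <- accel + stats::rnorm(n, 0, sqrt(noise_var))
  names(gap) <- d$subject_id
  d$gap_z <- unname(zscore_gaps(gap)[d$subject_id])
  d$smoking_cat <- factor(
    ifelse(d$smoking_status == "never", "never",
    ifelse(d$smoking_status == "former", "former",
    ifelse(d$cigarettes_day >= 16, "heavy", "light"))),
    levels = c("heavy", "light", "former", "never"))
  res <- gap_on_factor(d, "gap_z", "smoking_cat")
  nev <- res[res$category == "never", ]
  list(contrast = nev$estimate, se = nev$se,
       expected = -accel_diff_years / gap_sd, n = n)
}
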