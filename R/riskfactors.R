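# Cross-sectional linear models of age-gap z-scores on lifestyle factors,
# and the 0-20 healthy lifestyle index (HLI).

#' Default healthy lifestyle index cutpoints
#'
#' Reads the editable cutpoint configuration shipped with the package
#' (`inst/extdata/hli_cutpoints.yaml`). Each of the five components (BMI,
#' smoking, alcohol, diet, physical activity) is scored 0-4 with higher
#' values healthier; the cutpoints are data, not code, and can be replaced
#' by any file with the same structure.
#'
#' @param path optional path to an alternative YAML file.
#' @return a named list of component definitions.
#' @export
default_hli_cutpoints <- function(path = system.file("extdata",
                                                     "hli_cutpoints.yaml",
                                                     package = "protage")) {
  yaml::read_yaml(path)
}

score_bins <- function(x, breaks, scores) {
  chk(!is.unsorted(breaks, strictly = TRUE),
      "cutpoint breaks must be strictly increasing (overlapping bins)")
  chk(length(scores) == length(breaks) + 1,
      "need one score per bin (length(breaks) + 1)")
  scores[findInterval(x, breaks) + 1L]
}

#' Compute the healthy lifestyle index
#'
#' Sums five 0-4 component scores (BMI, smoking, alcohol, diet, physical
#' activity) into a 0-20 total, and assigns quintiles of the total over the
#' scoring population (sample quantiles; ties go to the lower quintile).
#'
#' @param profile data.frame with columns `bmi`, `smoking_status`,
#'   `cigarettes_day`, `alcohol_gday`, `diet_score`, `activity_met`.
#' @param cutpoints configuration as returned by [default_hli_cutpoints()].
#' @return data.frame with the five component scores, `hli_total` (0-20) and
#'   `hli_quintile` (1-5).
#' @export
compute_hli <- function(profile, cutpoints = default_hli_cutpoints()) {
  need <- c("bmi", "smoking_status", "cigarettes_day", "alcohol_gday",
            "diet_score", "activity_met")
  chk(all(need %in% names(profile)), "profile lacks columns: ",
      paste(setdiff(need, names(profile)), collapse = ", "))
  chk(all(profile$alcohol_gday >= 0) && all(profile$activity_met >= 0) &&
        all(profile$cigarettes_day >= 0),
      "continuous lifestyle values must be non-negative")
  sm <- cutpoints$smoking
  smoking <- ifelse(profile$smoking_status == "never", sm$never,
             ifelse(profile$smoking_status == "former", sm$former,
                    score_bins(profile$cigarettes_day,
                               unlist(sm$current_breaks),
                               unlist(sm$current_scores))))
  out <- data.frame(
    score_bmi = score_bins(profile$bmi, unlist(cutpoints$bmi$breaks),
                           unlist(cutpoints$bmi$scores)),
    score_smoking = smoking,
    score_alcohol = score_bins(profile$alcohol_gday,
                               unlist(cutpoints$alcohol$breaks),
                               unlist(cutpoints$alcohol$scores)),
    score_diet = score_bins(profile$diet_score, unlist(cutpoints$diet$breaks),
                            unlist(cutpoints$diet$scores)),
    score_activity = score_bins(profile$activity_met,
                                unlist(cutpoints$activity$breaks),
                                unlist(cutpoints$activity$scores)))
  chk(all(as.matrix(out) >= 0 & as.matrix(out) <= 4), "component scores must be 0-4")
  out$hli_total <- rowSums(out)
  qs <- stats::quantile(out$hli_total, probs = seq(0.2, 0.8, by = 0.2),
                        names = FALSE)
  # ties assigned to the lower quintile: right-closed bins (-inf, q20], ...
  out$hli_quintile <- findInterval(out$hli_total, qs, left.open = TRUE) + 1L
  out
}

#' Regress an age-gap z-score on a categorical lifestyle factor
#'
#' Ordinary least squares of the gap z-score on a categorical factor
#' (reference = first level, by convention the least healthy category) with
#' adjustment covariates, typically age, sex and center. Run within the
#' subcohort for a representative cross-section.
#'
#' @param data data.frame containing the gap column, the factor and the
#'   adjustment columns.
#' @param gap_col name of the gap z-score column.
#' @param factor_col name of the categorical factor column; coerced to a
#'   factor whose first level is the reference.
#' @param adjust adjustment covariate names (default age, sex, center).
#' @return data.frame with one row per non-reference category: estimate (SD
#'   units), se, ci_low, ci_high, p, n.
#' @export
gap_on_factor <- function(data, gap_col, factor_col,
                          adjust = c("age", "sex", "center")) {
  f <- data[[factor_col]]
  if (!is.factor(f)) f <- factor(f)
  counts <- table(f)
  if (any(counts == 0)) {
    warning("dropping empty categories: ",
            paste(names(counts)[counts == 0], collapse = ", "))
    f <- droplevels(f)
  }
  chk(sum(f == levels(f)[1]) >= 2, "reference category needs >= 2 observations")
  d <- data
  d$..factor <- f
  fm <- stats::as.formula(paste(gap_col, "~ ..factor +",
                                paste(adjust, collapse = " + ")))
  fit <- stats::lm(fm, data = d)
  sm <- summary(fit)$coefficients
  rows <- grep("^\\.\\.factor", rownames(sm))
  data.frame(
    factor = factor_col,
    category = sub("^\\.\\.factor", "", rownames(sm)[rows]),
    reference = levels(f)[1],
    estimate = sm[rows, 1], se = sm[rows, 2],
    ci_low = sm[rows, 1] - 1.96 * sm[rows, 2],
    ci_high = sm[rows, 1] + 1.96 * sm[rows, 2],
    p = sm[rows, 4], n = length(stats::fitted(fit)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Mutually adjusted risk-factor model per clock
#'
#' One OLS per clock of the gap z-score on all risk factors simultaneously
#' (continuous factors should be standardized by the caller where declared
#' so), plus adjustment covariates. Returns the clock x factor coefficient
#' matrix for heatmap export together with the full coefficient table.
#'
#' @param data data.frame with one gap column per clock plus factor and
#'   adjustment columns.
#' @param gap_cols named character vector or character vector of gap z-score
#'   columns (one per clock).
#' @param factors character vector of risk-factor columns.
#' @param adjust adjustment covariates.
#' @return list with `coef` (matrix clocks x factor terms) and `table`
#'   (long data.frame with estimate, se, p per clock and term).
#' @export
gap_on_factors_mutual <- function(data, gap_cols, factors,
                                  adjust = c("age", "sex", "center")) {
  rhs <- paste(c(factors, adjust), collapse = " + ")
  tabs <- lapply(gap_cols, function(gc) {
    fit <- stats::lm(stats::as.formula(paste(gc, "~", rhs)), data = data)
    if (any(is.na(stats::coef(fit)))) {
      stop("rank-deficient design; aliased columns: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    X <- stats::model.matrix(fit)
    fcols <- colnames(X)[attr(X, "assign") %in% seq_along(factors)]
    data.frame(clock = gc, term = fcols, estimate = sm[fcols, 1],
               se = sm[fcols, 2], p = sm[fcols, 4],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  terms <- unique(tab$term)
  mat <- matrix(NA_real_, length(gap_cols), length(terms),
                dimnames = list(gap_cols, terms))
  for (r in seq_len(nrow(tab))) mat[tab$clock[r], tab$term[r]] <- tab$estimate[r]
  list(coef = mat, table = tab)
}
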