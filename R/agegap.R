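# Age gaps: lowess detrending of clock predictions, z-scoring, the Global
# ensemble gap and the per-z to per-year conversion.

#' Lowess-detrended age gap
#'
#' Fits a locally weighted linear scatterplot smoother (tricube kernel,
#' span `fraction`, no robustifying iterations by default) of predicted age
#' on chronological age, evaluated at every observed age, and returns
#' `gap_i = predicted_i - smooth(chronological_i)` in years. Detrending
#' against the smoother rather than the identity removes both the regression-
#' to-the-mean compression of clock predictions and any non-linearity in the
#' predicted-vs-chronological relationship, so the gap is uncorrelated with
#' chronological age by construction.
#'
#' @param predicted named numeric vector of clock-predicted ages.
#' @param chronological named numeric vector of chronological ages (same
#'   subject keys as `predicted`).
#' @param fraction smoother span in (0, 1]; default 2/3.
#' @param iterations robustifying iterations (default 0).
#' @return named numeric vector of gaps (years).
#' @export
lowess_detrend <- function(predicted, chronological, fraction = 2/3,
                           iterations = 0) {
  chk(is_num1(fraction) && fraction > 0 && fraction <= 1,
      "fraction must lie in (0, 1]")
  chk(length(predicted) >= 10, "need at least 10 subjects")
  chk(!is.null(names(predicted)) && !is.null(names(chronological)),
      "predicted and chronological must be named by subject_id")
  chk(setequal(names(predicted), names(chronological)),
      "predicted and chronological must cover the same subjects")
  chrono <- chronological[names(predicted)]
  o <- order(chrono)
  sm <- stats::lowess(chrono[o], predicted[o], f = fraction,
                      iter = iterations, delta = 0)
  gap <- predicted
  gap[o] <- predicted[o] - sm$y
  gap
}

#' Z-score age gaps over a scoring population
#'
#' Standardizes gaps with the mean and SD (n - 1 convention) computed over
#' the stated scoring population, applied to all subjects.
#'
#' @param gaps named numeric vector of gaps (years).
#' @param population subject IDs defining the scoring population (default:
#'   all subjects).
#' @return named numeric vector of gap z-scores.
#' @export
zscore_gaps <- function(gaps, population = names(gaps)) {
  chk(!is.null(names(gaps)), "gaps must be named by subject_id")
  chk(all(population %in% names(gaps)), "population contains unknown subjects")
  chk(length(population) >= 2, "scoring population must have at least 2 subjects")
  g <- gaps[population]
  s <- sd1(g)
  chk(s > 0, "scoring-population SD of gaps must be > 0")
  (gaps - mean(g)) / s
}

#' Global ensemble age gap
#'
#' The Global gap is the unweighted mean of per-clock gaps for each subject,
#' subsequently z-scored. Averaging clocks that share a biological-age signal
#' but carry independent error reduces the error variance, which is why the
#' ensemble gap tracks the latent signal more closely than any single clock.
#'
#' @param gaps_by_clock named list of named gap vectors, one per clock
#'   (at least two clocks; every clock must cover the same subject set —
#'   clocks with missing subjects are an error, not averaged pairwise).
#' @param population scoring population passed to [zscore_gaps()].
#' @return list with components `gap` (years) and `gap_z`.
#' @export
global_gap <- function(gaps_by_clock, population = NULL) {
  chk(is.list(gaps_by_clock) && length(gaps_by_clock) >= 2,
      "need at least 2 clocks")
  subjects <- names(gaps_by_clock[[1]])
  for (nm in names(gaps_by_clock)) {
    chk(setequal(names(gaps_by_clock[[nm]]), subjects),
        "clock '", nm, "' does not cover the common subject set")
  }
  m <- vapply(gaps_by_clock, function(g) g[subjects], numeric(length(subjects)))
  gap <- rowMeans(m)
  names(gap) <- subjects
  if (is.null(population)) population <- subjects
  list(gap = gap, gap_z = zscore_gaps(gap, population))
}

#' Convert a per-z log hazard to a per-year hazard ratio
#'
#' One gap z-score unit spans `gap_sd` years, so the hazard ratio per year
#' of age gap is `exp(logHR_per_z / gap_sd)`.
#'
#' @param logHR_per_z log hazard ratio per gap z-score.
#' @param gap_sd SD of the gap (years), > 0.
#' @return hazard ratio per year of age gap.
#' @export
per_year_effect <- function(logHR_per_z, gap_sd) {
  chk(all(is.finite(logHR_per_z)), "logHR_per_z must be finite")
  chk(is_num1(gap_sd) && gap_sd > 0, "gap_sd must be a positive number")
  exp(logHR_per_z / gap_sd)
}

#' Build an age-gap table for a set of clocks
#'
#' Applies [lowess_detrend()] and [zscore_gaps()] per clock and appends the
#' Global ensemble (unweighted mean over the supplied clocks).
#'
#' @param predicted_by_clock named list of predicted-age vectors.
#' @param chronological named chronological ages.
#' @param fraction lowess span.
#' @param global_name label for the ensemble row group (default "Global");
#'   set to `NULL` to omit the ensemble.
#' @param global_clocks clocks to include in the ensemble (default: all).
#' @return data.frame with columns subject_id, clock, predicted_age, gap,
#'   gap_z.
#' @export
age_gap_table <- function(predicted_by_clock, chronological, fraction = 2/3,
                          global_name = "Global",
                          global_clocks = names(predicted_by_clock)) {
  gaps <- lapply(predicted_by_clock, lowess_detrend, chronological = chronological,
                 fraction = fraction)
  rows <- lapply(names(gaps), function(nm) {
    g <- gaps[[nm]]
    data.frame(subject_id = names(g), clock = nm,
               predicted_age = unname(predicted_by_clock[[nm]][names(g)]),
               gap = unname(g), gap_z = unname(zscore_gaps(g)),
               stringsAsFactors = FALSE)
  })
  if (!is.null(global_name) && length(global_clocks) >= 2) {
    gg <- global_gap(gaps[global_clocks])
    pred <- rowMeans(vapply(predicted_by_clock[global_clocks],
                            function(p) p[names(gg$gap)],
                            numeric(length(gg$gap))))
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = names(gg$gap), clock = global_name,
      predicted_age = unname(pred), gap = unname(gg$gap),
      gap_z = unname(gg$gap_z), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
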