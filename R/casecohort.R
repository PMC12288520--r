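# Case-cohort survival inference: Prentice risk-set construction, a
# stratified left-truncated Cox partial-likelihood engine (Breslow ties,
# Newton-Raphson, robust sandwich variance grouped by subject), BH-FDR,
# Harrell's concordance, lasso clock selection and lag sensitivity.

#' Build analysis strata from sex, center and 5-year age bands
#'
#' @param data data.frame with `sex`, `center` and an age column.
#' @param age_col name of the age column used for banding (recruitment age).
#' @param width age band width in years.
#' @param origin band origin; bands are `[origin + k*width, origin + (k+1)*width)`
#'   so the default aligns bands to multiples of 5.
#' @return character vector of stratum keys.
#' @export
make_strata <- function(data, age_col = "entry_age", width = 5, origin = 0) {
  band <- floor((data[[age_col]] - origin) / width) * width + origin
  paste(data$sex, data$center, sprintf("[%g,%g)", band, band + width), sep = "|")
}

#' Apply Prentice risk-set entry rules to a case-cohort sample
#'
#' Subcohort members (cases and non-cases) are at risk from their entry age
#' to their exit age with weight 1. Cases outside the subcohort enter the
#' risk set only just before their own failure (`exit_age - eps`), so they
#' contribute their own failure but stand in no other risk sets. A
#' non-subcohort non-case violates the design and is rejected.
#'
#' @param records case-cohort event table with columns `subject_id`,
#'   `entry_age`, `exit_age`, `event`, `in_subcohort` (plus covariates).
#' @param eps late-entry offset in years (default 1e-6; estimates are
#'   insensitive to it over 1e-4 to 1e-8).
#' @return `records` with `start`, `stop` and `weight` columns added.
#' @export
prentice_weights <- function(records, eps = 1e-6) {
  chk(all(c("subject_id", "entry_age", "exit_age", "event", "in_subcohort")
          %in% names(records)), "records lack required case-cohort columns")
  bad <- !records$in_subcohort & !records$event
  chk(!any(bad), "design violation: ", sum(bad),
      " non-subcohort non-case record(s) present")
  records$start <- ifelse(records$in_subcohort, records$entry_age,
                          records$exit_age - eps)
  records$stop <- records$exit_age
  records$weight <- 1
  attr(records, "prentice_eps") <- eps
  records
}

# ---- Cox partial-likelihood engine (Breslow ties) --------------------------

# Precompute per-stratum sort orders and event structure; invariant across
# Newton iterations.
cox_prepare <- function(start, stop, event, X, strata, weights) {
  split_idx <- split(seq_along(stop), strata)
  strata_dropped <- 0L
  out <- list()
  for (s in names(split_idx)) {
    idx <- split_idx[[s]]
    ev <- idx[event[idx]]
    if (length(ev) == 0) { strata_dropped <- strata_dropped + 1L; next }
    dtimes <- sort(unique(stop[ev]))
    o_stop <- idx[order(stop[idx])]
    o_start <- idx[order(start[idx])]
    out[[s]] <- list(
      idx = idx, ev = ev, dtimes = dtimes,
      o_stop = o_stop, o_start = o_start,
      # for each event time: rows with stop >= t / start >= t via prefix sums
      n_stop_lt = findInterval(dtimes, stop[o_stop], left.open = TRUE),
      n_start_lt = findInterval(dtimes, start[o_start], left.open = TRUE),
      d = as.vector(rowsum(weights[ev], stop[ev])),          # keyed by sorted unique stop
      sum_wx = rowsum(weights[ev] * X[ev, , drop = FALSE], stop[ev]))
  }
  list(strata = out, strata_dropped = strata_dropped)
}

# suffix sums of M rows with key >= t, using precomputed order and counts
suffix_ge <- function(M, ord, n_lt) {
  cs <- apply(M[ord, , drop = FALSE], 2, cumsum)
  cs <- rbind(0, cs)
  tot <- cs[nrow(cs), ]
  sweep(-cs[n_lt + 1L, , drop = FALSE], 2, tot, "+")
}

# log-likelihood, score and information at beta
cox_quantities <- function(prep, start, stop, event, X, weights, beta,
                           want_resid = FALSE, subject = NULL) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  resid <- if (want_resid) matrix(0, length(eta), p) else NULL
  for (st in prep$strata) {
    idx <- st$idx
    M <- max(eta[idx])
    q0 <- weights[idx] * exp(eta[idx] - M)
    Xs <- X[idx, , drop = FALSE]
    Q <- cbind(q0, q0 * Xs,
               q0 * Xs[, pairs[, 1], drop = FALSE] * Xs[, pairs[, 2], drop = FALSE])
    ord_stop <- match(st$o_stop, idx)
    ord_start <- match(st$o_start, idx)
    S <- suffix_ge(Q, ord_stop, st$n_stop_lt) -
      suffix_ge(Q, ord_start, st$n_start_lt)
    S0 <- S[, 1]
    S1 <- S[, 2:(p + 1), drop = FALSE]
    S2 <- S[, -(1:(p + 1)), drop = FALSE]
    d <- st$d
    ll <- ll + sum(weights[st$ev] * eta[st$ev]) - sum(d * (log(S0) + M))
    r <- S1 / S0
    U <- U + colSums(st$sum_wx) - colSums(d * r)
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      v <- sum(d * (S2[, k] / S0 - r[, a] * r[, b]))
      I[a, b] <- I[a, b] + v
      if (a != b) I[b, a] <- I[b, a] + v
    }
    if (want_resid) {
      as_k <- d / S0                       # scaled by e^{M}: pairs with exp(eta - M)
      cumA <- c(0, cumsum(as_k))
      cumB <- rbind(0, apply(as_k * r, 2, cumsum))
      fi_stop <- findInterval(stop[idx], st$dtimes)
      fi_start <- findInterval(start[idx], st$dtimes)
      A_i <- cumA[fi_stop + 1L] - cumA[fi_start + 1L]
      B_i <- cumB[fi_stop + 1L, , drop = FALSE] - cumB[fi_start + 1L, , drop = FALSE]
      term2 <- exp(eta[idx] - M) * (Xs * A_i - B_i)
      term1 <- matrix(0, length(idx), p)
      is_ev <- event[idx]
      ev_t <- findInterval(stop[idx][is_ev], st$dtimes)
      term1[is_ev, ] <- Xs[is_ev, , drop = FALSE] - r[ev_t, , drop = FALSE]
      resid[idx, ] <- weights[idx] * (term1 - term2)
    }
  }
  list(loglik = ll, score = U, info = I, resid = resid)
}

name_aliased <- function(I, colnames_X) {
  q <- qr(I)
  if (q$rank < ncol(I)) colnames_X[q$pivot[(q$rank + 1):ncol(I)]] else character()
}

# Core Newton-Raphson maximizer of the stratified, left-truncated, weighted
# Breslow partial likelihood.
cox_engine <- function(start, stop, event, X, strata, weights, subject,
                       max_iter = 50, tol = 1e-9) {
  keep <- stop > start
  if (!all(keep)) {
    start <- start[keep]; stop <- stop[keep]; event <- event[keep]
    X <- X[keep, , drop = FALSE]; strata <- strata[keep]
    weights <- weights[keep]; subject <- subject[keep]
  }
  chk(sum(event) > 0, "no events: cannot fit a Cox model")
  p <- ncol(X)
  prep <- cox_prepare(start, stop, event, X, strata, weights)
  chk(length(prep$strata) > 0, "no events: all strata are eventless")
  beta <- numeric(p)
  q <- cox_quantities(prep, start, stop, event, X, weights, beta)
  for (it in seq_len(max_iter)) {
    if (max(abs(q$score)) < tol) break
    delta <- tryCatch(solve(q$info, q$score), error = function(e) {
      aliased <- name_aliased(q$info, colnames(X))
      stop("information matrix is singular; collinear covariates: ",
           paste(aliased, collapse = ", "), call. = FALSE)
    })
    stepsize <- 1
    repeat {
      cand <- beta + stepsize * delta
      qn <- cox_quantities(prep, start, stop, event, X, weights, cand)
      if (is.finite(qn$loglik) && qn$loglik >= q$loglik - 1e-12) break
      stepsize <- stepsize / 2
      chk(stepsize > 1e-10, "step-halving failed; partial likelihood not increasing")
    }
    beta <- beta + stepsize * delta
    q <- qn
    if (it == max_iter && max(abs(q$score)) >= tol)
      stop("Newton iterations did not converge in ", max_iter,
           " iterations; gradient norm ", format(max(abs(q$score))), call. = FALSE)
  }
  qr_ <- cox_quantities(prep, start, stop, event, X, weights, beta,
                        want_resid = TRUE)
  iinv <- tryCatch(solve(qr_$info), error = function(e) {
    aliased <- name_aliased(qr_$info, colnames(X))
    stop("information matrix is singular; collinear covariates: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  })
  Usub <- rowsum(qr_$resid, subject)
  D <- Usub %*% iinv
  vrob <- t(D) %*% D
  list(coef = stats::setNames(beta, colnames(X)),
       var_model = iinv, var_robust = vrob,
       se_model = sqrt(diag(iinv)), se_robust = sqrt(diag(vrob)),
       loglik = qr_$loglik, score = qr_$score,
       score_norm = max(abs(qr_$score)), iter = it,
       n = length(unique(subject)), n_events = sum(event),
       n_strata_dropped = prep$strata_dropped,
       linear_predictor = drop(X %*% beta))
}

cox_design <- function(records, covariates) {
  chk(length(covariates) >= 1, "at least one covariate is required")
  chk(all(covariates %in% names(records)),
      "records lack covariate columns: ",
      paste(setdiff(covariates, names(records)), collapse = ", "))
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(f, data = records)
  X[, -1, drop = FALSE]
}

#' Fit a stratified, Prentice-weighted Cox model (general covariate set)
#'
#' Maximizes the stratified, left-truncated, weighted Cox partial likelihood
#' (Breslow tie handling) by Newton-Raphson, with a robust sandwich variance
#' grouped by subject (the default for case-cohort data, where the Prentice
#' risk-set modification invalidates the model-based variance).
#'
#' @param records data.frame with `subject_id`, risk interval columns
#'   (`start`/`stop` from [prentice_weights()], or `entry_age`/`exit_age`
#'   for a full cohort), `event`, optionally `stratum` and `weight`, and all
#'   covariate columns (factors are expanded to dummies).
#' @param covariates character vector of covariate column names.
#' @param robust use the sandwich variance for SEs (default TRUE).
#' @param max_iter,tol Newton-Raphson controls.
#' @return list with `coef`, `se`, `se_model`, `se_robust`, `loglik`,
#'   `score_norm`, `n`, `n_events`, `n_strata_dropped`, `linear_predictor`
#'   and the variance matrices.
#' @export
cox_model <- function(records, covariates, robust = TRUE, max_iter = 50,
                      tol = 1e-9) {
  start <- if ("start" %in% names(records)) records$start else records$entry_age
  stop_ <- if ("stop" %in% names(records)) records$stop else records$exit_age
  strata <- if ("stratum" %in% names(records)) as.character(records$stratum)
            else rep("all", nrow(records))
  w <- if ("weight" %in% names(records)) records$weight else rep(1, nrow(records))
  X <- cox_design(records, covariates)
  fit <- cox_engine(start, stop_, as.logical(records$event), X, strata, w,
                    records$subject_id, max_iter = max_iter, tol = tol)
  if (fit$n_strata_dropped > 0)
    message(fit$n_strata_dropped, " eventless strata dropped")
  fit$se <- if (robust) fit$se_robust else fit$se_model
  fit$robust <- robust
  fit
}

#' Association of an age-gap exposure with an endpoint
#'
#' Convenience wrapper around [cox_model()] returning one association row
#' for the exposure: log hazard per exposure unit (a gap z-score in the
#' intended use), SE, 95% CI on the hazard-ratio scale and a two-sided
#' Wald p-value.
#'
#' @param records as in [cox_model()]; should carry an `endpoint` column.
#' @param exposure name of the (numeric) exposure column.
#' @param adjust character vector of adjustment covariate columns (empty for
#'   the base model).
#' @param clock,model labels recorded in the result (defaults: the exposure
#'   name; `"base"` or `"adjusted"` according to `adjust`).
#' @param robust sandwich variance (default TRUE).
#' @return a one-row data.frame (class `assoc_result`) with columns clock,
#'   endpoint, model, logHR, se, hr, ci_low, ci_high, p, q, n, n_events; the
#'   full fit is attached as attribute `"fit"`.
#' @export
fit_stratified_cox <- function(records, exposure, adjust = character(),
                               clock = exposure,
                               model = if (length(adjust)) "adjusted" else "base",
                               robust = TRUE) {
  fit <- cox_model(records, c(exposure, adjust), robust = robust)
  i <- 1L  # exposure is the first design column (numeric exposure assumed)
  logHR <- fit$coef[[i]]
  se <- fit$se[[i]]
  out <- data.frame(
    clock = clock,
    endpoint = if ("endpoint" %in% names(records)) records$endpoint[1] else NA_character_,
    model = model, logHR = logHR, se = se, hr = exp(logHR),
    ci_low = exp(logHR - 1.96 * se), ci_high = exp(logHR + 1.96 * se),
    p = 2 * stats::pnorm(-abs(logHR / se)), q = NA_real_,
    n = fit$n, n_events = fit$n_events, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", class(out))
  attr(out, "fit") <- fit
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment preserving input order (a thin validating wrapper
#' over [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  chk(is.numeric(pvalues) && all(is.finite(pvalues)), "p-values must be finite")
  chk(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Harrell's concordance index under left truncation and censoring
#'
#' For every event at age `t`, the comparable set is the subjects still at
#' risk at `t` (entered before `t`, exited after `t`). A pair is concordant
#' when the failing member carries the higher risk score; score ties count
#' 0.5. Tied event ages are not comparable.
#'
#' @param records subject-level data.frame with `subject_id`, `entry_age`,
#'   `exit_age`, `event`.
#' @param risk_score named numeric vector (higher = riskier) covering all
#'   subjects.
#' @return concordance in \[0, 1\]; errors when no usable pairs exist.
#' @export
harrell_c <- function(records, risk_score) {
  chk(!is.null(names(risk_score)), "risk_score must be named by subject_id")
  chk(all(records$subject_id %in% names(risk_score)),
      "risk_score missing for some subjects")
  s <- unname(risk_score[records$subject_id])
  entry <- records$entry_age; exit <- records$exit_age
  ev_idx <- which(as.logical(records$event))
  chk(length(ev_idx) > 0, "no events: concordance undefined")
  conc <- 0; total <- 0
  for (i in ev_idx) {
    at_risk <- entry < exit[i] & exit > exit[i]
    m <- sum(at_risk)
    if (m == 0) next
    conc <- conc + sum(s[i] > s[at_risk]) + 0.5 * sum(s[i] == s[at_risk])
    total <- total + m
  }
  chk(total > 0, "no usable pairs: concordance undefined")
  conc / total
}

#' Lasso-penalized Cox selection of age-gap exposures
#'
#' Fits an L1-penalized stratified (start, stop] Cox model over a lambda
#' path via `glmnet`, chooses lambda at the cross-validation minimum of the
#' partial-likelihood deviance, and refits the exposures with nonzero
#' coefficients unpenalized (Prentice-weighted and stratified, with the
#' adjustment covariates) through [fit_stratified_cox()]. Adjustment
#' covariates are included unpenalized in the selection model.
#'
#' @param records Prentice-prepared records (see [prentice_weights()]) with
#'   `stratum` and all candidate/adjustment columns.
#' @param candidates character vector (>= 2) of candidate exposure columns.
#' @param adjust adjustment covariate columns.
#' @param n_folds CV folds.
#' @param seed fold-assignment seed.
#' @param ... passed to [glmnet::cv.glmnet()] (e.g. `nlambda`,
#'   `lambda.min.ratio`).
#' @return list with `selected` (character, possibly empty, with a warning
#'   when empty), `lambda_min`, `cv_fit`, and `refit` (an `assoc_result`
#'   data.frame with one row per selected exposure, or NULL).
#' @export
lasso_cox_select <- function(records, candidates, adjust = character(),
                             n_folds = 5, seed = 1L, ...) {
  chk(length(candidates) >= 2, "need at least 2 candidate exposures")
  keep <- records$stop > records$start
  records <- records[keep, , drop = FALSE]
  X <- cox_design(records, c(candidates, adjust))
  asg <- attr(stats::model.matrix(
    stats::as.formula(paste("~", paste(c(candidates, adjust), collapse = "+"))),
    data = records), "assign")[-1]
  pf <- as.numeric(asg <= length(candidates))
  y <- survival::Surv(records$start, records$stop, as.numeric(records$event))
  ys <- glmnet::stratifySurv(y, as.character(records$stratum))
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(X)))
  cv <- glmnet::cv.glmnet(X, ys, family = "cox", foldid = foldid,
                          penalty.factor = pf, ...)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  cand_cols <- colnames(X)[asg <= length(candidates)]
  selected <- cand_cols[co[cand_cols, 1] != 0]
  if (length(selected) == 0) {
    warning("lasso shrank all candidate coefficients to zero at the CV minimum")
    return(list(selected = character(), lambda_min = cv$lambda.min,
                cv_fit = cv, refit = NULL))
  }
  refit <- do.call(rbind, lapply(selected, function(ex) {
    fit_stratified_cox(records, exposure = ex,
                       adjust = c(setdiff(selected, ex), adjust),
                       clock = ex, model = "lasso_refit")
  }))
  list(selected = selected, lambda_min = cv$lambda.min, cv_fit = cv,
       refit = refit)
}

#' Compare model discrimination with Harrell's concordance
#'
#' Fits each candidate covariate set with [cox_model()], scores subjects
#' with the fitted linear predictor, and reports Harrell's C with a
#' subject-level bootstrap percentile CI (coefficients held fixed across
#' resamples).
#'
#' @param records Prentice-prepared records with all covariate columns.
#' @param model_specs named list of covariate-name vectors.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed bootstrap seed.
#' @return data.frame: model, c_index, ci_low, ci_high, n, n_events.
#' @export
compare_models_concordance <- function(records, model_specs, n_boot = 200,
                                       seed = 1L) {
  chk(is.list(model_specs) && length(model_specs) >= 1 &&
        !is.null(names(model_specs)), "model_specs must be a named list")
  rows <- lapply(names(model_specs), function(nm) {
    fit <- cox_model(records, model_specs[[nm]])
    keep <- records$stop > records$start
    rec <- records[keep, , drop = FALSE]
    lp <- stats::setNames(fit$linear_predictor, rec$subject_id)
    cidx <- harrell_c(rec, lp)
    set.seed(derive_seed(seed, match(nm, names(model_specs))))
    cb <- vapply(seq_len(n_boot), function(b) {
      ii <- sample(nrow(rec), replace = TRUE)
      rb <- rec[ii, , drop = FALSE]
      rb$subject_id <- as.character(seq_along(ii))
      lpb <- stats::setNames(unname(lp)[ii], rb$subject_id)
      tryCatch(harrell_c(rb, lpb), error = function(e) NA_real_)
    }, numeric(1))
    ci <- stats::quantile(cb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(model = nm, c_index = cidx, ci_low = ci[1], ci_high = ci[2],
               n = fit$n, n_events = fit$n_events, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Lag sensitivity analysis
#'
#' Re-runs an association after treating events within `lag` years of entry
#' as non-events: subcohort members with early events are censored at the
#' event age; non-subcohort early cases (no longer cases) leave the sample,
#' as the case-cohort design requires.
#'
#' @param records case-cohort sample (pre-Prentice: needs `in_subcohort`,
#'   `entry_age`, `exit_age`, `event`, `stratum` and covariates).
#' @param exposure,adjust as in [fit_stratified_cox()].
#' @param lag_years numeric vector of lags (default `c(2, 5)`).
#' @param eps Prentice late-entry offset.
#' @param ... passed to [fit_stratified_cox()].
#' @return an `assoc_result` data.frame with one row per lag (model label
#'   `"lag<k>"`).
#' @export
lag_sensitivity <- function(records, exposure, adjust = character(),
                            lag_years = c(2, 5), eps = 1e-6, ...) {
  chk(all(lag_years >= 0), "lags must be >= 0")
  do.call(rbind, lapply(lag_years, function(lag) {
    r <- records
    early <- r$event & (r$exit_age - r$entry_age <= lag)
    r <- r[!(early & !r$in_subcohort), , drop = FALSE]
    r$event[r$event & (r$exit_age - r$entry_age <= lag)] <- FALSE
    out <- fit_stratified_cox(prentice_weights(r, eps = eps), exposure,
                              adjust = adjust,
                              model = paste0("lag", lag), ...)
    out
  }))
}
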