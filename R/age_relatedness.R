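# Age-relatedness of endpoints: Gompertz-Makeham fits to banded incidence,
# Spearman correlation of age-gap effect sizes with the Gompertz slope, and
# complete-linkage clustering of association matrices.

#' Build an incidence series from an event table
#'
#' Aggregates person-years and event counts into non-overlapping age bands;
#' person-years are the overlap of each subject's (entry, exit) interval
#' with the band, and an event is counted in the band containing its age.
#'
#' @param events event table (`entry_age`, `exit_age`, `event`).
#' @param endpoint label stored in the series.
#' @param width band width in years (default 5).
#' @return data.frame: endpoint, age_lo, age_hi, events, person_years
#'   (bands with zero person-years are dropped).
#' @export
incidence_series <- function(events, endpoint = events$endpoint[1], width = 5) {
  lo <- floor(min(events$entry_age) / width) * width
  hi <- ceiling(max(events$exit_age) / width) * width
  bands <- seq(lo, hi - width, by = width)
  py <- vapply(bands, function(b) {
    sum(pmax(0, pmin(events$exit_age, b + width) - pmax(events$entry_age, b)))
  }, numeric(1))
  ev <- vapply(bands, function(b) {
    sum(events$event & events$exit_age >= b & events$exit_age < b + width)
  }, numeric(1))
  keep <- py > 0
  data.frame(endpoint = endpoint, age_lo = bands[keep],
             age_hi = bands[keep] + width, events = ev[keep],
             person_years = py[keep], stringsAsFactors = FALSE)
}

gm_negloglik <- function(par, m, y, py) {
  mu <- py * (par[1] + par[2] * exp(par[3] * m))
  if (any(mu <= 0) || any(!is.finite(mu))) return(Inf)
  -sum(stats::dpois(y, mu, log = TRUE))
}

# same likelihood on the (log c, log a, b) scale, where optimization and
# numerical differentiation are well conditioned; drop_c fixes c = 0
gm_negloglik_u <- function(u, m, y, py, drop_c = FALSE) {
  if (drop_c) gm_negloglik(c(0, exp(u[1]), u[2]), m, y, py)
  else gm_negloglik(c(exp(u[1]), exp(u[2]), u[3]), m, y, py)
}

# moment-matched (c, a) start for a fixed b: least squares of the crude rate
# on exp(b m), clamped to the positive orthant
gm_start_ca <- function(b, m, y, py) {
  r <- y / py
  e <- exp(b * m)
  a0 <- max(stats::cov(r, e) / stats::var(e), 1e-12 * mean(r) / mean(e),
            .Machine$double.xmin)
  c0 <- max(mean(r - a0 * e), 1e-6 * mean(r))
  c(c0, a0)
}

#' Fit a Gompertz-Makeham hazard to banded incidence
#'
#' Maximizes the Poisson likelihood
#' `events ~ Poisson(person_years * (c + a*exp(b*midpoint)))` over
#' `(c >= 0, a > 0, b)`, with multiple starts over a log-spaced grid of `b`
#' values spanning reported human disease slopes (20 starts in
#' \[1e-3, 0.3\]/yr). A solution on the `c = 0` boundary is reported with
#' `boundary_c = TRUE`, not an error. The SE of `b` comes from the observed
#' information (numerical Hessian at the MLE).
#'
#' @param series data.frame with `age_lo`, `age_hi`, `events`,
#'   `person_years` (at least 4 bands; the hazard is evaluated at band
#'   midpoints).
#' @return object of class `gompertz_fit`: list with `makeham_c`, `scale_a`,
#'   `rate_b`, `se_b`, `loglik`, `boundary_c`.
#' @export
fit_gompertz_makeham <- function(series) {
  chk(nrow(series) >= 4, "need at least 4 age bands")
  chk(all(series$person_years > 0), "person_years must be > 0")
  chk(all(series$events >= 0), "event counts must be >= 0")
  chk(sum(series$events) > 0, "all-zero event counts: nothing to fit")
  m <- (series$age_lo + series$age_hi) / 2
  y <- series$events
  py <- series$person_years
  crude <- sum(y) / sum(py)

  best <- NULL
  for (b0 in exp(seq(log(1e-3), log(0.3), length.out = 20))) {
    ca <- gm_start_ca(b0, m, y, py)
    u0 <- c(log(ca[1]), log(ca[2]), b0)
    fit <- tryCatch({
      f1 <- stats::optim(u0, gm_negloglik_u, m = m, y = y, py = py,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
      stats::optim(f1$par, gm_negloglik_u, m = m, y = y, py = py,
                   method = "BFGS", control = list(maxit = 500))
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  chk(!is.null(best), "Gompertz-Makeham optimization failed from all starts")
  u <- best$par
  par <- c(exp(u[1]), exp(u[2]), u[3])
  # a Makeham term that has collapsed to a negligible share of the hazard is
  # a boundary solution: refit with c = 0 and report it flagged
  boundary_c <- par[1] <= 1e-8 * (par[2] * exp(par[3] * min(m)))
  if (boundary_c) {
    f0 <- stats::optim(u[2:3], gm_negloglik_u, m = m, y = y, py = py,
                       drop_c = TRUE, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (f0$value <= best$value + 1e-9) {
      par <- c(0, exp(f0$par[1]), f0$par[2])
      best <- f0
      H <- pracma::hessian(gm_negloglik_u, f0$par, m = m, y = y, py = py,
                           drop_c = TRUE)
      se_b <- tryCatch(sqrt(solve(H)[2, 2]), error = function(e) NA_real_)
    } else {
      boundary_c <- FALSE
    }
  }
  if (!boundary_c) {
    H <- pracma::hessian(gm_negloglik_u, u, m = m, y = y, py = py)
    se_b <- tryCatch(sqrt(solve(H)[3, 3]), error = function(e) NA_real_)
  }
  structure(list(makeham_c = par[1], scale_a = par[2], rate_b = par[3],
                 se_b = se_b, loglik = -best$value, boundary_c = boundary_c),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("<gompertz_fit> c=%.3g a=%.3g b=%.4f (se %.4f)%s\n",
              x$makeham_c, x$scale_a, x$rate_b, x$se_b,
              if (x$boundary_c) " [c at boundary]" else ""))
  invisible(x)
}

#' Correlate age-gap effect sizes with disease age-relatedness
#'
#' Spearman rank correlation between per-z log hazards and the Gompertz
#' slopes (rate of incidence increase with age) across endpoints matched by
#' label. Exact permutation p-value for n <= 10 pairs, normal approximation
#' otherwise.
#'
#' @param logHRs named numeric vector, endpoint -> log hazard per gap z.
#' @param betas named numeric vector, endpoint -> Gompertz rate b.
#' @return list with `rho`, `p`, `n` (shared endpoints; at least 5 required).
#' @export
correlate_age_relatedness <- function(logHRs, betas) {
  shared <- intersect(names(logHRs), names(betas))
  chk(length(shared) >= 5, "need at least 5 shared endpoints (got ",
      length(shared), ")")
  ct <- suppressWarnings(
    stats::cor.test(logHRs[shared], betas[shared], method = "spearman",
                    exact = length(shared) <= 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Order rows and columns of an association matrix by complete linkage
#'
#' Complete-linkage agglomerative clustering on Euclidean distances, rows
#' and columns independently; `stats::hclust` breaks distance ties
#' deterministically by original index. A single row (or column) yields the
#' identity order.
#'
#' @param mat numeric matrix (e.g. clocks x endpoints of log hazards); no
#'   missing cells allowed.
#' @return list with `row_order`, `col_order` (leaf orders), and the two
#'   `hclust` objects (`NULL` for single-element dimensions).
#' @export
cluster_associations <- function(mat) {
  chk(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  chk(!anyNA(mat), "missing cells are not allowed")
  one <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), hclust = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
    list(order = hc$order, hclust = hc)
  }
  r <- one(mat); cc <- one(t(mat))
  list(row_order = r$order, col_order = cc$order,
       row_hclust = r$hclust, col_hclust = cc$hclust)
}
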