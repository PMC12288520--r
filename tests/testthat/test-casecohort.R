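test_that("a 4-subject toy matches brute-force partial-likelihood maximization", {
  d <- data.frame(subject_id = c("a", "b", "c", "d"),
                  entry_age = c(50, 51, 49, 52),
                  exit_age = c(55, 58, 60, 62),
                  event = c(TRUE, TRUE, FALSE, TRUE),
                  x = c(1.2, -0.4, 0.3, 0.9),
                  endpoint = "toy", stringsAsFactors = FALSE)
  fit <- cox_model(d, "x", robust = FALSE)
  brute <- optimize(oracle_cox1_loglik, c(-10, 10), maximum = TRUE,
                    entry = d$entry_age, exit = d$exit_age,
                    event = d$event, x = d$x, tol = 1e-12)
  expect_equal(unname(fit$coef), brute$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, brute$objective, tolerance = 1e-9)
  expect_lt(fit$score_norm, 1e-6)
})

test_that("full-cohort fits match survival::coxph to 1e-6 (coef, SEs, loglik)", {
  d <- make_surv_fixture(500, beta = 0.4, seed = 3)
  d$x2 <- rbinom(500, 1, 0.4)
  fit <- cox_model(d, c("x", "x2"))
  cp <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ x + x2 + strata(stratum),
    data = d, ties = "breslow", robust = TRUE, id = subject_id)
  expect_equal(unname(fit$coef), unname(coef(cp)), tolerance = 1e-6)
  expect_equal(unname(fit$se_model), unname(sqrt(diag(cp$naive.var))),
               tolerance = 1e-6)
  expect_equal(unname(fit$se_robust), unname(sqrt(diag(cp$var))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, cp$loglik[2], tolerance = 1e-8)
  expect_lt(fit$score_norm, 1e-6)
})

test_that("ties are handled by the Breslow convention", {
  d <- make_surv_fixture(120, beta = 0.5, seed = 11)
  d$exit_age <- d$entry_age + round(d$exit_age - d$entry_age) + 0.5  # force ties
  d <- d[d$exit_age > d$entry_age, ]
  fit <- cox_model(d, "x")
  cp <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ x + strata(stratum),
    data = d, ties = "breslow", robust = TRUE, id = subject_id)
  expect_equal(unname(fit$coef), unname(coef(cp)), tolerance = 1e-6)
  expect_equal(unname(fit$se_robust), unname(sqrt(diag(cp$var))),
               tolerance = 1e-6)
})

test_that("Prentice rules: subcohort at risk throughout, outside cases only at failure", {
  d <- make_surv_fixture(300, beta = 0.3, seed = 5)
  ev <- data.frame(subject_id = d$subject_id, endpoint = "m",
                   entry_age = d$entry_age, exit_age = d$exit_age,
                   event = d$event, in_subcohort = NA)
  cc <- sample_case_cohort(ev, 0.4, seed = 8)
  cc <- merge(cc, d[, c("subject_id", "x", "stratum")], by = "subject_id")
  pp <- prentice_weights(cc)
  sub <- pp$in_subcohort
  expect_equal(pp$start[sub], pp$entry_age[sub])
  out <- !sub & pp$event
  expect_gt(sum(out), 0)
  expect_equal(pp$start[out], pp$exit_age[out] - 1e-6)
  expect_true(all(pp$weight == 1))
  # design violation rejected
  bad <- cc; bad$event[which(!bad$in_subcohort)[1]] <- FALSE
  expect_error(prentice_weights(bad), "design violation")
  # full-cohort limit: everyone in the subcohort reproduces the plain fit
  cc1 <- sample_case_cohort(ev, 1, seed = 8)
  cc1 <- merge(cc1, d[, c("subject_id", "x", "stratum")], by = "subject_id")
  f_plain <- cox_model(cc1, "x")
  f_pren <- cox_model(prentice_weights(cc1), "x")
  expect_equal(f_pren$coef, f_plain$coef, tolerance = 1e-10)
  expect_equal(f_pren$se_robust, f_plain$se_robust, tolerance = 1e-10)
})

test_that("estimates are invariant to the Prentice epsilon over 1e-4 to 1e-8", {
  d <- make_surv_fixture(400, beta = 0.5, seed = 6)
  ev <- data.frame(subject_id = d$subject_id, endpoint = "m",
                   entry_age = d$entry_age, exit_age = d$exit_age,
                   event = d$event, in_subcohort = NA)
  cc <- merge(sample_case_cohort(ev, 0.3, seed = 2),
              d[, c("subject_id", "x", "stratum")], by = "subject_id")
  coefs <- vapply(c(1e-4, 1e-6, 1e-8), function(e)
    cox_model(prentice_weights(cc, eps = e), "x")$coef, numeric(1))
  expect_lt(max(coefs) - min(coefs), 1e-6)
})

test_that("case-cohort estimates agree with the full-cohort oracle", {
  diffs <- vapply(1:5, function(r) {
    d <- make_surv_fixture(1500, beta = 0.4, seed = 100 + r)
    full <- cox_model(d, "x")
    ev <- data.frame(subject_id = d$subject_id, endpoint = "m",
                     entry_age = d$entry_age, exit_age = d$exit_age,
                     event = d$event, in_subcohort = NA)
    cc <- merge(sample_case_cohort(ev, 0.3, seed = r),
                d[, c("subject_id", "x", "stratum")], by = "subject_id")
    fcc <- cox_model(prentice_weights(cc), "x")
    abs(fcc$coef - full$coef) / fcc$se
  }, numeric(1))
  expect_true(all(diffs < 2))
})

test_that("null-exposure confidence intervals achieve nominal coverage", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(5000 + r)
    n <- 250
    d <- data.frame(subject_id = as.character(1:n),
                    entry_age = runif(n, 40, 60), x = rnorm(n))
    t_ev <- d$entry_age + rexp(n, 0.06)        # hazard free of x
    cens <- d$entry_age + runif(n, 2, 20)
    d$exit_age <- pmin(t_ev, cens); d$event <- t_ev <= cens
    d$endpoint <- "null"
    fit <- fit_stratified_cox(d, "x")
    if (abs(fit$logHR) < 1.96 * fit$se) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("stratum contributions are invariant to time shifts in other strata", {
  d <- make_surv_fixture(300, beta = 0.4, seed = 13)
  f1 <- cox_model(d, "x")
  d2 <- d
  shift <- d2$stratum == unique(d2$stratum)[1]
  d2$entry_age[shift] <- d2$entry_age[shift] + 100
  d2$exit_age[shift] <- d2$exit_age[shift] + 100
  f2 <- cox_model(d2, "x")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("degenerate fits fail loudly", {
  d <- make_surv_fixture(100, seed = 17)
  d$event <- FALSE
  expect_error(cox_model(d, "x"), "no events")
  d2 <- make_surv_fixture(100, seed = 18)
  d2$x_dup <- d2$x
  expect_error(cox_model(d2, c("x", "x_dup")), "collinear")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(31)
  for (r in 1:5) {
    p <- runif(20)^2
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in sorted p
    expect_true(all(q >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, NA)), "finite")
})

test_that("Harrell's C matches exhaustive pair enumeration and known limits", {
  # perfect ranking
  d <- data.frame(subject_id = as.character(1:20),
                  entry_age = rep(40, 20),
                  exit_age = 41:60, event = TRUE)
  s <- setNames(-d$exit_age, d$subject_id)
  expect_equal(harrell_c(d, s), 1)
  # hand-built table with censoring and a score tie, n = 6
  d6 <- data.frame(subject_id = letters[1:6],
                   entry_age = c(40, 42, 41, 45, 40, 43),
                   exit_age = c(50, 55, 52, 58, 60, 57),
                   event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  s6 <- setNames(c(2, 1.5, 1.5, 3, 0.5, 1.0), d6$subject_id)
  expect_equal(harrell_c(d6, s6),
               oracle_harrell_c(d6$entry_age, d6$exit_age, d6$event,
                                unname(s6[d6$subject_id])))
  # exact equality with the oracle on 50 random left-truncated subjects
  set.seed(61)
  for (r in 1:3) {
    dn <- make_surv_fixture(50, beta = 0.6, seed = 600 + r)
    sn <- setNames(round(rnorm(50), 1), dn$subject_id)   # induce ties
    expect_identical(harrell_c(dn, sn),
                     oracle_harrell_c(dn$entry_age, dn$exit_age, dn$event,
                                      unname(sn[dn$subject_id])))
  }
  # random scores concentrate near 1/2
  dr <- make_surv_fixture(500, beta = 0, seed = 62)
  set.seed(63)
  sr <- setNames(rnorm(500), dr$subject_id)
  expect_lt(abs(harrell_c(dr, sr) - 0.5), 0.05)
  d0 <- d; d0$event <- FALSE
  expect_error(harrell_c(d0, s), "no events")
})

test_that("fit_stratified_cox returns a well-formed association row", {
  d <- make_surv_fixture(400, beta = 0.5, seed = 21)
  res <- fit_stratified_cox(d, "x")
  expect_s3_class(res, "assoc_result")
  expect_equal(res$model, "base")
  expect_equal(res$hr, exp(res$logHR))
  expect_equal(res$ci_low, exp(res$logHR - 1.96 * res$se))
  expect_equal(res$ci_high, exp(res$logHR + 1.96 * res$se))
  expect_true(res$p >= 0 && res$p <= 1)
  expect_equal(res$n_events, sum(d$event))
})

test_that("lasso selection recovers informative exposures and refits them", {
  set.seed(71)
  n <- 2000
  d <- data.frame(subject_id = as.character(1:n), entry_age = runif(n, 40, 60))
  G <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  lp <- 0.5 * G[, 1] - 0.5 * G[, 2]
  t_ev <- d$entry_age + rexp(n, 0.05 * exp(lp))
  cens <- d$entry_age + runif(n, 2, 22)
  d$exit_age <- pmin(t_ev, cens); d$event <- t_ev <= cens
  d$endpoint <- "m"; d$stratum <- "all"; d$in_subcohort <- NA
  d <- cbind(d, G)
  cc <- sample_case_cohort(d, 0.5, seed = 72)
  sel <- lasso_cox_select(prentice_weights(cc), paste0("g", 1:6), seed = 73)
  expect_true(all(c("g1", "g2") %in% sel$selected))
  expect_lte(length(setdiff(sel$selected, c("g1", "g2"))), 2)
  expect_s3_class(sel$refit, "assoc_result")
  expect_setequal(sel$refit$clock, sel$selected)
  # refit signs match the generating effects
  expect_gt(sel$refit$logHR[sel$refit$clock == "g1"], 0)
  expect_lt(sel$refit$logHR[sel$refit$clock == "g2"], 0)
  expect_error(lasso_cox_select(prentice_weights(cc), "g1"), "2 candidate")
})

test_that("concordance comparison ranks models carrying independent signal", {
  # two independent informative covariates (a lifestyle-like factor and an
  # age-gap-like exposure) plus pure noise
  set.seed(81)
  n <- 800
  d <- data.frame(subject_id = as.character(1:n),
                  entry_age = runif(n, 40, 60),
                  w = rnorm(n), x = rnorm(n), z = rnorm(n))
  t_ev <- d$entry_age + rexp(n, 0.05 * exp(0.5 * d$w + 0.5 * d$x))
  cens <- d$entry_age + runif(n, 2, 22)
  d$exit_age <- pmin(t_ev, cens); d$event <- t_ev <= cens
  d$endpoint <- "m"; d$stratum <- "all"; d$in_subcohort <- TRUE
  d <- prentice_weights(d)
  out <- compare_models_concordance(
    d, list(w_only = "w", x_only = "x", combined = c("w", "x"),
            noise_only = "z", combined_noise = c("w", "x", "z")),
    n_boot = 50, seed = 4)
  cc <- setNames(out$c_index, out$model)
  expect_gt(cc["combined"], cc["w_only"])
  expect_gt(cc["combined"], cc["x_only"])
  expect_lt(abs(cc["noise_only"] - 0.5), 0.06)
  # adding pure noise moves C by less than the bootstrap CI half-width
  halfwidth <- (out$ci_high - out$ci_low)[out$model == "combined"] / 2
  expect_lt(abs(cc["combined_noise"] - cc["combined"]), halfwidth)
  expect_true(all(out$ci_low <= out$c_index & out$c_index <= out$ci_high))
})

test_that("lag sensitivity censors early events and degenerates correctly", {
  d <- make_surv_fixture(500, beta = 0.5, seed = 91)
  ev <- data.frame(subject_id = d$subject_id, endpoint = "m",
                   entry_age = d$entry_age, exit_age = d$exit_age,
                   event = d$event, in_subcohort = NA)
  cc <- merge(sample_case_cohort(ev, 0.5, seed = 92),
              d[, c("subject_id", "x", "stratum")], by = "subject_id")
  main <- fit_stratified_cox(prentice_weights(cc), "x")
  lag0 <- lag_sensitivity(cc, "x", lag_years = 0)
  expect_equal(lag0$logHR, main$logHR, tolerance = 1e-10)
  lag2 <- lag_sensitivity(cc, "x", lag_years = c(2, 5))
  expect_equal(lag2$model, c("lag2", "lag5"))
  expect_true(all(lag2$n_events < main$n_events))
  # estimates stay within one joint SE of the unlagged estimate
  expect_true(all(abs(lag2$logHR - main$logHR) <
                    sqrt(lag2$se^2 + main$se^2)))
  expect_error(lag_sensitivity(cc, "x", lag_years = 1000), "no events")
})
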