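make_matrix <- function(n = 6, p = 3, seed = 1, lo = 10, hi = 100) {
  set.seed(seed)
  m <- matrix(runif(n * p, lo, hi), n, p,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("A%02d", 1:p)))
  m
}

test_that("lift_intensities rescales columns multiplicatively", {
  m <- make_matrix(5, 4)
  f1 <- setNames(rep(1, 4), colnames(m))
  expect_equal(lift_intensities(m, f1), m)
  f2 <- f1; f2["A02"] <- 2
  lifted <- lift_intensities(m, f2)
  expect_equal(lifted[, "A02"], 2 * m[, "A02"])
  expect_equal(lifted[, -2], m[, -2])
  # column means scale by their factors
  set.seed(3)
  fr <- setNames(runif(4, 0.5, 3), colnames(m))
  expect_equal(colMeans(lift_intensities(m, fr)), colMeans(m) * fr)
  expect_error(lift_intensities(m, f1[-1]), "A01")
  expect_error(lift_intensities(m, setNames(c(-1, 1, 1, 1), colnames(m))),
               "positive")
})

test_that("apply_clock computes the declared affine transform", {
  m <- matrix(20, 1, 1, dimnames = list("s1", "A"))
  spec <- clock_spec("toy", intercept = 40, weights = c(A = 0.5))
  expect_equal(unname(apply_clock(m, spec)), 50)

  m2 <- make_matrix(4, 3)
  spec0 <- clock_spec("null", intercept = 62, weights = setNames(rep(0, 3),
                                                                 colnames(m2)))
  expect_equal(unname(apply_clock(m2, spec0)), rep(62, 4))

  # log10 preprocessing against a spreadsheet-style recomputation
  m3 <- make_matrix(2, 3, seed = 9)
  w <- c(A01 = 1.5, A02 = -2, A03 = 0.7)
  pp <- lapply(w, function(.) list(kind = "log10"))
  spec3 <- clock_spec("log", intercept = 10, weights = w, preprocess = pp)
  manual <- 10 + log10(m3) %*% w
  expect_equal(apply_clock(m3, spec3), drop(manual), tolerance = 1e-12)

  expect_error(apply_clock(m2[, 1:2], spec3), "A03")
})

test_that("apply_clock is affine under identity preprocessing", {
  m <- make_matrix(5, 3, seed = 4)
  w <- setNames(c(0.2, -0.1, 0.5), colnames(m))
  spec <- clock_spec("aff", intercept = 30, weights = w)
  p1 <- apply_clock(m, spec)
  p2 <- apply_clock(2 * m - m, spec)   # elementwise 2x - x == x
  expect_equal(p1, p2)
  # superposition: predictions minus intercept are linear in the matrix
  pa <- apply_clock(m, spec) - 30
  pb <- apply_clock(3 * m, spec) - 30
  expect_equal(pb, 3 * pa, tolerance = 1e-12)
})

test_that("clock specs round-trip through JSON with schema validation", {
  w <- c(A1 = 0.3, A2 = -1.2)
  pp <- list(A1 = list(kind = "zscore", mean = 5, sd = 2),
             A2 = list(kind = "log10"))
  spec <- clock_spec("rt", intercept = 51.7, weights = w, preprocess = pp,
                     organ = "liver", training_meta = "n=100")
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_json(spec, path)
  back <- read_clock_json(path)
  expect_equal(back$weights, spec$weights)
  expect_equal(back$intercept, spec$intercept)
  expect_equal(back$preprocess$A1$mean, 5)
  expect_equal(back$organ, "liver")
  # schema violations
  expect_error(clock_spec("bad", 0, numeric()), "non-empty")
  expect_error(clock_spec("bad", 0, c(A = 1),
                          list(A = list(kind = "zscore", mean = 0, sd = 0))),
               "sd > 0")
  expect_error(clock_spec("bad", 0, c(A = 1), list(A = list(kind = "sqrt"))),
               "unknown preprocess")
})

test_that("train_clock recovers age exactly in the noise-free limit", {
  cfg <- sim_config(n_subjects = 300, n_proteins = 40, n_organs = 0,
                    sigma_accel = 0, sigma_organ = 0, sigma_noise = 0,
                    lifestyle_effects = c(none = 0), seed = 31)
  s <- simulate_cohort(cfg)
  ages <- setNames(s$cohort$age, s$cohort$subject_id)
  spec <- train_clock(s$proteins, ages, seed = 5)
  pred <- apply_clock(s$proteins, spec)
  expect_gt(cor(pred, ages), 1 - 1e-6)
})

test_that("trained clocks generalize and fail under permuted labels", {
  cfg <- sim_config(n_subjects = 700, n_proteins = 60, n_organs = 0,
                    sigma_accel = 2, sigma_noise = 15,
                    lifestyle_effects = c(none = 0), seed = 32)
  s <- simulate_cohort(cfg)
  ages <- setNames(s$cohort$age, s$cohort$subject_id)
  tr <- s$cohort$subject_id[1:500]
  te <- s$cohort$subject_id[501:700]
  spec <- train_clock(s$proteins[tr, ], ages[tr], seed = 6)
  r_heldout <- cor(apply_clock(s$proteins[te, ], spec), ages[te])
  expect_gt(r_heldout, 0.75)

  # permuted labels: held-out r^2 within the permutation null
  set.seed(99)
  perm_ages <- setNames(sample(ages[tr]), tr)
  null_r2 <- replicate(200, cor(ages[te], sample(ages[te]))^2)
  spec_p <- suppressWarnings(train_clock(s$proteins[tr, ], perm_ages, seed = 6))
  pred_p <- apply_clock(s$proteins[te, ], spec_p)
  # a fully shrunk (constant) clock carries zero variance explained
  r2_p <- if (sd(pred_p) == 0) 0 else cor(pred_p, ages[te])^2
  expect_lt(r2_p, quantile(null_r2, 0.99) + 0.05)

  # training round-trip: apply_clock reproduces the model's fitted values
  fit_tr <- apply_clock(s$proteins[tr, ], spec)
  expect_equal(cor(fit_tr, ages[tr]) > 0.8, TRUE)
  expect_error(train_clock(s$proteins[tr, ], setNames(rep(50, 500), tr)),
               "constant")
  expect_error(train_clock(s$proteins[1:20, ], ages), "50 subjects")
})

test_that("organ selection partitions the analyte universe at a fixed threshold", {
  ann <- data.frame(
    analyte_id = sprintf("A%02d", 1:10),
    organ = c(rep("liver", 3), rep("heart", 3), rep("liver", 4)),
    enrichment = c(8, 8, 4.0, 9, 5, 8, 1, 1.5, 0.7, 2),
    stringsAsFactors = FALSE)
  liver <- select_organ_proteins(ann, "liver", 4)
  heart <- select_organ_proteins(ann, "heart", 4)
  orgm <- select_organ_proteins(ann, "organismal", 4)
  expect_true("A03" %in% liver)  # boundary enrichment 4.0 is inclusive
  expect_equal(sort(c(liver, heart, orgm)), sort(unique(ann$analyte_id)))
  expect_length(intersect(liver, heart), 0)
  expect_length(intersect(liver, orgm), 0)
  # threshold -> infinity: every organ empty, organismal = everything
  expect_length(select_organ_proteins(ann, "liver", Inf), 0)
  expect_equal(select_organ_proteins(ann, "organismal", Inf),
               sort(unique(ann$analyte_id)))
  expect_error(select_organ_proteins(ann, "kidney"), "unknown organ")
})

test_that("generator organ blocks are recovered exactly from the annotation", {
  cfg <- sim_config(n_subjects = 100, n_proteins = 60, n_organs = 3,
                    organ_block_size = 5, seed = 41)
  s <- simulate_cohort(cfg)
  for (k in paste0("organ", 1:3)) {
    truth <- s$protein_meta$analyte_id[s$protein_meta$organ == k]
    expect_equal(select_organ_proteins(s$annotation, k, 4), sort(truth))
  }
})

test_that("organ clocks track their own organ's acceleration best", {
  cfg <- sim_config(n_subjects = 2000, n_proteins = 80, n_organs = 2,
                    organ_block_size = 15, sigma_accel = 1, sigma_organ = 4,
                    sigma_noise = 4, lifestyle_effects = c(none = 0), seed = 42)
  s <- simulate_cohort(cfg)
  ages <- setNames(s$cohort$age, s$cohort$subject_id)
  for (k in c("organ1", "organ2")) {
    ids <- select_organ_proteins(s$annotation, k, 4)
    spec <- train_clock(s$proteins[, ids, drop = FALSE], ages,
                        seed = 7, name = k, organ = k)
    gap <- lowess_detrend(apply_clock(s$proteins, spec), ages)
    own <- cor(gap, s$latent[[paste0("accel_", k)]])
    other <- cor(gap, s$latent[[paste0("accel_",
                                       setdiff(c("organ1", "organ2"), k))]])
    expect_gt(own, other)
  }
})

test_that("LOF scores match the brute-force oracle and QC flags planted outliers", {
  set.seed(55)
  x <- matrix(rnorm(60 * 5), 60, 5)
  expect_equal(lof_scores(x, 10), oracle_lof(x, 10), tolerance = 1e-10)

  # homogeneous cloud + one point displaced 10 SD along the first PC
  cfg <- sim_config(n_subjects = 80, n_proteins = 30, n_organs = 0,
                    sigma_noise = 5, lifestyle_effects = c(none = 0), seed = 56)
  s <- simulate_cohort(cfg)
  m <- s$proteins
  m[7, ] <- m[7, ] * 3          # gross multiplicative shift on one subject
  flagged <- qc_outliers(m, n_components = 5, n_neighbors = 15, tukey_k = 1.5)
  expect_true(rownames(m)[7] %in% flagged)
  # tukey_k -> infinity: empty flag set
  expect_length(qc_outliers(m, 5, 15, tukey_k = 1e9), 0)
  expect_error(qc_outliers(m, n_components = 200), "n_components")
  expect_error(qc_outliers(m, 5, n_neighbors = 100), "n_neighbors")
})

test_that("duplicated subjects receive identical scores and flags", {
  cfg <- sim_config(n_subjects = 50, n_proteins = 20, n_organs = 0,
                    sigma_noise = 5, lifestyle_effects = c(none = 0), seed = 57)
  s <- simulate_cohort(cfg)
  m <- s$proteins
  m[3, ] <- m[3, ] * 4
  m2 <- rbind(m, m)
  rownames(m2) <- c(rownames(m), paste0(rownames(m), "_dup"))
  f2 <- qc_outliers(m2, 5, 21, 1.5)
  sc <- attr(f2, "scores")
  # each subject and its twin get the same score, so flags come in pairs
  expect_equal(unname(sc[rownames(m)]),
               unname(sc[paste0(rownames(m), "_dup")]), tolerance = 1e-12)
  expect_setequal(sub("_dup$", "", f2[grepl("_dup$", f2)]),
                  f2[!grepl("_dup$", f2)])
  expect_true(rownames(m)[3] %in% f2)
})
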