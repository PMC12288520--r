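# Configuration-driven orchestration: simulate (or ingest) -> QC -> clocks ->
# age gaps -> case-cohort associations -> FDR -> risk factors ->
# age-relatedness -> concordance, with a machine-readable manifest and log.

#' Build a validated run configuration
#'
#' @param simulate named list of [sim_config()] arguments (the generator
#'   supplies the cohort); alternatively supply `paths` with pre-existing
#'   tables.
#' @param paths optional named list of input files (`cohort`, `proteins`,
#'   `events`, `clocks_dir`, optionally `annotation`); when given, the
#'   simulate branch and clock training are skipped.
#' @param endpoints named list; each element may carry a `gompertz` list
#'   overriding the simulator's hazard parameters for that endpoint.
#' @param models which Cox models to fit (`"base"`, `"adjusted"`).
#' @param adjust adjustment covariate columns for the risk-factor model.
#' @param fdr_level FDR level in (0, 1).
#' @param lowess_fraction span of the age-gap smoother.
#' @param qc run multivariate outlier exclusion.
#' @param qc_params list(n_components, n_neighbors, tukey_k).
#' @param clocks list: `n_conventional`, `subset_fraction` (fraction of
#'   analytes seen by each conventional clock), `alpha`, `n_folds`,
#'   `enrichment_threshold`, `train_organ` (also fit organ-restricted
#'   clocks).
#' @param train_size subjects reserved for clock training; the simulator
#'   draws one cohort of `n_subjects + train_size` sharing a single set of
#'   protein-age parameters, and clocks are trained on the held-out
#'   training split so downstream gaps are out-of-sample.
#' @param subcohort_fraction case-cohort sampling fraction.
#' @param do_lags,lags run lag sensitivity for the Global clock on the first
#'   endpoint.
#' @param do_riskfactors,do_concordance,do_age_relatedness stage toggles.
#' @param concordance_boot bootstrap resamples for concordance CIs.
#' @param impute `"simple"` (mean/mode single imputation with a logged
#'   count) or `"none"` (abort on missing covariates).
#' @param seed master seed; every stochastic stage derives a child seed from
#'   it via [derive_seed()].
#' @param output_dir run directory.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(simulate = list(), paths = NULL,
                       endpoints = list(mortality = list()),
                       models = c("base", "adjusted"),
                       adjust = c("smoking_status", "alcohol_gday", "bmi",
                                  "diet_score", "activity_met", "education_f"),
                       fdr_level = 0.05, lowess_fraction = 2/3,
                       qc = TRUE,
                       qc_params = list(n_components = 10, n_neighbors = 20,
                                        tukey_k = 1.5),
                       clocks = list(n_conventional = 5, subset_fraction = 0.7,
                                     alpha = 0.5, n_folds = 5,
                                     enrichment_threshold = 4,
                                     train_organ = TRUE),
                       train_size = 800,
                       subcohort_fraction = NULL,
                       do_lags = FALSE, lags = c(2, 5),
                       do_riskfactors = TRUE, do_concordance = TRUE,
                       do_age_relatedness = TRUE, concordance_boot = 200,
                       impute = "simple",
                       seed = 1L, output_dir = tempfile("protage_run_")) {
  chk(fdr_level > 0 && fdr_level < 1, "fdr_level must lie in (0, 1)")
  chk(impute %in% c("simple", "none"), "impute must be 'simple' or 'none'")
  if (!is.null(paths)) {
    for (p in unlist(paths)) chk(file.exists(p), "input path does not exist: ", p)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; the full schema is
#' validated before any computation starts.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  chk(length(unknown) == 0, "unknown config keys: ",
      paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

impute_simple <- function(data, cols, log_fun = message) {
  n_imp <- 0L
  for (cl in intersect(cols, names(data))) {
    miss <- is.na(data[[cl]])
    if (!any(miss)) next
    n_imp <- n_imp + sum(miss)
    if (is.numeric(data[[cl]])) {
      data[[cl]][miss] <- mean(data[[cl]], na.rm = TRUE)
    } else {
      tb <- table(data[[cl]])
      data[[cl]][miss] <- names(tb)[which.max(tb)]
    }
  }
  if (n_imp > 0) log_fun(sprintf("imputed %d missing covariate values", n_imp))
  attr(data, "n_imputed") <- n_imp
  data
}

#' Run the full analysis pipeline
#'
#' Executes every stage declared in the configuration, writing TSV/JSON
#' artifacts, a deterministic machine-readable manifest (`manifest.json`)
#' and a timestamped log (`log.txt`) into the run directory. Any stage error
#' aborts with the stage name while preserving partial outputs. Stage
#' outputs are pure functions of (inputs, config, seed).
#'
#' @param config a [run_config()].
#' @return invisibly, the run directory; the manifest is attached as
#'   attribute `"manifest"`.
#' @export
run_analysis <- function(config) {
  chk(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "log.txt")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                            "\n", file = log_path, append = TRUE, sep = "")
  manifest <- list(package = "protage",
                   version = as.character(utils::packageVersion("protage")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, counts = list())
  stage <- function(name, expr) {
    logf("stage ", name, " start")
    out <- tryCatch(expr, error = function(e) {
      logf("stage ", name, " FAILED: ", conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logf("stage ", name, " done")
    out
  }
  seed <- config$seed

  # ---- data: simulate or ingest -------------------------------------------
  if (is.null(config$paths)) {
    sims <- stage("simulate", {
      sim_args <- config$simulate
      n_ana <- if (!is.null(sim_args$n_subjects)) sim_args$n_subjects
               else formals(sim_config)$n_subjects
      sim_args$n_subjects <- n_ana + config$train_size
      cfg <- do.call(sim_config, c(sim_args, list(seed = derive_seed(seed, 1))))
      all_sim <- simulate_cohort(cfg)
      # one protein-parameter draw; the first train_size subjects (an iid
      # subset) train the clocks, the remainder form the analysis cohort
      tr_idx <- seq_len(config$train_size)
      subset_sim <- function(s, idx) {
        list(cohort = s$cohort[idx, , drop = FALSE],
             proteins = s$proteins[idx, , drop = FALSE],
             latent = s$latent[idx, , drop = FALSE],
             annotation = s$annotation, protein_meta = s$protein_meta)
      }
      cfg$n_subjects <- n_ana
      list(train = subset_sim(all_sim, tr_idx),
           ana = subset_sim(all_sim, -tr_idx), cfg = cfg)
    })
    cohort <- sims$ana$cohort; proteins <- sims$ana$proteins
    latent <- sims$ana$latent; annotation <- sims$ana$annotation
    write_simulation(sims$ana, file.path(config$output_dir, "simulated"))
  } else {
    ing <- stage("ingest", {
      list(cohort = read_tsv_file(config$paths$cohort),
           proteins = {
             df <- utils::read.csv(config$paths$proteins, check.names = FALSE)
             m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
           },
           events = read_tsv_file(config$paths$events),
           annotation = if (!is.null(config$paths$annotation))
             read_tsv_file(config$paths$annotation) else NULL)
    })
    cohort <- ing$cohort; proteins <- ing$proteins
    latent <- NULL; annotation <- ing$annotation
  }
  manifest$counts$n_subjects <- nrow(cohort)

  # ---- QC ------------------------------------------------------------------
  excluded <- character()
  if (isTRUE(config$qc)) {
    excluded <- stage("qc", {
      qp <- config$qc_params
      qc_outliers(proteins, n_components = min(qp$n_components,
                                               min(dim(proteins)) - 1),
                  n_neighbors = min(qp$n_neighbors, nrow(proteins) - 1),
                  tukey_k = qp$tukey_k)
    })
    keep <- !(cohort$subject_id %in% excluded)
    cohort <- cohort[keep, , drop = FALSE]
    proteins <- proteins[cohort$subject_id, , drop = FALSE]
    if (!is.null(latent)) latent <- latent[keep, , drop = FALSE]
  }
  manifest$counts$qc_excluded <- length(excluded)
  manifest$counts$n_after_qc <- nrow(cohort)

  # ---- covariate preparation ----------------------------------------------
  cohort$education_f <- factor(cohort$education)
  adj <- config$adjust
  if (config$impute == "simple") {
    cohort <- impute_simple(cohort, adj, logf)
    manifest$counts$covariates_imputed <- attr(cohort, "n_imputed")
  } else {
    chk(!anyNA(cohort[, intersect(adj, names(cohort))]),
        "missing covariates present and impute = 'none'")
  }

  # ---- clocks --------------------------------------------------------------
  specs <- stage("clocks", {
    if (!is.null(config$paths) && !is.null(config$paths$clocks_dir)) {
      files <- list.files(config$paths$clocks_dir, "\\.json$", full.names = TRUE)
      lapply(files, read_clock_json)
    } else {
      ck <- config$clocks
      tr <- sims$train
      ages_tr <- stats::setNames(tr$cohort$age, tr$cohort$subject_id)
      conv <- lapply(seq_len(ck$n_conventional), function(k) {
        set.seed(derive_seed(seed, 10L + k))
        sub <- sample(colnames(tr$proteins),
                      round(ck$subset_fraction * ncol(tr$proteins)))
        train_clock(tr$proteins[, sub, drop = FALSE], ages_tr,
                    alpha = ck$alpha, n_folds = ck$n_folds,
                    seed = derive_seed(seed, 20L + k),
                    name = paste0("conv", k))
      })
      org <- list()
      if (isTRUE(ck$train_organ) && !is.null(tr$annotation)) {
        organs <- c(sort(unique(tr$annotation$organ[
          tr$annotation$enrichment >= ck$enrichment_threshold])), "organismal")
        org <- lapply(organs, function(o) {
          ids <- select_organ_proteins(tr$annotation, o, ck$enrichment_threshold)
          if (length(ids) < 2) return(NULL)
          train_clock(tr$proteins[, ids, drop = FALSE], ages_tr,
                      alpha = ck$alpha, n_folds = ck$n_folds,
                      seed = derive_seed(seed, 50L + match(o, organs)),
                      name = o, organ = o)
        })
        org <- Filter(Negate(is.null), org)
      }
      c(conv, org)
    }
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  clock_dir <- file.path(config$output_dir, "clocks")
  dir.create(clock_dir, showWarnings = FALSE)
  for (sp in specs) write_clock_json(sp, file.path(clock_dir,
                                                   paste0(sp$name, ".json")))
  conv_names <- names(specs)[vapply(specs, `[[`, "", "organ") == "conventional"]
  manifest$counts$n_clocks <- length(specs)

  # ---- age gaps ------------------------------------------------------------
  gaps <- stage("agegap", {
    predicted <- lapply(specs, function(sp) apply_clock(proteins, sp))
    ages <- stats::setNames(cohort$age, cohort$subject_id)
    tab <- age_gap_table(predicted, ages, fraction = config$lowess_fraction,
                         global_name = if (length(conv_names) >= 2) "Global" else NULL,
                         global_clocks = conv_names)
    write_tsv_file(tab, file.path(config$output_dir, "agegap.tsv"))
    tab
  })
  gap_wide <- stats::reshape(
    gaps[, c("subject_id", "clock", "gap_z")], direction = "wide",
    idvar = "subject_id", timevar = "clock")
  names(gap_wide) <- sub("^gap_z\\.", "gap_", names(gap_wide))
  clock_names <- unique(gaps$clock)

  # ---- survival: events, case-cohort sample, associations ------------------
  if (is.null(config$paths)) {
    events_all <- stage("simulate_survival", {
      do.call(rbind, lapply(seq_along(config$endpoints), function(e) {
        nm <- names(config$endpoints)[e]
        ov <- config$endpoints[[e]]$gompertz
        cfg_e <- sims$cfg
        cfg_e$gompertz[names(ov)] <- ov
        simulate_survival(cohort, latent, cfg_e, endpoint = nm,
                          seed = derive_seed(seed, 200L + e))
      }))
    })
  } else {
    events_all <- ing$events
    events_all <- events_all[events_all$subject_id %in% cohort$subject_id, ]
  }
  sub_frac <- if (!is.null(config$subcohort_fraction)) config$subcohort_fraction
              else if (is.null(config$paths)) sims$cfg$subcohort_fraction else 1
  sampled <- stage("case_cohort_sample",
                   sample_case_cohort(events_all, sub_frac,
                                      seed = derive_seed(seed, 300L)))
  manifest$counts$subcohort_size <-
    length(unique(sampled$subject_id[sampled$in_subcohort]))

  assoc <- stage("associations", {
    rows <- list()
    for (ep in unique(sampled$endpoint)) {
      rec <- sampled[sampled$endpoint == ep, , drop = FALSE]
      rec <- merge(rec, cohort, by = "subject_id")
      rec <- merge(rec, gap_wide, by = "subject_id")
      rec$stratum <- make_strata(rec)
      recp <- prentice_weights(rec)
      manifest$counts[[paste0("n_cases_", ep)]] <- sum(rec$event)
      for (cl in clock_names) {
        for (mo in config$models) {
          rows[[length(rows) + 1L]] <- fit_stratified_cox(
            recp, exposure = paste0("gap_", cl),
            adjust = if (mo == "adjusted") adj else character(),
            clock = cl, model = mo)
        }
      }
    }
    tab <- do.call(rbind, rows)
    # FDR families: conventional (+ Global) and organ-specific, per model
    fam <- ifelse(tab$clock %in% c(conv_names, "Global"), "conventional", "organ")
    for (f in unique(fam)) for (mo in unique(tab$model)) {
      sel <- fam == f & tab$model == mo
      tab$q[sel] <- bh_fdr(tab$p[sel])
    }
    write_tsv_file(tab, file.path(config$output_dir, "associations.tsv"))
    tab
  })

  # ---- lag sensitivity -----------------------------------------------------
  if (isTRUE(config$do_lags) && "Global" %in% clock_names) {
    stage("lags", {
      ep <- unique(sampled$endpoint)[1]
      rec <- merge(merge(sampled[sampled$endpoint == ep, ], cohort,
                         by = "subject_id"), gap_wide, by = "subject_id")
      rec$stratum <- make_strata(rec)
      out <- lag_sensitivity(rec, "gap_Global", adjust = adj,
                             lag_years = config$lags)
      write_tsv_file(out, file.path(config$output_dir, "lag_sensitivity.tsv"))
    })
  }

  # ---- risk factors (subcohort) -------------------------------------------
  if (isTRUE(config$do_riskfactors) && "Global" %in% clock_names) {
    stage("riskfactors", {
      subj <- unique(sampled$subject_id[sampled$in_subcohort])
      d <- merge(cohort[cohort$subject_id %in% subj, ], gap_wide,
                 by = "subject_id")
      d <- cbind(d, compute_hli(d))
      d$smoking_cat <- factor(
        ifelse(d$smoking_status == "never", "never",
        ifelse(d$smoking_status == "former", "former",
        ifelse(d$cigarettes_day >= 16, "current16plus", "currentlt16"))),
        levels = c("current16plus", "currentlt16", "former", "never"))
      d$hli_q <- factor(paste0("Q", d$hli_quintile),
                        levels = paste0("Q", 1:5))
      sm <- gap_on_factor(d, "gap_Global", "smoking_cat")
      hq <- gap_on_factor(d, "gap_Global", "hli_q")
      write_tsv_file(rbind(sm, hq),
                     file.path(config$output_dir, "riskfactor_categories.tsv"))
      d$alcohol_s <- as.numeric(scale(d$alcohol_gday))
      d$bmi_s <- as.numeric(scale(d$bmi))
      d$diet_s <- as.numeric(scale(d$diet_score))
      d$activity_s <- as.numeric(scale(d$activity_met))
      d$smoking_current <- as.numeric(d$smoking_status == "current")
      d$education_high <- as.numeric(d$education >= 5)
      mm <- gap_on_factors_mutual(
        d, paste0("gap_", intersect(c(conv_names, "Global"), clock_names)),
        factors = c("smoking_current", "alcohol_s", "bmi_s", "diet_s",
                    "activity_s", "education_high"))
      write_tsv_file(mm$table,
                     file.path(config$output_dir, "riskfactor_matrix.tsv"))
      manifest$counts$n_subcohort_riskfactors <- nrow(d)
    })
  }

  # ---- age-relatedness -----------------------------------------------------
  if (isTRUE(config$do_age_relatedness) && "Global" %in% clock_names) {
    stage("age_relatedness", {
      eps <- unique(events_all$endpoint)
      beta <- vapply(eps, function(ep) {
        fit_gompertz_makeham(
          incidence_series(events_all[events_all$endpoint == ep, ],
                           endpoint = ep))$rate_b
      }, numeric(1))
      glog <- assoc[assoc$clock == "Global" &
                      assoc$model == utils::tail(config$models, 1), ]
      logHRs <- stats::setNames(glog$logHR, glog$endpoint)
      tabl <- data.frame(endpoint = eps, rate_b = beta,
                         logHR_global = logHRs[eps], row.names = NULL)
      write_tsv_file(tabl, file.path(config$output_dir, "age_relatedness.tsv"))
      if (length(eps) >= 5) {
        ct <- correlate_age_relatedness(logHRs, beta)
        manifest$age_relatedness <- ct
      }
      m <- with(assoc[assoc$model == utils::tail(config$models, 1), ],
                tapply(logHR, list(clock, endpoint), mean))
      if (nrow(m) > 1 && ncol(m) > 1 && !anyNA(m)) {
        cl <- cluster_associations(m)
        jsonlite::write_json(list(row_order = rownames(m)[cl$row_order],
                                  col_order = colnames(m)[cl$col_order]),
                             file.path(config$output_dir, "heatmap_order.json"),
                             auto_unbox = TRUE)
      }
    })
  }

  # ---- concordance comparison ---------------------------------------------
  if (isTRUE(config$do_concordance) && "Global" %in% clock_names) {
    stage("concordance", {
      ep <- unique(sampled$endpoint)[1]
      rec <- merge(merge(sampled[sampled$endpoint == ep, ], cohort,
                         by = "subject_id"), gap_wide, by = "subject_id")
      rec$stratum <- make_strata(rec)
      recp <- prentice_weights(rec)
      organ_gaps <- paste0("gap_", setdiff(clock_names, c(conv_names, "Global")))
      specs_c <- list(risk_factors = adj, global_gap = "gap_Global",
                      combined = c(adj, "gap_Global"))
      if (length(organ_gaps) >= 2)
        specs_c$organ_gaps_risk_factors <- c(adj, organ_gaps)
      out <- compare_models_concordance(recp, specs_c,
                                        n_boot = config$concordance_boot,
                                        seed = derive_seed(seed, 400L))
      write_tsv_file(out, file.path(config$output_dir, "concordance.tsv"))
      out
    })
  }

  manifest$outputs <- sort(setdiff(list.files(config$output_dir,
                                              recursive = TRUE), "log.txt"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("run complete")
  out_dir <- config$output_dir
  attr(out_dir, "manifest") <- manifest
  invisible(out_dir)
}
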