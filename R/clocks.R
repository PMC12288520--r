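# Linear proteomic age clocks: representation, preprocessing "lifting",
# multivariate QC, application, elastic-net training, organ restriction.

#' Create a clock specification
#'
#' A clock is a named linear age predictor: `predicted_age_i = intercept +
#' sum_j weight_j * preprocess_j(x_ij)`, where each analyte's preprocessing
#' is one of `identity`, `log10`, or `zscore` (with stored training mean/SD).
#'
#' @param name clock label.
#' @param intercept intercept in years.
#' @param weights named numeric vector, analyte_id -> coefficient (non-empty).
#' @param preprocess named list, analyte_id -> `list(kind = "identity")`,
#'   `list(kind = "log10")` or `list(kind = "zscore", mean =, sd =)`. Missing
#'   entries default to identity.
#' @param organ organ label, or `"conventional"` / `"organismal"`.
#' @param training_meta free-text provenance (training n, age range).
#' @return an object of class `clock_spec`.
#' @export
clock_spec <- function(name, intercept, weights, preprocess = NULL,
                       organ = "conventional", training_meta = "") {
  chk(is.character(name) && length(name) == 1L, "name must be a single string")
  chk(is_num1(intercept), "intercept must be a finite number")
  chk(is.numeric(weights) && length(weights) > 0 && !is.null(names(weights)) &&
        all(nzchar(names(weights))), "weights must be a non-empty named numeric vector")
  chk(all(is.finite(weights)), "weights must be finite")
  if (is.null(preprocess)) preprocess <- list()
  for (id in names(weights)) {
    if (is.null(preprocess[[id]])) preprocess[[id]] <- list(kind = "identity")
    pp <- preprocess[[id]]
    chk(pp$kind %in% c("identity", "log10", "zscore"),
        "unknown preprocess kind '", pp$kind, "' for analyte ", id)
    if (pp$kind == "zscore") {
      chk(is_num1(pp$mean) && is_num1(pp$sd) && pp$sd > 0,
          "zscore preprocess for analyte ", id, " needs finite mean and sd > 0")
    }
  }
  structure(list(name = name, organ = organ, intercept = intercept,
                 weights = weights, preprocess = preprocess[names(weights)],
                 training_meta = training_meta),
            class = "clock_spec")
}

#' @export
print.clock_spec <- function(x, ...) {
  cat("<clock_spec> ", x$name, " (", x$organ, "): ",
      length(x$weights), " analytes, intercept ", signif(x$intercept, 4),
      "\n", sep = "")
  invisible(x)
}

#' Read / write a clock specification as JSON
#'
#' Schema: `{name, organ, intercept, weights: {id: coef},
#' preprocess: {id: {kind, mean?, sd?}}, training_meta}`. The reader
#' validates the schema and rejects files that do not conform.
#'
#' @param path JSON file path.
#' @return `read_clock_json` returns a `clock_spec`.
#' @export
read_clock_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("name", "organ", "intercept", "weights", "preprocess")
  chk(all(need %in% names(obj)),
      "clock JSON missing fields: ", paste(setdiff(need, names(obj)), collapse = ", "))
  w <- unlist(obj$weights)
  pp <- lapply(obj$preprocess, function(p) as.list(p))
  clock_spec(obj$name, obj$intercept, w, pp, organ = obj$organ,
             training_meta = if (is.null(obj$training_meta)) "" else obj$training_meta)
}

#' @rdname read_clock_json
#' @param spec a `clock_spec`.
#' @export
write_clock_json <- function(spec, path) {
  chk(inherits(spec, "clock_spec"), "spec must be a clock_spec")
  jsonlite::write_json(
    list(name = spec$name, organ = spec$organ, intercept = spec$intercept,
         weights = as.list(spec$weights), preprocess = spec$preprocess,
         training_meta = spec$training_meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Lift intensities between assay versions with multiplicative scale factors
#'
#' @param matrix numeric protein matrix (subjects x analytes).
#' @param scale_factors named positive numeric vector covering every analyte
#'   in the matrix; missing analytes are an error, as are non-positive factors.
#' @return the rescaled matrix.
#' @export
lift_intensities <- function(matrix, scale_factors) {
  ids <- colnames(matrix)
  missing <- setdiff(ids, names(scale_factors))
  chk(length(missing) == 0,
      "no scale factor for analytes: ", paste(missing, collapse = ", "))
  f <- scale_factors[ids]
  chk(all(is.finite(f)) && all(f > 0), "scale factors must be positive and finite")
  sweep(matrix, 2, f, "*")
}

#' Local outlier factor scores
#'
#' Classic k-nearest-neighbour LOF: the ratio of the average local
#' reachability density of a point's neighbours to its own. Neighbourhoods
#' include all points within the k-distance (ties included). Scores near 1
#' indicate inliers; scores substantially above 1 indicate local outliers.
#'
#' @param x numeric matrix (observations in rows).
#' @param k number of neighbours.
#' @return numeric vector of LOF scores.
#' @export
lof_scores <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  chk(is_count(k) && k >= 1, "k must be a positive integer")
  chk(k < n, "k (n_neighbors) must be smaller than the number of observations")
  # blockwise distance computation keeps memory bounded for large cohorts
  sq <- rowSums(x^2)
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  ndist <- vector("list", n)
  block <- max(1L, min(n, floor(2e7 / n)))
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(n, s + block - 1L)
    d2 <- outer(sq[idx], sq, "+") - 2 * x[idx, , drop = FALSE] %*% t(x)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    for (r in seq_along(idx)) {
      i <- idx[r]
      di <- d[r, ]; di[i] <- Inf
      o <- order(di)
      kd <- di[o[k]]
      nb <- which(di <= kd)
      kdist[i] <- kd
      nbrs[[i]] <- nb
      ndist[[i]] <- di[nb]
    }
  }
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[nbrs[[i]]], ndist[[i]])
    1 / mean(reach)
  }, numeric(1))
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], numeric(1))
}

#' Flag multivariate outlier subjects
#'
#' Projects the log10-transformed, column-standardized protein matrix onto
#' its top principal components, scores each subject with the local outlier
#' factor in that projection, and flags subjects whose score exceeds
#' `Q3 + tukey_k * IQR` of the score distribution (Tukey's rule).
#'
#' @param matrix positive protein matrix (subjects x analytes).
#' @param n_components number of principal components retained (must be
#'   smaller than both dimensions).
#' @param n_neighbors LOF neighbourhood size (must be < number of subjects).
#' @param tukey_k Tukey multiplier.
#' @return character vector of flagged subject IDs (possibly empty), with the
#'   LOF scores attached as attribute `"scores"`.
#' @export
qc_outliers <- function(matrix, n_components = 10, n_neighbors = 20,
                        tukey_k = 1.5) {
  chk(all(matrix > 0), "intensities must be positive before log transform")
  chk(is_count(n_components) && n_components >= 1 &&
        n_components < min(dim(matrix)),
      "n_components must be < min(n_subjects, n_analytes)")
  chk(n_neighbors < nrow(matrix), "n_neighbors must be < number of subjects")
  lx <- log10(matrix)
  sds <- apply(lx, 2, sd1)
  keep <- sds > 0
  z <- scale(lx[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = n_components)
  scores <- lof_scores(pc$x, k = n_neighbors)
  names(scores) <- rownames(matrix)
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + tukey_k * (q[2] - q[1])
  flagged <- names(scores)[scores > thr]
  attr(flagged, "scores") <- scores
  flagged
}

preprocess_column <- function(x, pp, id) {
  switch(pp$kind,
         identity = x,
         log10 = {
           chk(all(x > 0), "log10 preprocessing needs positive intensities (analyte ",
               id, ")")
           log10(x)
         },
         zscore = (x - pp$mean) / pp$sd)
}

#' Apply a clock to a protein matrix
#'
#' @param matrix numeric protein matrix (subjects x analytes).
#' @param spec a [clock_spec()].
#' @return named numeric vector of predicted ages (years), one per subject.
#'   Analytes required by the clock but absent from the matrix are an error
#'   (there is deliberately no silent imputation).
#' @export
apply_clock <- function(matrix, spec) {
  chk(inherits(spec, "clock_spec"), "spec must be a clock_spec")
  ids <- names(spec$weights)
  missing <- setdiff(ids, colnames(matrix))
  chk(length(missing) == 0,
      "matrix is missing analytes required by clock '", spec$name, "': ",
      paste(missing, collapse = ", "))
  X <- matrix[, ids, drop = FALSE]
  for (j in seq_along(ids)) {
    X[, j] <- preprocess_column(X[, j], spec$preprocess[[ids[j]]], ids[j])
  }
  pred <- spec$intercept + drop(X %*% spec$weights)
  names(pred) <- rownames(matrix)
  pred
}

#' Train an elastic-net proteomic age clock
#'
#' Cross-validated elastic-net regression of chronological age on
#' column-standardized intensities; the returned [clock_spec()] stores the
#' training means/SDs as `zscore` preprocessing entries so the clock is
#' self-contained. Lambda is chosen at the cross-validation minimum.
#'
#' @param matrix protein matrix (subjects x analytes).
#' @param ages named numeric vector of chronological ages covering the
#'   matrix rows.
#' @param alpha elastic-net mixing (1 = lasso, 0 = ridge).
#' @param n_folds CV folds.
#' @param seed integer seed controlling fold assignment (deterministic).
#' @param name,organ labels stored in the returned `clock_spec`.
#' @return a `clock_spec` (analytes with zero coefficients are dropped).
#' @export
train_clock <- function(matrix, ages, alpha = 0.5, n_folds = 5, seed = 1L,
                        name = "trained", organ = "conventional") {
  chk(nrow(matrix) >= 50, "need at least 50 subjects to train a clock")
  chk(!is.null(names(ages)), "ages must be named by subject_id")
  chk(all(rownames(matrix) %in% names(ages)), "ages missing for some subjects")
  y <- ages[rownames(matrix)]
  chk(all(is.finite(y)), "ages must be finite")
  chk(sd1(y) > 0, "age vector is constant; cannot train")
  mu <- colMeans(matrix)
  sds <- apply(matrix, 2, sd1)
  keep <- sds > 0
  chk(any(keep), "all analytes are constant")
  Z <- scale(matrix[, keep, drop = FALSE], center = mu[keep], scale = sds[keep])
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(Z)))
  cv <- glmnet::cv.glmnet(Z, y, alpha = alpha, foldid = foldid,
                          standardize = FALSE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  beta <- co[-1, 1]
  nz <- which(beta != 0)
  if (length(nz) == 0) {  # fully shrunk: keep the single largest-|cv| analyte at 0
    warning("elastic net shrank all coefficients to zero; clock predicts the mean age")
    nz <- 1L
  }
  ids <- colnames(Z)[nz]
  pp <- lapply(ids, function(id) list(kind = "zscore", mean = unname(mu[id]),
                                      sd = unname(sds[id])))
  names(pp) <- ids
  clock_spec(name = name, intercept = co[1, 1], weights = beta[nz],
             preprocess = pp, organ = organ,
             training_meta = sprintf("n=%d, age range %.1f-%.1f, alpha=%g",
                                     nrow(Z), min(y), max(y), alpha))
}

#' Select organ-enriched analytes from an annotation table
#'
#' @param annotation data.frame with columns `analyte_id`, `organ`,
#'   `enrichment` (fold-change of organ expression over the maximum of other
#'   organs; one row per (analyte, organ)).
#' @param organ organ label, or `"organismal"` for analytes below threshold
#'   for every organ.
#' @param fold_threshold inclusion threshold; the boundary is inclusive
#'   (enrichment equal to the threshold is selected).
#' @return character vector of analyte IDs.
#' @export
select_organ_proteins <- function(annotation, organ, fold_threshold = 4) {
  chk(all(c("analyte_id", "organ", "enrichment") %in% names(annotation)),
      "annotation must have columns analyte_id, organ, enrichment")
  chk(all(annotation$enrichment > 0), "enrichment values must be > 0")
  organs <- unique(annotation$organ)
  if (identical(organ, "organismal")) {
    enriched <- unique(annotation$analyte_id[annotation$enrichment >= fold_threshold])
    return(sort(setdiff(unique(annotation$analyte_id), enriched)))
  }
  chk(organ %in% organs, "unknown organ '", organ, "'")
  sel <- annotation$organ == organ & annotation$enrichment >= fold_threshold
  sort(unique(annotation$analyte_id[sel]))
}
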