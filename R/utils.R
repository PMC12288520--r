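# Internal helpers shared across modules.

chk <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child seed from a master seed
#'
#' One master seed governs every stochastic stage of an analysis run; each
#' stage draws its own child seed through this deterministic map so that
#' stages stay independent yet reproducible. Child seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer identifying the stage (or stage + replicate).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  chk(is_count(abs(seed)), "seed must be an integer")
  chk(is_count(offset), "offset must be a non-negative integer")
  as.integer((abs(seed) %% 1000003) * 1009 + 7 * offset + 1)
}

#' Read and write the package's tab-separated tables
#'
#' All tabular artifacts (cohort, latent state, events, age gaps,
#' association results) are plain TSV with a header row and unquoted values.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return `read_tsv_file` returns a data.frame; `write_tsv_file` returns
#'   the path invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# sample SD convention used package-wide: denominator n - 1
sd1 <- function(x) stats::sd(x)
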