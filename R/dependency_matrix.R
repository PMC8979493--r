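# Dependency-score matrix container and per-profile normalization.

#' Construct a dependency-score matrix
#'
#' A `dependency_matrix` holds a genes x samples matrix of quantitative
#' knockout-effect scores (e.g. CERES gene-effect scores, where -1 is the
#' median of common-essential genes and 0 the median of non-dependencies).
#' Missing values are permitted per cell.
#'
#' @param scores numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids character vectors of row/column identifiers;
#'   default to the dimnames of `scores`.
#' @param entrez optional integer vector of Entrez ids parallel to `gene_ids`.
#' @return An object of class `dependency_matrix`: a list with `scores`
#'   (a named numeric matrix), `gene_ids`, `sample_ids` and `entrez`.
#' @export
dependency_matrix <- function(scores, gene_ids = rownames(scores),
                              sample_ids = colnames(scores), entrez = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    dmx_validation_error("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(scores) != length(gene_ids) || ncol(scores) != length(sample_ids))
    dmx_validation_error("id lists do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    dmx_validation_error(paste0("duplicate gene ids: ",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (anyDuplicated(sample_ids))
    dmx_validation_error(paste0("duplicate sample ids: ",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  dimnames(scores) <- list(gene_ids, sample_ids)
  structure(list(scores = scores, gene_ids = gene_ids,
                 sample_ids = sample_ids, entrez = entrez),
            class = "dependency_matrix")
}

#' @export
print.dependency_matrix <- function(x, ...) {
  cat(sprintf("dependency_matrix: %d genes x %d samples (%d missing cells)\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  invisible(x)
}

#' Z-score a dependency profile
#'
#' Centers and scales one gene's score vector to mean 0, sample standard
#' deviation 1 (denominator n - 1). Missing values are passed through
#' unchanged and excluded from the moments.
#'
#' @param scores numeric vector of per-sample scores for one gene.
#' @return numeric vector of z-scores, same length and names as the input.
#' @export
zscore_profile <- function(scores) {
  fin <- is.finite(scores)
  if (sum(fin) < 2L)
    dmx_degenerate_error("need at least 2 finite values to z-score")
  s <- sd(scores[fin])
  if (!is.finite(s) || s <= 0)
    dmx_degenerate_error("zero-variance profile cannot be z-scored")
  out <- scores
  out[fin] <- (scores[fin] - mean(scores[fin])) / s
  out
}

#' Select genes with extreme-outlier samples
#'
#' Flags genes whose z-scored profile has at least
#' `max(1, ceiling(min_outlier_fraction * n))` samples at least `n_sigma`
#' sample standard deviations from the profile mean (n counts finite values).
#' With `n_sigma = 6` and the default fraction this is the classical
#' "six sigma" pre-filter for screen profiles (one extreme sample suffices);
#' `n_sigma = 3, min_outlier_fraction = 0.2` is the variant used for
#' dependency-probability matrices.
#'
#' @param x a [dependency_matrix()].
#' @param n_sigma positive number of standard deviations.
#' @param min_outlier_fraction required fraction of outlier samples in
#'   \[0, 1\]; the implied count is never below 1.
#' @return character vector of gene ids passing the filter. Degenerate
#'   (zero-variance or nearly-all-missing) rows are skipped with a warning.
#' @export
sigma_outlier_filter <- function(x, n_sigma = 6, min_outlier_fraction = 0) {
  stopifnot(inherits(x, "dependency_matrix"), n_sigma > 0,
            min_outlier_fraction >= 0, min_outlier_fraction <= 1)
  keep <- character(0)
  skipped <- character(0)
  for (g in x$gene_ids) {
    row <- x$scores[g, ]
    z <- tryCatch(zscore_profile(row), depmex_degenerate_error = function(e) NULL)
    if (is.null(z)) { skipped <- c(skipped, g); next }
    nfin <- sum(is.finite(z))
    need <- max(1L, ceiling(min_outlier_fraction * nfin))
    if (sum(abs(z) >= n_sigma, na.rm = TRUE) >= need) keep <- c(keep, g)
  }
  if (length(skipped)) {
    warning(sprintf("skipped %d degenerate profile(s): %s", length(skipped),
                    paste(head(skipped, 5L), collapse = ", ")),
            call. = FALSE)
    dmx_log("sigma_filter", skipped = skipped)
  }
  keep
}
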