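# Binary genomic-alteration and cancer-type feature matrices built from
# annotated mutation tables and sample metadata.

ONCOGENIC_VOCAB <- c("Oncogenic", "Likely Oncogenic", "Likely Neutral",
                     "Inconclusive", "Unknown", "Resistance")
EFFECT_VOCAB <- c("Gain-of-function", "Likely Gain-of-function",
                  "Loss-of-function", "Likely Loss-of-function",
                  "Switch-of-function", "Likely Switch-of-function",
                  "Neutral", "Likely Neutral", "Inconclusive", "Unknown", "")
NOT_ONCOGENIC <- c("Likely Neutral", "Inconclusive", "Unknown", "Resistance")
GOF_EFFECTS <- c("Gain-of-function", "Likely Gain-of-function")
LOF_EFFECTS <- c("Loss-of-function", "Likely Loss-of-function")

# Variant classes treated as synonymous/conserving and excluded upstream.
SILENT_CLASSES <- c("Silent", "silent", "Other conserving", "other conserving")

#' Mutation record table
#'
#' Validates and normalizes a table of annotated somatic mutations. One row
#' per mutation call, with the annotation columns produced by an
#' OncoKB-style annotator.
#'
#' @param gene,sample character vectors (non-empty entries required).
#' @param variant_class variant classification (e.g. Missense_Mutation).
#' @param protein_change protein-level change string (may be empty).
#' @param in_oncokb logical: is the gene curated in OncoKB?
#' @param oncogenic one of `Oncogenic`, `Likely Oncogenic`, `Likely
#'   Neutral`, `Inconclusive`, `Unknown`, `Resistance`.
#' @param mutation_effect one of the OncoKB biological-effect categories
#'   (Gain/Loss/Switch-of-function and their Likely variants, Neutral,
#'   Inconclusive, Unknown) or empty.
#' @return A `data.frame` of class `mutation_records`.
#' @export
mutation_records <- function(gene, sample, variant_class = "Missense_Mutation",
                             protein_change = "", in_oncokb = TRUE,
                             oncogenic = "Unknown", mutation_effect = "Unknown") {
  df <- data.frame(gene = as.character(gene), sample = as.character(sample),
                   variant_class = as.character(variant_class),
                   protein_change = as.character(protein_change),
                   in_oncokb = as.logical(in_oncokb),
                   oncogenic = as.character(oncogenic),
                   mutation_effect = as.character(mutation_effect),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$gene)) || any(!nzchar(df$sample)))
    dmx_validation_error("gene and sample must be non-empty",
                         rows = which(!nzchar(df$gene) | !nzchar(df$sample)))
  bad <- which(!(df$oncogenic %in% ONCOGENIC_VOCAB) & df$in_oncokb)
  if (length(bad))
    dmx_validation_error(
      paste0("unknown ONCOGENIC value(s) in rows ",
             paste(head(bad, 10L), collapse = ", "), ": ",
             paste(unique(df$oncogenic[bad]), collapse = ", ")), rows = bad)
  bad <- which(!(df$mutation_effect %in% EFFECT_VOCAB) & df$in_oncokb)
  if (length(bad))
    dmx_validation_error(
      paste0("unknown MUTATION_EFFECT value(s) in rows ",
             paste(head(bad, 10L), collapse = ", "), ": ",
             paste(unique(df$mutation_effect[bad]), collapse = ", ")),
      rows = bad)
  class(df) <- c("mutation_records", "data.frame")
  df
}

#' Drop synonymous / conserving mutation calls
#' @param records a [mutation_records()] table.
#' @return the table without `Silent` / `Other conserving` rows.
#' @export
filter_nonsynonymous <- function(records) {
  drop <- records$variant_class %in% SILENT_CLASSES
  if (any(drop)) dmx_log("features", dropped_silent = sum(drop))
  records[!drop, , drop = FALSE]
}

# A / I / O class of one annotated mutation
classify_mutation <- function(oncogenic, mutation_effect) {
  ifelse(oncogenic %in% NOT_ONCOGENIC, "O",
    ifelse(mutation_effect %in% GOF_EFFECTS, "A",
      ifelse(mutation_effect %in% LOF_EFFECTS, "I", "O")))
}

new_feature_matrix <- function(a, feature_ids, sample_ids, feature_kind,
                               feature_gene, feature_class) {
  storage.mode(a) <- "integer"
  stopifnot(all(a %in% c(0L, 1L)))
  dimnames(a) <- list(feature_ids, sample_ids)
  structure(list(feature_ids = feature_ids, sample_ids = sample_ids, a = a,
                 feature_kind = feature_kind, feature_gene = feature_gene,
                 feature_class = feature_class),
            class = "feature_matrix")
}

#' Binary feature matrix
#'
#' Container for an m x n binary matrix of features (rows) across samples
#' (columns). Mutation features carry labels `GENE(A)`, `GENE(I)`,
#' `GENE(O)`; cancer-type features `CancerType:<name>`.
#'
#' @param a binary matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param feature_kind `"mutation"` or `"cancer_type"` per row.
#' @param feature_gene,feature_class per-row gene symbol and A/I/O class
#'   (`NA` for cancer-type rows); parsed from labels when omitted.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(a, feature_kind = NULL, feature_gene = NULL,
                           feature_class = NULL) {
  a <- as.matrix(a)
  if (is.null(rownames(a)) || is.null(colnames(a)))
    dmx_validation_error("feature matrix needs feature and sample names")
  ids <- rownames(a)
  if (is.null(feature_kind))
    feature_kind <- ifelse(grepl("^CancerType:", ids), "cancer_type",
                           "mutation")
  parsed <- regmatches(ids, regexec("^(.*)\\(([AIO])\\)$", ids))
  if (is.null(feature_gene))
    feature_gene <- vapply(parsed, function(p)
      if (length(p) == 3L) p[2] else NA_character_, character(1))
  if (is.null(feature_class))
    feature_class <- vapply(parsed, function(p)
      if (length(p) == 3L) p[3] else NA_character_, character(1))
  new_feature_matrix(a, ids, colnames(a), feature_kind, feature_gene,
                     feature_class)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features (%d mutation, %d cancer-type) x %d samples\n",
              length(x$feature_ids), sum(x$feature_kind == "mutation"),
              sum(x$feature_kind == "cancer_type"), length(x$sample_ids)))
  invisible(x)
}

#' Group annotated mutations into GENE(A)/(I)/(O) features
#'
#' For each OncoKB-curated gene, mutations are grouped by annotation:
#' not-oncogenic calls (Likely Neutral, Inconclusive, Unknown; Resistance
#' is treated likewise and logged) go to `GENE(O)`; oncogenic calls
#' (Oncogenic, Likely Oncogenic) with Gain-of-function or Likely
#' Gain-of-function effect to `GENE(A)`; oncogenic with Loss-of-function
#' or Likely Loss-of-function effect to `GENE(I)`; oncogenic with any
#' other effect to `GENE(O)`. `a[i, j] = 1` iff sample j carries at least
#' one mutation in feature i; all-zero features are dropped (so are
#' features below `min_freq` mutated samples).
#'
#' Records should already be restricted to non-synonymous classes (see
#' [filter_nonsynonymous()]); genes not curated in OncoKB are ignored.
#'
#' @param records a [mutation_records()] table.
#' @param sample_ids sample universe (columns); defaults to the samples
#'   present in `records`.
#' @param min_freq minimum number of mutated samples per kept feature.
#' @return A `feature_matrix` with mutation rows only.
#' @export
group_mutation_features <- function(records, sample_ids = NULL,
                                    min_freq = 1L) {
  if (!inherits(records, "mutation_records"))
    records <- mutation_records(records$gene, records$sample,
                                records$variant_class, records$protein_change,
                                records$in_oncokb, records$oncogenic,
                                records$mutation_effect)
  rec <- records[records$in_oncokb, , drop = FALSE]
  if (any(rec$oncogenic == "Resistance"))
    dmx_log("features", resistance_mapped_to_O =
              sum(rec$oncogenic == "Resistance"))
  if (is.null(sample_ids)) sample_ids <- sort(unique(records$sample))
  if (nrow(rec) == 0L)
    return(new_feature_matrix(
      matrix(0L, 0L, length(sample_ids)), character(0), sample_ids,
      character(0), character(0), character(0)))
  cls <- classify_mutation(rec$oncogenic, rec$mutation_effect)
  label <- paste0(rec$gene, "(", cls, ")")
  feats <- sort(unique(label))
  a <- matrix(0L, length(feats), length(sample_ids),
              dimnames = list(feats, sample_ids))
  sj <- match(rec$sample, sample_ids)
  if (anyNA(sj))
    dmx_validation_error(paste0("records reference unknown samples: ",
      paste(unique(rec$sample[is.na(sj)]), collapse = ", ")))
  a[cbind(match(label, feats), sj)] <- 1L
  keep <- rowSums(a) >= max(1L, as.integer(min_freq))
  a <- a[keep, , drop = FALSE]
  feats <- feats[keep]
  gene <- sub("\\(([AIO])\\)$", "", feats)
  fcls <- sub("^.*\\(([AIO])\\)$", "\\1", feats)
  new_feature_matrix(a, feats, sample_ids, rep("mutation", length(feats)),
                     gene, fcls)
}

#' Cancer-type indicator features
#'
#' One binary row per distinct cancer-type label; rows are disjoint by
#' construction and the column sums over the cancer-type block equal 1.
#'
#' @param metadata named character vector (names = sample ids, values =
#'   cancer-type labels) or a data.frame with columns `sample` and
#'   `cancer_type`.
#' @return A `feature_matrix` with cancer-type rows only.
#' @export
cancer_type_features <- function(metadata) {
  if (is.data.frame(metadata)) {
    stopifnot(all(c("sample", "cancer_type") %in% names(metadata)))
    metadata <- setNames(as.character(metadata$cancer_type),
                         as.character(metadata$sample))
  }
  missing <- names(metadata)[is.na(metadata) | !nzchar(metadata)]
  if (length(missing))
    dmx_validation_error(paste0("samples without a cancer-type label: ",
                                paste(missing, collapse = ", ")))
  if (anyDuplicated(names(metadata)))
    dmx_validation_error("duplicate sample ids in metadata")
  types <- sort(unique(metadata))
  sample_ids <- names(metadata)
  a <- matrix(0L, length(types), length(sample_ids),
              dimnames = list(paste0("CancerType:", types), sample_ids))
  a[cbind(match(metadata, types), seq_along(sample_ids))] <- 1L
  new_feature_matrix(a, rownames(a), sample_ids,
                     rep("cancer_type", length(types)),
                     rep(NA_character_, length(types)),
                     rep(NA_character_, length(types)))
}

#' Merge mutation and cancer-type feature matrices
#'
#' Row-wise concatenation after aligning samples by id.
#'
#' @param mut,ct [feature_matrix()] objects over the same sample set.
#' @return the combined `feature_matrix`; feature kinds are preserved.
#' @export
merge_feature_matrices <- function(mut, ct) {
  stopifnot(inherits(mut, "feature_matrix"), inherits(ct, "feature_matrix"))
  if (length(ct$feature_ids) == 0L) return(mut)
  if (length(mut$feature_ids) == 0L) return(ct)
  if (!setequal(mut$sample_ids, ct$sample_ids))
    dmx_validation_error(paste0("sample ids differ: ",
      paste(head(c(setdiff(mut$sample_ids, ct$sample_ids),
                   setdiff(ct$sample_ids, mut$sample_ids)), 5L),
            collapse = ", ")))
  ct_a <- ct$a[, mut$sample_ids, drop = FALSE]
  dup <- intersect(mut$feature_ids, ct$feature_ids)
  if (length(dup))
    dmx_validation_error(paste0("duplicate feature ids: ",
                                paste(dup, collapse = ", ")))
  new_feature_matrix(rbind(mut$a, ct_a),
                     c(mut$feature_ids, ct$feature_ids), mut$sample_ids,
                     c(mut$feature_kind, ct$feature_kind),
                     c(mut$feature_gene, ct$feature_gene),
                     c(mut$feature_class, ct$feature_class))
}
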