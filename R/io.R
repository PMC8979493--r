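# Readers and writers for screen matrices, mutation tables, metadata,
# feature matrices and result tables. Matrices travel as comma-separated
# files, tables as tab-separated; all writes are atomic (temp + rename).

strip_entrez <- function(ids) {
  m <- regmatches(ids, regexec("^(.*?)\\s*\\((\\d+)\\)$", ids))
  list(id = vapply(m, function(p) if (length(p) == 3L) p[2] else NA_character_,
                   character(1)),
       entrez = vapply(m, function(p)
         if (length(p) == 3L) as.integer(p[3]) else NA_integer_, integer(1)))
}

#' Read a dependency-score matrix from CSV
#'
#' Expects a DepMap-style layout: first column holds row identifiers, the
#' header the column identifiers. Gene symbols carrying an
#' `" (EntrezID)"` suffix are stripped; the Entrez ids are kept in the
#' `entrez` field.
#'
#' @param path CSV file path.
#' @param genes_in `"rows"` (default) or `"cols"` — where genes live.
#' @return a [dependency_matrix()].
#' @export
read_dependency_matrix <- function(path, genes_in = c("rows", "cols")) {
  genes_in <- match.arg(genes_in)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L)
    dmx_validation_error(sprintf("'%s': no data columns", path))
  row_ids <- dt[[1L]]
  body <- as.matrix(dt[, -1L, with = FALSE])
  if (!is.numeric(body)) {
    bad <- which(!vapply(dt[, -1L, with = FALSE], is.numeric, logical(1)))
    badrows <- which(!grepl("^\\s*(NA|[-+eE.0-9]*)\\s*$",
                            as.character(dt[[bad[1] + 1L]])))
    dmx_validation_error(sprintf(
      "'%s': non-numeric values in column %d (e.g. line %s)", path,
      bad[1] + 1L,
      paste(head(badrows + 1L, 3L), collapse = ", ")))
  }
  if (anyDuplicated(row_ids))
    dmx_validation_error(sprintf("'%s': duplicate row ids", path))
  if (genes_in == "cols") {
    body <- t(body)
    gene_raw <- colnames(dt)[-1L]
    sample_ids <- row_ids
  } else {
    gene_raw <- row_ids
    sample_ids <- colnames(dt)[-1L]
  }
  se <- strip_entrez(gene_raw)
  gene_ids <- ifelse(is.na(se$id), gene_raw, se$id)
  dimnames(body) <- NULL
  dependency_matrix(body, gene_ids = gene_ids, sample_ids = sample_ids,
                    entrez = se$entrez)
}

#' Write a dependency matrix to CSV (genes in rows)
#' @param x a [dependency_matrix()]; @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_dependency_matrix <- function(x, path) {
  stopifnot(inherits(x, "dependency_matrix"))
  atomic_write(path, function(tmp) {
    dt <- data.table::data.table(gene_id = x$gene_ids)
    dt <- cbind(dt, data.table::as.data.table(x$scores))
    data.table::fwrite(dt, tmp, sep = ",", na = "NA")
  })
}

#' Read an annotated mutation table
#'
#' Accepts tab- or comma-delimited tables with columns `Hugo_Symbol`, a
#' sample id (`Tumor_Sample_Barcode` or `DepMap_ID`),
#' `Variant_Classification`, `Protein_Change` (optional), and the
#' annotator columns `GENE_IN_ONCOKB`, `ONCOGENIC`, `MUTATION_EFFECT`.
#' Silent / other-conserving rows are dropped (count logged).
#'
#' @param path file path.
#' @param drop_silent drop synonymous classes (default `TRUE`).
#' @return a [mutation_records()] table.
#' @export
read_mutation_table <- function(path, drop_silent = TRUE) {
  dt <- data.table::fread(path, header = TRUE)
  need <- c("Hugo_Symbol", "Variant_Classification", "GENE_IN_ONCOKB",
            "ONCOGENIC", "MUTATION_EFFECT")
  idcol <- intersect(c("Tumor_Sample_Barcode", "DepMap_ID"), names(dt))
  missing <- c(setdiff(need, names(dt)),
               if (length(idcol) == 0L) "Tumor_Sample_Barcode/DepMap_ID")
  if (length(missing))
    dmx_validation_error(sprintf("'%s': missing required column(s): %s", path,
                                 paste(missing, collapse = ", ")))
  pc <- if ("Protein_Change" %in% names(dt)) dt$Protein_Change else ""
  okb <- dt$GENE_IN_ONCOKB
  if (!is.logical(okb)) okb <- toupper(as.character(okb)) %in% c("TRUE", "T", "1", "YES")
  rec <- mutation_records(dt$Hugo_Symbol, dt[[idcol[1L]]],
                          dt$Variant_Classification, pc, okb,
                          dt$ONCOGENIC, dt$MUTATION_EFFECT)
  n0 <- nrow(rec)
  if (drop_silent) rec <- filter_nonsynonymous(rec)
  if (nrow(rec) < n0)
    message(sprintf("read_mutation_table: dropped %d silent/conserving rows",
                    n0 - nrow(rec)))
  rec
}

#' Write mutation records as a tab-separated table
#' @param records a [mutation_records()]; @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  atomic_write(path, function(tmp) {
    dt <- data.table::data.table(
      Hugo_Symbol = records$gene, DepMap_ID = records$sample,
      Variant_Classification = records$variant_class,
      Protein_Change = records$protein_change,
      GENE_IN_ONCOKB = records$in_oncokb, ONCOGENIC = records$oncogenic,
      MUTATION_EFFECT = records$mutation_effect)
    data.table::fwrite(dt, tmp, sep = "\t")
  })
}

#' Read sample metadata (cancer types)
#'
#' @param path CSV path with a sample-id column and a cancer-type column.
#' @param type_col cancer-type column name (default `"Cancer_type"`).
#' @param id_col sample-id column name; default: first of `DepMap_ID`,
#'   `sample`, or the first column.
#' @return named character vector, sample id -> cancer type. Errors list
#'   any samples with missing labels.
#' @export
read_metadata <- function(path, type_col = "Cancer_type", id_col = NULL) {
  dt <- data.table::fread(path, header = TRUE)
  if (is.null(id_col))
    id_col <- intersect(c("DepMap_ID", "sample", "sample_id"),
                        names(dt))[1] %||% names(dt)[1]
  if (!type_col %in% names(dt))
    dmx_validation_error(sprintf("'%s': no column '%s'", path, type_col))
  lab <- setNames(as.character(dt[[type_col]]), as.character(dt[[id_col]]))
  bad <- names(lab)[is.na(lab) | !nzchar(lab)]
  if (length(bad))
    dmx_validation_error(paste0("samples without a cancer-type label: ",
                                paste(bad, collapse = ", ")))
  lab
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Write a feature matrix (dense CSV and sparse triplet TSV)
#' @param x a [feature_matrix()]; @param path base path: writes
#'   `<path>.csv` (dense) and `<path>.triplets.tsv` (feature, sample, 1).
#' @return character vector of the two paths, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  dense <- paste0(path, ".csv")
  atomic_write(dense, function(tmp) {
    dt <- data.table::data.table(feature_id = x$feature_ids,
                                 feature_kind = x$feature_kind)
    dt <- cbind(dt, data.table::as.data.table(x$a))
    data.table::fwrite(dt, tmp, sep = ",")
  })
  trip <- paste0(path, ".triplets.tsv")
  atomic_write(trip, function(tmp) {
    idx <- which(x$a == 1L, arr.ind = TRUE)
    dt <- data.table::data.table(feature_id = x$feature_ids[idx[, 1L]],
                                 sample_id = x$sample_ids[idx[, 2L]],
                                 value = 1L)
    data.table::fwrite(dt[order(feature_id, sample_id)], tmp, sep = "\t")
  })
  invisible(c(dense, trip))
}

#' Read a dense feature-matrix CSV written by [write_feature_matrix()]
#' @param path the `.csv` path.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  a <- as.matrix(dt[, -(1:2), with = FALSE])
  rownames(a) <- dt$feature_id
  feature_matrix(a, feature_kind = dt$feature_kind)
}

#' Write association results and a run manifest
#'
#' Emits `associations.tsv` (one row per tested profile: profile id,
#' direction, `|`-joined features, weight, per-feature p-values, set
#' p-value, q-value, permutations used, responsive coverage) and
#' `manifest.json` (package version, seed, parameters, config hash).
#'
#' @param results list of association rows (as built by [run_pipeline()]).
#' @param dir output directory.
#' @param config the run configuration to record.
#' @return path of the associations table, invisibly.
#' @export
write_results <- function(results, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.table::rbindlist(lapply(results, function(r)
    data.table::data.table(
      profile = r$gene_id, direction = r$direction,
      features = paste(r$feature_set, collapse = "|"),
      weight = r$weight,
      feature_p = paste(sprintf("%.6g", r$feature_p), collapse = "|"),
      set_p = r$set_p, q = r$fdr_q, n_perm = r$n_perm %||% NA_integer_,
      covered_responsive = r$covered_responsive %||% NA_integer_,
      n_responsive = r$n_responsive %||% NA_integer_)))
  out <- file.path(dir, "associations.tsv")
  atomic_write(out, function(tmp) data.table::fwrite(tab, tmp, sep = "\t"))
  manifest <- list(
    package = "depmex",
    version = as.character(utils::packageVersion("depmex")),
    seed = config$seed %||% NA,
    parameters = config[setdiff(names(config), "seed")],
    config_hash = substr(digest_config(config), 1L, 16L),
    n_results = length(results))
  atomic_write(file.path(dir, "manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, null = "null"))
  invisible(out)
}

digest_config <- function(config) {
  if (is.null(config)) return("none")
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        null = "null", force = TRUE)
  # small stable rolling hash; avoids a digest-package dependency
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a synthetic cohort to a directory
#'
#' Emits the file formats the readers consume (`dependency.csv`,
#' `mutations.tsv`, `metadata.csv` when present) plus a `truth.json`
#' ground-truth manifest.
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dependency_matrix(cohort$dep, file.path(dir, "dependency.csv"))
  write_mutation_table(cohort$records, file.path(dir, "mutations.tsv"))
  if (!is.null(cohort$metadata))
    atomic_write(file.path(dir, "metadata.csv"), function(tmp)
      data.table::fwrite(data.table::data.table(
        DepMap_ID = names(cohort$metadata),
        Cancer_type = unname(cohort$metadata)), tmp, sep = ","))
  truth <- cohort$truth
  atomic_write(file.path(dir, "truth.json"), function(tmp)
    jsonlite::write_json(list(genes = truth$genes,
                              responsive = truth$responsive,
                              planted = truth$planted,
                              spec = unclass(cohort$spec)),
                         tmp, auto_unbox = TRUE, null = "null"))
  invisible(dir)
}
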