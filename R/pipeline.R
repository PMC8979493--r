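# Top-level pipeline: score -> features -> per-profile association ->
# model selection -> significance -> BH across profiles.

#' Pipeline run configuration
#'
#' Bundles every tunable of a pipeline run. Defaults follow the reference
#' protocol: 10,000 model-selection permutations with removal threshold
#' 1e-4, up to 500,000 significance permutations, discovery at
#' `q <= 0.2`, set size at most 3 for mutation-only runs and 5 when
#' cancer-type features are present.
#'
#' @param dependency_path,mutations_path,metadata_path input files
#'   (metadata optional; any may be `NULL` when an in-memory `cohort` is
#'   passed to [run_pipeline()]).
#' @param genes_in orientation of the dependency CSV (`"rows"`/`"cols"`).
#' @param k maximum feature-set size; `NULL` = 3 without metadata, 5 with.
#' @param direction `"auto"` (each profile tested in its own responsive
#'   direction) or `"both"`.
#' @param sigma_prefilter keep only genes passing
#'   [sigma_outlier_filter()] at this many sds (`NULL` disables);
#'   `min_outlier_fraction` its companion fraction.
#' @param n_model_select,alpha_remove model-selection budget and removal
#'   threshold.
#' @param n_significance_max,stop_threshold significance budget and
#'   adaptive-stop threshold (`NULL` disables early stopping).
#' @param fdr_threshold discovery threshold on BH q-values.
#' @param min_freq minimum mutated samples per feature.
#' @param min_n minimum finite scores per profile for mixture fitting.
#' @param permute_features_directly see [association_significance()].
#' @param seed master seed; every stage derives named sub-seeds from it.
#' @param out_dir output directory (`NULL` = no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(dependency_path = NULL, mutations_path = NULL,
                       metadata_path = NULL, genes_in = "rows", k = NULL,
                       direction = c("auto", "both"),
                       sigma_prefilter = NULL, min_outlier_fraction = 0,
                       n_model_select = 10000L, alpha_remove = 1e-4,
                       n_significance_max = 500000L, stop_threshold = 0.25,
                       fdr_threshold = 0.2, min_freq = 1L, min_n = 20L,
                       permute_features_directly = FALSE,
                       seed = 1L, out_dir = NULL) {
  direction <- match.arg(direction)
  cfg <- as.list(environment())
  stopifnot(n_model_select > 0L, n_significance_max > 0L,
            fdr_threshold > 0, alpha_remove > 0)
  class(cfg) <- "run_config"
  cfg
}

# score every profile: z-score, optional sigma prefilter, 2C calls
score_profiles <- function(dep, config) {
  zs <- dep$scores
  degenerate <- character(0)
  for (g in dep$gene_ids) {
    z <- tryCatch(zscore_profile(dep$scores[g, ]),
                  depmex_degenerate_error = function(e) NULL)
    if (is.null(z)) { degenerate <- c(degenerate, g); zs[g, ] <- NA }
    else zs[g, ] <- z
  }
  keep <- setdiff(dep$gene_ids, degenerate)
  zdep <- dependency_matrix(zs[keep, , drop = FALSE])
  if (!is.null(config$sigma_prefilter)) {
    keep <- suppressWarnings(sigma_outlier_filter(
      zdep, n_sigma = config$sigma_prefilter,
      min_outlier_fraction = config$min_outlier_fraction))
    dmx_log("score", sigma_kept = length(keep))
  }
  calls <- lapply(keep, function(g) {
    gs <- derive_seed(config$seed, paste0("score:", g))
    ok <- tryCatch(select_two_component(zdep$scores[g, ], seed = gs,
                                        min_n = config$min_n),
                   depmex_fit_error = function(e) NA)
    if (isTRUE(as.logical(ok))) {
      prof <- compute_2c_profile(zdep$scores[g, ], seed = gs, gene_id = g)
      list(gene_id = g, is_2c = TRUE, bic_1c = attr(ok, "bic_1c"),
           bic_2c = attr(ok, "bic_2c"), profile = prof)
    } else {
      # FALSE = called one-component; NA = fit failure (skipped)
      list(gene_id = g, is_2c = as.logical(ok),
           bic_1c = attr(ok, "bic_1c") %||% NA_real_,
           bic_2c = attr(ok, "bic_2c") %||% NA_real_, profile = NULL)
    }
  })
  list(zdep = zdep, calls = calls, degenerate = degenerate)
}

#' Run the full association pipeline
#'
#' Scores differential dependencies, builds the feature matrix, finds the
#' optimal feature set per 2C profile in its responsive direction, prunes
#' it by conditional permutation, evaluates fixed-margin significance and
#' applies BH FDR across all tested profiles. Identical config and seed
#' give identical outputs.
#'
#' @param config a [run_config()].
#' @param cohort optional in-memory cohort (as from [generate_cohort()]);
#'   when `NULL`, inputs are read from the paths in `config`.
#' @return invisibly, a list with `calls` (per-gene differential
#'   dependency table), `associations` (list of association rows),
#'   `table` (data.frame view), and `paths` of any files written.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    dep <- read_dependency_matrix(config$dependency_path, config$genes_in)
    records <- read_mutation_table(config$mutations_path)
    metadata <- if (!is.null(config$metadata_path))
      read_metadata(config$metadata_path) else NULL
    mut_features <- group_mutation_features(
      filter_nonsynonymous(records), sample_ids = dep$sample_ids,
      min_freq = config$min_freq)
    features <- if (is.null(metadata)) mut_features
      else merge_feature_matrices(mut_features,
                                  cancer_type_features(metadata[dep$sample_ids]))
  } else {
    dep <- cohort$dep; records <- cohort$records
    metadata <- cohort$metadata; features <- cohort$features
  }
  k <- config$k %||% (if (is.null(metadata)) 3L else 5L)

  scored <- score_profiles(dep, config)
  profiles <- Filter(function(cl) isTRUE(cl$is_2c), scored$calls)
  dmx_log("pipeline", n_2c = length(profiles))

  associations <- list()
  for (cl in profiles) {
    prof <- cl$profile
    dirs <- if (config$direction == "auto") prof$direction
            else c("increased", "decreased")
    for (dr in dirs) {
      row <- tryCatch({
        inst <- weighted_instance(prof$d, dr, features)
        res <- solve_exclusive_cover(inst, k = k, gene_id = prof$gene_id)
        gs <- derive_seed(config$seed, paste0("assoc:", prof$gene_id, dr))
        if (length(res$feature_set)) {
          ms <- conditional_model_selection(
            res$feature_set, inst, n_perm = config$n_model_select,
            alpha_remove = config$alpha_remove, seed = gs)
          sig <- association_significance(
            ms$retained_set, inst, full_records = records, k = k,
            max_perm = config$n_significance_max, seed = gs,
            stop_threshold = config$stop_threshold,
            min_freq = config$min_freq,
            permute_features_directly = config$permute_features_directly)
          resp <- sum(if (dr == "increased") inst$d_prime < 0
                      else inst$d_prime > 0, na.rm = TRUE)
          covd <- feature_set_samples(ms$retained_set, inst, dr)
          list(gene_id = prof$gene_id, direction = dr,
               feature_set = ms$retained_set,
               weight = sig$observed_weight, feature_p = ms$feature_p,
               set_p = sig$p, n_perm = sig$n_perm, fdr_q = NA_real_,
               covered_responsive = covd, n_responsive = resp,
               model_selection = ms)
        } else {
          list(gene_id = prof$gene_id, direction = dr,
               feature_set = character(0), weight = 0,
               feature_p = numeric(0), set_p = 1, n_perm = 0L,
               fdr_q = NA_real_, covered_responsive = 0L,
               n_responsive = NA_integer_, model_selection = NULL)
        }
      }, depmex_error = function(e) {
        dmx_log("pipeline", gene = prof$gene_id, direction = dr,
                error = conditionMessage(e))
        NULL
      })
      if (!is.null(row)) associations[[length(associations) + 1L]] <- row
    }
  }
  # one BH family per run
  if (length(associations)) {
    q <- bh_fdr(vapply(associations, `[[`, numeric(1), "set_p"))
    for (i in seq_along(associations)) associations[[i]]$fdr_q <- q[i]
  }

  calls_tab <- data.table::rbindlist(lapply(scored$calls, function(cl)
    data.table::data.table(
      gene_id = cl$gene_id, is_2c = isTRUE(cl$is_2c),
      direction = if (!is.null(cl$profile)) cl$profile$direction
                  else NA_character_,
      responsive_n = if (!is.null(cl$profile)) cl$profile$responsive_n
                     else NA_integer_,
      bic_1c = cl$bic_1c, bic_2c = cl$bic_2c)))

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p1 <- file.path(config$out_dir, "differential_dependencies.tsv")
    atomic_write(p1, function(tmp) data.table::fwrite(calls_tab, tmp,
                                                      sep = "\t"))
    d2 <- do.call(rbind, lapply(profiles, function(cl) cl$profile$d))
    if (!is.null(d2)) {
      rownames(d2) <- vapply(profiles, function(cl) cl$gene_id, character(1))
      p2 <- file.path(config$out_dir, "two_component_scores.csv")
      atomic_write(p2, function(tmp) {
        dt <- data.table::data.table(gene_id = rownames(d2))
        dt <- cbind(dt, data.table::as.data.table(d2))
        data.table::fwrite(dt, tmp, sep = ",", na = "NA")
      })
      paths <- c(paths, p2)
    }
    p3 <- write_results(associations, config$out_dir, config = unclass(config))
    paths <- c(paths, p1, p3)
  }

  tab <- if (length(associations))
    data.frame(
      profile = vapply(associations, `[[`, character(1), "gene_id"),
      direction = vapply(associations, `[[`, character(1), "direction"),
      features = vapply(associations, function(r)
        paste(r$feature_set, collapse = "|"), character(1)),
      weight = vapply(associations, `[[`, numeric(1), "weight"),
      set_p = vapply(associations, `[[`, numeric(1), "set_p"),
      q = vapply(associations, `[[`, numeric(1), "fdr_q"),
      stringsAsFactors = FALSE)
    else data.frame(profile = character(0), direction = character(0),
                    features = character(0), weight = numeric(0),
                    set_p = numeric(0), q = numeric(0))

  invisible(list(calls = as.data.frame(calls_tab), associations = associations,
                 table = tab, paths = paths, k = k))
}

# number of responsive-sign samples covered by a feature set
feature_set_samples <- function(M, inst, direction) {
  if (length(M) == 0L) return(0L)
  idx <- match(M, inst$features$feature_ids)
  cov <- colSums(inst$features$a[idx, , drop = FALSE]) > 0L
  resp <- if (direction == "increased") inst$d_prime < 0 else inst$d_prime > 0
  sum(cov & resp, na.rm = TRUE)
}
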