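# Model selection by conditional permutation, empirical significance by
# fixed-margin (curveball) matrix randomization, and BH FDR control.

#' Curveball randomization of a binary matrix
#'
#' Samples a binary matrix with the same row sums and column sums as the
#' input by repeated random pair trades: two rows exchange a random split
#' of the columns they do not share. The trade chain is approximately
#' uniform over the fixed-margin class.
#'
#' @param A binary matrix.
#' @param n_trades number of attempted trades; default `5 * nrow(A)`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a binary matrix of the same dimensions and margins.
#' @export
curveball_randomize <- function(A, n_trades = 5L * nrow(A), seed = NULL) {
  A <- as.matrix(A)
  stopifnot(all(A %in% c(0L, 1L)))
  rows <- apply(A, 1L, function(r) which(r == 1L), simplify = FALSE)
  rows <- with_seed_(seed, curveball_lists(rows, n_trades))
  out <- matrix(0L, nrow(A), ncol(A), dimnames = dimnames(A))
  for (i in seq_along(rows)) out[i, rows[[i]]] <- 1L
  out
}

# core trade loop over row coverage lists (column indices); compiled in
# src/bb.cpp, draws from the R RNG so runs are seed-reproducible
curveball_lists <- function(rows, n_trades) {
  if (length(rows) < 2L) return(rows)
  .curveball_cpp(lapply(rows, as.integer), as.integer(n_trades))
}

# Fast weight evaluation used by the permutation loops: canonical U-space
# pieces of one instance plus the current feature set.
inst_core_env <- function(inst) {
  core <- solver_core(inst)
  core$n <- length(core$v)
  core
}

# U of a feature set given core pieces and coverage lists per set member
set_U <- function(core, idx) {
  if (length(idx) == 0L) return(0)
  cnt <- integer(core$n)
  U <- 0
  for (g in unique(core$grp[idx])) {
    members <- idx[core$grp[idx] == g]
    jj <- unique(unlist(core$cov[members]))
    U <- U + sum(ifelse(cnt[jj] == 0L, core$v[jj], -core$absdp[jj]))
    cnt[jj] <- cnt[jj] + 1L
  }
  U
}

#' Conditional-permutation model selection over an optimal feature set
#'
#' Evaluates each feature's contribution to the set weight by permuting
#' that feature's row across samples (preserving its mutation count) and
#' recomputing the set weight. The per-feature empirical p-value is the
#' add-one-corrected fraction of permutations whose weight is at least as
#' extreme as observed (`<=` for increased, `>=` for decreased
#' dependencies). The single worst feature is removed if its p-value
#' exceeds `alpha_remove`, p-values are recomputed on the reduced set, and
#' the process repeats until every retained feature passes.
#'
#' Note the add-one estimator floors p at `1/(n_perm + 1)`; `alpha_remove`
#' is only attainable when `n_perm >= 1/alpha_remove - 1`.
#'
#' @param Mstar character vector: the optimal feature set to prune.
#' @param inst a [weighted_instance()].
#' @param n_perm permutations per feature test (default 10000).
#' @param alpha_remove retention threshold on the per-feature p-value
#'   (default 1e-4).
#' @param seed integer seed.
#' @return A `model_selection_report`: list with `initial_set`,
#'   `retained_set`, `feature_p` (named, for the final iteration's
#'   surviving features plus each removed feature at removal time),
#'   `removed`, `n_perm`.
#' @export
conditional_model_selection <- function(Mstar, inst, n_perm = 10000L,
                                        alpha_remove = 1e-4, seed = 1L) {
  stopifnot(inherits(inst, "weighted_instance"), length(Mstar) >= 1L)
  core <- inst_core_env(inst)
  idx_all <- match(Mstar, core$labels)
  if (anyNA(idx_all))
    dmx_validation_error(paste0("unknown feature(s): ",
                                paste(Mstar[is.na(idx_all)], collapse = ", ")))
  removed <- character(0)
  removed_p <- numeric(0)
  cur <- idx_all
  final_p <- setNames(numeric(0), character(0))
  with_seed_(derive_seed(seed, "model_selection"), {
    repeat {
      if (length(cur) == 0L) break
      U_obs <- set_U(core, cur)
      pvals <- vapply(seq_along(cur), function(ii) {
        m_idx <- cur[ii]
        others <- cur[-ii]
        # fixed contribution of the other features
        cnt_other <- integer(core$n)
        for (g in unique(core$grp[others])) {
          jj <- unique(unlist(core$cov[others[core$grp[others] == g]]))
          cnt_other[jj] <- cnt_other[jj] + 1L
        }
        U_other <- set_U(core, others)
        # samples already covered by m's own penalty group (two-hit partner)
        partner_cov <- unlist(core$cov[others[core$grp[others] ==
                                                core$grp[m_idx]]])
        sz <- length(core$cov[[m_idx]])
        hits <- 0L
        for (b in seq_len(n_perm)) {
          jj <- sample.int(core$n, sz)
          newj <- if (length(partner_cov)) jj[match(jj, partner_cov, 0L) == 0L]
                  else jj
          dU <- sum(ifelse(cnt_other[newj] == 0L, core$v[newj],
                           -core$absdp[newj]))
          if (U_other + dU >= U_obs - 1e-12) hits <- hits + 1L
        }
        (1 + hits) / (1 + n_perm)
      }, numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] > alpha_remove) {
        removed <- c(removed, core$labels[cur[worst]])
        removed_p <- c(removed_p, pvals[worst])
        cur <- cur[-worst]
      } else {
        final_p <- setNames(pvals, core$labels[cur])
        break
      }
    }
  })
  structure(list(initial_set = Mstar, retained_set = sort(core$labels[cur]),
                 feature_p = final_p,
                 removed = setNames(removed_p, removed), n_perm = n_perm),
            class = "model_selection_report")
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat(sprintf("model selection: retained {%s} of {%s} (%d permutations)\n",
              paste(x$retained_set, collapse = ", "),
              paste(x$initial_set, collapse = ", "), x$n_perm))
  invisible(x)
}

# Build the distinct-mutation-identity representation used to condition on
# true mutation margins: one row per distinct mutation (gene + variant +
# annotation), coverage = samples carrying it.
mutation_identity_rows <- function(records, sample_ids) {
  key <- paste(records$gene, records$variant_class, records$protein_change,
               records$in_oncokb, records$oncogenic, records$mutation_effect,
               sep = "\r")
  uk <- unique(key)
  ki <- match(key, uk)
  sj <- match(records$sample, sample_ids)
  if (anyNA(sj))
    dmx_validation_error("mutation records reference samples outside cohort")
  cov <- split(sj, ki)
  cov <- lapply(cov, unique)
  first <- match(seq_along(uk), ki)
  attrs <- records[first, c("gene", "in_oncokb", "oncogenic",
                            "mutation_effect"), drop = FALSE]
  cls <- classify_mutation(attrs$oncogenic, attrs$mutation_effect)
  label <- ifelse(attrs$in_oncokb, paste0(attrs$gene, "(", cls, ")"),
                  NA_character_)
  list(cov = cov[as.character(seq_along(uk))], label = label,
       gene = attrs$gene)
}

#' Empirical significance of an association by fixed-margin randomization
#'
#' Compares the observed set weight against optimal weights recomputed on
#' randomized cohorts: each permutation curveball-randomizes the full
#' mutation matrix (all non-synonymous mutations, one row per distinct
#' mutation identity, so per-mutation frequencies and per-sample burdens
#' are preserved), re-derives the OncoKB feature matrix by the same
#' grouping rules, and solves the same k-constrained optimization (no
#' model selection). Cancer-type features, whose margins are fixed by
#' construction, are held fixed. The empirical p-value uses the add-one
#' estimator `p = (1 + #extreme) / (1 + N)`.
#'
#' @param Mbar character vector: the retained feature set (observed
#'   statistic is its weight).
#' @param inst a [weighted_instance()].
#' @param full_records [mutation_records()] for all mutations (including
#'   genes not in OncoKB), required to condition on true margins. May be
#'   `NULL` only with `permute_features_directly = TRUE`.
#' @param k cardinality bound passed to the solver.
#' @param max_perm permutation budget (default 500000; tests use far less).
#' @param seed integer seed.
#' @param stop_threshold adaptive early stop: stop when the 99% CI of p
#'   lies entirely above this (default 0.25, above any FDR-relevant value);
#'   `NULL` disables early stopping.
#' @param min_freq feature-frequency filter applied when re-grouping.
#' @param permute_features_directly if `TRUE`, curveball the feature matrix
#'   itself instead of re-grouping mutations (approximate, faster).
#' @return A `significance_report`: `observed_weight`, `p`, `n_perm`,
#'   `perm_weights` (first 1000 permuted optima; the search is seeded just
#'   below the observed statistic, so optima weaker than the observed
#'   weight are censored at that bound), `direction`.
#' @export
association_significance <- function(Mbar, inst, full_records = NULL,
                                     k = 3L, max_perm = 500000L, seed = 1L,
                                     stop_threshold = 0.25, min_freq = 1L,
                                     permute_features_directly = FALSE) {
  stopifnot(inherits(inst, "weighted_instance"))
  core <- inst_core_env(inst)
  W_obs <- feature_set_weight(Mbar, inst)
  if (length(Mbar) == 0L)
    return(structure(list(observed_weight = 0, p = 1, n_perm = 0L,
                          perm_weights = numeric(0),
                          direction = inst$direction),
                     class = "significance_report"))
  U_obs <- if (inst$direction == "increased") -W_obs else W_obs

  fm <- inst$features
  ct_rows <- which(fm$feature_kind == "cancer_type")
  ct_cov <- core$cov[ct_rows]
  ct_grp_base <- seq_along(ct_rows)  # cancer-type rows: own penalty groups

  if (!permute_features_directly) {
    if (is.null(full_records))
      dmx_error("full mutation records are required to condition on margins",
                "depmex_validation_error")
    ident <- mutation_identity_rows(full_records, inst$sample_ids)
    n_trades <- 5L * length(ident$cov)
    # identity -> feature grouping is invariant under permutation
    okb <- which(!is.na(ident$label))
    ident_groups <- split(okb, ident$label[okb])
    glabels <- names(ident_groups)
    ggene <- sub("\\(([AIO])\\)$", "", glabels)
    gcls <- sub("^.*\\(([AIO])\\)$", "\\1", glabels)
    ggrp_key <- ifelse(gcls %in% c("I", "O"), paste0("g:", ggene), glabels)
  } else {
    mut_rows <- which(fm$feature_kind == "mutation")
    mut_cov_obs <- core$cov[mut_rows]
    mut_labels_obs <- fm$feature_ids[mut_rows]
    n_trades <- 5L * length(mut_rows)
  }

  hits <- 0L; n_done <- 0L
  keep_w <- numeric(0)
  batch <- 200L
  with_seed_(derive_seed(seed, "significance"), {
    while (n_done < max_perm) {
      nb <- min(batch, max_perm - n_done)
      for (b in seq_len(nb)) {
        if (!permute_features_directly) {
          rcov <- curveball_lists(ident$cov, n_trades)
          fcov <- lapply(ident_groups, function(ix)
            unique(unlist(rcov[ix], use.names = FALSE)))
          grp_key <- ggrp_key
        } else {
          fcov <- curveball_lists(mut_cov_obs, n_trades)
          labels <- mut_labels_obs
          gene <- sub("\\(([AIO])\\)$", "", labels)
          cls <- sub("^.*\\(([AIO])\\)$", "\\1", labels)
          grp_key <- ifelse(cls %in% c("I", "O"), paste0("g:", gene), labels)
        }
        keep <- lengths(fcov) >= max(1L, min_freq)
        fcov <- fcov[keep]; grp_key <- grp_key[keep]
        all_cov <- c(fcov, ct_cov)
        all_grp <- match(c(grp_key, paste0("ct:", ct_grp_base)),
                         unique(c(grp_key, paste0("ct:", ct_grp_base))))
        # incumbent seeded just below the observed statistic: the search
        # only resolves whether the permuted optimum reaches it, which is
        # all the hit count needs, and prunes hard on null permutations
        sol <- bb_solve(core$v, core$absdp, all_cov, all_grp, k,
                        init_U = U_obs - 1e-7)
        if (sol$U >= U_obs - 1e-12) hits <- hits + 1L
        if (length(keep_w) < 1000L)
          keep_w <- c(keep_w, u_to_w(sol$U, inst$direction))
      }
      n_done <- n_done + nb
      if (!is.null(stop_threshold) && n_done >= 200L && hits > 0L) {
        lower <- qbeta(0.005, hits, n_done - hits + 1L)
        if (is.finite(lower) && lower > stop_threshold) break
      }
    }
  })
  p <- (1 + hits) / (1 + n_done)
  structure(list(observed_weight = W_obs, p = p, n_perm = n_done,
                 perm_weights = keep_w, direction = inst$direction),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("significance: W = %.6g, p = %.4g (%d permutations, %s)\n",
              x$observed_weight, x$p, x$n_perm, x$direction))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjusted p-values with monotonicity enforcement. The
#' conventional discovery threshold for screen associations is
#' `q <= 0.2`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return numeric vector of q-values, same order and names.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    dmx_validation_error("p-values must be finite and within [0, 1]")
  p.adjust(pvalues, method = "BH")
}
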