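# Exclusivity-penalized weighted coverage: the weight function over feature
# sets, normalization of 2C profiles, and two exact solvers (depth-first
# branch-and-bound, and exhaustive enumeration as an independent oracle).

#' Normalize a 2C profile into a weighted optimization instance
#'
#' Divides the per-sample 2C scores by `|S|`, where `S` is the total 2C
#' score mass on the responsive side (`S = sum of d_j over d_j < 0` for
#' increased dependencies, over `d_j > 0` for decreased), so the responsive
#' mass of the normalized scores `d'` sums to -1 (increased) or +1
#' (decreased). The per-sample co-occurrence penalty is `rho_j = -|d'_j|`
#' for increased and `+|d'_j|` for decreased dependencies. Samples with
#' missing scores are treated as uncoverable and carry zero weight.
#'
#' @param d numeric vector of per-sample 2C scores (names = sample ids).
#' @param direction `"increased"` or `"decreased"`.
#' @param features a [feature_matrix()] over the same samples (matched by
#'   id when both are named).
#' @return A `weighted_instance`: list with `d_prime`, `rho`, `direction`,
#'   `features`, and `sample_ids`.
#' @export
weighted_instance <- function(d, direction = c("increased", "decreased"),
                              features) {
  direction <- match.arg(direction)
  stopifnot(inherits(features, "feature_matrix"))
  if (!is.null(names(d))) {
    if (!setequal(names(d), features$sample_ids))
      dmx_validation_error("score and feature sample ids differ")
    d <- d[features$sample_ids]
  } else if (length(d) != length(features$sample_ids)) {
    dmx_validation_error("score length does not match feature matrix")
  }
  resp <- if (direction == "increased") d < 0 else d > 0
  S <- sum(d[which(resp)], na.rm = TRUE)
  if (!is.finite(S) || S == 0)
    dmx_error("no responsive-side score mass (S = 0)", "depmex_degenerate_error")
  dp <- d / abs(S)
  dp[!is.finite(dp)] <- NA_real_
  rho <- if (direction == "increased") -abs(dp) else abs(dp)
  structure(list(d_prime = setNames(dp, features$sample_ids),
                 rho = setNames(rho, features$sample_ids),
                 direction = direction, features = features,
                 sample_ids = features$sample_ids),
            class = "weighted_instance")
}

#' @export
print.weighted_instance <- function(x, ...) {
  cat(sprintf(
    "weighted_instance: %s dependency, %d samples, %d features\n",
    x$direction, length(x$sample_ids), length(x$features$feature_ids)))
  invisible(x)
}

# Penalty groups: features are penalized per co-occurring group, where the
# inactivating (I) and other (O) features of the same gene form one group
# (two-hit exception: a second hit on the same gene is not a co-occurrence).
penalty_group_of <- function(features) {
  ids <- features$feature_ids
  gene <- features$feature_gene
  cls <- features$feature_class
  grp <- ids
  io <- !is.na(cls) & cls %in% c("I", "O") & !is.na(gene)
  grp[io] <- paste0("gene-group:", gene[io])
  match(grp, unique(grp))
}

#' Weight of a feature set
#'
#' `W(M) = sum over covered samples j of d'_j - (c_j(M) - 1) * rho_j`,
#' where `c_j(M)` counts the penalty groups of `M` that cover sample `j`:
#' the same gene's (I) and (O) features count once together (two-hit
#' exception), every other feature counts separately. Mutually exclusive
#' sets are not penalized; each additional co-occurring group costs
#' `|d'_j|` toward the unfavorable direction. `W(empty set) = 0`. Samples
#' with missing `d'` do not contribute.
#'
#' @param M character vector of feature ids (possibly empty).
#' @param inst a [weighted_instance()].
#' @return numeric weight.
#' @export
feature_set_weight <- function(M, inst) {
  stopifnot(inherits(inst, "weighted_instance"))
  if (length(M) == 0L) return(0)
  idx <- match(M, inst$features$feature_ids)
  if (anyNA(idx))
    dmx_validation_error(paste0("unknown feature(s): ",
                                paste(M[is.na(idx)], collapse = ", ")))
  a <- inst$features$a[idx, , drop = FALSE]
  grp <- penalty_group_of(inst$features)[idx]
  # c_j = number of distinct penalty groups covering j
  cj <- integer(ncol(a))
  for (g in unique(grp))
    cj <- cj + as.integer(colSums(a[grp == g, , drop = FALSE]) > 0L)
  covered <- colSums(a) > 0L
  ok <- covered & !is.na(inst$d_prime)
  sum(inst$d_prime[ok] - (cj[ok] - 1L) * inst$rho[ok])
}

# Internal canonical form used by both solvers: maximize
#   U(M) = sum_{j in Gamma(M)} v_j - (c_j(M) - 1) * |d'_j|
# with v = -d' (increased) or +d' (decreased); then W = -U (increased)
# or W = U (decreased). The empty set has U = 0 and only strictly
# positive-U sets are reported.
solver_core <- function(inst) {
  dp <- inst$d_prime
  dp[is.na(dp)] <- 0  # missing samples carry no weight
  v <- if (inst$direction == "increased") -dp else dp
  cov <- lapply(seq_along(inst$features$feature_ids), function(i)
    which(inst$features$a[i, ] == 1L & !is.na(inst$d_prime)))
  list(v = v, absdp = abs(dp), cov = cov,
       grp = penalty_group_of(inst$features),
       labels = inst$features$feature_ids)
}

u_to_w <- function(U, direction) if (direction == "increased") -U else U

build_result <- function(inst, M, gene_id = NULL) {
  W <- feature_set_weight(M, inst)
  if (length(M)) {
    idx <- match(M, inst$features$feature_ids)
    a <- inst$features$a[idx, , drop = FALSE]
    cj <- colSums(a)
    covered <- inst$sample_ids[cj > 0L]
  } else {
    cj <- integer(length(inst$sample_ids)); covered <- character(0)
  }
  structure(list(gene_id = gene_id, direction = inst$direction,
                 feature_set = M, weight = W, covered_samples = covered,
                 coverage_counts = setNames(as.integer(cj), inst$sample_ids),
                 feature_p = NULL, set_p = NA_real_, fdr_q = NA_real_),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result%s: {%s} W = %.6g (%s, %d samples covered)\n",
              if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              paste(x$feature_set, collapse = ", "), x$weight, x$direction,
              length(x$covered_samples)))
  invisible(x)
}

#' Exact optimal feature set (branch-and-bound)
#'
#' Finds the feature set of optimal weight — minimum for increased
#' dependencies, maximum for decreased — over all subsets of at most `k`
#' features, by exact depth-first branch-and-bound with an admissible
#' per-feature bound (a feature can contribute at most the responsive-sign
#' score mass it covers). Returns the empty set (weight 0) when no set
#' improves on 0. Ties are broken to the lexicographically smallest set of
#' sorted feature labels (shorter prefixes first).
#'
#' @param inst a [weighted_instance()].
#' @param k maximum set size, or `NULL` for unconstrained.
#' @param gene_id optional identifier copied into the result.
#' @return An `association_result` with `feature_set`, `weight`,
#'   `covered_samples`, `coverage_counts`.
#' @export
solve_exclusive_cover <- function(inst, k = 3L, gene_id = NULL) {
  stopifnot(inherits(inst, "weighted_instance"))
  core <- solver_core(inst)
  m <- length(core$labels)
  if (m == 0L) return(build_result(inst, character(0), gene_id))
  if (is.null(k)) k <- m
  k <- min(as.integer(k), m)
  stopifnot(k >= 1L)
  ord <- order(core$labels)  # label order => first-found optimum is lex-min
  sol <- bb_solve(core$v, core$absdp, core$cov[ord], core$grp[ord], k)
  build_result(inst, sort(core$labels[ord][sol$idx]), gene_id)
}

# Exact branch-and-bound over coverage lists in the canonical maximize-U
# form; returns indices (into `cov`) of the first-found optimal set.
# Thin wrapper over the compiled search (src/bb.cpp).
bb_solve <- function(v, absdp, cov, grp, k, init_U = 0) {
  m <- length(cov)
  if (m == 0L) return(list(idx = integer(0), U = max(0, init_U)))
  k <- min(as.integer(k), m)
  .bb_solve_cpp(lapply(cov, as.integer), as.integer(grp), as.numeric(v),
                as.numeric(absdp), k, as.numeric(init_U))
}

# lexicographic comparison of sorted label vectors, shorter prefix first
lex_less <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (i in seq_len(min(la, lb))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  la < lb
}

#' Exact optimal feature set (exhaustive enumeration oracle)
#'
#' Enumerates every subset of size at most `k` and returns the optimum of
#' [feature_set_weight()] under the same direction convention and
#' tie-break as [solve_exclusive_cover()]. Intended as an independent
#' correctness oracle for small instances.
#'
#' @inheritParams solve_exclusive_cover
#' @param max_subsets guard on the enumeration budget (default 1e6).
#' @return An `association_result`.
#' @export
solve_exclusive_cover_enum <- function(inst, k = 3L, gene_id = NULL,
                                       max_subsets = 1e6) {
  stopifnot(inherits(inst, "weighted_instance"))
  labels <- sort(inst$features$feature_ids)
  m <- length(labels)
  if (is.null(k)) k <- m
  k <- min(as.integer(k), m)
  total <- sum(choose(m, 0:k))
  if (total > max_subsets)
    dmx_error(sprintf("enumeration budget exceeded (%g subsets)", total),
              "depmex_budget_error")
  better <- function(Wnew, Wold) {
    if (inst$direction == "increased") Wnew < Wold - 1e-9
    else Wnew > Wold + 1e-9
  }
  ties <- function(Wnew, Wold) abs(Wnew - Wold) <= 1e-9
  best_M <- character(0); best_W <- 0
  for (sz in seq_len(k)) {
    combs <- combn(labels, sz, simplify = FALSE)
    for (M in combs) {
      W <- feature_set_weight(M, inst)
      # the empty set (lexicographically smallest) holds W = 0, so a set
      # tying 0 never replaces it; among tying non-empty optima keep lex-min
      if (better(W, best_W) || (ties(W, best_W) && lex_less(M, best_M))) {
        best_M <- M; best_W <- W
      }
    }
  }
  build_result(inst, best_M, gene_id)
}
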