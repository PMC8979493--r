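# Seeded synthetic cohorts with known ground truth: two-component
# dependency profiles on the z-score scale, sparse mutation features with
# heterogeneous per-sample burdens, and planted approximately mutually
# exclusive feature sets enriched in the responsive samples.

#' Specification of a synthetic cohort
#'
#' Defaults mirror the structure of a processed CRISPR dependency screen:
#' 769 samples (cell lines), profiles z-scored to unit marginal variance,
#' a 23% responsive minority for differential genes, component separation
#' of 4 pooled standard deviations, 87% of differential genes with
#' increased dependency, sparse background mutations with gamma-distributed
#' per-sample rate multipliers (hypermutator-like burden heterogeneity).
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param differential_fraction fraction of genes that are true
#'   two-component differential dependencies.
#' @param responsive_fraction mixture weight of the responsive component.
#' @param delta_mu component separation in pooled within-component sd units.
#' @param family `"gaussian"` or `"t"` score noise; `t_df` its df.
#' @param prob_increased probability a differential gene has increased
#'   (negative-side minority) direction.
#' @param n_planted_features planted features per differential gene.
#' @param planted_coverage fraction of responsive samples covered by the
#'   planted set.
#' @param exclusivity probability a covered sample carries exactly one
#'   planted feature.
#' @param n_background_features,background_rate decoy feature count and
#'   base per-feature rate (half of the decoys are OncoKB-annotated and
#'   enter the feature matrix; half only contribute to mutation margins).
#' @param rate_heterogeneity gamma shape of the per-sample rate multiplier
#'   (mean 1, variance `1/rate_heterogeneity`); smaller = more dispersed.
#' @param n_cancer_types number of cancer-type labels (0 = no metadata).
#' @param plant_cancer_type if `TRUE` (needs `n_cancer_types > 0`), one
#'   differential gene's responsive set is exactly the first cancer type.
#' @param seed master seed; all generation is deterministic given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 769L, n_genes = 50L,
                        differential_fraction = 0.2,
                        responsive_fraction = 0.23, delta_mu = 4,
                        family = c("gaussian", "t"), t_df = 10,
                        prob_increased = 0.87,
                        n_planted_features = 3L, planted_coverage = 0.9,
                        exclusivity = 0.95,
                        n_background_features = 30L, background_rate = 0.03,
                        rate_heterogeneity = 1,
                        n_cancer_types = 0L, plant_cancer_type = FALSE,
                        seed = 1L) {
  family <- match.arg(family)
  spec <- list(n_samples = as.integer(n_samples),
               n_genes = as.integer(n_genes),
               differential_fraction = differential_fraction,
               responsive_fraction = responsive_fraction,
               delta_mu = delta_mu, family = family, t_df = t_df,
               prob_increased = prob_increased,
               n_planted_features = as.integer(n_planted_features),
               planted_coverage = planted_coverage,
               exclusivity = exclusivity,
               n_background_features = as.integer(n_background_features),
               background_rate = background_rate,
               rate_heterogeneity = rate_heterogeneity,
               n_cancer_types = as.integer(n_cancer_types),
               plant_cancer_type = isTRUE(plant_cancer_type),
               seed = as.integer(seed))
  fracs <- c(differential_fraction, responsive_fraction, planted_coverage,
             exclusivity, prob_increased)
  if (any(fracs < 0 | fracs > 1) || spec$n_samples < 2L)
    dmx_validation_error("invalid cohort specification")
  class(spec) <- "cohort_spec"
  spec
}

# unit-variance noise draw
score_noise <- function(n, spec) {
  if (spec$family == "gaussian") rnorm(n)
  else rt(n, spec$t_df) * sqrt((spec$t_df - 2) / spec$t_df)
}

#' Generate a dependency-score matrix with known responsive sets
#'
#' Differential genes get two-component profiles on the z-score scale:
#' within-component sd `sigma_c = 1 / sqrt(1 + pi (1 - pi) delta_mu^2)` so
#' the marginal variance is 1, background mean `pi * delta_mu * sigma_c`
#' and responsive mean `delta_mu * sigma_c` lower (increased direction;
#' mirrored for decreased). Non-differential genes are unit-variance
#' one-component noise.
#'
#' @param spec a [cohort_spec()].
#' @param responsive_sets optional named list overriding the responsive
#'   sample indices per differential gene (used to plant cancer-type-driven
#'   dependencies).
#' @return list with `dep` (a [dependency_matrix()]) and `truth`
#'   (per-gene data.frame + `responsive` list of sample-id vectors).
#' @export
generate_dependency_matrix <- function(spec, responsive_sets = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("DEP%03d", seq_len(spec$n_genes))
  n_diff <- round(spec$n_genes * spec$differential_fraction)
  with_seed_(derive_seed(spec$seed, "dependency"), {
    scores <- matrix(NA_real_, spec$n_genes, n,
                     dimnames = list(gene_ids, sample_ids))
    pi1 <- spec$responsive_fraction
    sigma_c <- 1 / sqrt(1 + pi1 * (1 - pi1) * spec$delta_mu^2)
    sep <- spec$delta_mu * sigma_c
    truth <- data.frame(gene_id = gene_ids,
                        is_differential = seq_len(spec$n_genes) <= n_diff,
                        direction = NA_character_,
                        mu_responsive = NA_real_, mu_background = NA_real_,
                        sigma = NA_real_, stringsAsFactors = FALSE)
    responsive <- vector("list", spec$n_genes)
    names(responsive) <- gene_ids
    for (g in seq_len(spec$n_genes)) {
      if (g <= n_diff) {
        gid <- gene_ids[g]
        rs <- if (!is.null(responsive_sets) && !is.null(responsive_sets[[gid]]))
          match(responsive_sets[[gid]], sample_ids)
        else sample.int(n, round(pi1 * n))
        inc <- runif(1) < spec$prob_increased
        pi_g <- length(rs) / n
        # means centered so the marginal mean is ~0 on the z-score scale
        mu_bg <- if (inc) pi_g * sep else -pi_g * sep
        mu_rs <- if (inc) mu_bg - sep else mu_bg + sep
        x <- mu_bg + sigma_c * score_noise(n, spec)
        x[rs] <- mu_rs + sigma_c * score_noise(length(rs), spec)
        scores[g, ] <- x
        truth$direction[g] <- if (inc) "increased" else "decreased"
        truth$mu_responsive[g] <- mu_rs
        truth$mu_background[g] <- mu_bg
        truth$sigma[g] <- sigma_c
        responsive[[g]] <- sample_ids[sort(rs)]
      } else {
        scores[g, ] <- score_noise(n, spec)
      }
    }
    list(dep = dependency_matrix(scores),
         truth = list(genes = truth, responsive = responsive))
  })
}

# planted feature attributes: distinct synthetic genes, classes cycling
# through A/I/O so grouping and the two-hit machinery see all classes
planted_feature_attrs <- function(gene_idx, n_feats) {
  cls <- rep(c("A", "I", "O"), length.out = n_feats)
  gene <- sprintf("PG%03d_%d", gene_idx, seq_len(n_feats))
  onc <- ifelse(cls == "O", "Likely Neutral", "Oncogenic")
  eff <- ifelse(cls == "A", "Gain-of-function",
                ifelse(cls == "I", "Loss-of-function", "Unknown"))
  data.frame(gene = gene, class = cls, oncogenic = onc, effect = eff,
             label = paste0(gene, "(", cls, ")"), stringsAsFactors = FALSE)
}

#' Generate mutation records and feature matrix with planted sets
#'
#' For each differential gene, `n_planted_features` features partition a
#' `planted_coverage` fraction of its responsive samples; each covered
#' sample carries a second planted feature with probability
#' `1 - exclusivity`. Background decoy features are drawn as
#' gamma-mixed Bernoulli (per-sample rate multiplier
#' `Gamma(shape = h, rate = h)`), giving over-dispersed per-sample
#' mutation burdens; half are OncoKB-annotated decoys, half non-OncoKB
#' margin filler.
#'
#' @param spec a [cohort_spec()].
#' @param truth output of [generate_dependency_matrix()]'s `truth`.
#' @return list with `records` ([mutation_records()]), `features`
#'   (mutation-only [feature_matrix()]) and `planted` (named list:
#'   gene id -> planted feature labels).
#' @export
generate_feature_matrix <- function(spec, truth) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  with_seed_(derive_seed(spec$seed, "features"), {
    rec <- list()
    planted <- list()
    diff_genes <- truth$genes$gene_id[truth$genes$is_differential]
    for (gi in seq_along(diff_genes)) {
      gid <- diff_genes[gi]
      rs <- match(truth$responsive[[gid]], sample_ids)
      n_cov <- round(spec$planted_coverage * length(rs))
      if (n_cov < spec$n_planted_features)
        dmx_error(sprintf(
          "infeasible planting for %s: %d covered samples < %d features",
          gid, n_cov, spec$n_planted_features), "depmex_validation_error")
      covered <- sample(rs, n_cov)
      attrs <- planted_feature_attrs(gi, spec$n_planted_features)
      assign1 <- rep(seq_len(spec$n_planted_features), length.out = n_cov)
      assign1 <- sample(assign1)  # balanced random partition
      for (f in seq_len(spec$n_planted_features)) {
        sj <- covered[assign1 == f]
        # exclusivity violations: a second planted feature on the sample
        others <- which(assign1 != f)
        extra <- covered[others[runif(length(others)) <
                                  (1 - spec$exclusivity) /
                                    max(1, spec$n_planted_features - 1)]]
        sj <- unique(c(sj, extra))
        if (length(sj) == 0L) next
        pc <- paste0("p.", attrs$class[f], sample.int(3L, length(sj),
                                                      replace = TRUE))
        rec[[length(rec) + 1L]] <- data.frame(
          gene = attrs$gene[f], sample = sample_ids[sj],
          variant_class = "Missense_Mutation", protein_change = pc,
          in_oncokb = TRUE, oncogenic = attrs$oncogenic[f],
          mutation_effect = attrs$effect[f], stringsAsFactors = FALSE)
      }
      planted[[gid]] <- attrs$label
    }
    # background decoys with heterogeneous per-sample burden
    lambda <- rgamma(n, shape = spec$rate_heterogeneity,
                     rate = spec$rate_heterogeneity)
    for (b in seq_len(spec$n_background_features)) {
      in_okb <- b %% 2L == 0L
      f_rate <- spec$background_rate * exp(runif(1, -0.7, 0.7))
      p <- pmin(0.5, f_rate * lambda)
      sj <- which(runif(n) < p)
      if (length(sj) == 0L) next
      cls <- sample(c("A", "I", "O"), 1L)
      rec[[length(rec) + 1L]] <- data.frame(
        gene = sprintf("BG%03d", b), sample = sample_ids[sj],
        variant_class = "Missense_Mutation",
        protein_change = paste0("p.B", sample.int(3L, length(sj), TRUE)),
        in_oncokb = in_okb,
        oncogenic = if (in_okb) switch(cls, A = "Oncogenic",
                                       I = "Likely Oncogenic",
                                       O = "Unknown") else "Unknown",
        mutation_effect = if (in_okb) switch(cls,
          A = "Likely Gain-of-function", I = "Loss-of-function",
          O = "Unknown") else "Unknown",
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rec)
    records <- mutation_records(rec$gene, rec$sample, rec$variant_class,
                                rec$protein_change, rec$in_oncokb,
                                rec$oncogenic, rec$mutation_effect)
    features <- group_mutation_features(records, sample_ids = sample_ids)
    list(records = records, features = features, planted = planted)
  })
}

#' Generate a full synthetic cohort
#'
#' Composes the dependency-matrix and feature generators plus optional
#' cancer-type labels into one bundle with a ground-truth manifest.
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort` list: `dep`, `features` (mutation + cancer-type),
#'   `mutation_features`, `records`, `metadata` (or `NULL`), `truth`
#'   (genes table, responsive sets, planted feature sets), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))
  responsive_override <- NULL
  metadata <- NULL
  if (spec$n_cancer_types > 0L) {
    metadata <- with_seed_(derive_seed(spec$seed, "cancer_types"), {
      w <- rgamma(spec$n_cancer_types, shape = 2)
      types <- sprintf("Type%02d", seq_len(spec$n_cancer_types))
      lab <- sample(types, spec$n_samples, replace = TRUE, prob = w / sum(w))
      # every type must appear so the indicator block is full rank
      lab[seq_len(spec$n_cancer_types)] <- types
      setNames(lab, sample_ids)
    })
    if (spec$plant_cancer_type)
      responsive_override <- list(DEP001 = names(metadata)[metadata ==
                                                             "Type01"])
  }
  gen <- generate_dependency_matrix(spec, responsive_sets =
                                      responsive_override)
  fg <- generate_feature_matrix(spec, gen$truth)
  features <- if (is.null(metadata)) fg$features
    else merge_feature_matrices(fg$features, cancer_type_features(metadata))
  truth <- gen$truth
  truth$planted <- fg$planted
  if (spec$plant_cancer_type && spec$n_cancer_types > 0L)
    truth$planted_cancer_type <- c(DEP001 = "CancerType:Type01")
  structure(list(dep = gen$dep, features = features,
                 mutation_features = fg$features, records = fg$records,
                 metadata = metadata, truth = truth, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: %d genes x %d samples, %d features, %d mutation records\n",
    nrow(x$dep$scores), ncol(x$dep$scores), length(x$features$feature_ids),
    nrow(x$records)))
  invisible(x)
}
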