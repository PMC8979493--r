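# Curveball randomization, conditional model selection, permutation
# significance, BH FDR.

test_that("curveball preserves both margin vectors on every draw", {
  set.seed(401)
  for (rep in 1:25) {
    m <- sample(3:10, 1); n <- sample(4:12, 1)
    A <- matrix(rbinom(m * n, 1, 0.35), m, n)
    B <- curveball_randomize(A, seed = rep)
    expect_identical(rowSums(B), rowSums(A))
    expect_identical(colSums(B), colSums(A))
    expect_true(all(B %in% c(0L, 1L)))
  }
  # the all-ones matrix is its own (unique) randomization
  A1 <- matrix(1L, 3, 4)
  expect_identical(curveball_randomize(A1, seed = 1), A1)
  # determinism given seed
  A <- matrix(rbinom(80, 1, 0.3), 8, 10)
  expect_identical(curveball_randomize(A, seed = 7),
                   curveball_randomize(A, seed = 7))
})

test_that("small fixed-margin state spaces are sampled near-uniformly", {
  # 2 x 2 checkerboard: exactly two states; 2000 draws here (the full
  # 10,000-draw version runs in the acceptance suite)
  A <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  hits <- withr::with_seed(11L, {
    vapply(1:2000, function(i)
      curveball_randomize(A, n_trades = 10L)[1, 1], integer(1))
  })
  expect_equal(mean(hits), 0.5, tolerance = 0.04)
})

test_that("model selection drops uninformative features, keeps planted", {
  set.seed(421)
  n <- 200
  sample_ids <- sprintf("s%03d", 1:n)
  d <- setNames(rep(0.2, n), sample_ids)
  resp <- 1:20
  d[resp] <- -1  # 20 responsive samples
  planted_cov <- sample_ids[resp]
  decoy_cov <- sample_ids[sample.int(n, 25)]
  fm <- fm_from_cov(list("PL(A)" = planted_cov, "DC(A)" = decoy_cov),
                    sample_ids)
  inst <- weighted_instance(d, "increased", fm)
  ms <- conditional_model_selection(c("PL(A)", "DC(A)"), inst,
                                    n_perm = 400L, alpha_remove = 2 / 401,
                                    seed = 5L)
  expect_identical(ms$retained_set, "PL(A)")
  expect_true("DC(A)" %in% names(ms$removed))
  # the planted p sits at the add-one floor
  expect_equal(unname(ms$feature_p["PL(A)"]), 1 / 401, tolerance = 1e-12)

  # a feature with no mutated samples: permutation leaves the weight
  # unchanged, p_m = 1, removed
  fm0 <- fm_from_cov(list("PL(A)" = planted_cov, "NIL(A)" = character(0)),
                     sample_ids)
  inst0 <- weighted_instance(d, "increased", fm0)
  ms0 <- conditional_model_selection(c("NIL(A)", "PL(A)"), inst0,
                                     n_perm = 200L, alpha_remove = 2 / 201,
                                     seed = 6L)
  expect_identical(ms0$retained_set, "PL(A)")
  expect_equal(unname(ms0$removed["NIL(A)"]), 1)

  # singleton covering all responsive samples exclusively is retained
  ms1 <- conditional_model_selection("PL(A)", inst, n_perm = 400L,
                                     alpha_remove = 2 / 401, seed = 7L)
  expect_identical(ms1$retained_set, "PL(A)")
  expect_true(all(ms1$feature_p <= 2 / 401))
})

test_that("model selection is deterministic and nests its result", {
  set.seed(431)
  inst <- random_instance(30, 6, "increased", p_one = 0.3)
  M <- inst$features$feature_ids[1:4]
  a <- conditional_model_selection(M, inst, n_perm = 100L,
                                   alpha_remove = 0.05, seed = 3L)
  b <- conditional_model_selection(M, inst, n_perm = 100L,
                                   alpha_remove = 0.05, seed = 3L)
  expect_identical(a, b)
  expect_true(all(a$retained_set %in% M))
})

test_that("association significance: planted signal, empty set, errors", {
  set.seed(443)
  n <- 120
  sample_ids <- sprintf("s%03d", 1:n)
  d <- setNames(rep(0.25, n), sample_ids)
  resp <- 1:24
  d[resp] <- -1
  # strong planted association: covers 0.9 of responsive, exclusive
  rec <- mutation_records(
    gene = c(rep("PL", 22), rep("BG", 40)),
    sample = c(sample_ids[1:22], sample(sample_ids, 40, replace = TRUE)),
    protein_change = c(rep("p.1", 22), sprintf("p.b%d", 1:40)),
    in_oncokb = c(rep(TRUE, 22), rep(FALSE, 40)),
    oncogenic = "Oncogenic", mutation_effect = "Gain-of-function")
  fm <- group_mutation_features(rec, sample_ids = sample_ids)
  inst <- weighted_instance(d, "increased", fm)
  res <- solve_exclusive_cover(inst, k = 3)
  expect_identical(res$feature_set, "PL(A)")
  sig <- association_significance(res$feature_set, inst, rec, k = 3,
                                  max_perm = 500L, seed = 9L,
                                  stop_threshold = NULL)
  expect_equal(sig$p, 1 / 501, tolerance = 1e-12)  # add-one floor
  expect_equal(sig$observed_weight, res$weight)
  expect_equal(sig$n_perm, 500L)

  # p bounds hold
  expect_gte(sig$p, 1 / (sig$n_perm + 1))
  expect_lte(sig$p, 1)

  # empty set: p = 1 by convention
  sig0 <- association_significance(character(0), inst, rec, k = 3,
                                   max_perm = 100L, seed = 1L)
  expect_equal(sig0$p, 1)
  expect_equal(sig0$observed_weight, 0)

  # conditioning requires the full mutation table
  expect_error(association_significance("PL(A)", inst, NULL, k = 3,
                                        max_perm = 10L, seed = 1L),
               class = "depmex_validation_error")

  # determinism
  sig2 <- association_significance(res$feature_set, inst, rec, k = 3,
                                   max_perm = 500L, seed = 9L,
                                   stop_threshold = NULL)
  expect_equal(sig2$p, sig$p)
})

test_that("direct feature permutation route works and stops adaptively", {
  set.seed(457)
  n <- 60
  sample_ids <- sprintf("s%03d", 1:n)
  d <- setNames(rep(0.3, n), sample_ids)
  d[1:12] <- -1
  # weak signal: permuted optima often reach it, so the 99% CI on p rises
  # above the stop threshold and the loop exits early
  fm <- fm_from_cov(list("W(A)" = sample_ids[c(1:3, 40:44)],
                         "X(A)" = sample_ids[sample.int(n, 10)]),
                    sample_ids)
  inst <- weighted_instance(d, "increased", fm)
  M <- solve_exclusive_cover(inst, k = 2)$feature_set
  sig <- association_significance(M, inst, NULL, k = 2, max_perm = 50000L,
                                  seed = 3L, stop_threshold = 0.25,
                                  permute_features_directly = TRUE)
  expect_lt(sig$n_perm, 50000L)  # stopped early
  expect_gte(sig$p, 1 / (sig$n_perm + 1))
})

test_that("bh_fdr reproduces step-up adjustment", {
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  p <- withr::with_seed(5L, runif(50))
  q <- bh_fdr(p)
  expect_true(all(q >= p))           # q >= p always
  expect_true(all(q >= 0 & q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "depmex_validation_error")
  expect_error(bh_fdr(c(0.5, NA)), class = "depmex_validation_error")
})
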