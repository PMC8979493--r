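# Score normalization, the exclusivity-penalized weight, and the two
# exact solvers.

test_that("normalize_scores scales responsive mass to unit sum", {
  fm3 <- fm_from_cov(list("X(A)" = "s1"), c("s1", "s2", "s3"))
  inst <- weighted_instance(setNames(c(-2, -1, 1), c("s1", "s2", "s3")),
                            "increased", fm3)
  expect_equal(unname(inst$d_prime), c(-2 / 3, -1 / 3, 1 / 3))
  expect_equal(unname(inst$rho), c(-2 / 3, -1 / 3, -1 / 3))
  expect_equal(sum(inst$d_prime[inst$d_prime < 0]), -1, tolerance = 1e-9)

  inst2 <- weighted_instance(setNames(c(-1, 2, 2), c("s1", "s2", "s3")),
                             "decreased", fm3)
  expect_equal(unname(inst2$d_prime), c(-0.25, 0.5, 0.5))
  expect_equal(sum(inst2$d_prime[inst2$d_prime > 0]), 1, tolerance = 1e-9)
  expect_equal(unname(inst2$rho), c(0.25, 0.5, 0.5))

  fm2 <- fm_from_cov(list("X(A)" = "s1"), c("s1", "s2"))
  inst3 <- weighted_instance(setNames(c(-1, 0), c("s1", "s2")),
                             "increased", fm2)
  expect_equal(unname(inst3$d_prime), c(-1, 0))

  # no responsive-side mass
  expect_error(weighted_instance(setNames(c(1, 2), c("s1", "s2")),
                                 "increased", fm2),
               class = "depmex_degenerate_error")
})

test_that("feature_set_weight reproduces the worked examples", {
  inst <- worked_instance()
  expect_equal(feature_set_weight(c("F1(A)", "F2(A)"), inst), -0.4)
  expect_equal(feature_set_weight("F2(A)", inst), -1.0)
  expect_equal(feature_set_weight(character(0), inst), 0)
  expect_error(feature_set_weight("NOPE(A)", inst),
               class = "depmex_validation_error")
})

test_that("uniform scores reduce to the Dendrix weight", {
  # d'_j = 1, rho_j = 1 for all j: W(M) = 2|Gamma(M)| - sum_m |Gamma(m)|
  fm <- fm_from_cov(list("F1(A)" = c("s1", "s2"), "F2(A)" = c("s2", "s3")),
                    c("s1", "s2", "s3"))
  inst <- weighted_instance(setNames(c(1, 1, 1), c("s1", "s2", "s3")),
                            "decreased", fm)
  inst$d_prime[] <- 1; inst$rho[] <- 1
  expect_equal(feature_set_weight(c("F1(A)", "F2(A)"), inst), 2 * 3 - 4)

  # property: holds for every subset of random binary matrices
  set.seed(211)
  for (rep in 1:20) {
    n <- sample(4:9, 1); m <- sample(2:6, 1)
    a <- matrix(rbinom(m * n, 1, 0.4), m, n,
                dimnames = list(sprintf("R%d(A)", 1:m),
                                sprintf("s%d", 1:n)))
    a[1, 1] <- 1L  # at least one covered sample
    fmr <- feature_matrix(a)
    instr <- weighted_instance(setNames(rep(1, n), colnames(a)),
                               "decreased", fmr)
    instr$d_prime[] <- 1; instr$rho[] <- 1
    for (sz in 1:m) {
      for (M in utils::combn(rownames(a), sz, simplify = FALSE)) {
        gam <- sum(colSums(a[M, , drop = FALSE]) > 0)
        dendrix <- 2 * gam - sum(a[M, ])
        expect_equal(feature_set_weight(M, instr), dendrix,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("two-hit exception: same-gene I/O co-occurrence is not penalized", {
  fm <- fm_from_cov(list("TP53(I)" = "s1", "TP53(O)" = "s1",
                         "TP53(A)" = "s1"),
                    c("s1", "s2"))
  inst <- weighted_instance(setNames(c(-1, -1), c("s1", "s2")),
                            "increased", fm)
  expect_equal(unname(inst$d_prime[1]), -0.5)
  expect_equal(feature_set_weight(c("TP53(I)", "TP53(O)"), inst), -0.5)
  # but (A) co-occurring with (I) of the same gene is penalized:
  # W = d' - (c - 1) rho = -0.5 - 1 * (-0.5) = 0
  expect_equal(feature_set_weight(c("TP53(I)", "TP53(A)"), inst), 0)
})

test_that("solver finds the optimum and the empty set when nothing helps", {
  inst <- worked_instance()
  res <- solve_exclusive_cover(inst, k = 2)
  expect_identical(res$feature_set, "F2(A)")
  expect_equal(res$weight, -1.0)
  expect_equal(feature_set_weight(res$feature_set, inst), res$weight,
               tolerance = 1e-9)
  expect_setequal(res$covered_samples, c("s1", "s2"))

  # only background-sign coverage: empty set, weight 0
  fm <- fm_from_cov(list("B1(A)" = "s3", "B2(A)" = "s3"), c("s1", "s2", "s3"))
  inst_bg <- weighted_instance(setNames(c(-1, -0.5, 2), c("s1", "s2", "s3")),
                               "increased", fm)
  res_bg <- solve_exclusive_cover(inst_bg, k = 2)
  expect_identical(res_bg$feature_set, character(0))
  expect_equal(res_bg$weight, 0)

  # single feature covering the single responsive sample
  fm1 <- fm_from_cov(list("Z(A)" = "s1"), c("s1", "s2"))
  inst1 <- weighted_instance(setNames(c(-2, 1), c("s1", "s2")),
                             "increased", fm1)
  res1 <- solve_exclusive_cover_enum(inst1, k = 1)
  expect_identical(res1$feature_set, "Z(A)")
  expect_equal(res1$weight, -1)
})

test_that("branch-and-bound agrees with exhaustive enumeration", {
  set.seed(307)
  for (i in 1:60) {
    dir <- sample(c("increased", "decreased"), 1)
    inst <- random_instance(sample(5:20, 1), sample(2:10, 1), dir)
    k <- sample(1:4, 1)
    r1 <- solve_exclusive_cover(inst, k)
    r2 <- solve_exclusive_cover_enum(inst, k)
    expect_equal(r1$weight, r2$weight, tolerance = 1e-9)
    expect_identical(r1$feature_set, r2$feature_set)
  }
  # unconstrained search also agrees
  set.seed(311)
  inst <- random_instance(12, 8, "increased")
  expect_equal(solve_exclusive_cover(inst, k = NULL)$weight,
               solve_exclusive_cover_enum(inst, k = NULL)$weight,
               tolerance = 1e-9)
})

test_that("objective terms match the weight algebraically", {
  # per covered responsive-sign sample the contribution is (2 - c_j) d'_j;
  # per covered background-sign sample it is c_j |d'_j| (increased search)
  set.seed(313)
  inst <- random_instance(15, 6, "increased")
  labels <- inst$features$feature_ids
  for (M in utils::combn(labels, 3, simplify = FALSE)[1:10]) {
    idx <- match(M, labels)
    a <- inst$features$a[idx, , drop = FALSE]
    cj <- colSums(a)
    dp <- inst$d_prime
    grp <- depmex:::penalty_group_of(inst$features)[idx]
    cjg <- integer(ncol(a))
    for (g in unique(grp))
      cjg <- cjg + as.integer(colSums(a[grp == g, , drop = FALSE]) > 0)
    covered <- cj > 0
    resp <- covered & dp < 0
    bg <- covered & dp >= 0
    w_terms <- sum((2 - cjg[resp]) * dp[resp]) + sum(cjg[bg] * abs(dp[bg]))
    expect_equal(feature_set_weight(M, inst), w_terms, tolerance = 1e-9)
  }
})

test_that("coverage monotonicity of the objective", {
  set.seed(331)
  n <- 12
  d <- setNames(-abs(rnorm(n)), sprintf("s%03d", 1:n))
  d[9:12] <- abs(d[9:12])  # background-sign tail
  fm <- fm_from_cov(list("A1(A)" = names(d)[1:3], "A2(A)" = names(d)[4:6],
                         "BG(A)" = names(d)[9:10]), names(d))
  inst <- weighted_instance(d, "increased", fm)
  w1 <- feature_set_weight("A1(A)", inst)
  w12 <- feature_set_weight(c("A1(A)", "A2(A)"), inst)
  # adding exclusive responsive coverage strictly improves (more negative)
  expect_lt(w12, w1)
  # adding background-only coverage never improves
  w12b <- feature_set_weight(c("A1(A)", "A2(A)", "BG(A)"), inst)
  expect_gte(w12b, w12)
})

test_that("enumeration guards its budget", {
  set.seed(337)
  inst <- random_instance(10, 12, "increased")
  expect_error(solve_exclusive_cover_enum(inst, k = 6, max_subsets = 100),
               class = "depmex_budget_error")
  # brute-force optimality: the optimum is <= every enumerated subset
  r <- solve_exclusive_cover_enum(inst, k = 3)
  labels <- inst$features$feature_ids
  for (sz in 1:3)
    for (M in utils::combn(labels, sz, simplify = FALSE))
      expect_lte(r$weight, feature_set_weight(M, inst) + 1e-9)
})
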