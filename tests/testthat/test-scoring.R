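# Profile normalization, outlier prefilter, mixture fits, 2C scoring.

test_that("zscore_profile centers and scales, passes missing through", {
  expect_equal(zscore_profile(c(-1, 0, 1)), c(-1, 0, 1))
  expect_error(zscore_profile(c(2, 2, 2)), class = "depmex_degenerate_error")
  expect_error(zscore_profile(c(1, NA)), class = "depmex_degenerate_error")

  x <- withr::with_seed(42L, rnorm(1000, mean = 5, sd = 2))
  z <- zscore_profile(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  x[c(3, 17)] <- NA
  z <- zscore_profile(x)
  expect_true(all(is.na(z[c(3, 17)])))
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-12)
})

test_that("sigma_outlier_filter keeps genes with extreme samples", {
  row1 <- c(rep(0, 100), 10)           # one extreme sample, z = 9.95
  z <- zscore_profile(row1)
  expect_equal(max(abs(z)), 9.9504, tolerance = 1e-4)
  row2 <- rnorm(101, sd = 0.5)         # no 6-sigma outliers
  dep <- dependency_matrix(rbind(row1, row2),
                           gene_ids = c("g_out", "g_null"),
                           sample_ids = sprintf("s%d", 1:101))
  expect_identical(sigma_outlier_filter(dep, n_sigma = 6), "g_out")

  # degenerate rows are skipped with a warning, not an error
  dep2 <- dependency_matrix(rbind(row1, rep(3, 101)),
                            gene_ids = c("g_out", "g_const"),
                            sample_ids = sprintf("s%d", 1:101))
  expect_warning(kept <- sigma_outlier_filter(dep2, 6), "degenerate")
  expect_identical(kept, "g_out")
})

test_that("sigma filter fraction mode requires the stated outlier count", {
  # a point mass of fraction f sits sqrt((1-f)/f) sds from the mean, so
  # 8/100 samples at a common extreme value clear |z| >= 3 (3.39 sds)
  # while Chebyshev caps the >= 3 sd fraction at 1/9 for any profile
  set.seed(61)
  row <- c(rnorm(92, 0, 1e-3), rep(-4, 8))
  dep <- dependency_matrix(matrix(row, 1), gene_ids = "g",
                           sample_ids = sprintf("s%d", 1:100))
  expect_identical(sigma_outlier_filter(dep, 3, 0.05), "g")   # need 5, have 8
  expect_length(sigma_outlier_filter(dep, 3, 0.09), 0)        # need 9, have 8
})

test_that("fit_mixture: BIC identity, degenerate input, determinism", {
  x <- withr::with_seed(7L, c(rnorm(800), rnorm(200, -5)))
  for (fam in c("gaussian", "t")) {
    for (k in 1:2) {
      f <- fit_mixture(x, k, fam, seed = 3L)
      expect_equal(f$bic, f$n_params * log(f$n) - 2 * f$log_likelihood,
                   tolerance = 1e-12)
      expect_equal(sum(f$weight), 1, tolerance = 1e-9)
      expect_true(all(f$sigma > 0))
      expect_true(!is.unsorted(f$mu))  # component 1 has the smaller mean
    }
  }
  expect_equal(depmex:::mixture_n_params(1, "t"), 3L)
  expect_equal(depmex:::mixture_n_params(2, "t"), 7L)

  # constant profile: location recovered, scale floored, loglik finite
  f <- fit_mixture(rep(2.5, 30), 1L, "gaussian", seed = 1L)
  expect_equal(f$mu, 2.5)
  expect_equal(f$sigma, 1e-6)
  expect_true(is.finite(f$log_likelihood))

  expect_error(fit_mixture(rnorm(10), 2L, "t", seed = 1L),
               class = "depmex_fit_error")

  f1 <- fit_mixture(x, 2L, "t", seed = 11L)
  f2 <- fit_mixture(x, 2L, "t", seed = 11L)
  expect_identical(f1, f2)
})

test_that("two-component fit recovers planted parameters", {
  x <- withr::with_seed(19L, c(rnorm(800), rnorm(200, -5)))
  f <- fit_mixture(x, 2L, "gaussian", seed = 5L)
  expect_equal(f$mu[1], -5, tolerance = 0.15)
  expect_equal(f$mu[2], 0, tolerance = 0.15)
  expect_equal(f$weight[1], 0.2, tolerance = 0.03)
  ft <- fit_mixture(x, 2L, "t", seed = 5L)
  expect_equal(ft$mu[1], -5, tolerance = 0.15)
})

test_that("select_two_component compares t-mixture BICs and is deterministic", {
  bim <- withr::with_seed(23L, c(rnorm(592, 0, 0.8), rnorm(177, -3.2, 0.8)))
  uni <- withr::with_seed(29L, rnorm(769))
  s_b <- select_two_component(bim, seed = 2L)
  s_u <- select_two_component(uni, seed = 2L)
  expect_true(as.logical(s_b))
  expect_false(as.logical(s_u))
  expect_lt(attr(s_b, "bic_2c"), attr(s_b, "bic_1c"))
  expect_gt(attr(s_u, "bic_2c"), attr(s_u, "bic_1c"))
  expect_identical(select_two_component(bim, seed = 2L), s_b)
})

test_that("2C scores are posterior log odds with component 1 = smaller mean", {
  # closed-form checks on a constructed equal-weight fit
  fit <- depmex:::new_mixture_fit("gaussian", c(0.5, 0.5), c(-1, 0),
                                  c(0.5, 0.5), NULL, 0, 100L)
  lo <- depmex:::posterior_log_odds(fit, c(-0.5, -1))
  expect_equal(lo[1], 0, tolerance = 1e-12)   # midpoint symmetry
  expect_equal(lo[2], -2, tolerance = 1e-12)  # -1 / (2 * 0.25)

  x <- withr::with_seed(31L, c(rnorm(600, 0, 0.7), rnorm(150, -3.5, 0.7)))
  x[c(5, 10)] <- NA
  p <- compute_2c_profile(x, seed = 4L, gene_id = "g1")
  expect_s3_class(p, "two_component_profile")
  expect_identical(p$direction, "increased")
  expect_identical(p$responsive_component, 1L)
  expect_true(all(is.na(p$d[c(5, 10)])))
  ok <- is.finite(p$d)
  # posterior normalization
  expect_true(all(abs(rowSums(p$posterior[ok, ]) - 1) < 1e-9))
  # monotone in the raw score along the fitted axis between the means
  mid <- ok & x > p$fit$mu[1] & x < p$fit$mu[2]
  o <- order(x[mid])
  expect_false(is.unsorted(p$d[mid][o]))
  # responsive minority => fewer assigned samples than the background
  expect_lt(p$responsive_n, sum(ok) / 2)
})

test_that("decreased direction when the minority sits on the positive side", {
  x <- withr::with_seed(37L, c(rnorm(600, 0, 0.7), rnorm(120, 3.2, 0.7)))
  p <- compute_2c_profile(x, seed = 6L)
  expect_identical(p$direction, "decreased")
  expect_identical(p$responsive_component, 2L)
})

test_that("norm_lrt separates gaussian from heavy-skew profiles", {
  g <- withr::with_seed(41L, rnorm(769))
  s <- withr::with_seed(43L, c(rnorm(692), rnorm(77, -6, 1)))
  lrt_g <- norm_lrt(g, seed = 2L)
  lrt_s <- norm_lrt(s, seed = 2L)
  expect_lt(lrt_g, 10)
  expect_gt(lrt_s, 125)
  expect_identical(norm_lrt(s, seed = 2L), lrt_s)
  expect_error(norm_lrt(rnorm(5), seed = 1L), class = "depmex_fit_error")
})
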