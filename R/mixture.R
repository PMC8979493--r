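# One- and two-component Gaussian / t mixture fits by EM, BIC model
# selection, and per-sample log posterior odds ("2C") scoring.
#
# Model: a knockout splits the cohort into a background population and a
# minority responsive population, so a differential dependency's score
# profile is a two-component mixture; the t family absorbs the heavy tails
# of screen scores. Model selection compares BIC of the one- and
# two-component t fits; posterior scores come from a two-component Gaussian
# fit of the same profile.

SIGMA_FLOOR <- 1e-6
NU_RANGE <- c(2.1, 100)
EM_TOL <- 1e-8
EM_MAXIT <- 200L
N_RESTARTS <- 5L

# log density of the location-scale t
dt_ls <- function(x, mu, sigma, nu) {
  dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma)
}

comp_logdens <- function(x, mu, sigma, nu, family) {
  if (family == "gaussian") dnorm(x, mu, sigma, log = TRUE)
  else dt_ls(x, mu, sigma, nu)
}

mixture_n_params <- function(n_components, family) {
  per <- if (family == "gaussian") 2L else 3L
  as.integer(n_components) * per + (as.integer(n_components) - 1L)
}

new_mixture_fit <- function(family, weight, mu, sigma, nu, loglik, n) {
  k <- length(mu)
  o <- order(mu)  # component 1 = smaller location
  np <- mixture_n_params(k, family)
  structure(list(
    n_components = k, family = family,
    weight = weight[o], mu = mu[o], sigma = sigma[o],
    nu = if (family == "t") nu[o] else rep(NA_real_, k),
    log_likelihood = loglik, n = n,
    n_params = np, bic = np * log(n) - 2 * loglik
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component %s mixture fit (n = %d)\n", x$n_components,
              x$family, x$n))
  for (i in seq_len(x$n_components))
    cat(sprintf("  comp %d: pi = %.4f, mu = %.4f, sigma = %.4f%s\n", i,
                x$weight[i], x$mu[i], x$sigma[i],
                if (x$family == "t") sprintf(", nu = %.2f", x$nu[i]) else ""))
  cat(sprintf("  logLik = %.4f, BIC = %.4f\n", x$log_likelihood, x$bic))
  invisible(x)
}

# One-component ML fits --------------------------------------------------

fit_one_gaussian <- function(x) {
  n <- length(x)
  mu <- mean(x)
  sigma <- max(sqrt(mean((x - mu)^2)), SIGMA_FLOOR)
  ll <- sum(dnorm(x, mu, sigma, log = TRUE))
  new_mixture_fit("gaussian", 1, mu, sigma, NULL, ll, n)
}

# ECME for a single t: weighted location/scale updates given latent u,
# profile optimization over nu.
fit_one_t <- function(x) {
  n <- length(x)
  mu <- stats::median(x); sigma <- max(sd(x), SIGMA_FLOOR); nu <- 10
  ll_old <- -Inf
  for (it in seq_len(EM_MAXIT)) {
    d2 <- ((x - mu) / sigma)^2
    u <- (nu + 1) / (nu + d2)
    mu <- sum(u * x) / sum(u)
    sigma <- max(sqrt(sum(u * (x - mu)^2) / n), SIGMA_FLOOR)
    nu <- optimize(function(lv) sum(dt_ls(x, mu, sigma, exp(lv))),
                   log(NU_RANGE), maximum = TRUE, tol = 1e-6)$maximum
    nu <- exp(nu)
    ll <- sum(dt_ls(x, mu, sigma, nu))
    if (is.finite(ll) && ll - ll_old < EM_TOL && it > 2L) break
    ll_old <- ll
  }
  new_mixture_fit("t", 1, mu, sigma, nu, ll, n)
}

# Two-component EM -------------------------------------------------------

# Standard ECM: responsibilities tau; for the t family, latent scale
# weights u and a per-component digamma equation for nu (Liu-Rubin
# update). Inner loop compiled in src/em.cpp; returns NULL for collapsed
# or spike (hard count < 2) solutions.
em_two <- function(x, family, init) {
  fit <- .em_two_cpp(x, family == "t", init$weight, init$mu,
                     pmax(init$sigma, SIGMA_FLOOR),
                     if (family == "t") init$nu else c(10, 10),
                     EM_MAXIT, EM_TOL)
  if (!isTRUE(fit$ok) || !is.finite(fit$loglik)) return(NULL)
  if (family != "t") fit$nu <- c(NA_real_, NA_real_)
  fit
}

two_comp_inits <- function(x, family, n_restarts) {
  s <- max(sd(x), SIGMA_FLOOR)
  inits <- list()
  km <- tryCatch(kmeans(x, centers = 2L, nstart = 3L), error = function(e) NULL)
  if (!is.null(km) && min(km$size) >= 2L) {
    cs <- as.numeric(km$centers)
    sds <- pmax(tapply(x, km$cluster, sd), 0.1 * s)
    inits[[1]] <- list(weight = km$size / length(x), mu = cs,
                       sigma = as.numeric(sds), nu = c(10, 10))
  }
  # quantile split: a minority low component is the expected shape
  q <- quantile(x, c(0.1, 0.6))
  inits[[length(inits) + 1L]] <- list(weight = c(0.2, 0.8),
    mu = as.numeric(q), sigma = c(s, s), nu = c(10, 10))
  for (r in seq_len(n_restarts)) {
    cs <- sort(sample(x, 2L))
    inits[[length(inits) + 1L]] <- list(weight = c(0.5, 0.5), mu = cs,
      sigma = c(s, s) * runif(1, 0.5, 1.5), nu = c(10, 10))
  }
  inits
}

#' Fit a mixture model to a score profile
#'
#' Maximum-likelihood fit of a one- or two-component Gaussian or t mixture
#' by EM with multiple restarts (k-means style initialization plus random
#' restarts), deterministic given `seed`. Missing values are dropped before
#' fitting. The scale parameters are floored at 1e-6 and t degrees of
#' freedom are bounded to \[2.1, 100\].
#'
#' @param scores numeric vector of per-sample scores.
#' @param n_components 1 or 2.
#' @param family `"t"` or `"gaussian"`.
#' @param seed integer seed controlling the random restarts.
#' @param min_n minimum number of finite values required (default 20).
#' @return A `mixture_fit`: components ordered by location (component 1 has
#'   the smaller mean), with `log_likelihood`, `n_params` and
#'   `bic = n_params * log(n) - 2 * log_likelihood`.
#' @export
fit_mixture <- function(scores, n_components = 2L,
                        family = c("t", "gaussian"), seed = 1L, min_n = 20L) {
  family <- match.arg(family)
  x <- scores[is.finite(scores)]
  if (length(x) < min_n)
    dmx_error(sprintf("need >= %d finite values, got %d", min_n, length(x)),
              "depmex_fit_error")
  if (n_components == 1L) {
    return(if (family == "gaussian") fit_one_gaussian(x) else fit_one_t(x))
  }
  stopifnot(n_components == 2L)
  best <- NULL
  with_seed_(seed, {
    for (init in two_comp_inits(x, family, N_RESTARTS)) {
      fit <- em_two(x, family, init)
      if (!is.null(fit) &&
          (is.null(best) || fit$loglik > best$loglik + 1e-12)) best <- fit
    }
  })
  if (is.null(best))
    dmx_error("two-component EM failed to converge from any restart",
              "depmex_fit_error")
  new_mixture_fit(family, best$weight, best$mu, best$sigma, best$nu,
                  best$loglik, length(x))
}

#' Is a profile a two-component ("2C") differential dependency?
#'
#' Fits one- and two-component t mixtures and returns `TRUE` iff the
#' two-component fit has the smaller BIC.
#'
#' @inheritParams fit_mixture
#' @return logical scalar; attributes `bic_1c` and `bic_2c` carry the BICs.
#' @export
select_two_component <- function(scores, seed = 1L, min_n = 20L) {
  f1 <- fit_mixture(scores, 1L, "t", seed = derive_seed(seed, "t1"),
                    min_n = min_n)
  f2 <- fit_mixture(scores, 2L, "t", seed = derive_seed(seed, "t2"),
                    min_n = min_n)
  structure(f2$bic < f1$bic, bic_1c = f1$bic, bic_2c = f2$bic)
}

# Posterior log odds of the two components of a Gaussian mixture fit at x.
posterior_log_odds <- function(fit, x) {
  l1 <- log(fit$weight[1]) +
    comp_logdens(x, fit$mu[1], fit$sigma[1], fit$nu[1], fit$family)
  l2 <- log(fit$weight[2]) +
    comp_logdens(x, fit$mu[2], fit$sigma[2], fit$nu[2], fit$family)
  l2 - l1
}

#' Score samples by log posterior odds of the responsive component
#'
#' Fits a two-component Gaussian mixture and computes, per sample, the 2C
#' score `d_j = ln Pr(z = 2 | p_j) - ln Pr(z = 1 | p_j)` where component 1
#' is the component with the smaller mean. Samples are hard-assigned to the
#' component with the larger posterior; the component with fewer assigned
#' samples is the responsive component (tie: component 1, logged). The
#' profile direction is `"increased"` iff the responsive component is
#' component 1, i.e. the minority sits on the negative (stronger-dependency)
#' side.
#'
#' @param scores numeric vector of per-sample scores (names kept).
#' @param seed integer seed for the mixture fit.
#' @param gene_id optional identifier stored in the result.
#' @return A `two_component_profile`: list with `gene_id`, `d` (2C scores;
#'   `NA` where the input was missing), `direction`, `responsive_component`,
#'   `responsive_n`, `posterior` (n x 2 matrix) and `fit`.
#' @export
compute_2c_profile <- function(scores, seed = 1L, gene_id = NULL) {
  fit <- fit_mixture(scores, 2L, "gaussian", seed = derive_seed(seed, "g2"))
  fin <- is.finite(scores)
  d <- rep(NA_real_, length(scores))
  names(d) <- names(scores)
  lo <- posterior_log_odds(fit, scores[fin])
  d[fin] <- lo
  post2 <- 1 / (1 + exp(-lo))
  posterior <- matrix(NA_real_, length(scores), 2L,
                      dimnames = list(names(scores), c("comp1", "comp2")))
  posterior[fin, 1L] <- 1 - post2
  posterior[fin, 2L] <- post2
  hard <- ifelse(lo > 0, 2L, 1L)
  sizes <- tabulate(hard, 2L)
  responsive <- if (sizes[1] == sizes[2]) {
    dmx_log("compute_2c_profile", event = "component_size_tie",
            gene_id = gene_id)
    1L
  } else which.min(sizes)
  structure(list(
    gene_id = gene_id, d = d,
    direction = if (responsive == 1L) "increased" else "decreased",
    responsive_component = responsive,
    responsive_n = sizes[responsive],
    posterior = posterior, fit = fit
  ), class = "two_component_profile")
}

#' @export
print.two_component_profile <- function(x, ...) {
  cat(sprintf(
    "two_component_profile%s: %s dependency, responsive comp %d (n = %d/%d)\n",
    if (is.null(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
    x$direction, x$responsive_component, x$responsive_n,
    sum(is.finite(x$d))))
  invisible(x)
}

# NormLRT comparison statistic -------------------------------------------

# Azzalini skew-t log density (location xi, scale omega, slant alpha, df nu)
dskewt_log <- function(x, xi, omega, alpha, nu) {
  z <- (x - xi) / omega
  log(2) + dt(z, nu, log = TRUE) - log(omega) +
    pt(alpha * z * sqrt((nu + 1) / (nu + z^2)), nu + 1, log.p = TRUE)
}

#' Divergence of a profile from normality (NormLRT score)
#'
#' `LRT = 2 * (lnL(skew-t ML fit) - lnL(Gaussian ML fit))`. A comparison
#' statistic for differential-dependency calling (threshold 125 in the RNAi
#' screen literature); not used by the main pipeline.
#'
#' @inheritParams fit_mixture
#' @return numeric LRT score.
#' @export
norm_lrt <- function(scores, seed = 1L, min_n = 20L) {
  x <- scores[is.finite(scores)]
  if (length(x) < min_n)
    dmx_error(sprintf("need >= %d finite values, got %d", min_n, length(x)),
              "depmex_fit_error")
  g <- fit_one_gaussian(x)
  m0 <- mean(x); s0 <- sd(x)
  nll <- function(p) {
    v <- -sum(dskewt_log(x, p[1], exp(p[2]), p[3], 2.1 + exp(p[4])))
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  with_seed_(seed, {
    for (a0 in c(0, -4, 4)) {
      p0 <- c(m0, log(s0), a0, log(10))
      fit <- tryCatch(optim(p0, nll, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10)),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
  })
  if (is.null(best)) dmx_error("skew-t fit failed", "depmex_fit_error")
  2 * (-best$value - g$log_likelihood)
}
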