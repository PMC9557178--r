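test_that("matern_correlation matches its closed forms and conventions", {
  p1 <- matern_params(100, 1, nu = 1)
  expect_equal(p1$kappa, sqrt(8) / 100, tolerance = 1e-12)
  expect_equal(matern_correlation(0, p1), 1)

  # nu = 0.5 is the exponential model: r(d) = exp(-kappa d), kappa = 2/rho
  p05 <- matern_params(100, 1, nu = 0.5)
  d <- seq(0, 1000, length.out = 100)
  expect_equal(matern_correlation(d, p05), exp(-p05$kappa * d),
               tolerance = 1e-10)
  expect_equal(matern_correlation(100, p05), exp(-2), tolerance = 1e-12)

  # at the range the correlation is "approximately 0.1" (0.139 for nu = 1)
  expect_equal(matern_correlation(100, p1), 0.1396675, tolerance = 1e-6)

  # continuous near 0, strictly decreasing, vanishing at large d
  dd <- seq(1e-8, 2000, length.out = 400)
  r <- matern_correlation(dd, p1)
  expect_true(all(diff(r) < 0))
  expect_lt(r[400], 1e-6)
  expect_equal(matern_correlation(1e-10, p1), 1, tolerance = 1e-6)

  # internal fast path agrees with the reference implementation
  expect_equal(geoprev:::matern_corr_vec(dd, p1$kappa, 1), r,
               tolerance = 1e-12)

  expect_error(matern_params(-1, 1), "range_rho")
  expect_error(matern_params(1, -1), "sigma")
  expect_error(matern_correlation(-1, p1), ">= 0")
})

test_that("build_covariance matches the element-wise oracle", {
  set.seed(11)
  xy <- cbind(x = runif(5, 0, 300), y = runif(5, 0, 300))
  params <- matern_params(120, 0.8)
  S <- build_covariance(xy, params, jitter = 0)
  D <- as.matrix(dist(xy))
  oracle <- 0.8^2 * matern_correlation(D, params)
  expect_equal(unname(S), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(S, t(S), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))

  # single point and sigma = 0 edge cases
  s1 <- build_covariance(cbind(1, 1), params, jitter = 1e-6)
  expect_equal(dim(s1), c(1L, 1L))
  expect_equal(s1[1, 1], 0.64 + 1e-6, ignore_attr = TRUE)
  s0 <- build_covariance(xy, matern_params(120, 0), jitter = 1e-4)
  expect_equal(unname(s0), diag(1e-4, 5), tolerance = 1e-15,
               ignore_attr = TRUE)

  # duplicate points still factorize thanks to jitter escalation
  dup <- rbind(xy, xy[1, , drop = FALSE])
  Sd <- build_covariance(dup, params)
  expect_true(is.matrix(chol(Sd)))
})

test_that("log_likelihood matches hand arithmetic and survives extremes", {
  rec <- records_from_counts(1L, 2L)
  expect_equal(log_likelihood(rec, 0), log(2) - log(4), tolerance = 1e-12)

  # y = 0 with eta -> -inf contributes log C(n,0) = 0
  rec0 <- records_from_counts(0L, 7L)
  expect_equal(log_likelihood(rec0, -40), 0, tolerance = 1e-10)

  # overflow guard at eta = +/-40
  recb <- records_from_counts(c(3L, 5L), c(10L, 9L))
  expect_true(is.finite(log_likelihood(recb, c(40, -40))))
  expect_true(is.finite(log_likelihood(recb, c(-40, 40))))

  # agrees with dbinom for moderate eta across a grid
  eta <- seq(-3, 3, length.out = 7)
  for (e in eta) {
    expect_equal(log_likelihood(recb, c(e, e)),
                 sum(dbinom(c(3, 5), c(10, 9), plogis(e), log = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("log_posterior assembles the stated prior terms", {
  set.seed(12)
  n <- 8
  rec <- records_from_counts(rbinom(n, 10, 0.4), rep(10L, n))
  X <- matrix(rnorm(2 * n), n, 2)
  coords <- project_equirect(rec$lon, rec$lat)
  data <- list(y = rec$n_underweight, n = rec$n_children, X = X,
               coords_km = coords)
  priors <- prior_spec(rho0 = 10)

  # at beta = 0 the beta-prior term is z * (0.5 log prec - 0.5 log 2pi)
  st_nofield <- list(alpha = 0.3, beta = c(0, 0), zeta = NULL,
                     log_rho = NULL, log_sigma = NULL)
  lp0 <- log_posterior(st_nofield, data, priors)
  eta <- 0.3 + drop(X %*% c(0, 0))
  beta_term <- 2 * (0.5 * log(1e-4) - 0.5 * log(2 * pi))
  expect_equal(lp0, log_likelihood(rec, eta) + beta_term, tolerance = 1e-10)

  # doubling the precision lowers the log prior of any nonzero beta
  stb <- st_nofield; stb$beta <- c(0.5, -0.2)
  lp1 <- log_posterior(stb, data, priors)
  lp2 <- log_posterior(stb, data, prior_spec(beta_precision = 2e-4,
                                             rho0 = 10))
  # same likelihood/alpha: only the quadratic and normalizing terms change
  prec1 <- 1e-4; prec2 <- 2e-4; b2 <- sum(stb$beta^2)
  expect_equal(lp2 - lp1,
               2 * 0.5 * log(prec2 / prec1) - 0.5 * (prec2 - prec1) * b2,
               tolerance = 1e-10)

  # with the field at zeta = 0, sigma -> small: differs from the no-field
  # model only by the hyperprior + MVN normalizing terms
  st_field <- stb
  st_field$zeta <- rep(0, n)
  st_field$log_rho <- log(50)
  st_field$log_sigma <- log(1e-4)
  lpf <- log_posterior(st_field, data, priors)
  lpn <- log_posterior(stb, data, priors)
  params <- matern_params(50, 1e-4)
  S <- build_covariance(coords, params)
  U <- chol(S)
  extra <- -0.5 * n * log(2 * pi) - sum(log(diag(U))) +
    geoprev:::log_pc_prior(log(50), log(1e-4), priors)
  expect_equal(lpf - lpn, extra, tolerance = 1e-8)

  # non-finite states return -Inf, never an error
  bad <- stb; bad$alpha <- NaN
  expect_identical(log_posterior(bad, data, priors), -Inf)
})

test_that("PC prior density integrates to 1 and meets its tail conditions", {
  priors <- prior_spec(rho0 = 50, p_rho = 0.05, sigma0 = 1, p_sigma = 0.05)
  # integrate the joint density over the log-scale parameterization
  f <- Vectorize(function(lr, ls)
    exp(geoprev:::log_pc_prior(lr, ls, priors)))
  ig <- integrate(function(lr) sapply(lr, function(l)
    integrate(function(ls) f(l, ls), -15, 8)$value), -8, 15)
  expect_equal(ig$value, 1, tolerance = 1e-4)
  # P(rho < rho0) = p_rho
  p_below <- integrate(function(lr) sapply(lr, function(l)
    integrate(function(ls) f(l, ls), -15, 8)$value), -8, log(50))
  expect_equal(p_below$value, 0.05, tolerance = 1e-4)
})

test_that("intercept-only MCMC matches deterministic grid quadrature", {
  rec <- records_from_counts(30L, 100L)
  fit <- fit_mcmc(rec, X = NULL, include_field = FALSE, chains = 2,
                  iter = 4000, burnin = 1000, thin = 1, seed = 7)
  oracle <- quad_posterior_alpha(30, 100)
  d <- fit$draws$alpha
  # batch-means Monte Carlo standard error
  nb <- 40
  bm <- colMeans(matrix(d, ncol = nb))
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(mean(d) - oracle$mean), 2 * se)
  expect_lt(abs(var(d) - oracle$var), 0.25 * oracle$var)
  expect_equal(unname(plogis(fit$summaries["alpha", "mean"])), 0.30,
               tolerance = 0.02)
})

test_that("identical seed and config give bit-identical draws", {
  set.seed(13)
  sim <- simulate_dataset(counts_per_wave = 40, spec = grid_spec(8, 8),
                          seed = 31)
  dm <- standardize(sim$design)
  f1 <- fit_mcmc(sim$records, dm, chains = 1, iter = 60, burnin = 30,
                 thin = 1, seed = 5)
  f2 <- fit_mcmc(sim$records, dm, chains = 1, iter = 60, burnin = 30,
                 thin = 1, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_mcmc(sim$records, dm, chains = 1, iter = 60, burnin = 30,
                 thin = 1, seed = 6)
  expect_false(identical(f1$draws$alpha, f3$draws$alpha))
})

test_that("waic matches hand arithmetic and the zero-variance closed form", {
  # two draws, one observation, per-draw log-liks -1 and -2
  w <- waic(matrix(c(-1, -2), nrow = 2))
  expect_equal(w$lppd, log((exp(-1) + exp(-2)) / 2), tolerance = 1e-10)
  expect_equal(w$p_waic, 0.5, tolerance = 1e-12)
  expect_equal(w$waic, 3.7598, tolerance = 1e-4)

  # all draws identical: p_waic = 0, waic = -2 sum log p
  ll <- matrix(rep(c(-1.3, -0.7, -2.1), each = 5), nrow = 5)
  wz <- waic(ll)
  expect_equal(wz$p_waic, 0)
  expect_equal(wz$waic, -2 * sum(ll[1, ]))

  expect_error(waic(matrix(-1, 1, 3)), "2 stored draws")
})

test_that("compare_models ranks ascending with stable ties", {
  mk <- function(w) list(waic = w, p_waic = 1, lppd = -w / 2)
  tab <- compare_models(list(a = mk(10), b = mk(7), c = mk(9)))
  expect_equal(tab$label, c("b", "c", "a"))
  expect_equal(tab$delta_waic, c(0, 2, 3))
  expect_true(all(tab$delta_waic >= 0))
  one <- compare_models(list(only = mk(4)))
  expect_equal(one$delta_waic, 0)
  tie <- compare_models(list(x = mk(5), y = mk(5)))
  expect_equal(tie$label, c("x", "y"))
})
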