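test_that("covariate surfaces are deterministic, standardized and smooth", {
  spec <- grid_spec(50, 50, cell_size = 0.2)
  a <- simulate_covariate_surfaces(2, spec, smoothness_range = 1, seed = 5)
  b <- simulate_covariate_surfaces(2, spec, smoothness_range = 1, seed = 5)
  expect_identical(a[[1]]$values, b[[1]]$values)
  expect_identical(a[[2]]$values, b[[2]]$values)
  expect_false(identical(a[[1]]$values, a[[2]]$values))

  for (g in a) {
    expect_lt(abs(mean(g$values)), 0.05)
    expect_lt(abs(sqrt(mean((g$values - mean(g$values))^2)) - 1), 0.05)
  }

  # large smoothing -> strong neighbor correlation; tiny -> near zero
  neighbor_cor <- function(v) stats::cor(as.vector(v[, -1]),
                                         as.vector(v[, -ncol(v)]))
  smooth <- simulate_covariate_surfaces(1, spec, smoothness_range = 1,
                                        seed = 9)[[1]]
  rough <- simulate_covariate_surfaces(1, spec, smoothness_range = 1e-6,
                                       seed = 9)[[1]]
  expect_gt(neighbor_cor(smooth$values), 0.8)
  expect_lt(abs(neighbor_cor(rough$values)), 0.2)

  expect_error(simulate_covariate_surfaces(1, spec, smoothness_range = 0,
                                           seed = 1), "smoothness_range")
  expect_error(simulate_covariate_surfaces(0, spec, 1, 1))
})

test_that("cluster locations honor counts, waves, bbox and the seed", {
  spec <- grid_spec(10, 10, origin_lon = 34, origin_lat = 14,
                    cell_size = 0.5)
  pts <- simulate_clusters(spec = spec, seed = 2)
  expect_equal(nrow(pts), 2547)
  expect_equal(as.integer(table(pts$wave)[c("2000", "2005", "2011", "2016", "2019")]),
               c(535L, 517L, 571L, 619L, 305L))

  one <- simulate_clusters(rep(1, 5), spec, seed = 2)
  expect_equal(nrow(one), 5)
  expect_equal(one$wave, c("2000", "2005", "2011", "2016", "2019"))

  expect_identical(simulate_clusters(c(10, 10), spec, seed = 3),
                   simulate_clusters(c(10, 10), spec, seed = 3))

  expect_true(all(pts$lon >= 34 - 0.25 & pts$lon <= 34 + 9 * 0.5 + 0.25))
  expect_true(all(pts$lat <= 14 + 0.25 & pts$lat >= 14 - 9 * 0.5 - 0.25))

  expect_error(simulate_clusters(integer(0), spec, seed = 1), "non-empty")
  expect_error(simulate_clusters(c(5, 0), spec, seed = 1), ">= 1")
})

test_that("latent field draws have the stated moments", {
  pts <- data.frame(lon = runif(500, 34, 39), lat = runif(500, 6, 11))

  # degenerate field at sigma = 0
  z0 <- simulate_field(pts, matern_params(100, 0), seed = 1)
  expect_lt(max(abs(z0)), 1e-6)

  # marginal variance: 200 replicate draws at 40 points
  set.seed(99)
  pts40 <- pts[1:40, ]
  params <- matern_params(80, 0.7)
  draws <- sapply(1:200, function(r) simulate_field(pts40, params, seed = r))
  v <- apply(draws, 1, var)
  # var of a sample variance of N(0, s2): 2 s4 / (n-1); 3 SEs
  se <- sqrt(2 * 0.7^4 / 199)
  expect_true(all(abs(v - 0.49) < 3 * se + 0.08))
  expect_lt(abs(mean(v) - 0.49), 3 * se / sqrt(40) + 0.05)

  # two points far beyond the range decorrelate
  far <- data.frame(lon = c(34, 39), lat = c(6, 11))  # ~770 km apart
  fparams <- matern_params(20, 1)
  fd <- sapply(1:1000, function(r) simulate_field(far, fparams, seed = r))
  expect_lt(abs(cor(fd[1, ], fd[2, ])), 0.1)

  # nearby points correlate strongly when rho is large
  near <- data.frame(lon = c(36, 36.05), lat = c(8, 8))
  nd <- sapply(1:300, function(r)
    simulate_field(near, matern_params(500, 1), seed = r))
  expect_gt(cor(nd[1, ], nd[2, ]), 0.9)
})

test_that("binomial outcomes follow the logit linear predictor", {
  set.seed(7)
  n_pts <- 400
  pts <- data.frame(lon = runif(n_pts, 34, 38), lat = runif(n_pts, 6, 10))

  # symmetric null: pooled fraction ~ 0.5 within 3 binomial SEs
  rec <- simulate_outcomes(pts, "2000", matrix(0, n_pts, 1),
                           synthetic_truth(0, 0, matern_params(100, 0.5),
                                           rep(0, n_pts), 1),
                           children_per_cluster = 20, seed = 3)
  p_hat <- sum(rec$n_underweight) / sum(rec$n_children)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / sum(rec$n_children)))

  # generating prevalence 33.8% is recovered at large n
  rec2 <- simulate_outcomes(pts, "2000", matrix(0, n_pts, 1),
                            synthetic_truth(qlogis(0.338), 0,
                                            matern_params(100, 0.5),
                                            rep(0, n_pts), 1),
                            children_per_cluster = 25, seed = 4)
  p2 <- sum(rec2$n_underweight) / sum(rec2$n_children)
  expect_lt(abs(p2 - 0.338), 3 * sqrt(0.338 * 0.662 / sum(rec2$n_children)))

  # beta = +1 on a standardized covariate raises the top-quartile log odds
  sgn <- replicate(100, {
    Xs <- matrix(rnorm(n_pts), n_pts, 1)
    r <- simulate_outcomes(pts, "2000", Xs,
                           synthetic_truth(0, 1, matern_params(100, 0.5),
                                           rep(0, n_pts), 1),
                           children_per_cluster = 10,
                           seed = sample.int(1e6, 1))
    hi <- Xs[, 1] >= quantile(Xs[, 1], 0.75)
    lo <- Xs[, 1] <= quantile(Xs[, 1], 0.25)
    lo_odds <- function(idx) {
      p <- (sum(r$n_underweight[idx]) + 0.5) /
        (sum(r$n_children[idx]) + 1)
      qlogis(p)
    }
    lo_odds(hi) - lo_odds(lo)
  })
  expect_gte(mean(sgn > 0), 0.95)

  # dimension mismatches are errors
  expect_error(simulate_outcomes(pts, "2000", matrix(0, n_pts, 2),
                                 synthetic_truth(0, 0, matern_params(1, 0),
                                                 rep(0, n_pts), 1),
                                 seed = 1), "beta_true")
  expect_error(simulate_outcomes(pts[1:5, ], "2000", matrix(0, 4, 1),
                                 synthetic_truth(0, 0, matern_params(1, 0),
                                                 rep(0, 5), 1),
                                 seed = 1), "rows")
})

test_that("simulate_dataset is deterministic end to end", {
  a <- simulate_dataset(counts_per_wave = c(15, 15),
                        spec = grid_spec(8, 8), seed = 21)
  b <- simulate_dataset(counts_per_wave = c(15, 15),
                        spec = grid_spec(8, 8), seed = 21)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  expect_identical(a$truth$field_values, b$truth$field_values)
  expect_identical(a$grids[[1]]$values, b$grids[[1]]$values)
  # records satisfy every invariant by construction (validated constructor)
  expect_s3_class(a$records, "cluster_records")
})
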