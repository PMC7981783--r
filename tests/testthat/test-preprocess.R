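test_that("random-forest imputation restores strongly predictable cells", {
  set.seed(1)
  n <- 120
  x <- rnorm(n)
  block <- cbind(x = x, y = 2 * x, z = rnorm(n))
  complete <- impute_missing(block)
  expect_identical(unclass(complete)[, ], block[, ])   # no-op when complete

  holdout <- 17
  block_na <- block
  block_na[holdout, "y"] <- NA
  imp <- impute_missing(block_na, seed = 99)
  expect_lt(abs(imp[holdout, "y"] - 2 * x[holdout]), 0.1 * sd(block[, "y"]))

  imp2 <- impute_missing(block_na, seed = 99)
  expect_equal(unclass(imp)[, ], unclass(imp2)[, ])    # same seed, same fill

  block_na[, "z"] <- NA
  expect_error(impute_missing(block_na), "entirely missing.*z")
})

test_that("Mahalanobis filter excludes rows beyond the chi-square cutoff", {
  set.seed(2)
  X <- matrix(rnorm(400 * 2), 400, 2)
  rownames(X) <- sprintf("S%03d", 1:400)
  X["S001", ] <- c(12, -12)    # unambiguous outlier
  f <- mahalanobis_filter(X, quantile = 0.999)
  # frozen from independent chi-square inversion: qchisq(0.999, 2) = 13.8155
  expect_equal(f$cutoff, 13.8155, tolerance = 1e-4)
  expect_true("S001" %in% f$excluded)
  expect_true(all(f$distances[f$kept] <= f$cutoff))
  expect_true(all(f$distances[f$excluded] > f$cutoff))
  # distance at the column mean is ~0; squared-Euclidean case
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(unname(f$distances["S010"]),
               drop(Xc["S010", ] %*% solve(cov(X), Xc["S010", ])),
               tolerance = 1e-10)
})

test_that("singular covariance errors unless shrinkage or MCD engaged", {
  set.seed(3)
  X <- matrix(rnorm(10 * 20), 10, 20)   # p > n
  expect_error(mahalanobis_filter(X), "shrinkage")
  f <- mahalanobis_filter(X, shrinkage = TRUE)
  expect_length(f$distances, 10)
  expect_true(all(is.finite(f$distances)))
})

test_that("null-model exclusion rate matches the 0.999 quantile", {
  set.seed(4)
  X <- matrix(rnorm(10000 * 5), 10000, 5)
  f <- mahalanobis_filter(X, quantile = 0.999)
  n_out <- length(f$excluded)
  expect_gte(n_out, qbinom(0.005, 10000, 0.001))
  expect_lte(n_out, qbinom(0.995, 10000, 0.001))
})

test_that("empirical-Bayes harmonization removes site location-scale shifts", {
  one_site <- matrix(rnorm(50 * 4), 50, 4)
  expect_equal(empirical_bayes_harmonize(one_site, rep("a", 50)), one_site)

  # residual site differences after EB adjustment are estimation noise;
  # judge them on the simulation average across features and seeds
  mean_gaps <- c()
  var_ratios <- c()
  for (s in 1:5) {
    set.seed(s)
    sites <- rep(c("a", "b"), each = 500)
    X <- matrix(rnorm(1000 * 10), 1000, 10)
    X[sites == "b", ] <- X[sites == "b", ] + 1          # shift d = 1
    adj <- empirical_bayes_harmonize(X, sites)
    for (j in 1:10) {
      mean_gaps <- c(mean_gaps,
                     abs(mean(adj[sites == "a", j]) -
                           mean(adj[sites == "b", j])) / sd(adj[, j]))
      var_ratios <- c(var_ratios,
                      var(adj[sites == "a", j]) / var(adj[sites == "b", j]))
    }
  }
  expect_lt(mean(mean_gaps), 0.05)
  expect_gt(mean(var_ratios), 0.9)
  expect_lt(mean(var_ratios), 1.1)

  sites <- rep(c("a", "b"), c(1, 49))
  expect_error(empirical_bayes_harmonize(matrix(rnorm(100), 50, 2), sites),
               "single subject")
  Xc <- cbind(rnorm(40), rnorm(40), rep(1, 40))
  expect_warning(empirical_bayes_harmonize(Xc, rep(c("a", "b"), 20)),
                 "constant")
})

test_that("harmonization preserves the planted canonical signal", {
  rs <- t(sapply(1:5, function(s) {
    spec <- synthetic_spec(600, 15, 15, n_modes = 1, target_r = 0.7,
                           n_sites = 3, site_shift_sd = 0.5,
                           site_scale_range = c(0.8, 1.25), seed = 40 + s)
    g <- generate_linked_blocks(spec)
    clean <- fit_first_mode(standardize_block(g$data$X),
                            standardize_block(g$data$Y), 0.7, 0.7)$r
    pert <- inject_site_effects(g$data, g$truth)
    Xh <- empirical_bayes_harmonize(pert$data$X, pert$data$sites)
    harm <- fit_first_mode(standardize_block(Xh),
                           standardize_block(pert$data$Y), 0.7, 0.7)$r
    c(clean = clean, harm = harm)
  }))
  expect_lt(mean(abs(rs[, "harm"] - rs[, "clean"])), 0.05)
})

test_that("standardization gives exact z-scores and flags bad columns", {
  expect_equal(drop(standardize_block(cbind(c(1, 2, 3)))), c(-1, 0, 1))
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- standardize_block(X)
  expect_true(all(abs(colMeans(Z)) < 1e-12))
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(standardize_block(Z)[, ], Z[, ], tolerance = 1e-12)
  X[, 2] <- 7
  expect_error(standardize_block(X), "zero-variance.*b")
  X[, 2] <- NA
  expect_error(standardize_block(X), "missing")
})

test_that("change scores are residualized exactly against baseline", {
  set.seed(6)
  n <- 150
  base <- matrix(rnorm(3 * n), n, 3,
                 dimnames = list(sprintf("S%03d", 1:n), c("a", "b", "c")))
  cs0 <- compute_change_scores(base, base)
  expect_true(all(cs0$residuals == 0))

  delta <- matrix(rnorm(3 * n, mean = 2), n, 3)   # independent of baseline
  cs <- compute_change_scores(base, base + delta)
  for (j in 1:3) {
    expect_lt(abs(cor(cs$residuals[, j], base[, j])), 1e-10)
    expect_equal(unname(cs$residuals[, j]),
                 unname(residuals(lm(delta[, j] ~ base[, j]))),
                 tolerance = 1e-10)
  }

  follow_bad <- base + delta
  rownames(follow_bad)[2] <- "S999"
  expect_error(compute_change_scores(base, follow_bad), "S999")
})

test_that("covariate regression leaves residuals orthogonal to covariates", {
  set.seed(7)
  n <- 100
  covs <- data.frame(age = rnorm(n, 14, 0.4), sex = rbinom(n, 1, 0.5))
  X <- matrix(rnorm(4 * n), n, 4)
  R <- regress_out_covariates(X, covs)
  expect_lt(max(abs(crossprod(cbind(1, covs$age, covs$sex), R))), 1e-8)

  lin <- cbind(3 + 2 * covs$age - covs$sex)
  expect_lt(max(abs(regress_out_covariates(lin, covs))), 1e-10)

  const <- data.frame(k = rep(1, n))
  expect_equal(regress_out_covariates(X, const),
               sweep(X, 2, colMeans(X)), tolerance = 1e-10)

  expect_error(regress_out_covariates(X, data.frame(a = covs$age,
                                                    b = 2 * covs$age)),
               "rank")
})
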