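test_that("spec validation rejects inconsistent cohort descriptions", {
  expect_error(synthetic_spec(100, 5, 5, n_modes = 6), "n_modes")
  expect_error(synthetic_spec(100, 10, 10, missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(100, 10, 10, n_modes = 2, support_x = 6,
                              support_y = 3, target_r = c(0.8, 0.5)),
               "support")
  expect_error(synthetic_spec(100, 10, 10, n_modes = 2,
                              support_x = 3, support_y = 3,
                              target_r = c(0.5, 0.8)),
               "decreasing")
})

test_that("identical specs generate bit-identical cohorts", {
  spec <- synthetic_spec(80, 12, 10, n_sites = 3, seed = 42)
  g1 <- generate_linked_blocks(spec)
  g2 <- generate_linked_blocks(spec)
  expect_identical(g1, g2)
})

test_that("ground truth has unit-norm weights with the requested supports", {
  spec <- synthetic_spec(50, 20, 15, n_modes = 2, support_x = c(5, 3),
                         support_y = c(4, 2), target_r = c(0.7, 0.4),
                         seed = 3)
  tr <- generate_linked_blocks(spec)$truth
  expect_equal(colSums(tr$true_weights_x^2), c(1, 1))
  expect_equal(colSums(tr$true_weights_x != 0), c(5, 3))
  expect_equal(colSums(tr$true_weights_y != 0), c(4, 2))
  # disjoint supports across modes
  expect_true(all(rowSums(tr$true_weights_x != 0) <= 1))
})

test_that("zero modes give independent noise; zero noise gives r = 1", {
  g0 <- generate_linked_blocks(synthetic_spec(900, 10, 10, n_modes = 0,
                                              seed = 5))
  set.seed(6)
  u <- rnorm(10); u <- u / sqrt(sum(u^2))
  v <- rnorm(10); v <- v / sqrt(sum(v^2))
  expect_lt(abs(cor(g0$data$X %*% u, g0$data$Y %*% v)), 3 / sqrt(900))

  g1 <- generate_linked_blocks(synthetic_spec(100, 8, 8, n_modes = 1,
                                              target_r = 1, noise_sd = 0,
                                              seed = 7))
  r <- cor(g1$data$X %*% g1$truth$true_weights_x,
           g1$data$Y %*% g1$truth$true_weights_y)
  expect_equal(drop(r), 1, tolerance = 1e-12)
})

test_that("signal scaling hits the target canonical correlation", {
  # Monte-Carlo check of the closed-form variance-ratio scale over 50 seeds
  rs <- vapply(1:50, function(s) {
    g <- generate_linked_blocks(synthetic_spec(2000, 10, 10, n_modes = 1,
                                               target_r = 0.6, noise_sd = 1,
                                               seed = s))
    cor(g$data$X %*% g$truth$true_weights_x,
        g$data$Y %*% g$truth$true_weights_y)
  }, numeric(1))
  expect_gt(mean(rs), 0.55)
  expect_lt(mean(rs), 0.65)
  expect_true(all(rs > 0.5 & rs < 0.7))
})

test_that("site effects shift and scale the imaging block as recorded", {
  spec0 <- synthetic_spec(200, 8, 6, n_sites = 2, site_shift_sd = 0,
                          site_scale_range = c(1, 1), seed = 8)
  g0 <- generate_linked_blocks(spec0)
  out0 <- inject_site_effects(g0$data, g0$truth)
  expect_equal(out0$data$X, g0$data$X)

  spec <- synthetic_spec(400, 8, 6, n_sites = 2, site_shift_sd = 1,
                         site_scale_range = c(1, 1), seed = 9)
  g <- generate_linked_blocks(spec)
  out <- inject_site_effects(g$data, g$truth)
  s1 <- out$data$sites == "site01"
  pre_diff <- colMeans(g$data$X[!s1, ]) - colMeans(g$data$X[s1, ])
  post_diff <- colMeans(out$data$X[!s1, ]) - colMeans(out$data$X[s1, ])
  shift_diff <- out$truth$site_params$shift["site02", ] -
    out$truth$site_params$shift["site01", ]
  expect_equal(post_diff - pre_diff, shift_diff, tolerance = 1e-10)

  # between-site variance of a null feature increases
  j <- ncol(g$data$X)   # outside the mode support
  between <- function(x, grp) {
    m <- tapply(x, grp, mean)
    sum(table(grp) * (m - mean(x))^2) / (length(x) - 1)
  }
  expect_gt(between(out$data$X[, j], out$data$sites),
            between(g$data$X[, j], g$data$sites))
})

test_that("missingness is MCAR in the non-imaging block only", {
  g <- generate_linked_blocks(synthetic_spec(500, 10, 20, seed = 10))
  d0 <- inject_missingness(g$data, 0, seed = 1)
  expect_false(anyNA(d0$Y))
  d <- inject_missingness(g$data, 0.05, seed = 1)
  expect_false(anyNA(d$X))
  n_miss <- sum(is.na(d$Y))
  expect_gte(n_miss, qbinom(0.005, 10000, 0.05))
  expect_lte(n_miss, qbinom(0.995, 10000, 0.05))
  expect_identical(is.na(d$Y), d$missing_mask)
  expect_error(inject_missingness(g$data, 1, seed = 1), "rate")
})

test_that("longitudinal pairs thin thickness-like features as specified", {
  spec <- synthetic_spec(2000, 10, 8, n_modes = 1, target_r = 0.6,
                         longitudinal = TRUE, thinning_mean = -0.12,
                         thinning_sd = 0.06, seed = 11)
  lp <- generate_longitudinal_pair(spec)
  thinning <- lp$followup$X - lp$baseline$X
  # mode signal is mean-zero; the systematic part is the thinning decrement
  expect_gte(mean(thinning), -0.13 - 0.05)
  expect_lte(mean(thinning), -0.11 + 0.05)
  expect_identical(lp$baseline$subject_id, lp$followup$subject_id)

  flat <- synthetic_spec(100, 6, 6, n_modes = 0, longitudinal = TRUE,
                         thinning_mean = 0, thinning_sd = 0, seed = 12)
  lp0 <- generate_longitudinal_pair(flat)
  expect_identical(lp0$followup$X, lp0$baseline$X)
  expect_identical(lp0$followup$Y, lp0$baseline$Y)
})

test_that("recovery scores are sign-invariant and match the F1 definition", {
  w <- c(0.6, 0.8, 0, 0)
  expect_equal(unname(weight_recovery_score(w, w)), c(1, 1))
  expect_equal(unname(weight_recovery_score(-w, w)), c(1, 1))
  truth <- c(1, 1, 1, 0, 0) / sqrt(3)
  est <- c(0, 1, 1, 1, 0) / sqrt(3)
  sc <- weight_recovery_score(est, truth)
  expect_equal(unname(sc["support_f1"]), 2 / 3)
  expect_equal(unname(sc["cosine"]), sum(est * truth))
  expect_error(weight_recovery_score(rep(0, 3), c(1, 0, 0)), "zero vector")
})

test_that("ordinal and binary non-imaging features take the coded levels", {
  spec <- synthetic_spec(300, 6, 20, n_modes = 1, support_y = 5,
                         n_ordinal = 4, n_binary = 3, seed = 13)
  g <- generate_linked_blocks(spec)
  sup <- which(g$truth$true_weights_y[, 1] != 0)
  free <- setdiff(seq_len(20), sup)
  ord_cols <- free[1:4]
  bin_cols <- free[5:7]
  for (j in ord_cols)
    expect_true(all(g$data$Y[, j] %in% 0:6))
  for (j in bin_cols)
    expect_true(all(g$data$Y[, j] %in% 0:1))
  expect_false(all(g$data$Y[, sup[1]] %in% 0:6))
})
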