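## Fast internal refit of the first mode on (sub)samples with fixed L1
## bounds; returns weights and the non-negative canonical correlation.
refit_mode <- function(X, Y, c1, c2) {
  fit <- fit_mode_pmd(crossprod(X, Y), c1, c2)
  vx <- drop(X %*% fit$u)
  vy <- drop(Y %*% fit$v)
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0)
    return(list(u = fit$u, v = fit$v, r = 0, vx = vx, vy = vy))
  r <- stats::cor(vx, vy)
  if (r < 0) {
    fit$u <- -fit$u
    vx <- -vx
    r <- -r
  }
  list(u = fit$u, v = fit$v, r = r, vx = vx, vy = vy)
}

#' Redundancy-reliability (RR) scores of the canonical cross-loadings
#'
#' For each of `n_resample` random 50% subsamples (without replacement) the
#' first mode is refitted at the fixed penalties and its cross-loadings
#' recomputed. A resample's RR score is the fraction of the full-sample
#' *reported* variables (those with `|cross-loading| > threshold` in the
#' full fit, pooled over both blocks) whose resampled cross-loading keeps
#' the same sign and still exceeds the threshold in magnitude. The
#' sign-and-threshold concordance form is a documented proxy for
#' cross-loading reliability, bounded in `[0, 1]`, so the conventional
#' median > 0.80 reporting criterion applies to it directly.
#'
#' @param X,Y Standardized blocks.
#' @param penalty_x,penalty_y Fixed penalties from tuning.
#' @param n_resample Number of 50% subsamples.
#' @param seed Integer seed.
#' @param threshold Small-effect cut-off defining the reported set.
#' @return List: `rr_scores` (length `n_resample`), `rr_median`.
#' @export
rr_score <- function(X, Y, penalty_x, penalty_y, n_resample = 500L,
                     seed = 1L, threshold = 0.1) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  full <- suppressWarnings(fit_first_mode(X, Y, penalty_x, penalty_y))
  ref <- c(full$cross_loadings_x, full$cross_loadings_y)
  rep_idx <- which(abs(ref) > threshold)
  if (length(rep_idx) == 0)
    stop("no variable passes the reported-effect threshold; RR undefined")
  ref_sign <- sign(ref[rep_idx])
  c1 <- penalty_x * sqrt(ncol(X))
  c2 <- penalty_y * sqrt(ncol(Y))
  n <- nrow(X)
  m <- floor(n / 2)
  set.seed(seed)
  scores <- vapply(seq_len(n_resample), function(b) {
    idx <- sample.int(n, m)
    fit <- refit_mode(X[idx, , drop = FALSE], Y[idx, , drop = FALSE], c1, c2)
    ## align the resampled mode's sign with the full-sample variates
    if (sum(fit$u * full$weights_x) + sum(fit$v * full$weights_y) < 0) {
      fit$vx <- -fit$vx
      fit$vy <- -fit$vy
    }
    cl <- c(safe_cor(X[idx, , drop = FALSE], fit$vy),
            safe_cor(Y[idx, , drop = FALSE], fit$vx))[rep_idx]
    mean(sign(cl) == ref_sign & abs(cl) > threshold, na.rm = TRUE)
  }, numeric(1))
  list(rr_scores = scores, rr_median = stats::median(scores))
}

#' Stability of the canonical correlation across subset sizes
#'
#' Repeats the first-mode fit in `reps` random subsets at each fraction of
#' the original sample size (default 10% to 150% in 10% steps, 1500 refits
#' in total): fractions up to 1 are drawn without replacement, fractions
#' above 1 with replacement. Fractions yielding fewer than 3 subjects are
#' skipped with a warning.
#'
#' @param X,Y Standardized blocks.
#' @param penalty_x,penalty_y Fixed penalties.
#' @param fractions Subset-size fractions of n.
#' @param reps Refits per fraction.
#' @param seed Integer seed.
#' @return Data frame with columns `fraction`, `rep`, `r`.
#' @export
stability_curve <- function(X, Y, penalty_x, penalty_y,
                            fractions = seq(0.1, 1.5, by = 0.1),
                            reps = 100L, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 20) stop("need at least 20 subjects for a stability curve")
  c1 <- penalty_x * sqrt(ncol(X))
  c2 <- penalty_y * sqrt(ncol(Y))
  set.seed(seed)
  out <- lapply(fractions, function(f) {
    m <- round(f * n)
    if (m < 3) {
      warning(sprintf("fraction %.2f gives %d subjects; skipped", f, m))
      return(NULL)
    }
    r <- vapply(seq_len(reps), function(b) {
      idx <- sample.int(n, m, replace = f > 1)
      refit_mode(X[idx, , drop = FALSE], Y[idx, , drop = FALSE], c1, c2)$r
    }, numeric(1))
    data.frame(fraction = f, rep = seq_len(reps), r = r)
  })
  do.call(rbind, out)
}

#' Split-half generalization of the first mode
#'
#' `n_splits` random 50/50 splits: the mode is fitted on the training half
#' and its weight vectors applied unchanged to the held-out half, where the
#' test canonical correlation is the plain Pearson correlation of the
#' projected variates. The generalization criterion is that the average
#' test-set correlation reaches at least 80% of the average training-set
#' correlation. Splits with a degenerate (zero-variance) test variate are
#' recorded as missing.
#'
#' @param X,Y Standardized blocks, n >= 20.
#' @param penalty_x,penalty_y Fixed penalties.
#' @param n_splits Number of random splits.
#' @param seed Integer seed.
#' @return List: `split_half` (data frame of `train_r`, `test_r` pairs),
#'   `test_train_ratio` (= `mean(test_r)/mean(train_r)`, missing splits
#'   dropped), `pass` (ratio >= 0.80).
#' @export
split_half_generalization <- function(X, Y, penalty_x, penalty_y,
                                      n_splits = 500L, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 20) stop("need at least 20 subjects for split-half analysis")
  c1 <- penalty_x * sqrt(ncol(X))
  c2 <- penalty_y * sqrt(ncol(Y))
  m <- floor(n / 2)
  set.seed(seed)
  res <- t(vapply(seq_len(n_splits), function(b) {
    idx <- sample.int(n, m)
    train <- refit_mode(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                        c1, c2)
    vx <- drop(X[-idx, , drop = FALSE] %*% train$u)
    vy <- drop(Y[-idx, , drop = FALSE] %*% train$v)
    test_r <- if (stats::sd(vx) == 0 || stats::sd(vy) == 0) NA_real_
              else stats::cor(vx, vy)
    c(train_r = train$r, test_r = test_r)
  }, numeric(2)))
  tab <- as.data.frame(res)
  ratio <- mean(tab$test_r, na.rm = TRUE) / mean(tab$train_r, na.rm = TRUE)
  list(split_half = tab, test_train_ratio = ratio, pass = ratio >= 0.80)
}

#' Association between scan quality and the canonical correlation
#'
#' For each of `n_resample` 50% subsamples, records the subsample's mean
#' per-subject quality score and its refitted canonical correlation, and
#' returns the Spearman correlation between the two series — a check that
#' the fitted association is not driven by image quality.
#'
#' @param quality Per-subject quality score, aligned with the rows.
#' @param X,Y Standardized blocks.
#' @param penalty_x,penalty_y Fixed penalties.
#' @param n_resample Number of subsamples.
#' @param seed Integer seed.
#' @return List: `quality_rho` (Spearman; `NA` with a warning for a
#'   constant quality vector), `table` (mean quality and r per resample).
#' @export
quality_association <- function(quality, X, Y, penalty_x, penalty_y,
                                n_resample = 500L, seed = 1L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (length(quality) != nrow(X))
    stop("'quality' must be aligned with the subjects")
  c1 <- penalty_x * sqrt(ncol(X))
  c2 <- penalty_y * sqrt(ncol(Y))
  n <- nrow(X)
  m <- floor(n / 2)
  set.seed(seed)
  res <- t(vapply(seq_len(n_resample), function(b) {
    idx <- sample.int(n, m)
    c(mean_quality = mean(quality[idx]),
      r = refit_mode(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                     c1, c2)$r)
  }, numeric(2)))
  tab <- as.data.frame(res)
  if (stats::sd(tab$mean_quality) == 0) {
    warning("constant quality score; Spearman correlation undefined")
    return(list(quality_rho = NA_real_, table = tab))
  }
  rho <- stats::cor(tab$mean_quality, tab$r, method = "spearman")
  list(quality_rho = rho, table = tab)
}

#' Sensitivity refit with age and sex regressed out
#'
#' Removes the age and sex columns from the non-imaging block, residualizes
#' both blocks on them (OLS with intercept), re-standardizes, re-tunes the
#' sparsity penalties and re-runs the permutation test — the standard check
#' that a brain-behaviour mode is not purely a biological-programming
#' (age/sex) effect.
#'
#' @param X Standardized imaging block.
#' @param Y Standardized non-imaging block containing `age_col` and
#'   `sex_col`.
#' @param age_col,sex_col Column names of the age and sex variables in `Y`.
#' @param n_perm Permutations for the refitted model.
#' @param seed Integer seed.
#' @param fdr_alpha Significance gate applied to the refitted exact P.
#' @return List: `tuning`, `permutation` (a `permutation_result`),
#'   `significant` (exact P < `fdr_alpha`), and the residualized blocks.
#' @export
sensitivity_refit_without_age_sex <- function(X, Y, age_col = "age",
                                              sex_col = "sex",
                                              n_perm = 1000L, seed = 1L,
                                              fdr_alpha = 0.001) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  missing_cols <- setdiff(c(age_col, sex_col), colnames(Y))
  if (length(missing_cols))
    stop("covariate column(s) absent from Y: ",
         paste(missing_cols, collapse = ", "))
  covs <- Y[, c(age_col, sex_col), drop = FALSE]
  Y2 <- Y[, setdiff(colnames(Y), c(age_col, sex_col)), drop = FALSE]
  Xr <- standardize_block(regress_out_covariates(X, covs))
  Yr <- standardize_block(regress_out_covariates(Y2, covs))
  tuned <- tune_sparsity(Xr, Yr)
  perm <- permutation_test(Xr, Yr, tuned$penalty_x, tuned$penalty_y,
                           n_perm = n_perm, seed = seed)
  list(tuning = tuned, permutation = perm,
       significant = perm$exact_p < fdr_alpha,
       X_residual = Xr, Y_residual = Yr)
}
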