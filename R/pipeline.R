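#' Configuration for an end-to-end sparse CCA run
#'
#' Collects every tunable of the pipeline with the conventional defaults:
#' 1000 permutations, a 10-point sparsity grid per block, Mahalanobis
#' quantile 0.999, 500 resamples and 500 splits in the robustness battery,
#' stability fractions 0.1-1.5, a strict small-effect threshold of 0.1 on
#' reported loadings, and an FDR significance gate of 0.001.
#'
#' @param kind `"baseline"` (cross-sectional) or `"change"` (longitudinal
#'   change scores; requires follow-up blocks).
#' @param penalty_x,penalty_y Fixed penalties; `NULL` (default) auto-tunes
#'   on the grid.
#' @param n_perm,n_resample,n_splits,stability_reps Resampling sizes.
#' @param fractions Stability-curve subset fractions.
#' @param fdr_alpha Significance gate on the FDR-adjusted P.
#' @param effect_threshold Reported-loading magnitude cut-off (strict).
#' @param mahalanobis_quantile Outlier-exclusion quantile.
#' @param harmonize Apply empirical-Bayes site harmonization.
#' @param impute_max_iter,impute_tol,impute_ntree Imputation controls.
#' @param run_robustness Run the (costly) robustness battery.
#' @param seed Integer seed governing every random stage.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(kind = c("baseline", "change"),
                            penalty_x = NULL, penalty_y = NULL,
                            n_perm = 1000L, n_resample = 500L,
                            n_splits = 500L, stability_reps = 100L,
                            fractions = seq(0.1, 1.5, by = 0.1),
                            fdr_alpha = 0.001, effect_threshold = 0.1,
                            mahalanobis_quantile = 0.999,
                            harmonize = TRUE,
                            impute_max_iter = 10L, impute_tol = 1e-3,
                            impute_ntree = 100L,
                            run_robustness = TRUE,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("'fdr_alpha' must be in (0, 1)")
  if (effect_threshold < 0) stop("'effect_threshold' must be >= 0")
  structure(list(kind = kind, penalty_x = penalty_x, penalty_y = penalty_y,
                 n_perm = as.integer(n_perm),
                 n_resample = as.integer(n_resample),
                 n_splits = as.integer(n_splits),
                 stability_reps = as.integer(stability_reps),
                 fractions = fractions,
                 fdr_alpha = fdr_alpha,
                 effect_threshold = effect_threshold,
                 mahalanobis_quantile = mahalanobis_quantile,
                 harmonize = harmonize,
                 impute_max_iter = as.integer(impute_max_iter),
                 impute_tol = impute_tol,
                 impute_ntree = as.integer(impute_ntree),
                 run_robustness = isTRUE(run_robustness),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full sparse CCA analysis pipeline
#'
#' Executes the stages in their canonical order — impute the non-imaging
#' block, Mahalanobis outlier exclusion on the imaging block,
#' empirical-Bayes site harmonization, change-score residualization for a
#' longitudinal run, column standardization, sparsity tuning, first-mode
#' fit, permutation inference with FDR adjustment, and the robustness
#' battery — and assembles a `run_report`. A mode is flagged `reported`
#' only if all three robustness criteria hold: FDR-adjusted P below
#' `fdr_alpha`, median RR score above 0.80, and split-half test/train
#' ratio of at least 0.80. Fully reproducible given `config$seed`.
#'
#' @param data A `two_block_dataset` (e.g. from
#'   [generate_linked_blocks()]), or a list with elements `X`, `Y`,
#'   `sites`, and optionally `quality`.
#' @param config A `run_config` from [pipeline_config()].
#' @param followup Optional follow-up `two_block_dataset` for
#'   `kind = "change"`.
#' @return An object of class `run_report`; see [write_report()] for the
#'   file layout it serializes to.
#' @export
run_pipeline <- function(data, config = pipeline_config(),
                         followup = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  X <- as.matrix(data$X)
  Y <- as.matrix(data$Y)
  sites <- data$sites
  quality <- data$quality
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (is.null(rownames(Y))) rownames(Y) <- rownames(X)
  note("input: %d subjects, %d imaging, %d non-imaging features",
       nrow(X), ncol(X), ncol(Y))
  if (config$kind == "change" && is.null(followup))
    stop("stage change_scores: kind = \"change\" requires 'followup'")

  ## 1. imputation (non-imaging only; imaging must be complete)
  if (anyNA(X)) stop("stage impute: imaging block contains missing values")
  if (anyNA(Y)) {
    n_miss <- sum(is.na(Y))
    Y <- impute_missing(Y, max_iter = config$impute_max_iter,
                        tol = config$impute_tol,
                        ntree = config$impute_ntree, seed = config$seed)
    note("impute: filled %d missing non-imaging cells in %d sweep(s)",
         n_miss, attr(Y, "iterations"))
  } else note("impute: no missing entries")

  ## 2. multivariate outlier exclusion on the imaging block
  filt <- mahalanobis_filter(X, quantile = config$mahalanobis_quantile)
  excluded <- filt$excluded
  if (length(excluded)) {
    keep_idx <- match(filt$kept, rownames(X))
    X <- X[keep_idx, , drop = FALSE]
    Y <- Y[keep_idx, , drop = FALSE]
    if (!is.null(sites)) sites <- droplevels(sites[keep_idx])
    if (!is.null(quality)) quality <- quality[keep_idx]
    if (!is.null(followup)) {
      followup$X <- followup$X[keep_idx, , drop = FALSE]
      followup$Y <- followup$Y[keep_idx, , drop = FALSE]
    }
  }
  note("outlier filter: excluded %d of %d subjects (quantile %.4f)",
       length(excluded), length(filt$distances),
       config$mahalanobis_quantile)

  ## 3. site harmonization (imaging block only)
  if (config$harmonize && !is.null(sites) && nlevels(droplevels(as.factor(sites))) > 1) {
    X <- empirical_bayes_harmonize(X, sites)
    if (!is.null(followup))
      followup$X <- empirical_bayes_harmonize(followup$X, sites)
    note("harmonize: empirical-Bayes adjustment across %d sites",
         nlevels(droplevels(as.factor(sites))))
  } else note("harmonize: skipped")

  ## 4. change scores for a longitudinal run
  if (config$kind == "change") {
    X <- compute_change_scores(X, followup$X)$residuals
    Y <- compute_change_scores(Y, followup$Y)$residuals
    note("change scores: residualized follow-up minus baseline")
  }

  ## 5. standardization
  X <- standardize_block(X)
  Y <- standardize_block(Y)

  ## 6. sparsity tuning (unless penalties fixed)
  if (is.null(config$penalty_x) || is.null(config$penalty_y)) {
    tuned <- tune_sparsity(X, Y)
    note("tuning: selected penalties (%.3f, %.3f), r = %.4f",
         tuned$penalty_x, tuned$penalty_y, tuned$r)
  } else {
    tuned <- list(penalty_x = config$penalty_x,
                  penalty_y = config$penalty_y, r = NA_real_,
                  fit_table = data.frame(penalty_x = config$penalty_x,
                                         penalty_y = config$penalty_y,
                                         r = NA_real_, converged = NA))
    note("tuning: penalties fixed at (%.3f, %.3f)",
         tuned$penalty_x, tuned$penalty_y)
  }

  ## 7. final fit + permutation inference
  mode <- fit_first_mode(X, Y, tuned$penalty_x, tuned$penalty_y)
  perm <- permutation_test(X, Y, tuned$penalty_x, tuned$penalty_y,
                           n_perm = config$n_perm, seed = config$seed)
  fdr_p <- fdr_adjust(perm$exact_p)  # single-model family: equals exact_p
  note("inference: r = %.4f, exact P = %.4g, mean (SD) permuted r = %.2f (%.2f)",
       mode$r, perm$exact_p, perm$mean_permuted, perm$sd_permuted)

  ## 8. robustness battery
  robustness <- NULL
  if (config$run_robustness) {
    rr <- rr_score(X, Y, tuned$penalty_x, tuned$penalty_y,
                   n_resample = config$n_resample, seed = config$seed,
                   threshold = config$effect_threshold)
    sh <- split_half_generalization(X, Y, tuned$penalty_x, tuned$penalty_y,
                                    n_splits = config$n_splits,
                                    seed = config$seed)
    st <- stability_curve(X, Y, tuned$penalty_x, tuned$penalty_y,
                          fractions = config$fractions,
                          reps = config$stability_reps, seed = config$seed)
    q_rho <- NA_real_
    if (!is.null(quality)) {
      qa <- quality_association(quality, X, Y, tuned$penalty_x,
                                tuned$penalty_y,
                                n_resample = config$n_resample,
                                seed = config$seed)
      q_rho <- qa$quality_rho
    }
    pass_flags <- c(fdr_significant = fdr_p < config$fdr_alpha,
                    rr_median = rr$rr_median > 0.80,
                    split_half = sh$test_train_ratio >= 0.80)
    robustness <- list(rr_scores = rr$rr_scores, rr_median = rr$rr_median,
                       stability = st, split_half = sh$split_half,
                       test_train_ratio = sh$test_train_ratio,
                       quality_rho = q_rho, pass_flags = pass_flags)
    note("robustness: median RR = %.3f, test/train = %.3f, quality rho = %.3f",
         rr$rr_median, sh$test_train_ratio, q_rho)
  }

  reported <- if (is.null(robustness)) fdr_p < config$fdr_alpha
              else all(robustness$pass_flags)

  cl_x <- mode$cross_loadings_x
  cl_y <- mode$cross_loadings_y
  variable_table <- data.frame(
    variable = c(colnames(X), colnames(Y)),
    block = rep(c("imaging", "nonimaging"), c(ncol(X), ncol(Y))),
    weight = c(mode$weights_x, mode$weights_y),
    cross_loading = c(cl_x, cl_y),
    reported = abs(c(cl_x, cl_y)) > config$effect_threshold,
    stringsAsFactors = FALSE)

  structure(list(
    config = config,
    penalty_x = tuned$penalty_x, penalty_y = tuned$penalty_y,
    tuning = tuned,
    mode = mode,
    r = mode$r,
    exact_p = perm$exact_p,
    fdr_adjusted_p = fdr_p,
    covariance_explained_percent = round(100 * covariance_explained(mode$r)),
    permutation = perm,
    robustness = robustness,
    reported = reported,
    variable_table = variable_table,
    n_subjects = nrow(X),
    excluded_subjects = excluded,
    log = log
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("sCCA run report (", x$config$kind, " analysis)\n", sep = "")
  cat(sprintf("  n = %d subjects (%d excluded as outliers)\n",
              x$n_subjects, length(x$excluded_subjects)))
  cat(sprintf("  penalties: (%.3f, %.3f)\n", x$penalty_x, x$penalty_y))
  cat(sprintf("  r = %.4f, exact P = %.4g, FDR P = %.4g\n",
              x$r, x$exact_p, x$fdr_adjusted_p))
  cat(sprintf("  covariance explained: %d%%\n",
              x$covariance_explained_percent))
  if (!is.null(x$robustness)) {
    pf <- x$robustness$pass_flags
    cat(sprintf("  robustness: RR median %.3f [%s], test/train %.3f [%s], FDR gate [%s]\n",
                x$robustness$rr_median,
                ifelse(pf["rr_median"], "pass", "fail"),
                x$robustness$test_train_ratio,
                ifelse(pf["split_half"], "pass", "fail"),
                ifelse(pf["fdr_significant"], "pass", "fail")))
  }
  cat(sprintf("  reported: %s\n", x$reported))
  invisible(x)
}
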