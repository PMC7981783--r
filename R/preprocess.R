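#' Iterative random-forest imputation of a mixed non-imaging block
#'
#' missForest-style chained imputation: missing cells are initialized with
#' column means, then columns are visited in order of increasing missingness,
#' each regressed on all other (currently imputed) columns with a random
#' forest and its missing cells replaced by forest predictions; sweeps repeat
#' until the relative change in the imputed values drops below `tol` or
#' `max_iter` sweeps. All columns are treated as numeric (ordinal codes as
#' integers, binaries as 0/1), matching a pipeline that standardizes mixed
#' variables jointly. Deterministic given `seed`.
#'
#' @param block Numeric matrix or data frame with `NA`s.
#' @param max_iter Maximum sweeps over the columns.
#' @param tol Relative-change stopping tolerance.
#' @param ntree Trees per forest.
#' @param seed Integer seed.
#' @return Completed matrix, with attributes `iterations` and
#'   `final_change`.
#' @export
impute_missing <- function(block, max_iter = 10L, tol = 1e-3,
                           ntree = 100L, seed = 1L) {
  X <- as.matrix(block)
  if (!is.numeric(X)) stop("'block' must be numeric")
  miss <- is.na(X)
  if (!any(miss)) {
    attr(X, "iterations") <- 0L
    attr(X, "final_change") <- 0
    return(X)
  }
  all_na <- colSums(!miss) == 0
  if (any(all_na))
    stop("column(s) entirely missing: ",
         paste(colnames(X)[all_na], collapse = ", "))
  set.seed(seed)
  for (j in seq_len(ncol(X)))
    X[miss[, j], j] <- mean(X[, j], na.rm = TRUE)
  order_cols <- order(colSums(miss))
  order_cols <- order_cols[colSums(miss)[order_cols] > 0]
  final_change <- Inf
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    X_old <- X
    for (j in order_cols) {
      obs <- !miss[, j]
      fit <- randomForest::randomForest(
        x = X[obs, -j, drop = FALSE], y = X[obs, j], ntree = ntree)
      X[!obs, j] <- stats::predict(fit, X[!obs, -j, drop = FALSE])
    }
    final_change <- sum((X - X_old)^2) / max(sum(X^2), .Machine$double.eps)
    if (final_change < tol) break
  }
  attr(X, "iterations") <- iter
  attr(X, "final_change") <- final_change
  X
}

## Ledoit-Wolf-style shrinkage of a sample covariance toward a scaled
## identity; used when the classical covariance is (near) singular.
shrink_covariance <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - mu * diag(p))^2)
  b2 <- 0
  for (i in seq_len(n))
    b2 <- b2 + sum((tcrossprod(Xc[i, ]) - S)^2)
  b2 <- min(b2 / n^2, d2)
  lam <- if (d2 > 0) b2 / d2 else 0
  lam * mu * diag(p) + (1 - lam) * S
}

#' Multivariate outlier exclusion by Mahalanobis distance
#'
#' Squared Mahalanobis distance of each row from the column means under the
#' sample covariance; rows whose distance exceeds the chi-square quantile
#' (df = number of features) at `quantile` are excluded. Applied to each
#' sample (baseline, change) separately by the pipeline. The `"classical"`
#' estimator is the default; `"mcd"` uses the robust minimum covariance
#' determinant; `shrinkage = TRUE` engages a Ledoit-Wolf-style shrinkage
#' covariance for near-singular problems (p approaching n).
#'
#' @param block Numeric matrix (imaging features), rownames = subject IDs.
#' @param quantile Chi-square cut-off level in (0, 1); the conventional
#'   0.999 by default.
#' @param method `"classical"` or `"mcd"`.
#' @param shrinkage Use the shrinkage covariance (classical method only).
#' @return List with `kept`, `excluded` (subject IDs), `distances` (squared
#'   distances, named), and `cutoff`.
#' @export
mahalanobis_filter <- function(block, quantile = 0.999,
                               method = c("classical", "mcd"),
                               shrinkage = FALSE) {
  X <- as.matrix(block)
  method <- match.arg(method)
  if (quantile <= 0 || quantile >= 1)
    stop("'quantile' must be strictly between 0 and 1")
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (method == "mcd") {
    est <- MASS::cov.rob(X, method = "mcd")
    ctr <- est$center
    S <- est$cov
  } else {
    ctr <- colMeans(X)
    S <- if (shrinkage) shrink_covariance(X) else stats::cov(X)
  }
  if (!shrinkage && method == "classical" &&
      rcond_sym(S) < .Machine$double.eps * 100)
    stop("sample covariance is singular; retry with shrinkage = TRUE ",
         "or method = \"mcd\"")
  d2 <- stats::mahalanobis(X, ctr, S)
  names(d2) <- rownames(X)
  cutoff <- stats::qchisq(quantile, df = ncol(X))
  out <- d2 > cutoff
  list(kept = rownames(X)[!out], excluded = rownames(X)[out],
       distances = d2, cutoff = cutoff)
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Empirical-Bayes (ComBat) harmonization of site effects
#'
#' Location-scale batch adjustment per feature with parametric
#' empirical-Bayes shrinkage of the per-site shift and scale estimates
#' toward pooled priors, as implemented in `sva::ComBat`. Optionally
#' protects variance attributable to biological covariates supplied in
#' `preserve`. A single site is a no-op; constant features are passed
#' through unchanged with a warning.
#'
#' @param block Numeric matrix, subjects in rows.
#' @param sites Factor (or coercible) of site labels, one per subject,
#'   every site with at least 2 subjects.
#' @param preserve Optional data frame / matrix of covariates whose
#'   variance must not be removed.
#' @return Harmonized matrix of the same dimension.
#' @export
empirical_bayes_harmonize <- function(block, sites, preserve = NULL) {
  X <- as.matrix(block)
  sites <- droplevels(as.factor(sites))
  if (length(sites) != nrow(X))
    stop("'sites' must have one label per subject")
  if (nlevels(sites) < 2) return(X)
  tab <- table(sites)
  if (any(tab < 2))
    stop("site(s) with a single subject: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    warning("constant feature(s) passed through unharmonized: ",
            paste(colnames(X)[const], collapse = ", "))
  keep <- which(!const)
  if (length(keep) == 0) return(X)
  if (length(keep) < 2)
    stop("empirical-Bayes harmonization needs at least 2 varying features")
  mod <- NULL
  if (!is.null(preserve))
    mod <- stats::model.matrix(~ ., data = as.data.frame(preserve))
  adj <- suppressMessages(
    sva::ComBat(dat = t(X[, keep, drop = FALSE]), batch = sites,
                mod = mod, par.prior = TRUE, prior.plots = FALSE))
  X[, keep] <- t(adj)
  X
}

#' Column-wise z-scoring
#'
#' Standardizes every column to mean 0 and standard deviation 1 (sample SD,
#' denominator n - 1), the conditioning applied to both blocks before any
#' sparse CCA fit.
#'
#' @param block Numeric matrix with no missing entries.
#' @return Standardized matrix.
#' @export
standardize_block <- function(block) {
  X <- as.matrix(block)
  if (anyNA(X)) stop("missing entries: impute before standardizing")
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(if (is.null(colnames(X))) which(zero) else colnames(X)[zero],
               collapse = ", "))
  scale(X)[, , drop = FALSE]
}

#' Residualized longitudinal change scores
#'
#' Per variable, the raw change `follow - base` is residualized on the
#' baseline value by simple OLS with intercept, removing the
#' regression-to-the-mean coupling between change and starting level; the
#' residuals are exactly uncorrelated with baseline.
#'
#' @param baseline,followup Numeric matrices with identical, aligned subject
#'   rows (rownames) and variables (colnames).
#' @return Object of class `change_score_table`: `residuals` (matrix) and
#'   `coefficients` (per-variable intercept and slope on baseline).
#' @export
compute_change_scores <- function(baseline, followup) {
  B <- as.matrix(baseline)
  F_ <- as.matrix(followup)
  if (!identical(dim(B), dim(F_)))
    stop("baseline and followup dimensions differ")
  if (!is.null(rownames(B)) && !is.null(rownames(F_)) &&
      !identical(rownames(B), rownames(F_))) {
    bad <- union(setdiff(rownames(B), rownames(F_)),
                 setdiff(rownames(F_), rownames(B)))
    if (length(bad))
      stop("subject mismatch between baseline and follow-up: ",
           paste(bad, collapse = ", "))
    stop("subjects present in both tables but ordered differently; align rows")
  }
  D <- F_ - B
  res <- D
  coefs <- matrix(NA_real_, ncol(B), 2,
                  dimnames = list(colnames(B), c("intercept", "slope")))
  for (j in seq_len(ncol(B))) {
    fit <- stats::lm.fit(cbind(1, B[, j]), D[, j])
    res[, j] <- fit$residuals
    coefs[j, ] <- fit$coefficients
  }
  structure(list(residuals = res, coefficients = coefs),
            class = "change_score_table")
}

#' Remove covariate-explained variance from every column
#'
#' Replaces each column of `block` by its residuals from OLS on the
#' covariates (with intercept); used for age/sex sensitivity refits.
#'
#' @param block Numeric matrix.
#' @param covariates Numeric matrix or data frame, complete and row-aligned
#'   with `block`.
#' @return Residual matrix, orthogonal to every covariate.
#' @export
regress_out_covariates <- function(block, covariates) {
  X <- as.matrix(block)
  C <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(C) != nrow(X)) stop("covariates not aligned with block")
  if (anyNA(C)) stop("covariates must be complete")
  ## constant covariates are absorbed by the intercept, not rank errors
  keep <- c(TRUE, apply(C[, -1, drop = FALSE], 2, stats::sd) > 0)
  C <- C[, keep, drop = FALSE]
  qrC <- qr(C)
  if (qrC$rank < ncol(C))
    stop("rank-deficient covariate matrix")
  qr.resid(qrC, X)
}
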