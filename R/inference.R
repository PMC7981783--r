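#' Candidate sparsity grid
#'
#' Ten linearly spaced candidate penalties per block, from `1/sqrt(dim)`
#' (near-singleton support) to 1 (no active L1 bound), endpoints inclusive —
#' the standard search range for the PMD penalty parameterization.
#'
#' @param p,q Numbers of features in the two blocks (>= 2).
#' @return List of class `sparsity_grid` with `candidates_x`,
#'   `candidates_y` (each length 10, non-decreasing).
#' @export
build_grid <- function(p, q) {
  if (p < 2 || q < 2) stop("'p' and 'q' must be >= 2")
  structure(list(candidates_x = seq(1 / sqrt(p), 1, length.out = 10),
                 candidates_y = seq(1 / sqrt(q), 1, length.out = 10)),
            class = "sparsity_grid")
}

#' Select sparsity penalties by in-sample canonical correlation
#'
#' Fits the first mode at every combination of the candidate penalties and
#' returns the pair maximizing the fitted canonical correlation; an exact
#' tie is broken toward the smallest `(penalty_x, penalty_y)` in
#' lexicographic order (the sparser model). The in-sample criterion is
#' optimistic by construction; its optimism is controlled downstream by the
#' permutation test and the robustness battery rather than by
#' cross-validated tuning.
#'
#' @param X,Y Standardized blocks.
#' @param grid A `sparsity_grid` (default: [build_grid()] on the data
#'   dimensions).
#' @return List: `penalty_x`, `penalty_y`, `r` (selected-cell correlation),
#'   and `fit_table` (data frame of all grid cells with their r and
#'   convergence flag).
#' @export
tune_sparsity <- function(X, Y, grid = build_grid(ncol(X), ncol(Y))) {
  stopifnot(inherits(grid, "sparsity_grid"))
  cx <- grid$candidates_x
  cy <- grid$candidates_y
  cells <- expand.grid(penalty_x = cx, penalty_y = cy,
                       KEEP.OUT.ATTRS = FALSE)
  ## order so that the first strict maximum is the lexicographically
  ## smallest (penalty_x, penalty_y) among ties
  cells <- cells[order(cells$penalty_x, cells$penalty_y), ]
  r <- numeric(nrow(cells))
  conv <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    fit <- tryCatch(
      suppressWarnings(fit_first_mode(X, Y, cells$penalty_x[i],
                                      cells$penalty_y[i])),
      error = function(e) NULL)
    if (is.null(fit)) {
      r[i] <- NA_real_
      conv[i] <- FALSE
    } else {
      r[i] <- fit$r
      conv[i] <- fit$converged
    }
  }
  if (all(is.na(r))) stop("sparsity tuning failed in every grid cell")
  best <- which.max(r)          # first maximum = lexicographic tie-break
  list(penalty_x = cells$penalty_x[best],
       penalty_y = cells$penalty_y[best],
       r = r[best],
       fit_table = cbind(cells, r = r, converged = conv))
}

#' Permutation test of the first sparse canonical mode
#'
#' Refits the first mode `n_perm` times with the rows of `Y` permuted
#' uniformly at random (X fixed) at the same, pre-tuned penalties, and
#' returns the exact permutation P value: the number of permutations whose
#' canonical correlation equals or exceeds the observed one, divided by
#' `n_perm`. With `conservative = TRUE` the P value is
#' `(count + 1) / (n_perm + 1)`, which is strictly positive.
#'
#' @param X,Y Standardized blocks, n >= 3.
#' @param penalty_x,penalty_y Penalties fixed in advance (not re-tuned per
#'   permutation).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param conservative Use the add-one P value.
#' @return Object of class `permutation_result`: `observed_r`,
#'   `permuted_r` (length `n_perm`), `exact_p`, `mean_permuted`,
#'   `sd_permuted`.
#' @export
permutation_test <- function(X, Y, penalty_x, penalty_y,
                             n_perm = 1000L, seed = 1L,
                             conservative = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) < 3) stop("need at least 3 subjects for a permutation test")
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  obs <- suppressWarnings(fit_first_mode(X, Y, penalty_x, penalty_y))
  set.seed(seed)
  n <- nrow(X)
  c1 <- penalty_x * sqrt(ncol(X))
  c2 <- penalty_y * sqrt(ncol(Y))
  perm_r <- vapply(seq_len(n_perm), function(b) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    fit <- fit_mode_pmd(crossprod(X, Yp), c1, c2)
    vx <- drop(X %*% fit$u)
    vy <- drop(Yp %*% fit$v)
    if (stats::sd(vx) == 0 || stats::sd(vy) == 0) return(0)
    abs(stats::cor(vx, vy))
  }, numeric(1))
  count <- sum(perm_r >= obs$r)
  p <- if (conservative) (count + 1) / (n_perm + 1) else count / n_perm
  structure(list(observed_r = obs$r, permuted_r = perm_r, exact_p = p,
                 mean_permuted = mean(perm_r),
                 sd_permuted = stats::sd(perm_r),
                 n_perm = as.integer(n_perm),
                 conservative = conservative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed r = %.4f, exact P = %.4g (%d permutations)\n",
    x$observed_r, x$exact_p, x$n_perm))
  cat(sprintf("  mean (SD) permuted r = %.2f (%.2f)\n",
              x$mean_permuted, x$sd_permuted))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted P values across the family of
#' tested modes/models; adjusted values are monotone in the raw values and
#' capped at 1.
#'
#' @param p_values Numeric vector of raw P values in `[0, 1]`.
#' @return Adjusted P values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("P values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
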