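#' Soft-thresholding operator
#'
#' Elementwise lasso shrinkage `sign(v) * max(|v| - delta, 0)`. This is the
#' operator through which the sparsity penalty sets canonical weights exactly
#' to zero.
#'
#' @param v Numeric vector.
#' @param delta Non-negative threshold.
#' @return Numeric vector of the same length as `v`.
#' @examples
#' soft_threshold(c(3, -1, 0.5), 1)  # 2, 0, 0
#' @export
soft_threshold <- function(v, delta) {
  if (!is.numeric(v)) stop("'v' must be numeric")
  if (length(delta) != 1L || !is.finite(delta) || delta < 0)
    stop("'delta' must be a single non-negative number")
  sign(v) * pmax(abs(v) - delta, 0)
}

## Maximize a'u over {u : ||u||_2 <= 1, ||u||_1 <= c}: the solution is
## u(d) = S(a, d) / ||S(a, d)||_2 with d = 0 when the L1 bound is already
## slack, otherwise the exact threshold making the bound bind. The L1 norm
## of u(d) is piecewise smooth in d with breakpoints at the sorted |a_i|;
## within the interval where the top k entries stay active it satisfies a
## quadratic in d, which is solved in closed form (a short bisection is the
## fallback for degenerate intervals).
l1_unit_vector <- function(a, c1) {
  aa <- abs(a)
  n2 <- sqrt(sum(aa * aa))
  if (n2 == 0) return(a)
  if (sum(aa) / n2 <= c1 + 1e-12) return(a / n2)
  v <- sort.int(aa, decreasing = TRUE)
  p <- length(v)
  S1 <- cumsum(v)
  S2 <- cumsum(v * v)
  ks <- seq_len(p)
  vnext <- c(v[-1], 0)
  ## ratio at the left end (d = vnext[k]) of each active-set interval; it
  ## increases with k, so the bound binds in the first interval whose left
  ## end reaches c1
  num <- S1 - ks * vnext
  den2 <- S2 - 2 * vnext * S1 + ks * vnext * vnext
  gleft <- num / sqrt(pmax(den2, .Machine$double.xmin))
  k <- which(gleft >= c1)[1L]
  d <- NA_real_
  if (!is.na(k)) {
    ## (S1 - k d)^2 = c^2 (S2 - 2 d S1 + k d^2) on that interval
    c2 <- c1 * c1
    A <- k * (k - c2)
    B <- -2 * S1[k] * (k - c2)
    C <- S1[k]^2 - c2 * S2[k]
    roots <- if (abs(A) < 1e-12 * max(1, abs(B))) {
      if (B != 0) -C / B else numeric(0)
    } else {
      disc <- B * B - 4 * A * C
      if (disc < 0) numeric(0)
      else c(-B - sqrt(disc), -B + sqrt(disc)) / (2 * A)
    }
    lo <- vnext[k]
    hi <- v[k]
    for (r in roots) {
      if (r >= lo - 1e-9 && r <= hi + 1e-9) {
        cand <- min(max(r, lo), hi)
        s <- aa - cand        # validate: squaring can admit spurious roots
        s[s < 0] <- 0
        ns <- sqrt(sum(s * s))
        if (ns > 0 && abs(sum(s) / ns - c1) <= 1e-6 * max(1, c1)) {
          d <- cand
          break
        }
      }
    }
  }
  if (is.na(d)) d <- l1_threshold_bisect(aa, c1)
  s <- aa - d
  s[s < 0] <- 0
  s <- s * sign(a)
  s / sqrt(sum(s * s))
}

## Fallback threshold search (should be unreachable in regular operation).
l1_threshold_bisect <- function(aa, c1, tol = 1e-12, max_bisect = 200L) {
  lo <- 0
  hi <- max(aa)
  for (i in seq_len(max_bisect)) {
    mid <- (lo + hi) / 2
    s <- aa - mid
    s[s < 0] <- 0
    ns <- sqrt(sum(s * s))
    if (ns == 0) {
      hi <- mid
      next
    }
    if (sum(s) / ns > c1) lo <- mid else hi <- mid
    if (hi - lo <= tol) break
  }
  hi
}

## One PMD mode on a fixed cross-product matrix M = X'Y.
## maximize u' M v  s.t. ||u||2 <= 1, ||v||2 <= 1, ||u||1 <= c1, ||v||1 <= c2
fit_mode_pmd <- function(M, c1, c2, tol = 1e-6, max_iter = 1000L) {
  sv <- svd(M, nu = 0L, nv = 1L)
  v <- drop(sv$v)
  u <- rep(0, nrow(M))
  obj_prev <- -Inf
  ascent_ok <- TRUE
  converged <- FALSE
  iter <- 0L
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    u_new <- l1_unit_vector(drop(M %*% v), c1)
    b <- drop(crossprod(M, u_new))
    v_new <- l1_unit_vector(b, c2)
    obj <- sum(b * v_new)
    if (obj < obj_prev - 1e-8 * max(1, abs(obj_prev))) ascent_ok <- FALSE
    obj_prev <- obj
    delta <- max(abs(u_new - u), abs(v_new - v))
    u <- u_new
    v <- v_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(u = u, v = v, objective = obj_prev, iterations = iter,
       final_change = delta, converged = converged, ascent_ok = ascent_ok)
}

#' Fit the first sparse canonical mode
#'
#' Solves the penalized matrix decomposition (PMD) form of sparse CCA:
#' maximize \eqn{w_x' (X'Y) w_y} subject to \eqn{\|w_x\|_2 \le 1},
#' \eqn{\|w_y\|_2 \le 1}, \eqn{\|w_x\|_1 \le penalty_x \sqrt{p}} and
#' \eqn{\|w_y\|_1 \le penalty_y \sqrt{q}}, by alternating soft-thresholded
#' power iterations. Penalties live on \eqn{(1/\sqrt{dim}, 1]}: 1 leaves the
#' L1 bound slack (dense weights), values near \eqn{1/\sqrt{dim}} force a
#' near-singleton support. Inputs are expected column-standardized; under
#' that convention PMD treats the within-block covariance as diagonal, so the
#' fitted mode maximizes cross-block covariance, and the canonical
#' correlation is reported as the Pearson correlation of the two variates.
#'
#' @param X n x p numeric matrix (imaging block), columns standardized.
#' @param Y n x q numeric matrix (non-imaging block), columns standardized.
#' @param penalty_x,penalty_y Sparsity penalties in (0, 1].
#' @param tol Convergence tolerance on the max absolute weight change.
#' @param max_iter Maximum alternating iterations.
#' @return An object of class `scca_mode`: sparse weight vectors
#'   `weights_x`/`weights_y`, the canonical variates, canonical correlation
#'   `r` (reported non-negative; both weight vectors are flipped if the raw
#'   fit is negative), cross-loadings, `covariance_explained = r^2`, and
#'   convergence information.
#' @seealso [fit_scca()] for multiple modes, [tune_sparsity()] for picking
#'   the penalties, [cross_loadings()].
#' @export
fit_first_mode <- function(X, Y, penalty_x = 1, penalty_y = 1,
                           tol = 1e-6, max_iter = 1000L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in input blocks; impute and filter first")
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  check_penalty(penalty_x, "penalty_x")
  check_penalty(penalty_y, "penalty_y")
  M <- crossprod(X, Y)
  mode <- pmd_mode_to_scca(fit_mode_pmd(M, penalty_x * sqrt(ncol(X)),
                                        penalty_y * sqrt(ncol(Y)),
                                        tol = tol, max_iter = max_iter),
                           X, Y)
  if (!mode$converged)
    warning("sCCA alternating updates did not converge within max_iter; ",
            "best iterate returned")
  mode
}

check_penalty <- function(p, name) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("'", name, "' must be a single value in (0, 1]")
}

## Dress a raw PMD solution as an scca_mode: variates, sign convention,
## correlation, cross-loadings, covariance explained.
pmd_mode_to_scca <- function(fit, X, Y) {
  u <- fit$u
  v <- fit$v
  vx <- drop(X %*% u)
  vy <- drop(Y %*% v)
  r <- if (stats::sd(vx) == 0 || stats::sd(vy) == 0) 0 else stats::cor(vx, vy)
  if (is.na(r)) r <- 0
  if (r < 0) {          # sign convention: r >= 0, flip both weight vectors
    u <- -u
    v <- -v
    vx <- -vx
    vy <- -vy
    r <- -r
  }
  structure(list(
    weights_x = u, weights_y = v,
    variate_x = vx, variate_y = vy,
    r = r,
    cross_loadings_x = safe_cor(X, vy),
    cross_loadings_y = safe_cor(Y, vx),
    covariance_explained = r^2,
    objective = fit$objective,
    iterations = fit$iterations,
    final_change = fit$final_change,
    converged = fit$converged && fit$ascent_ok
  ), class = "scca_mode")
}

## Column-wise Pearson correlation with a variate; zero-variance columns or
## a degenerate variate give NA rather than an error at this level.
safe_cor <- function(mat, variate) {
  if (stats::sd(variate) == 0) return(rep(NA_real_, ncol(mat)))
  drop(suppressWarnings(stats::cor(mat, variate)))
}

#' Fit an ordered sequence of sparse canonical modes
#'
#' Repeats [fit_first_mode()] on deflated cross-product matrices. Deflation
#' is Hotelling deflation of \eqn{X'Y}: after a mode \eqn{(w_x, w_y)} with
#' objective \eqn{d = w_x' X'Y w_y}, the rank-one term \eqn{d\, w_x w_y'} is
#' subtracted before the next mode is fitted. Later modes are therefore
#' approximately (not exactly) uncorrelated with earlier ones.
#'
#' @inheritParams fit_first_mode
#' @param n_modes Number of modes, at most `min(p, q)`.
#' @return An object of class `scca_model` with elements `modes` (list of
#'   `scca_mode`), `penalties`, and `convergence` (per-mode iterations and
#'   final change).
#' @export
fit_scca <- function(X, Y, penalty_x = 1, penalty_y = 1, n_modes = 1L,
                     tol = 1e-6, max_iter = 1000L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (n_modes < 1L) stop("'n_modes' must be >= 1")
  if (n_modes > min(ncol(X), ncol(Y)))
    stop("'n_modes' exceeds min(p, q) = ", min(ncol(X), ncol(Y)))
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in input blocks; impute and filter first")
  check_penalty(penalty_x, "penalty_x")
  check_penalty(penalty_y, "penalty_y")
  M <- crossprod(X, Y)
  c1 <- penalty_x * sqrt(ncol(X))
  c2 <- penalty_y * sqrt(ncol(Y))
  modes <- vector("list", n_modes)
  for (k in seq_len(n_modes)) {
    fit <- fit_mode_pmd(M, c1, c2, tol = tol, max_iter = max_iter)
    modes[[k]] <- pmd_mode_to_scca(fit, X, Y)
    d <- drop(crossprod(fit$u, M %*% fit$v))
    M <- M - d * tcrossprod(fit$u, fit$v)
  }
  structure(list(
    modes = modes,
    penalties = c(penalty_x = penalty_x, penalty_y = penalty_y),
    convergence = data.frame(
      mode = seq_len(n_modes),
      iterations = vapply(modes, `[[`, integer(1), "iterations"),
      final_change = vapply(modes, `[[`, numeric(1), "final_change"),
      converged = vapply(modes, `[[`, logical(1), "converged")
    )
  ), class = "scca_model")
}

#' @export
print.scca_mode <- function(x, ...) {
  cat("Sparse canonical mode\n")
  cat(sprintf("  r = %.4f (covariance explained: %d%%)\n",
              x$r, round(100 * x$covariance_explained)))
  cat(sprintf("  nonzero weights: %d (X block), %d (Y block)\n",
              sum(x$weights_x != 0), sum(x$weights_y != 0)))
  cat(sprintf("  converged: %s in %d iterations\n",
              x$converged, x$iterations))
  invisible(x)
}

#' @export
print.scca_model <- function(x, ...) {
  cat(sprintf("Sparse CCA model: %d mode(s), penalties (%.3f, %.3f)\n",
              length(x$modes), x$penalties[1], x$penalties[2]))
  for (k in seq_along(x$modes))
    cat(sprintf("  mode %d: r = %.4f, support %d + %d\n", k, x$modes[[k]]$r,
                sum(x$modes[[k]]$weights_x != 0),
                sum(x$modes[[k]]$weights_y != 0)))
  invisible(x)
}

#' Canonical cross-loadings
#'
#' Pearson correlation of every original variable with the canonical variate
#' of the *opposite* block: each column of `X` against `variate_y` and each
#' column of `Y` against `variate_x`. Cross-loadings, unlike the sparse
#' weights, are defined for all variables and are the quantity the
#' robustness battery tracks.
#'
#' @param mode An `scca_mode` with populated variates.
#' @param X,Y The data blocks the mode was fitted on.
#' @return List with `cross_loadings_x` (length p) and `cross_loadings_y`
#'   (length q).
#' @export
cross_loadings <- function(mode, X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (stats::sd(mode$variate_x) == 0 || stats::sd(mode$variate_y) == 0)
    stop("zero-variance canonical variate; cross-loadings undefined")
  list(cross_loadings_x = safe_cor(X, mode$variate_y),
       cross_loadings_y = safe_cor(Y, mode$variate_x))
}

#' Proportion of covariance accounted for by a mode
#'
#' The squared canonical correlation, the quantity conventionally reported as
#' "the mode accounted for N% of the covariance" (the reporting layer rounds
#' `100 * r^2` to the nearest integer percent).
#'
#' @param r Canonical correlation, `|r| <= 1`.
#' @return `r^2`, a proportion in `[0, 1]`.
#' @examples
#' round(100 * covariance_explained(0.30))  # 9
#' round(100 * covariance_explained(0.62))  # 38
#' @export
covariance_explained <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop("'r' must be a correlation in [-1, 1]")
  r^2
}

#' Select variables of at least small effect
#'
#' Indices of loadings strictly exceeding the threshold in magnitude
#' (`|loading| > threshold`); the conventional small-effect cut-off of 0.1
#' is the default, and a loading of exactly 0.1 is excluded.
#'
#' @param loadings Numeric vector of (cross-)loadings.
#' @param threshold Non-negative magnitude cut-off.
#' @return Integer indices of the reported variables.
#' @export
filter_by_effect <- function(loadings, threshold = 0.1) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  which(abs(loadings) > threshold)
}

#' In-sample whitening of a data block
#'
#' Transforms a centered block so its sample covariance is the identity
#' (multiplication by the inverse Cholesky factor of the sample covariance).
#' PMD-style sparse CCA treats the within-block covariance as diagonal; on
#' whitened blocks the unpenalized fit coincides exactly with classical CCA,
#' which is itself invariant under within-block linear maps.
#'
#' @param X Numeric matrix with n > p and full column rank.
#' @return Whitened matrix of the same dimension.
#' @export
whiten_block <- function(X) {
  X <- as.matrix(X)
  X <- sweep(X, 2, colMeans(X))
  S <- stats::cov(X)
  R <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite; cannot whiten"))
  X %*% backsolve(R, diag(ncol(X)))
}
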