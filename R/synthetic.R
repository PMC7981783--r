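#' Specification for a synthetic two-block cohort
#'
#' Describes a cohort in which an imaging block (continuous morphometric
#' features) and a non-imaging block (mixed continuous/ordinal/binary
#' features) share `n_modes` latent sparse canonical modes. Each mode k has a
#' latent standard-normal score per subject, sparse unit weight vectors with
#' `support_x[k]` / `support_y[k]` nonzeros (supports disjoint across modes,
#' so the population canonical structure is exactly the planted one), and a
#' signal scale chosen in closed form so the population correlation of the
#' two true variates equals `target_r[k]`: with shared latent z and
#' independent Gaussian noise of sd \eqn{\sigma}, a variate \eqn{a z + e}
#' against \eqn{a z + e'} has correlation \eqn{a^2/(a^2+\sigma^2)}, so
#' \eqn{a = \sigma \sqrt{r/(1-r)}}.
#'
#' @param n_subjects,p_imaging,q_nonimaging Cohort and block dimensions.
#' @param n_modes Number of planted modes (0 gives pure independent noise).
#' @param support_x,support_y Per-mode nonzero counts (recycled to
#'   `n_modes`).
#' @param target_r Per-mode population canonical correlation, strictly
#'   decreasing across modes.
#' @param noise_sd Additive Gaussian noise sd for both blocks.
#' @param n_sites Number of acquisition sites (labels assigned uniformly).
#' @param site_shift_sd SD of per-site, per-feature additive offsets; the
#'   default gives clearly visible (> 0.2 SD) batch shifts.
#' @param site_scale_range Range of per-site multiplicative scales.
#' @param missing_rate MCAR missingness rate for the non-imaging block.
#' @param longitudinal If `TRUE`, a follow-up timepoint can be generated.
#' @param thinning_mean,thinning_sd Mean/sd (same units as the features) of
#'   the per-subject follow-up decrement applied to thickness-like columns;
#'   defaults emulate the ~0.12-0.13 mm global cortical thinning reported
#'   over a 5-year adolescent inter-scan interval.
#' @param n_ordinal,n_binary Number of non-imaging columns discretized by
#'   thresholding their latent Gaussian into 7 ordinal levels (coded 0-6) or
#'   2 levels (0/1); only columns outside every mode support are eligible.
#' @param seed Integer seed; identical specs give bit-identical cohorts.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects, p_imaging, q_nonimaging,
                           n_modes = 1L,
                           support_x = 5L, support_y = 5L,
                           target_r = 0.7,
                           noise_sd = 1,
                           n_sites = 1L,
                           site_shift_sd = 0.5,
                           site_scale_range = c(0.8, 1.25),
                           missing_rate = 0,
                           longitudinal = FALSE,
                           thinning_mean = -0.125, thinning_sd = 0.06,
                           n_ordinal = 0L, n_binary = 0L,
                           seed = 1L) {
  stopifnot(n_subjects >= 1, p_imaging >= 1, q_nonimaging >= 1,
            n_modes >= 0, n_sites >= 1, noise_sd >= 0)
  if (n_modes > min(p_imaging, q_nonimaging))
    stop("invalid spec: n_modes exceeds min(p_imaging, q_nonimaging)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid spec: missing_rate must be in [0, 1)")
  if (n_modes > 0) {
    support_x <- as.integer(rep_len(support_x, n_modes))
    support_y <- as.integer(rep_len(support_y, n_modes))
    target_r <- rep_len(target_r, n_modes)
    if (any(support_x < 1) || any(support_y < 1))
      stop("invalid spec: supports must be positive")
    if (sum(support_x) > p_imaging || sum(support_y) > q_nonimaging)
      stop("invalid spec: total support exceeds block dimension ",
           "(supports are disjoint across modes)")
    if (any(target_r < 0) || any(target_r > 1))
      stop("invalid spec: target_r must lie in [0, 1]")
    if (n_modes > 1 && any(diff(target_r) >= 0))
      stop("invalid spec: target_r must be strictly decreasing across modes")
    if (noise_sd > 0 && any(target_r >= 1))
      stop("invalid spec: target_r = 1 requires noise_sd = 0")
  } else {
    support_x <- integer(0)
    support_y <- integer(0)
    target_r <- numeric(0)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    p_imaging = as.integer(p_imaging),
    q_nonimaging = as.integer(q_nonimaging),
    n_modes = as.integer(n_modes),
    support_x = support_x, support_y = support_y,
    target_r = target_r, noise_sd = noise_sd,
    n_sites = as.integer(n_sites),
    site_shift_sd = site_shift_sd,
    site_scale_range = site_scale_range,
    missing_rate = missing_rate,
    longitudinal = isTRUE(longitudinal),
    thinning_mean = thinning_mean, thinning_sd = thinning_sd,
    n_ordinal = as.integer(n_ordinal), n_binary = as.integer(n_binary),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

## Sparse unit weight vectors with disjoint supports across modes, in the
## classic simulation design for sparse singular vectors: equal-magnitude
## entries with random signs (first entry positive for identifiability),
## unit L2 norm, exactly the requested nonzero count.
make_true_weights <- function(dim, supports) {
  K <- length(supports)
  W <- matrix(0, dim, K)
  offset <- 0L
  for (k in seq_len(K)) {
    idx <- offset + seq_len(supports[k])
    signs <- sample(c(-1, 1), supports[k], replace = TRUE)
    signs[1] <- 1
    W[idx, k] <- signs / sqrt(supports[k])
    offset <- offset + supports[k]
  }
  W
}

## Signal scale per mode from the closed-form variance ratio (see
## synthetic_spec); noiseless cohorts use scale 1 (correlation is 1 anyway).
signal_scale <- function(target_r, noise_sd) {
  if (noise_sd == 0) return(rep(1, length(target_r)))
  noise_sd * sqrt(target_r / (1 - target_r))
}

#' Generate a two-block cohort with known canonical structure
#'
#' Draws the latent factor model described in [synthetic_spec()]:
#' `X = Z A Wx' + Ex`, `Y = Z A Wy' + Ey` with shared latent scores `Z`,
#' disjoint sparse unit weights, closed-form signal scales and independent
#' Gaussian noise. Site labels and a per-subject quality score are attached
#' but site effects and missingness are *not* applied here (see
#' [inject_site_effects()], [inject_missingness()]).
#'
#' @param spec A `synthetic_spec`.
#' @return List with `data` (a `two_block_dataset`: matrices `X`, `Y`,
#'   `subject_id`, `sites` factor, `quality` numeric) and `truth` (a
#'   `ground_truth`: `true_weights_x`/`true_weights_y` matrices with one
#'   unit column per mode, `true_r`, and the spec).
#' @export
generate_linked_blocks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  p <- spec$p_imaging
  q <- spec$q_nonimaging
  K <- spec$n_modes
  Wx <- make_true_weights(p, spec$support_x)
  Wy <- make_true_weights(q, spec$support_y)
  a <- signal_scale(spec$target_r, spec$noise_sd)
  Z <- matrix(stats::rnorm(n * K), n, K)
  X <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  Y <- matrix(stats::rnorm(n * q, sd = spec$noise_sd), n, q)
  if (K > 0) {
    X <- X + Z %*% (t(Wx) * a)
    Y <- Y + Z %*% (t(Wy) * a)
  }
  Y <- discretize_columns(Y, Wy, spec$n_ordinal, spec$n_binary)
  subject_id <- sprintf("S%04d", seq_len(n))
  dimnames(X) <- list(subject_id, sprintf("img_%03d", seq_len(p)))
  dimnames(Y) <- list(subject_id, sprintf("nim_%03d", seq_len(q)))
  sites <- factor(sprintf("site%02d", sample.int(spec$n_sites, n, TRUE)),
                  levels = sprintf("site%02d", seq_len(spec$n_sites)))
  quality <- stats::rbeta(n, 9, 1)       # automated QC score in (0, 1]
  data <- structure(list(X = X, Y = Y, subject_id = subject_id,
                         sites = sites, quality = quality),
                    class = "two_block_dataset")
  truth <- structure(list(true_weights_x = Wx, true_weights_y = Wy,
                          true_r = spec$target_r, signal_scale = a,
                          site_params = NULL, missing_mask = NULL,
                          spec = spec),
                     class = "ground_truth")
  list(data = data, truth = truth)
}

## Threshold latent-Gaussian columns (outside every mode support) into
## ordinal (7 levels, 0-6, with population probabilities decaying like the
## substance-use frequency items) or binary (median-split 0/1) codes.
discretize_columns <- function(Y, Wy, n_ordinal, n_binary) {
  if (n_ordinal + n_binary == 0) return(Y)
  free <- which(rowSums(abs(Wy)) == 0)
  if (length(free) < n_ordinal + n_binary)
    stop("not enough non-support columns to discretize; reduce n_ordinal/",
         "n_binary or increase q_nonimaging")
  ord_cols <- free[seq_len(n_ordinal)]
  bin_cols <- free[n_ordinal + seq_len(n_binary)]
  probs <- c(0.55, 0.18, 0.1, 0.07, 0.05, 0.03, 0.02)
  cuts <- stats::qnorm(cumsum(probs)[-7])
  for (j in ord_cols) {
    z <- scale(Y[, j])
    Y[, j] <- findInterval(z, cuts)
  }
  for (j in bin_cols) Y[, j] <- as.numeric(Y[, j] > stats::median(Y[, j]))
  Y
}

#' Apply additive and multiplicative site effects to the imaging block
#'
#' Each site s gets, per imaging feature j, an additive offset
#' `shift[s, j] ~ N(0, site_shift_sd^2)` and a multiplicative scale
#' `scale[s, j] ~ U(site_scale_range)`; imaging rows become
#' `X * scale + shift` by site. Only the imaging block is perturbed; the
#' non-imaging block is untouched, mirroring pipelines that harmonize
#' imaging features only. Parameters are recorded in the ground truth.
#'
#' @param data A `two_block_dataset` with site labels.
#' @param truth The matching `ground_truth` (supplies the spec's site-effect
#'   magnitudes and seed).
#' @return List with the perturbed `data` and the updated `truth` (element
#'   `site_params`: per-site shift and scale matrices).
#' @export
inject_site_effects <- function(data, truth) {
  stopifnot(inherits(data, "two_block_dataset"),
            inherits(truth, "ground_truth"))
  spec <- truth$spec
  if (any(is.na(data$sites)) ||
      !all(data$sites %in% levels(data$sites)))
    stop("unknown or missing site label")
  set.seed(spec$seed + 1L)
  p <- ncol(data$X)
  S <- nlevels(data$sites)
  shift <- matrix(stats::rnorm(S * p, sd = spec$site_shift_sd), S, p,
                  dimnames = list(levels(data$sites), colnames(data$X)))
  scl <- matrix(stats::runif(S * p, min(spec$site_scale_range),
                             max(spec$site_scale_range)), S, p,
                dimnames = dimnames(shift))
  idx <- as.integer(data$sites)
  data$X <- data$X * scl[idx, , drop = FALSE] + shift[idx, , drop = FALSE]
  truth$site_params <- list(shift = shift, scale = scl)
  list(data = data, truth = truth)
}

#' Inject missing-completely-at-random entries into the non-imaging block
#'
#' Sets entries of `Y` to `NA` independently at the given rate; the imaging
#' block is never touched (only non-imaging features are imputed
#' downstream). The realized mask is recorded on the dataset.
#'
#' @param data A `two_block_dataset`.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The dataset with `Y` containing `NA`s and element `missing_mask`
#'   (logical matrix) recorded.
#' @export
inject_missingness <- function(data, rate, seed) {
  stopifnot(inherits(data, "two_block_dataset"))
  if (rate < 0 || rate >= 1) stop("'rate' must be in [0, 1)")
  set.seed(seed)
  mask <- matrix(stats::runif(length(data$Y)) < rate,
                 nrow(data$Y), ncol(data$Y), dimnames = dimnames(data$Y))
  data$Y[mask] <- NA_real_
  data$missing_mask <- mask
  data
}

#' Generate an aligned baseline / follow-up cohort pair
#'
#' The baseline cohort comes from [generate_linked_blocks()]. The follow-up
#' adds (i) a per-subject, per-feature decrement
#' `N(thinning_mean, thinning_sd)` to the thickness-like imaging columns
#' (all imaging columns by default), emulating cortical thinning over the
#' inter-scan interval, and (ii) a fresh draw of the linked-mode model
#' (new latent scores and noise, same true weights and scales) so that the
#' change scores carry the same planted canonical structure. With zero
#' modes the change component vanishes and follow-up differs from baseline
#' only by the thinning term.
#'
#' @param spec A `synthetic_spec` with `longitudinal = TRUE`.
#' @param thickness_cols Indices of imaging columns receiving the thinning
#'   decrement (default: all).
#' @return List with `baseline` and `followup` (`two_block_dataset`s with
#'   identical subject ordering) and `truth`.
#' @export
generate_longitudinal_pair <- function(spec,
                                       thickness_cols = seq_len(spec$p_imaging)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!spec$longitudinal)
    stop("spec must have longitudinal = TRUE")
  gen <- generate_linked_blocks(spec)
  base <- gen$data
  truth <- gen$truth
  set.seed(spec$seed + 2L)
  n <- spec$n_subjects
  K <- spec$n_modes
  dX <- matrix(0, n, spec$p_imaging)
  dY <- matrix(0, n, spec$q_nonimaging)
  if (K > 0) {
    Z2 <- matrix(stats::rnorm(n * K), n, K)
    dX <- Z2 %*% (t(truth$true_weights_x) * truth$signal_scale) +
      matrix(stats::rnorm(n * spec$p_imaging, sd = spec$noise_sd), n)
    dY <- Z2 %*% (t(truth$true_weights_y) * truth$signal_scale) +
      matrix(stats::rnorm(n * spec$q_nonimaging, sd = spec$noise_sd), n)
  }
  thin <- matrix(0, n, spec$p_imaging)
  if (length(thickness_cols) && (spec$thinning_mean != 0 || spec$thinning_sd != 0))
    thin[, thickness_cols] <- stats::rnorm(n * length(thickness_cols),
                                           mean = spec$thinning_mean,
                                           sd = spec$thinning_sd)
  follow <- base
  follow$X <- base$X + dX + thin
  follow$Y <- base$Y + dY
  list(baseline = base, followup = follow, truth = truth)
}

#' Recovery score of an estimated weight vector against the truth
#'
#' `cosine` is the absolute cosine similarity (sign-invariant, since a
#' canonical mode is defined up to a joint sign flip); `support_f1` is the
#' F1 score of the estimated nonzero pattern against the true one.
#'
#' @param estimated,truth Numeric vectors of equal length; neither all-zero.
#' @return Named numeric vector `c(cosine = , support_f1 = )`.
#' @export
weight_recovery_score <- function(estimated, truth) {
  if (length(estimated) != length(truth))
    stop("'estimated' and 'truth' must have equal length")
  ne <- sqrt(sum(estimated^2))
  nt <- sqrt(sum(truth^2))
  if (ne == 0 || nt == 0) stop("zero vector: recovery score undefined")
  cosine <- abs(sum(estimated * truth)) / (ne * nt)
  est_set <- estimated != 0
  true_set <- truth != 0
  tp <- sum(est_set & true_set)
  f1 <- if (tp == 0) 0 else 2 * tp / (sum(est_set) + sum(true_set))
  c(cosine = cosine, support_f1 = f1)
}

#' @export
print.two_block_dataset <- function(x, ...) {
  cat(sprintf("Two-block dataset: %d subjects, %d imaging + %d non-imaging features, %d site(s)\n",
              nrow(x$X), ncol(x$X), ncol(x$Y), nlevels(x$sites)))
  if (!is.null(x$missing_mask))
    cat(sprintf("  missing non-imaging entries: %d (%.1f%%)\n",
                sum(x$missing_mask), 100 * mean(x$missing_mask)))
  invisible(x)
}
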