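# Standardized two-block cohorts used across the test files.

make_cohort <- function(n = 400, p = 20, q = 20, n_modes = 1,
                        support = 5, target_r = 0.7, seed = 1, ...) {
  spec <- synthetic_spec(n_subjects = n, p_imaging = p, q_nonimaging = q,
                         n_modes = n_modes, support_x = support,
                         support_y = support, target_r = target_r,
                         seed = seed, ...)
  gen <- generate_linked_blocks(spec)
  gen$X <- standardize_block(gen$data$X)
  gen$Y <- standardize_block(gen$data$Y)
  gen
}

# First canonical correlation of classical CCA, the independent oracle for
# the unpenalized sparse fit on whitened blocks.
classical_cca_r <- function(X, Y) {
  stats::cancor(X, Y)$cor[1]
}
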