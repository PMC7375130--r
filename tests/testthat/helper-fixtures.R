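# Small cohort/spec constructors shared across tests. All fixtures are
# generated in code under fixed seeds.

small_spec <- function(n = 150, m = 120, ..., seed = 101) {
  synth_spec(n_subjects = n, n_voxels = m, n_signal_components = 5,
             demand_levels = c(hi = 0.9, lo = 0.1), ..., seed = seed)
}

small_cohort <- function(spec = small_spec()) generate_cohort(spec)

# Simulate raw battery scores directly from a bifactor truth (no covariate
# or family machinery) for factor-recovery tests.
simulate_bifactor_scores <- function(n, lambda_g = rep(0.7, 10),
                                     lambda_f = default_group_loadings(0.4),
                                     seed = 1) {
  set.seed(seed)
  g <- rnorm(n)
  fgrp <- matrix(rnorm(n * ncol(lambda_f)), n)
  uniq <- sqrt(pmax(0, 1 - lambda_g^2 - rowSums(lambda_f^2)))
  scores <- outer(g, lambda_g) + fgrp %*% t(lambda_f) +
    sweep(matrix(rnorm(n * 10), n, 10), 2, uniq, `*`)
  colnames(scores) <- battery_tests()
  list(scores = scores, g = g)
}

# Random family table (subject_id, family_id) without the full generator.
random_family_table <- function(n_families, max_size = 5) {
  sizes <- sample.int(max_size, n_families, replace = TRUE)
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(sum(sizes))),
    family_id = rep(sprintf("F%03d", seq_len(n_families)), sizes))
}
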