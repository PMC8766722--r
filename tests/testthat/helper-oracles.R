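# Independent oracles and small fixture builders used across the suite.

# Mann-Whitney AUC: U / (n1 * n0) from midranks. Independent of the
# threshold-sweep implementation in the package.
auc_rank_oracle <- function(truth, scores) {
  r <- rank(scores)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Brute-force two-stage correlation pruning, written directly from the two
# rules: (1) drop |r| > r_top vs the first-ranked feature; (2) scan the
# surviving list from the second entry on, each survivor dropping any later
# survivor with |r| > r_pairwise. Keep-list construction, no shared code
# with the package implementation.
prune_bruteforce <- function(cm, ranked, r_top, r_pairwise) {
  keep <- ranked[1]
  for (f in ranked[-1]) {
    if (abs(cm[ranked[1], f]) <= r_top) keep <- c(keep, f)
  }
  i <- 2
  while (i <= length(keep)) {
    anchor <- keep[i]
    new_keep <- keep[seq_len(i)]
    for (f in keep[-seq_len(i)]) {
      if (abs(cm[anchor, f]) <= r_pairwise) new_keep <- c(new_keep, f)
    }
    keep <- new_keep
    i <- i + 1
  }
  keep
}

# Small single-modality table with planted signal in the first columns.
make_table <- function(n_per_group = 10, p = 6, n_inf = 0, d = 0, seed = 1,
                       modality = "toy") {
  cfg <- cohort_config(n_per_group, list(
    modality_spec(modality, p, n_informative = n_inf, effect_size = d)
  ), seed = seed)
  generate_multimodal_cohort(cfg)$tables[[modality]]
}

# Two-modality cohort with a tunable shared latent factor.
make_two_modality <- function(n_per_group = 20, p = 5, d = 1.5,
                              loading = 0, seed = 1) {
  cohort_config(n_per_group, list(
    modality_spec("m1", p, n_informative = p, effect_size = d,
                  latent_loading = loading),
    modality_spec("m2", p, n_informative = p, effect_size = d,
                  latent_loading = loading)
  ), seed = seed)
}
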