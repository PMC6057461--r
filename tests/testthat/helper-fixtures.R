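# Shared fixtures: small synthetic studies with known ground truth.

default_design <- function() study_design()

# tiny noise-free study: deterministic arm means, no missingness
noiseless_sim <- function(n_genes = 20L, frac_up = 0.05, frac_down = 0,
                          seed = 1L) {
  generate_expression_study(
    default_design(),
    sim_config(n_genes = n_genes, frac_up_gradual = frac_up,
               frac_down_gradual = frac_down, low_intensity_frac = 0,
               noise_log2_sd = 0, missing_rate = 0, effect_step = 2,
               seed = seed))
}

# desk-scale study under the default noise conditions
default_sim <- function(seed = 11L) {
  generate_expression_study(default_design(),
                            sim_config(n_genes = 2000L, seed = seed))
}

# per-arm mean of a gene's intensities (NA-aware), for oracles
arm_means_of <- function(study, gene) {
  c(tapply(study$intensities[gene, ], study$arms, mean, na.rm = TRUE))
}

# labels fixture with a fixed number of up-regulated genes, no simulation
label_fixture <- function(n_genes = 500L, n_up = 50L) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  labels <- rep("null", n_genes)
  labels[seq_len(n_up)] <- "up_gradual"
  stats::setNames(labels, genes)
}

# exhaustive hypergeometric oracle: P[overlap >= k] by enumerating all
# C(N, n) selections of a universe of size N against a set of size K
hyper_upper_tail_enum <- function(N, K, n, k) {
  stopifnot(N <= 12)
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)  # WLOG the set is the first K elements
  hits <- apply(draws, 2L, function(d) sum(d %in% in_set) >= k)
  mean(hits)
}
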