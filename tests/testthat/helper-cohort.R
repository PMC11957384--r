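# Small cohort factories used across tests. All cohorts are generated in
# code at test time; nothing is read from disk.

three_modality_config <- function(seed = 1, effect = 1.5,
                                  n = c(PD = 30, PL = 25, HC = 20),
                                  tp = 2, miss = 0.15, dropout = 0) {
  cohort_config(
    n_per_class = n,
    n_timepoints = tp,
    modalities = list(
      modality_spec("mrna", "nb_counts", 120, 20, rep(effect, tp),
                    missing_rate = miss),
      modality_spec("snp", "genotype_pc", 40, 15, rep(effect, tp),
                    missing_rate = miss),
      modality_spec("clinical", "clinical", 6, 2, rep(0.3 * effect, tp),
                    missing_rate = miss / 2)),
    dropout_rate = dropout,
    seed = seed)
}

small_cohort <- function(seed = 1, ...) {
  apply_missingness(generate_cohort(three_modality_config(seed = seed, ...)))
}

random_affinity <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(sprintf("P%02d", seq_len(n)), sprintf("P%02d", seq_len(n)))
  W
}

block_affinity <- function(n_per_block = 6, within = 0.9, between = 0.1,
                           seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_block
  W <- matrix(between, n, n) + matrix(stats::runif(n * n, 0, 0.02), n, n)
  W <- (W + t(W)) / 2
  blk <- rep(c(TRUE, FALSE), each = n_per_block)
  W[blk, blk] <- within
  W[!blk, !blk] <- within
  diag(W) <- 1
  dimnames(W) <- list(sprintf("P%02d", seq_len(n)), sprintf("P%02d", seq_len(n)))
  W
}
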