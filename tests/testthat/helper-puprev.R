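# Desk-scale configs used across tests. The stated-world defaults (n = 20,000,
# d = 500) live in synthetic_config(); these are smaller variants for unit
# tests that only need structure, not statistical power.
tiny_config <- function(seed = 1L, ...) {
  synthetic_config(n_records = 1500, n_covariates = 80, n_informative = 16,
                   seed = seed, ...)
}

small_config <- function(seed = 1L, ...) {
  synthetic_config(n_records = 6000, n_covariates = 200, n_informative = 40,
                   seed = seed, ...)
}

snar_config <- function(seed = 1L, n_records = 6000, n_covariates = 200, ...) {
  synthetic_config(n_records = n_records, n_covariates = n_covariates,
                   n_informative = 40, n_subtypes = 2,
                   label_propensities = c(0.9, 0.05), seed = seed, ...)
}

fast_cc <- classifier_config()

# Fraction of unlabeled records that are latent positives (generator truth).
true_unlabeled_alpha <- function(cohort) {
  sum(cohort$latent_status == 1L & cohort$labels == 0L) / sum(cohort$labels == 0L)
}

# Rand index between two partitions (pair-counting agreement).
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    ai <- a[i] == a[(i + 1):n]
    bi <- b[i] == b[(i + 1):n]
    agree <- agree + sum(ai == bi)
  }
  agree / choose(n, 2)
}

# A synthetic score_set without fitting a classifier.
make_score_set <- function(scores_P, scores_U) {
  structure(list(scores_P = scores_P, scores_U = scores_U,
                 fold_map = NULL), class = "score_set")
}
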