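# Shared fixture builders. Everything is generated in code; no data files.

# random positive-definite covariance via a Wishart-style construction
rand_pd <- function(n, seed = 1, df_extra = 5) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + df_extra)), n + df_extra, n)
  crossprod(A) / (n + df_extra)
}

# n labels over exactly K = min(K, n) systems, each system non-empty
rand_labels <- function(n, K, seed = 1) {
  K <- min(K, n)
  set.seed(seed)
  pool <- paste0("s", seq_len(K))
  sample(c(pool, sample(pool, n - K, replace = TRUE)))
}

# independent oracle for Gaussian entropy: eigenvalue log-sum
entropy_oracle <- function(cov) {
  0.5 * sum(log(eigen((cov + t(cov)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values))
}

# oracle for integration over a partition, built only from entropy_oracle
integration_oracle <- function(cov, labels = NULL) {
  if (is.null(labels)) labels <- as.character(seq_len(nrow(cov)))
  blocks <- split(seq_along(labels), labels)
  sum(vapply(blocks, function(idx)
    entropy_oracle(cov[idx, idx, drop = FALSE]), numeric(1))) -
    entropy_oracle(cov)
}

# a small two-level-by-two hierarchy: K7 networks x K17 subnetworks each,
# m parcels per subnetwork
toy_hp <- function(K7 = 2, K17 = 2, m = 5) {
  n <- K7 * K17 * m
  level7 <- rep(LETTERS[seq_len(K7)], each = K17 * m)
  level17 <- rep(paste0(rep(LETTERS[seq_len(K7)], each = K17),
                        rep(seq_len(K17), K7)), each = m)
  hierarchical_partition(paste0("p", seq_len(n)), level7, level17)
}

# partition-equality up to label renaming
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
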