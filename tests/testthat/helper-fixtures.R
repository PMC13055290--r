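# Small in-code fixtures shared across test files.

# A tiny deterministic count table: 4 samples x 5 ASVs.
tiny_counts <- function() {
  m <- matrix(c(
    10, 0, 5, 1, 4,
    8, 2, 0, 1, 9,
    0, 6, 5, 1, 8,
    3, 3, 3, 1, 10
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("S", 1:4), paste0("ASV", 1:5)))
  tibble::as_tibble(m, rownames = "sample_id")
}

random_counts <- function(n_samples, n_asvs, lambda = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, lambda), n_samples, n_asvs,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              paste0("A", seq_len(n_asvs))))
  m[rowSums(m) == 0, 1] <- 1
  m
}

# Brute-force Bray-Curtis for the oracle comparisons.
bc_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- 1 - 2 * sum(pmin(m[i, ], m[j, ])) / (sum(m[i, ]) + sum(m[j, ]))
  }
  d
}

# Exhaustive Newman modularity over all partitions of <= 9 nodes.
modularity_oracle <- function(g) {
  n <- igraph::vcount(g)
  part <- rep(1L, n)
  best <- -Inf
  recurse <- function(i, k) {
    if (i > n) {
      q <- igraph::modularity(g, part)
      if (q > best) best <<- q
      return(invisible())
    }
    for (grp in seq_len(k + 1)) {
      part[i] <<- grp
      recurse(i + 1, max(k, grp))
    }
  }
  recurse(2L, 1L)
  best
}
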