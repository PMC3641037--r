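# Small deterministic fixtures shared across test files.

# Square labelled matrix from a vector of upper-triangle values (row-wise).
dist_from_upper <- function(v, n, labels = paste0("i", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  # fill by (i, j) in row-major pair order
  k <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) { m[i, j] <- v[k]; k <- k + 1 }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

random_marker_matrix <- function(n, L, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * L, 1L, runif(L, 0.2, 0.8)[rep(seq_len(L), each = n)]),
                n, L)
    dimnames(m) <- list(sprintf("i%02d", seq_len(n)), sprintf("l%03d", seq_len(L)))
    m
  })
}

# Two-cluster marker data with cluster band frequencies 0.9 / 0.1.
two_cluster_markers <- function(n_per = 20, L = 100, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rbinom(n_per * L, 1, 0.9), n_per),
               matrix(rbinom(n_per * L, 1, 0.1), n_per))
    dimnames(x) <- list(sprintf("i%02d", seq_len(2 * n_per)),
                        sprintf("l%03d", seq_len(L)))
    x
  })
}

# Tiny coding alignment: ingroup of near-identical sequences + outgroup.
toy_alignment <- function() {
  s <- c(
    in1 = "ATGGCTGCTAAAGCTGGT",
    in2 = "ATGGCTGCTAAAGCTGGT",
    in3 = "ATGGCTGCAAAAGCTGGT", # syn change at codon 3 (GCT->GCA is pos 9)
    out = "ATGGCAGCTAAAGCTGGC"
  )
  m <- do.call(rbind, strsplit(s, ""))
  rownames(m) <- names(s)
  coding_alignment(m, outgroups = "out")
}
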