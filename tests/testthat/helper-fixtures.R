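# shared fixtures and independent oracles

# small simulated dataset; memoised per (n, seed) within a test run
sim_cache <- new.env(parent = emptyenv())
small_sim <- function(n = 300, seed = 5, ...) {
  key <- paste(n, seed, length(list(...)), sep = "_")
  if (is.null(sim_cache[[key]]))
    sim_cache[[key]] <- simulate_atlas(synthetic_spec(n_genes = n, seed = seed, ...))
  sim_cache[[key]]
}

# eight-archetype (no flat background) conditions for recovery checks
eight_archetype_weights <- function() {
  stats::setNames(c(rep(0.125, 8), 0), ARCHETYPES)
}

# unigene-level named sequence vector from a simulation
sim_gene_seqs <- function(sim) {
  first <- sim$records[sim$records$isoform_id == "i1", ]
  stats::setNames(first$sequence, first$gene_id)
}

# brute-force Gotoh local-alignment score (BLOSUM62, gap of length g costs
# open + g * ext), independent of the Biostrings-backed implementation
sw_oracle_score <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (consume B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B (consume A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + BLOSUM62[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# hypergeometric upper tail by direct pmf enumeration (base-R dhyper)
tail_oracle <- function(N, K, n, k) {
  kmax <- min(n, K)
  if (k > kmax) stop("invalid k")
  sum(stats::dhyper(k:kmax, K, N - K, n))
}

random_aa <- function(n, len, seed) {
  set.seed(seed)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(aa, len, replace = TRUE), collapse = ""), character(1)),
    paste0("s", seq_len(n)))
}
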