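# internal helpers shared across modules

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the 20 standard amino acids with approximate background frequencies
# (Robinson & Robinson-style composition, renormalized)
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
AA_BACKGROUND <- c(0.078, 0.051, 0.045, 0.054, 0.019, 0.043, 0.063, 0.074,
                   0.022, 0.051, 0.091, 0.057, 0.022, 0.039, 0.052, 0.071,
                   0.058, 0.013, 0.032, 0.065)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)
names(AA_BACKGROUND) <- AA_ALPHABET

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic local RNG scope: runs `expr` under `seed` and restores
# the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = AA_BACKGROUND),
        collapse = "")
}
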