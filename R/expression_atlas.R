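# Per-compartment expression quantities: replicate means, presence calls,
# compartment-overlap partitions, Top-N groups, PCA, per-gene one-way ANOVA.

# tissue label of a "tissue_replicate" column name
column_tissue <- function(cols) sub("_[0-9]+$", "", cols)

#' Average TPM across biological replicates
#'
#' @param matrix genes x (tissue_replicate) numeric matrix, columns named
#'   like `M1_1`.
#' @param tissues tissues expected present; a missing tissue column set is a
#'   hard error.
#' @return genes x tissue matrix of arithmetic means.
#' @export
average_replicates <- function(matrix, tissues = MIDGUT_TISSUES) {
  tis <- column_tissue(colnames(matrix))
  missing <- setdiff(tissues, tis)
  if (length(missing))
    stopf("expression matrix lacks columns for tissue(s): %s",
          paste(missing, collapse = ", "))
  out <- vapply(tissues, function(t)
    rowMeans(matrix[, tis == t, drop = FALSE]), numeric(nrow(matrix)))
  rownames(out) <- rownames(matrix)
  out
}

#' Call per-tissue presence from mean TPM
#'
#' A gene is present in a tissue iff its mean TPM is strictly greater than
#' `tpm_min` (default 1; a mean of exactly 1 TPM is absent). Genes absent
#' everywhere keep an all-FALSE row.
#'
#' @param mean_table genes x tissue mean-TPM matrix.
#' @param tpm_min presence threshold (strict `>`).
#' @return logical matrix of the same shape, with attribute `threshold`.
#' @export
presence_calls <- function(mean_table, tpm_min = 1) {
  structure(mean_table > tpm_min, threshold = tpm_min)
}

#' Count genes in every compartment-overlap pattern
#'
#' Partitions the genes present in at least one of the named tissues into the
#' 15 non-empty presence patterns (the cells of a 4-set Venn diagram).
#'
#' @param presence logical presence matrix.
#' @param tissues tissues defining the partition (default M1-M4).
#' @return named integer vector over all non-empty patterns (names like
#'   `"M1"`, `"M1&M3"`, `"M1&M2&M3&M4"`); sums to the number of genes present
#'   somewhere.
#' @export
overlap_partition <- function(presence, tissues = c("M1", "M2", "M3", "M4")) {
  unknown <- setdiff(tissues, colnames(presence))
  if (length(unknown))
    stopf("unknown tissue name(s): %s", paste(unknown, collapse = ", "))
  p <- presence[, tissues, drop = FALSE]
  k <- length(tissues)
  patterns <- lapply(seq_len(2^k - 1), function(code) {
    tissues[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
  })
  names(patterns) <- vapply(patterns, paste, character(1), collapse = "&")
  gene_pattern <- apply(p, 1, function(row) paste(tissues[row], collapse = "&"))
  counts <- table(factor(gene_pattern[gene_pattern != ""],
                         levels = names(patterns)))
  out <- as.integer(counts)
  names(out) <- names(patterns)
  out
}

#' Select the N most highly expressed genes of a tissue
#'
#' Ranks genes by mean TPM in `tissue` (descending); ties spanning rank `n`
#' are resolved in favor of lexicographically smaller gene IDs, which makes
#' the group at `n` a subset of the group at `n + 1`.
#'
#' @param mean_table genes x tissue mean-TPM matrix.
#' @param tissue tissue name.
#' @param n group size (default 500); must not exceed the gene count.
#' @return character vector of `n` gene IDs.
#' @export
top_n <- function(mean_table, tissue, n = 500) {
  if (!tissue %in% colnames(mean_table)) stopf("unknown tissue '%s'", tissue)
  if (n > nrow(mean_table))
    stopf("n = %d exceeds gene count %d", n, nrow(mean_table))
  v <- mean_table[, tissue]
  ord <- order(-v, rownames(mean_table))
  rownames(mean_table)[ord][seq_len(n)]
}

#' PCA summary of the replicate samples
#'
#' Samples are the (tissue, replicate) columns; genes are the variables,
#' centered and scaled to unit variance (zero-variance genes are dropped
#' first).
#'
#' @param matrix genes x (tissue_replicate) matrix.
#' @return list with `scores` (samples x PC), `explained` (non-increasing
#'   fractions of variance), `dropped` (zero-variance genes).
#' @export
pca_summary <- function(matrix) {
  if (ncol(matrix) < 2) stopf("PCA needs at least 2 samples")
  v <- apply(matrix, 1, stats::var)
  dropped <- rownames(matrix)[v == 0 | is.na(v)]
  m <- matrix[v > 0 & !is.na(v), , drop = FALSE]
  pc <- stats::prcomp(t(m), center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl, dropped = dropped)
}

#' Per-gene one-way ANOVA across gut regions
#'
#' Tests, for each gene, whether mean expression differs between the midgut
#' compartments, on log2(TPM + 1) replicate values, with the standard
#' between/within sum-of-squares decomposition. Genes whose replicate values
#' are all identical (zero between- and within-group variance) report F = 0,
#' p = 1; nonzero between-group with zero within-group variance reports
#' F = Inf, p = 0. Benjamini-Hochberg adjusted p-values are added across the
#' tested genes.
#'
#' @param matrix genes x (tissue_replicate) matrix of TPM.
#' @param gene_subset optional gene IDs to test (default: all rows).
#' @param tissues groups to compare (default M1-M4); at least 2.
#' @param log_transform apply log2(TPM + 1) first (default TRUE).
#' @param alpha BH significance level for the `significant` flag.
#' @return data.frame with gene_id, F, df1, df2, p, fdr, significant.
#' @export
anova_by_region <- function(matrix, gene_subset = NULL,
                            tissues = c("M1", "M2", "M3", "M4"),
                            log_transform = TRUE, alpha = 0.05) {
  if (length(tissues) < 2) stopf("ANOVA needs at least 2 groups")
  tis <- column_tissue(colnames(matrix))
  keep_col <- tis %in% tissues
  if (!is.null(gene_subset)) matrix <- matrix[gene_subset, , drop = FALSE]
  x <- matrix[, keep_col, drop = FALSE]
  g <- factor(tis[keep_col], levels = tissues)
  reps <- table(g)
  if (any(reps < 2)) stopf("ANOVA needs >= 2 replicates per tissue")
  if (log_transform) x <- log2(x + 1)

  n_tot <- ncol(x)
  k <- length(tissues)
  grand <- rowMeans(x)
  ss_between <- numeric(nrow(x))
  ss_within <- numeric(nrow(x))
  for (t in tissues) {
    xt <- x[, g == t, drop = FALSE]
    mt <- rowMeans(xt)
    ss_between <- ss_between + ncol(xt) * (mt - grand)^2
    ss_within <- ss_within + rowSums((xt - mt)^2)
  }
  df1 <- k - 1
  df2 <- n_tot - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  zero_both <- ss_between < 1e-12 & ss_within < 1e-12
  f[zero_both] <- 0; p[zero_both] <- 1
  blow <- ss_within < 1e-12 & ss_between >= 1e-12
  f[blow] <- Inf; p[blow] <- 0
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(x), F = f, df1 = df1, df2 = df2,
             p = p, fdr = fdr, significant = fdr < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
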