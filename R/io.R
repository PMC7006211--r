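# plain-text I/O around the standard formats

#' Read a protein FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a replicate expression matrix from TSV
#'
#' Expects a `gene_id` column followed by `tissue_replicate` columns
#' (`M1_1`, ..., `carcass_4`).
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id") stopf("expression TSV must start with a gene_id column")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression (or mean-TPM) matrix to TSV
#' @param m numeric matrix with gene rownames.
#' @param path output file.
#' @export
write_expression_tsv <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular homology hit table (BLAST outfmt-6 dialect)
#'
#' Column order: query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value,
#' bit score. The mismatch/gap-open columns are read but unused.
#' @param path TSV file without header.
#' @return data.frame of hit records.
#' @export
read_hit_table <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 12) stopf("hit table must have 12 columns, got %d", ncol(d))
  names(d) <- c("query", "subject", "identity", "align_len", "mismatches",
                "gap_opens", "q_start", "q_end", "s_start", "s_end",
                "e_value", "bit_score")
  d
}

#' Write hits in 12-column tabular format
#' @param hits hit data.frame as produced by [similarity_search()].
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  d <- data.frame(hits$query, hits$subject, hits$identity, hits$align_len,
                  hits$mismatches %||% 0L, hits$gap_opens %||% 0L,
                  hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                  format(hits$e_value, digits = 6),
                  round(hits$bit_score, 1))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a taxon- or term-annotation TSV
#' @param path TSV with header.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
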