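# Reduction of a redundant Trinity protein set to a unigene set:
# longest-isoform selection, containment deduplication, contaminant removal.

#' Parse Trinity-style accessions into gene and isoform identifiers
#'
#' Accepts accessions like `TRINITY_DN1000_c115_g1_i1` (the `TRINITY_` prefix
#' is optional) and splits them at the gene ("g") level.
#'
#' @param accessions character vector.
#' @return data.frame with `accession`, `gene_id` (e.g. `DN1000_c115_g1`) and
#'   `isoform_id` (e.g. `i1`); unparseable accessions get NA in both fields.
#' @export
parse_trinity_id <- function(accessions) {
  pat <- "^(?:TRINITY_)?(DN[0-9]+_c[0-9]+_g[0-9]+)_(i[0-9]+)$"
  m <- regmatches(accessions, regexec(pat, accessions))
  gene <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                 character(1))
  iso <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_,
                character(1))
  data.frame(accession = accessions, gene_id = gene, isoform_id = iso,
             stringsAsFactors = FALSE)
}

# coerce input (records data.frame or named FASTA vector) to the canonical
# record data.frame
as_unigene_records <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    ids <- parse_trinity_id(names(x))
    x <- data.frame(accession = names(x), gene_id = ids$gene_id,
                    isoform_id = ids$isoform_id, sequence = unname(x),
                    length = nchar(unname(x)), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x),
            all(c("accession", "gene_id", "isoform_id", "sequence") %in% names(x)))
  if (is.null(x$length)) x$length <- nchar(x$sequence)
  x
}

#' Keep the longest protein of each gene
#'
#' Reduces an isoform-level protein set to one record per Trinity gene by
#' keeping the longest isoform; ties on length are broken by the
#' lexicographically smaller isoform identifier. Records whose accession does
#' not parse are rejected with a warning and reported in the `rejected`
#' attribute rather than silently dropped.
#'
#' @param records record data.frame (or named sequence vector; accessions are
#'   parsed with [parse_trinity_id()]).
#' @return one-record-per-gene data.frame, ordered by gene_id, with attribute
#'   `rejected` holding any unparseable accessions.
#' @export
select_longest_isoform <- function(records) {
  records <- as_unigene_records(records)
  bad <- is.na(records$gene_id) | is.na(records$isoform_id)
  rejected <- records$accession[bad]
  if (length(rejected))
    warnf("rejected %d record(s) with unparseable accessions (e.g. '%s')",
          length(rejected), rejected[1])
  records <- records[!bad, , drop = FALSE]
  ord <- order(records$gene_id, -records$length, records$isoform_id)
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(records$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejected = rejected)
}

#' Remove proteins entirely contained within larger proteins
#'
#' Drops every unigene whose sequence is an exact substring (identity 1.0) of
#' another surviving unigene's sequence. Identical sequences keep the record
#' with the lexicographically smaller gene_id. The result does not depend on
#' input order.
#'
#' @param unigenes one-record-per-gene data.frame.
#' @return the surviving records, ordered by gene_id, with attribute
#'   `removed` listing dropped gene_ids.
#' @export
remove_contained <- function(unigenes) {
  unigenes <- as_unigene_records(unigenes)
  stopifnot(!anyDuplicated(unigenes$gene_id))
  # canonical order: longer first, then smaller gene_id (the survivor of any
  # identical pair)
  ord <- order(-unigenes$length, unigenes$gene_id)
  u <- unigenes[ord, , drop = FALSE]

  # duplicates of an identical sequence: keep first occurrence in canonical order
  dup <- duplicated(u$sequence)
  keep <- !dup

  # for remaining candidates, drop those contained in any strictly longer
  # surviving sequence; scanning in decreasing length order makes survival
  # well-defined and order-independent
  lens <- u$length
  for (i in which(keep)) {
    longer <- which(keep & lens > lens[i])
    longer <- longer[longer != i]
    if (length(longer) &&
        any(vapply(u$sequence[longer],
                   function(h) grepl(u$sequence[i], h, fixed = TRUE),
                   logical(1))))
      keep[i] <- FALSE
  }
  removed <- sort(u$gene_id[!keep])
  out <- u[keep, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, removed = removed)
}

#' Discard genes with significant similarity to excluded taxa
#'
#' Removes unigenes whose best annotated hit falls in an excluded taxon group
#' (bacteria or plants by default) with e-value strictly below `e_max`. The
#' removed set is returned separately because bacterial-like genes are
#' analyzed (symbiont expression along the gut) before being discarded.
#'
#' @param unigenes one-record-per-gene data.frame.
#' @param taxa data.frame with `gene_id`, `taxon_group`, `e_value`.
#' @param e_max significance threshold (strict `<`), default 1e-05.
#' @param excluded taxon groups to discard (case-insensitive).
#' @return list with `kept` and `removed` record data.frames.
#' @export
filter_taxon <- function(unigenes, taxa, e_max = 1e-05,
                         excluded = c("bacteria", "plants")) {
  unigenes <- as_unigene_records(unigenes)
  stopifnot(all(c("gene_id", "taxon_group", "e_value") %in% names(taxa)))
  unknown <- setdiff(taxa$gene_id, unigenes$gene_id)
  if (length(unknown))
    warnf("taxon annotation references %d unknown gene_id(s); ignored",
          length(unknown))
  taxa <- taxa[taxa$gene_id %in% unigenes$gene_id, , drop = FALSE]
  # best (smallest e-value) hit per gene decides
  taxa <- taxa[order(taxa$gene_id, taxa$e_value), , drop = FALSE]
  best <- taxa[!duplicated(taxa$gene_id), , drop = FALSE]
  bad_genes <- best$gene_id[tolower(best$taxon_group) %in% tolower(excluded) &
                              best$e_value < e_max]
  drop <- unigenes$gene_id %in% bad_genes
  kept <- unigenes[!drop, , drop = FALSE]
  removed <- unigenes[drop, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Run the full unigene reduction
#'
#' Fixed stage order: longest-isoform selection, containment deduplication,
#' then taxon filtering.
#'
#' @inheritParams select_longest_isoform
#' @inheritParams filter_taxon
#' @return list with `unigenes` (final kept records), `removed_taxon`,
#'   `removed_contained`, `rejected` and per-stage `counts`.
#' @export
build_unigene_set <- function(records, taxa, e_max = 1e-05,
                              excluded = c("bacteria", "plants")) {
  sel <- select_longest_isoform(records)
  ded <- remove_contained(sel)
  # annotations for genes dropped by dedup are expected; don't warn on them
  taxa_known <- taxa[taxa$gene_id %in% ded$gene_id, , drop = FALSE]
  fil <- filter_taxon(ded, taxa_known, e_max = e_max, excluded = excluded)
  list(unigenes = fil$kept,
       removed_taxon = fil$removed,
       removed_contained = attr(ded, "removed"),
       rejected = attr(sel, "rejected"),
       counts = c(records_in = nrow(as_unigene_records(records)),
                  genes = nrow(sel),
                  after_dedup = nrow(ded),
                  after_taxon_filter = nrow(fil$kept)))
}
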