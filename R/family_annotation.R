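# Homology-based gene-family identification: the P450 pipeline (forward +
# reciprocal search, length window, domain motif, fragment joining) and the
# nutrient-transporter pipeline (reciprocal family vote, transmembrane-count
# and family length-SD filters, iterative search).

#' Reference family panel
#'
#' A named reference family with member sequences from (typically two)
#' reference species and the length statistics used by the length filter.
#'
#' @param name family name (e.g. "AAAP", "APC", "SP", "CYP").
#' @param members_by_species named list (species -> named sequence vector).
#' @param type `"transporter"` or `"p450"`; controls which extra filters a
#'   candidate must pass.
#' @param tm_min minimum predicted transmembrane segments for candidates
#'   (transporter families; 0 disables).
#' @return a `family_panel` with `min_len`, `max_len` and sample `sd_len`
#'   over all members (0 for a single member).
#' @export
family_panel <- function(name, members_by_species,
                         type = c("transporter", "p450"), tm_min = 3L) {
  type <- match.arg(type)
  members <- unlist(unname(members_by_species))
  if (length(members) < 1) stopf("family panel '%s' has no members", name)
  lens <- nchar(members)
  structure(list(name = name, members_by_species = members_by_species,
                 members = members, type = type, tm_min = as.integer(tm_min),
                 min_len = min(lens), max_len = max(lens),
                 sd_len = if (length(lens) > 1) stats::sd(lens) else 0),
            class = "family_panel")
}

# pooled panel member sequences and their family labels (member names kept
# as-is; unlist on an unnamed outer list avoids name mangling)
pool_panels <- function(panels) {
  seqs <- unlist(unname(lapply(panels, function(p) p$members)))
  fam <- unlist(unname(lapply(panels, function(p)
    stats::setNames(rep(p$name, length(p$members)), names(p$members)))))
  list(seqs = seqs, family = fam)
}

#' Family length filter
#'
#' Keeps a candidate iff its length lies within one standard deviation of the
#' family's length extremes: (min_len - sd) <= length <= (max_len + sd),
#' bounds inclusive. Lengths and the sample SD are computed over the combined
#' reference members (both species).
#'
#' @param length candidate protein length(s) in residues.
#' @param panel a [family_panel()].
#' @return logical keep/drop vector.
#' @export
length_filter <- function(length, panel) {
  stopifnot(inherits(panel, "family_panel"))
  length >= (panel$min_len - panel$sd_len) &
    length <= (panel$max_len + panel$sd_len)
}

#' Classify a candidate into a reference family by reciprocal-hit voting
#'
#' Given the candidate's hits against the pooled panel members (sorted by
#' e-value, ties by bit score then subject ID), family F is assigned iff:
#' (i) the top hit is in F; (ii) with >= 5 panel members in F, at least 4 of
#' the top 5 hits are in F -- with fewer than 5 members, all of F's members
#' appear in the top 5; and (iii) the best percent identity to any member of
#' F is at least `min_identity`.
#'
#' @param hits hit table for one candidate query against the pooled panel
#'   members (see [similarity_search()]).
#' @param panels named list of [family_panel()] objects.
#' @param min_identity identity threshold for rule (iii), default 20.
#' @return list with `family` (name or NA), `top_family`, `votes` (top-5
#'   votes for the top family), `best_identity`.
#' @export
classify_family <- function(hits, panels, min_identity = 20) {
  pool <- pool_panels(panels)
  no_call <- list(family = NA_character_, top_family = NA_character_,
                  votes = 0L, best_identity = NA_real_)
  if (is.null(hits) || nrow(hits) == 0) return(no_call)
  hits <- hits[order(hits$e_value, -hits$bit_score, hits$subject), , drop = FALSE]
  fam_of <- unname(pool$family[hits$subject])
  top_fam <- fam_of[1]
  top5 <- utils::head(hits, 5)
  top5_fam <- pool$family[top5$subject]
  votes <- sum(top5_fam == top_fam)
  fam_size <- sum(pool$family == top_fam)
  rule_ii <- if (fam_size >= 5) {
    votes >= 4
  } else {
    fam_members <- names(pool$family)[pool$family == top_fam]
    all(fam_members %in% top5$subject)
  }
  best_id <- suppressWarnings(max(hits$identity[fam_of == top_fam]))
  res <- list(family = NA_character_, top_family = top_fam,
              votes = as.integer(votes), best_identity = best_id)
  if (rule_ii && is.finite(best_id) && best_id >= min_identity)
    res$family <- top_fam
  res
}

#' P450 candidate identification
#'
#' A unigene is a P450 candidate iff (a) a curated P450 query hits it with
#' e-value <= `e_max` and query coverage > `cov_min`; (b) the reciprocal
#' search of the unigene against the curated set yields a hit under the same
#' thresholds; (c) its length is within `len_range` (inclusive); and (d) it
#' carries a P450 domain -- by default the heme-ligand motif
#' F-x-x-G-x-[RH]-x-C-x-G, or membership in an externally supplied per-gene
#' domain table.
#'
#' @param unigenes named sequences (names = gene IDs).
#' @param curated named curated P450 sequences (reference species).
#' @param hits optional precomputed forward hit table (curated queries vs
#'   unigene subjects); computed with [similarity_search()] when NULL.
#' @param e_max e-value cutoff, default 1e-3.
#' @param cov_min query-coverage cutoff (strict `>`), default 0.4.
#' @param len_range inclusive candidate length window, default c(150, 650).
#' @param motif domain motif regex; ignored when `domain_genes` is given.
#' @param domain_genes optional character vector of gene IDs with an
#'   externally assigned P450 domain (e.g. a Pfam scan).
#' @return data.frame of candidate calls with evidence columns.
#' @export
p450_candidates <- function(unigenes, curated, hits = NULL,
                            e_max = 1e-3, cov_min = 0.4,
                            len_range = c(150, 650),
                            motif = P450_MOTIF_REGEX,
                            domain_genes = NULL, seed_screen = TRUE) {
  if (is.null(hits))
    hits <- similarity_search(curated, unigenes, seed_screen = seed_screen)
  fwd <- hits[hits$e_value <= e_max & hits$q_cov > cov_min, , drop = FALSE]
  cand_ids <- sort(unique(fwd$subject))
  if (length(cand_ids) == 0) return(empty_family_calls())
  cand <- unigenes[cand_ids]

  rec <- similarity_search(cand, curated, seed_screen = seed_screen)
  rec <- rec[rec$e_value <= e_max & rec$q_cov > cov_min, , drop = FALSE]
  reciprocal_ok <- cand_ids %in% rec$query

  len <- nchar(cand)
  len_ok <- len >= len_range[1] & len <= len_range[2]

  domain_ok <- if (!is.null(domain_genes)) cand_ids %in% domain_genes
  else grepl(motif, cand)

  keep <- reciprocal_ok & len_ok & domain_ok
  data.frame(gene_id = cand_ids, family = ifelse(keep, "CYP", NA_character_),
             length = len, reciprocal_ok = reciprocal_ok, len_ok = len_ok,
             domain_ok = domain_ok,
             stringsAsFactors = FALSE, row.names = NULL)[keep, , drop = FALSE]
}

empty_family_calls <- function() {
  data.frame(gene_id = character(0), family = character(0),
             length = integer(0), stringsAsFactors = FALSE)
}

# maximal suffix/prefix exact overlap (>= min_overlap) of a over b
best_overlap <- function(a, b, min_overlap) {
  max_ov <- min(nchar(a), nchar(b)) - 1L
  for (ov in rev(seq_len(max_ov))) {
    if (ov < min_overlap) break
    if (substr(a, nchar(a) - ov + 1L, nchar(a)) == substr(b, 1L, ov))
      return(ov)
  }
  0L
}

#' Join overlapping sequence fragments
#'
#' Two fragments are joined when a suffix of one equals a prefix of the other
#' over at least `min_overlap` residues at 100% identity; the joined length
#' is l1 + l2 - overlap. Identical fragments collapse to a single record and
#' fragments fully contained in another are dropped first. Joining repeats to
#' a fixed point; a fragment with several incompatible join partners is left
#' unjoined and the conflict is recorded. The result does not depend on input
#' order.
#'
#' @param fragments named character vector of candidate sequences.
#' @param min_overlap minimum exact overlap (default 20).
#' @return named character vector of merged sequences (joined records get
#'   names like `id1+id2`), with attribute `conflicts` listing fragments left
#'   unjoined because of incompatible overlaps.
#' @export
merge_fragments <- function(fragments, min_overlap = 20) {
  stopifnot(!is.null(names(fragments)))
  frags <- fragments[order(names(fragments))]
  # identical sequences: keep the lexicographically smallest id
  frags <- frags[!duplicated(unname(frags))]
  # containment: drop fragments that are substrings of a longer fragment
  drop <- vapply(seq_along(frags), function(i) {
    any(vapply(seq_along(frags), function(j)
      j != i && nchar(frags[j]) > nchar(frags[i]) &&
        grepl(frags[i], frags[j], fixed = TRUE), logical(1)))
  }, logical(1))
  frags <- frags[!drop]

  conflicts <- character(0)
  repeat {
    ids <- names(frags)
    joins <- list()
    for (a in ids) for (b in ids) {
      if (a == b) next
      ov <- best_overlap(frags[[a]], frags[[b]], min_overlap)
      if (ov > 0) joins[[length(joins) + 1L]] <- list(a = a, b = b, ov = ov)
    }
    if (length(joins) == 0) break
    left <- vapply(joins, `[[`, character(1), "a")
    right <- vapply(joins, `[[`, character(1), "b")
    conflicted <- c(left[duplicated(left)], right[duplicated(right)])
    usable <- !(left %in% conflicted) & !(right %in% conflicted)
    # a fragment may appear once as left and once as right of a chain; that
    # is compatible -- true conflicts are two joins competing for the same end
    if (!any(usable)) {
      conflicts <- unique(c(conflicts, conflicted))
      break
    }
    # apply the first usable join, then rescan (keeps chains deterministic)
    j <- joins[usable][[1]]
    merged <- paste0(frags[[j$a]],
                     substr(frags[[j$b]], j$ov + 1L, nchar(frags[[j$b]])))
    frags <- frags[setdiff(names(frags), c(j$a, j$b))]
    frags[[paste(j$a, j$b, sep = "+")]] <- merged
    frags <- frags[order(names(frags))]
  }
  structure(frags, conflicts = unique(conflicts))
}

#' Iterative family annotation of a unigene set
#'
#' Round 1 searches the reference panels against the unigenes; hits passing
#' the e-value and query-coverage cutoffs become candidates, which are
#' classified by reciprocal-hit voting ([classify_family()]) and filtered --
#' transporter families by transmembrane-segment count and the family
#' length-SD window, P450-type families by the domain motif and the fixed
#' 150-650 residue window. Accepted candidates join the query set and rounds
#' repeat until no new acceptance (or `max_rounds`); earlier calls are never
#' revoked.
#'
#' @param unigenes named sequences (names = gene IDs).
#' @param panels named list of [family_panel()] objects.
#' @param e_max e-value cutoff, default 1e-3.
#' @param cov_min query-coverage cutoff (strict `>`), default 0.4.
#' @param min_identity rule-(iii) identity threshold, default 20.
#' @param max_rounds iteration cap, default 5.
#' @param p450_len_range inclusive length window for P450-type families.
#' @return data.frame of family calls: gene_id, family, length, round,
#'   votes, best_identity, tm_count.
#' @export
iterative_annotate <- function(unigenes, panels, e_max = 1e-3, cov_min = 0.4,
                               min_identity = 20, max_rounds = 5,
                               p450_len_range = c(150, 650),
                               seed_screen = TRUE) {
  pool <- pool_panels(panels)
  calls <- list()
  called <- character(0)
  evaluated <- character(0)
  new_queries <- pool$seqs
  fwd_all <- NULL

  for (round in seq_len(max_rounds)) {
    # only the queries added this round need searching; earlier hits persist
    hits <- similarity_search(new_queries, unigenes, seed_screen = seed_screen)
    fwd_all <- rbind(fwd_all,
                     hits[hits$e_value <= e_max & hits$q_cov > cov_min, ,
                          drop = FALSE])
    # classification against the fixed panels is round-invariant, so each
    # candidate only needs evaluating once
    cand_ids <- sort(setdiff(unique(fwd_all$subject), evaluated))
    if (length(cand_ids) == 0) break
    evaluated <- c(evaluated, cand_ids)

    rec <- similarity_search(unigenes[cand_ids], pool$seqs,
                             seed_screen = seed_screen)
    rec <- rec[rec$e_value <= e_max, , drop = FALSE]

    new_called <- character(0)
    for (g in cand_ids) {
      cl <- classify_family(rec[rec$query == g, , drop = FALSE], panels,
                            min_identity = min_identity)
      if (is.na(cl$family)) next
      panel <- panels[[cl$family]]
      len <- nchar(unigenes[[g]])
      if (panel$type == "p450") {
        if (len < p450_len_range[1] || len > p450_len_range[2]) next
        if (!grepl(P450_MOTIF_REGEX, unigenes[[g]])) next
        tm <- NA_integer_
      } else {
        tm <- count_tm(unigenes[[g]])
        if (tm < panel$tm_min) next
        if (!length_filter(len, panel)) next
      }
      calls[[g]] <- data.frame(gene_id = g, family = cl$family, length = len,
                               round = round, votes = cl$votes,
                               best_identity = cl$best_identity,
                               tm_count = tm, stringsAsFactors = FALSE)
      new_called <- c(new_called, g)
    }
    if (length(new_called) == 0) break
    called <- c(called, new_called)
    new_queries <- unigenes[new_called]
  }
  if (length(calls) == 0)
    return(data.frame(gene_id = character(0), family = character(0),
                      length = integer(0), round = integer(0),
                      votes = integer(0), best_identity = numeric(0),
                      tm_count = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$family, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family expression summary
#'
#' After excluding genes whose mean TPM is <= 1 in every compartment, reports
#' per family and tissue the average member TPM and the number of members
#' above each high-expression threshold (strict `>`).
#'
#' @param calls family-call data.frame (gene_id, family).
#' @param mean_table genes x tissue mean-TPM matrix.
#' @param thresholds high-expression thresholds, default c(5, 50).
#' @return data.frame: family, tissue, n_members, mean_tpm and one
#'   `n_over_<t>` column per threshold; families with no surviving member get
#'   zero rows flagged in the `empty_families` attribute.
#' @export
summarize_family_expression <- function(calls, mean_table,
                                        thresholds = c(5, 50)) {
  fams <- sort(unique(calls$family))
  rows <- list()
  empty <- character(0)
  for (f in fams) {
    members <- calls$gene_id[calls$family == f]
    members <- intersect(members, rownames(mean_table))
    sub <- mean_table[members, , drop = FALSE]
    surviving <- rownames(sub)[apply(sub, 1, max) > 1]
    sub <- sub[surviving, , drop = FALSE]
    if (nrow(sub) == 0) empty <- c(empty, f)
    for (t in colnames(mean_table)) {
      r <- data.frame(family = f, tissue = t, n_members = nrow(sub),
                      mean_tpm = if (nrow(sub)) mean(sub[, t]) else 0,
                      stringsAsFactors = FALSE)
      for (th in thresholds)
        r[[paste0("n_over_", th)]] <- if (nrow(sub)) sum(sub[, t] > th) else 0L
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows) %||% data.frame()
  rownames(out) <- NULL
  structure(out, empty_families = empty)
}
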