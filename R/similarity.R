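# Pairwise protein similarity search: Smith-Waterman local alignment with
# BLOSUM62 and affine gaps, plus a Karlin-Altschul e-value layer, producing
# hit tables interchangeable with external 12-column (outfmt-6 style) output.

# ungapped Karlin-Altschul constants used for the bit-score / e-value layer
KA_LAMBDA <- 0.267
KA_K <- 0.041

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

# map k-mer -> subject indices, for the seeding screen
build_kmer_index <- function(subjects, k) {
  km <- lapply(subjects, seq_kmers, k = k)
  split(rep(seq_along(subjects), lengths(km)), unlist(km))
}

seeded_subjects <- function(query, index, k) {
  qk <- seq_kmers(query, k)
  sort(unique(unlist(index[qk], use.names = FALSE)))
}

empty_hits <- function() {
  data.frame(query = character(0), subject = character(0),
             identity = numeric(0), align_len = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             e_value = numeric(0), bit_score = numeric(0), score = numeric(0),
             q_len = integer(0), s_len = integer(0), q_cov = numeric(0),
             stringsAsFactors = FALSE)
}

#' Smith-Waterman similarity search
#'
#' Aligns every query against every subject with local Smith-Waterman
#' (BLOSUM62, affine gap open 11 / extend 1, so a gap of length g costs
#' 11 + g) and reports identity over the aligned region, coverage, bit score
#' S' = (lambda * S - ln K) / ln 2 and e-value E = m * n * 2^(-S') with m, n
#' the query and subject lengths. Hits are sorted by e-value, then bit score
#' (descending), then subject ID.
#'
#' @param queries named character vector of protein sequences.
#' @param subjects named character vector of protein sequences.
#' @param e_max only report hits with e-value <= `e_max` (default `Inf`:
#'   report everything).
#' @param seed_screen if TRUE, only align query/subject pairs that share at
#'   least one exact `seed_k`-mer (a BLAST-style seeding heuristic; unrelated
#'   pairs are skipped and reported as no hit). FALSE (default) aligns every
#'   pair.
#' @param seed_k seed word length for the screen.
#' @return data.frame of hit records: query, subject, identity (0-100),
#'   align_len, mismatches, gap_opens, q_start, q_end, s_start, s_end,
#'   e_value, bit_score, plus q_len, s_len, q_cov.
#' @export
similarity_search <- function(queries, subjects, e_max = Inf,
                              seed_screen = FALSE, seed_k = 6) {
  if (length(queries) == 0 || length(subjects) == 0)
    stopf("similarity_search: empty query or subject set")
  if (any(nchar(queries) == 0) || any(nchar(subjects) == 0))
    stopf("similarity_search: empty sequence")
  if (is.null(names(queries)) || is.null(names(subjects)))
    stopf("similarity_search: sequences must be named")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  subj_set <- Biostrings::AAStringSet(subjects)
  kmer_index <- if (seed_screen) build_kmer_index(subjects, seed_k) else NULL
  out <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    s_idx <- seq_along(subjects)
    if (seed_screen) {
      s_idx <- seeded_subjects(q, kmer_index, seed_k)
      if (length(s_idx) == 0) next
    }
    pa <- Biostrings::pairwiseAlignment(
      pattern = subj_set[s_idx], subject = q, type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
    s <- Biostrings::score(pa)
    bit <- (KA_LAMBDA * s - log(KA_K)) / log(2)
    m <- nchar(q); n_len <- nchar(subjects)[s_idx]
    ev <- m * n_len * 2^(-bit)
    ins <- Biostrings::nindel(pa)
    gap_opens <- Biostrings::insertion(ins)[, "Length"] +
      Biostrings::deletion(ins)[, "Length"]
    d <- data.frame(
      query = names(queries)[qi],
      subject = names(subjects)[s_idx],
      identity = Biostrings::pid(pa, type = "PID1"),
      align_len = Biostrings::nchar(pa),
      mismatches = Biostrings::nmismatch(pa),
      gap_opens = gap_opens,
      q_start = Biostrings::start(Biostrings::subject(pa)),
      q_end = Biostrings::end(Biostrings::subject(pa)),
      s_start = Biostrings::start(Biostrings::pattern(pa)),
      s_end = Biostrings::end(Biostrings::pattern(pa)),
      e_value = ev,
      bit_score = bit,
      score = s,
      q_len = m,
      s_len = n_len,
      stringsAsFactors = FALSE)
    out[[qi]] <- d
  }
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0) return(empty_hits())
  hits$q_cov <- (hits$q_end - hits$q_start + 1) / hits$q_len
  hits <- hits[hits$e_value <= e_max, , drop = FALSE]
  hits <- hits[order(hits$e_value, -hits$bit_score, hits$subject), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Slides a window over the sequence, averages Kyte-Doolittle hydropathy,
#' and turns maximal runs of windows above the threshold into segments;
#' segments separated by fewer than `min_gap` residues are merged. Unknown
#' residues contribute hydropathy 0 with a warning.
#'
#' @param sequence one protein sequence.
#' @param window window width (default 19, about one membrane-spanning
#'   helix).
#' @param threshold mean-hydropathy cutoff (default 1.6).
#' @param min_gap segments closer than this many residues are merged.
#' @return data.frame with `start`, `end` (residue coordinates); zero rows if
#'   the sequence is shorter than the window or has no hydrophobic stretch.
#' @export
predict_tm <- function(sequence, window = 19, threshold = 1.6, min_gap = 5) {
  aa <- strsplit(sequence, "")[[1]]
  h <- KD_SCALE[aa]
  if (anyNA(h)) {
    warnf("unknown residue(s) in sequence; hydropathy 0 assumed")
    h[is.na(h)] <- 0
  }
  L <- length(h)
  if (L < window)
    return(data.frame(start = integer(0), end = integer(0)))
  cs <- cumsum(c(0, h))
  win_mean <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
  above <- win_mean > threshold
  if (!any(above))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values],
                    end = ends[r$values] + window - 1L)
  # merge segments separated by < min_gap residues
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))[-1]) {
    if (seg$start[i] - merged$end[nrow(merged)] - 1 < min_gap)
      merged$end[nrow(merged)] <- seg$end[i]
    else merged <- rbind(merged, seg[i, ])
  }
  rownames(merged) <- NULL
  merged
}

#' Number of predicted transmembrane segments
#' @inheritParams predict_tm
#' @return integer count.
#' @export
count_tm <- function(sequence, window = 19, threshold = 1.6, min_gap = 5) {
  nrow(predict_tm(sequence, window, threshold, min_gap))
}
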