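# Fisher's-exact term enrichment over gene groups with BH FDR control.

#' Build a 2x2 contingency table for one group and one term
#'
#' Counts by exact set intersection; duplicated (gene, term) annotations
#' count once.
#'
#' @param group character vector of gene IDs (must be a subset of the
#'   universe).
#' @param term_genes gene IDs annotated with the term; IDs outside the
#'   universe are ignored with a warning.
#' @param universe all gene IDs under consideration.
#' @return list `(N, n, K, k)`: universe size, group size, term size in the
#'   universe, term size in the group.
#' @export
build_contingency <- function(group, term_genes, universe) {
  group <- unique(group); term_genes <- unique(term_genes)
  universe <- unique(universe)
  if (!all(group %in% universe))
    stopf("group contains %d gene(s) outside the universe",
          sum(!group %in% universe))
  outside <- setdiff(term_genes, universe)
  if (length(outside))
    warnf("%d term annotation(s) reference genes outside the universe; ignored",
          length(outside))
  term_genes <- intersect(term_genes, universe)
  list(N = length(universe), n = length(group),
       K = length(term_genes), k = length(intersect(group, term_genes)))
}

# log choose, vectorized
lch <- function(n, k) lchoose(n, k)

#' One-sided Fisher's exact test (over-representation)
#'
#' Upper-tail hypergeometric probability P(X >= k) for X ~
#' Hypergeometric(N, K, n), computed by summing the log-space pmf terms, so
#' it is stable down to p ~ 1e-300. Vectorized over `k`.
#'
#' @param N universe size.
#' @param K genes in the universe annotated with the term.
#' @param n group size.
#' @param k genes in the group annotated with the term (may be a vector).
#' @return p-value(s) in (0, 1]; `k = 0` gives exactly 1.
#' @export
fisher_right_tail <- function(N, K, n, k) {
  if (K > N || n > N) stopf("invalid contingency table: K and n must be <= N")
  if (any(k < 0) || any(k > pmin(n, K)))
    stopf("invalid contingency table: k must be in [0, min(n, K)]")
  kmax <- min(n, K)
  kmin_support <- max(0L, n + K - N)
  # log pmf over the whole support once, then tail-sum per requested k
  support <- seq.int(kmin_support, kmax)
  logpmf <- lch(K, support) + lch(N - K, n - support) - lch(N, n)
  vapply(k, function(ki) {
    if (ki <= kmin_support) return(1)
    min(1, exp(logsumexp(logpmf[support >= ki])))
  }, numeric(1))
}

#' Fisher right tail from a contingency list
#' @param table output of [build_contingency()].
#' @return p-value.
#' @export
fisher_right_tail_table <- function(table) {
  fisher_right_tail(table$N, table$K, table$n, table$k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment q_(i) = min_(j >= i) p_(j) * m / j, capped at 1;
#' order-preserving and invariant under permutation of the input.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Term enrichment of gene groups
#'
#' Tests every (group, term) pair for over-representation with the one-sided
#' Fisher test. Terms annotated to fewer than `min_genes` genes (in the
#' universe by default, or in the group under `min_mode = "group"`) are
#' excluded before testing; BH adjustment is applied jointly across all
#' surviving tests of the run; rows with fdr below `fdr_max` are returned,
#' sorted by (group, fdr).
#'
#' @param groups named list of gene-ID vectors.
#' @param term_annotation data.frame with `gene_id`, `term_id` and optionally
#'   `term_kind`, `annotation`.
#' @param universe all genes under consideration (non-empty).
#' @param min_genes minimum term size, default 10.
#' @param fdr_max report threshold on the adjusted p (strict `<`), default
#'   0.001. `Inf` reports everything tested.
#' @param min_mode whether `min_genes` bounds the term size in the universe
#'   (`"universe"`, default) or the overlap with the group (`"group"`).
#' @return data.frame with group, term_id, term_kind, k, n, K, N, p_raw, fdr.
#' @export
enrich_groups <- function(groups, term_annotation, universe,
                          min_genes = 10, fdr_max = 0.001,
                          min_mode = c("universe", "group")) {
  min_mode <- match.arg(min_mode)
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  if (length(groups) == 0) stopf("need at least one group")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))

  ann <- unique(term_annotation[term_annotation$gene_id %in% universe,
                                c("gene_id", "term_id",
                                  intersect("term_kind", names(term_annotation)))])
  term_sets <- split(ann$gene_id, ann$term_id)
  term_kind <- if ("term_kind" %in% names(ann))
    vapply(split(ann$term_kind, ann$term_id), `[`, character(1), 1)
  else stats::setNames(rep(NA_character_, length(term_sets)), names(term_sets))

  if (min_mode == "universe")
    term_sets <- term_sets[lengths(term_sets) >= min_genes]

  rows <- list()
  N <- length(universe)
  for (g in names(groups)) {
    grp <- unique(groups[[g]])
    if (!all(grp %in% universe)) stopf("group '%s' is not a subset of the universe", g)
    n <- length(grp)
    for (t in names(term_sets)) {
      K <- length(term_sets[[t]])
      k <- length(intersect(grp, term_sets[[t]]))
      if (min_mode == "group" && k < min_genes) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, term_id = t, term_kind = term_kind[[t]],
        k = k, n = n, K = K, N = N,
        p_raw = fisher_right_tail(N, K, n, k),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(group = character(0), term_id = character(0),
                      term_kind = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_raw)
  n_tested <- nrow(out)
  out <- out[out$fdr < fdr_max, , drop = FALSE]
  out <- out[order(out$group, out$fdr, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}
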