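# Fuzzy C-means clustering of standardized mean-expression profiles along the
# midgut, with high-membership group extraction.

#' Clustering parameters
#'
#' @param c number of clusters (>= 2); eight in the midgut analysis.
#' @param m fuzzifier (> 1). Small values keep memberships decisive, which
#'   the alpha > 0.6 retention cut presumes.
#' @param tol convergence tolerance on the change in objective.
#' @param max_iter iteration cap per restart.
#' @param restarts number of seeded initializations; the best final objective
#'   wins.
#' @param alpha membership retention threshold in (0, 1).
#' @param seed integer seed for the initializations.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(c = 8, m = 1.25, tol = 1e-8, max_iter = 300,
                           restarts = 20, alpha = 0.6, seed = 1) {
  if (c < 2) stopf("cluster_params: c must be >= 2")
  if (m <= 1) stopf("cluster_params: fuzzifier m must be > 1")
  if (alpha <= 0 || alpha >= 1) stopf("cluster_params: alpha must be in (0, 1)")
  structure(list(c = as.integer(c), m = m, tol = tol,
                 max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), alpha = alpha,
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' Standardize mean expression profiles
#'
#' Per gene, subtracts the mean and divides by the standard deviation across
#' the selected tissues, so clustering sees relative expression patterns.
#' Genes with zero variance, or with mean TPM <= `tpm_min` in all selected
#' tissues, are excluded and reported.
#'
#' @param mean_table genes x tissue mean-TPM matrix.
#' @param tissues tissues to cluster over (default M1-M4: patterns along the
#'   midgut, carcass excluded).
#' @param tpm_min expression floor; genes never above it are excluded.
#' @return z-profile matrix with attribute `excluded`.
#' @export
standardize <- function(mean_table, tissues = c("M1", "M2", "M3", "M4"),
                        tpm_min = 1) {
  x <- mean_table[, tissues, drop = FALSE]
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  low <- apply(x, 1, max) <= tpm_min
  bad <- low | sd == 0 | is.na(sd)
  z <- (x[!bad, , drop = FALSE] - mu[!bad]) / sd[!bad]
  structure(z, excluded = rownames(x)[bad])
}

# squared Euclidean distances, genes x centroids
sq_dist <- function(x, centroids) {
  d <- outer(rowSums(x^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(x)), rowSums(centroids^2)) -
    2 * x %*% t(centroids)
  pmax(d, 0)
}

# membership update: u_ij proportional to d_ij^(-2/(m-1)); an exact or
# near-exact centroid hit (overflowing weight) gets full membership there,
# split equally if several
membership_from_dist <- function(d2, m) {
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  bad <- !is.finite(rowSums(w))
  if (any(bad)) {
    wb <- !is.finite(w[bad, , drop = FALSE]) | d2[bad, , drop = FALSE] == 0
    u[bad, ] <- wb / rowSums(wb)
  }
  u
}

#' Fuzzy C-means clustering
#'
#' Standard FCM with Euclidean distance: memberships
#' u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)), centroids the u^m-weighted means,
#' objective J = sum u^m d^2, which is non-increasing over iterations.
#' Centroids are initialized from distinct data rows; the best of
#' `params$restarts` runs by final objective is returned.
#'
#' @param z_matrix genes x tissue z-profile matrix (see [standardize()]).
#' @param params a [cluster_params()].
#' @return `fcm_result`: `centroids` (c x tissues), `membership` (genes x c,
#'   rows summing to 1), `objective`, `iterations`, `trace` (objective per
#'   iteration of the winning restart).
#' @export
fuzzy_cmeans <- function(z_matrix, params = cluster_params()) {
  x <- as.matrix(z_matrix)
  n_distinct <- nrow(unique(x))
  if (params$c > n_distinct)
    stopf("c = %d exceeds the number of distinct profiles (%d)",
          params$c, n_distinct)
  best <- NULL
  with_seed(params$seed, {
    for (r in seq_len(params$restarts)) {
      init <- x[!duplicated(x), , drop = FALSE]
      centroids <- init[sample(nrow(init), params$c), , drop = FALSE]
      trace <- numeric(0)
      j_old <- Inf
      for (it in seq_len(params$max_iter)) {
        d2 <- sq_dist(x, centroids)
        u <- membership_from_dist(d2, params$m)
        um <- u^params$m
        centroids <- (t(um) %*% x) / colSums(um)
        d2 <- sq_dist(x, centroids)
        j <- sum(um * d2)
        trace <- c(trace, j)
        if (abs(j_old - j) < params$tol) break
        j_old <- j
      }
      if (is.null(best) || j < best$objective) {
        best <- list(centroids = centroids, membership = u, objective = j,
                     iterations = it, trace = trace)
      }
    }
  })
  rownames(best$membership) <- rownames(x)
  colnames(best$membership) <- paste0("cluster", seq_len(params$c))
  rownames(best$centroids) <- paste0("cluster", seq_len(params$c))
  structure(best, class = "fcm_result")
}

#' Extract high-membership gene groups from a clustering
#'
#' A gene belongs to cluster j iff its membership u_ij is strictly greater
#' than `alpha`. With alpha > 0.5 assignments are unique; genes whose maximal
#' membership does not exceed alpha are reported as unassigned.
#'
#' @param result an `fcm_result`.
#' @param alpha membership retention threshold (strict `>`), default 0.6.
#' @return list of gene-ID vectors, one per cluster, with attribute
#'   `unassigned`.
#' @export
assign_members <- function(result, alpha = 0.6) {
  u <- result$membership
  groups <- lapply(seq_len(ncol(u)), function(j)
    rownames(u)[u[, j] > alpha])
  names(groups) <- colnames(u)
  assigned <- unlist(groups)
  structure(groups, unassigned = setdiff(rownames(u), assigned))
}

#' Hard cluster labels (argmax membership)
#' @param result an `fcm_result`.
#' @return named integer vector of cluster indices.
#' @export
hard_labels <- function(result) {
  u <- result$membership
  stats::setNames(max.col(u, ties.method = "first"), rownames(u))
}
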