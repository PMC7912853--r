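#' Normalized spectral clustering of a similarity network
#'
#' Standard normalized spectral clustering: form
#' `M = D^{-1/2} S D^{-1/2}` (D the degree matrix), take the k leading
#' eigenvectors, normalize the rows of the resulting n x k embedding to
#' unit length, and partition them with k-means (20 restarts under a fixed
#' seed, best within-cluster sum of squares kept).  Deterministic given
#' `seed`.
#'
#' Following the usual spectral-clustering convention, the affinity
#' diagonal (self-similarity, or the seed's own stationary mass in a fused
#' network) is zeroed before the Laplacian is formed: it carries no
#' between-sample information and would otherwise dominate the spectrum
#' whenever off-diagonal affinities are small.  Set
#' `zero_diagonal = FALSE` to keep it.
#'
#' @param s Symmetric nonnegative similarity matrix (fused or single
#'   layer).
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @param seed Integer RNG seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 20).
#' @param zero_diagonal Zero the affinity diagonal first (default `TRUE`).
#' @return An object of class `spectral_clustering`: list with `labels`
#'   (integer vector named by sample id), `k`, and `embedding` (the
#'   row-normalized n x k spectral coordinates).
#' @export
spectral_clustering <- function(s, k, seed = 42, nstart = 20,
                                zero_diagonal = TRUE) {
  n <- nrow(s)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k <= n - 1")
  if (zero_diagonal) diag(s) <- 0
  deg <- rowSums(s)
  if (any(deg <= 0)) stop("similarity matrix has a zero-degree sample")
  inv_sqrt <- 1 / sqrt(deg)
  m <- s * tcrossprod(inv_sqrt)
  eig <- eigen(m, symmetric = TRUE)
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  km <- withr_seed(seed, withCallingHandlers(
    stats::kmeans(u, centers = k, nstart = nstart, iter.max = 100),
    warning = function(w) {
      # near-duplicate embedding rows trip the Hartigan-Wong quick
      # transfer heuristic; the result is still the best of the restarts
      if (grepl("Quick-TRANSfer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  labels <- km$cluster
  names(labels) <- rownames(s)
  structure(list(labels = labels, k = k, embedding = u),
            class = "spectral_clustering")
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seven-index cluster-validity table over a range of cluster numbers
#'
#' For each candidate k the fused network is spectrally clustered and
#' scored with seven cluster-validity statistics: Ratkowsky-Lance, Tau,
#' Silhouette, C-index, SD-scat, SD-Dis and Calinski-Harabasz.  Each index
#' votes for the k at which it is optimal (respecting its max/min
#' direction); see [recommend_k()] for the vote summary.
#'
#' Distance-based indexes (Silhouette, C-index, Tau, Calinski-Harabasz)
#' are computed on the dissimilarity `1 - S / max(S)` by default
#' ([similarity_to_distance()]) or on Euclidean distances of the spectral
#' embedding when `distance = "embedding"`.  Coordinate-based indexes
#' (Ratkowsky-Lance, SD-scat, SD-Dis) always use a fixed spectral
#' embedding with `max(k_range)` dimensions so that scores are comparable
#' across k.
#'
#' @param s Symmetric nonnegative (fused) similarity matrix.
#' @param k_range Integer vector of candidate cluster numbers within
#'   `[2, n - 1]` (default `2:8`).
#' @param seed RNG seed passed to every [spectral_clustering()] call.
#' @param distance `"similarity"` (default) or `"embedding"`; source of
#'   pairwise distances for the distance-based indexes.
#' @return An object of class `validity_table`: list with `table`
#'   (data.frame: index, k, score), `optima` (named integer vector, best k
#'   per index), `votes` (table over k) and `recommended` (from
#'   [recommend_k()]).
#' @export
validity_index_table <- function(s, k_range = 2:8, seed = 42,
                                 distance = c("similarity", "embedding")) {
  distance <- match.arg(distance)
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(s)
  if (length(k_range) == 0L) stop("empty k_range")
  if (min(k_range) < 2L || max(k_range) >= n)
    stop("k_range must lie within [2, n - 1]")

  k_embed <- max(k_range)
  ref <- spectral_clustering(s, k_embed, seed = seed)
  x_embed <- ref$embedding
  d <- if (distance == "similarity") similarity_to_distance(s)
       else as.matrix(stats::dist(x_embed))

  directions <- c("ratkowsky_lance" = 1, "tau" = 1, "silhouette" = 1,
                  "c_index" = -1, "sd_scat" = -1, "sd_dis" = -1,
                  "calinski_harabasz" = 1)

  rows <- list()
  for (k in k_range) {
    cl <- spectral_clustering(s, k, seed = seed)
    lab <- cl$labels
    scores <- c(
      ratkowsky_lance = index_ratkowsky_lance(lab, x_embed),
      tau = index_tau(lab, d),
      silhouette = index_silhouette(lab, d),
      c_index = index_c(lab, d),
      sd_scat = index_sd_scat(lab, x_embed),
      sd_dis = index_sd_dis(lab, x_embed),
      calinski_harabasz = index_calinski_harabasz(lab, d))
    rows[[length(rows) + 1L]] <-
      data.frame(index = names(scores), k = k, score = unname(scores),
                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  optima <- vapply(names(directions), function(idx) {
    sub <- tab[tab$index == idx, ]
    sc <- sub$score * directions[[idx]]
    sub$k[which.max(sc)]  # which.max: first (smallest k) on exact ties
  }, integer(1))
  votes <- table(factor(optima, levels = k_range))
  res <- structure(list(table = tab, optima = optima, votes = votes,
                        recommended = NULL, k_range = k_range),
                   class = "validity_table")
  res$recommended <- recommend_k(res)
  res
}

#' Recommend cluster numbers by validity-index vote
#'
#' Each validity index votes for its optimal k; the two most voted cluster
#' numbers are recommended, in descending vote order, ties broken by the
#' smaller k.  When a single k collects every vote only that one is
#' returned.
#'
#' @param t A `validity_table` (or a plain integer vector of per-index
#'   optima).
#' @return Integer vector of length 1 or 2.
#' @export
recommend_k <- function(t) {
  optima <- if (inherits(t, "validity_table")) t$optima else as.integer(t)
  counts <- table(optima)
  ks <- as.integer(names(counts))
  ord <- order(-as.integer(counts), ks)
  utils::head(ks[ord], 2L)
}

#' @export
print.validity_table <- function(x, ...) {
  cat("Cluster-validity vote over k in {",
      paste(x$k_range, collapse = ", "), "}\n", sep = "")
  for (i in seq_along(x$optima))
    cat(sprintf("  %-18s -> k = %d\n", names(x$optima)[i], x$optima[i]))
  cat("recommended:", paste(x$recommended, collapse = ", "), "\n")
  invisible(x)
}
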