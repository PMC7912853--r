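#' Pairwise Euclidean distances between samples
#'
#' @param m Feature-by-sample numeric matrix with no missing values.
#' @return An n x n symmetric matrix of Euclidean distances with zero
#'   diagonal and sample ids as dimnames.
#' @export
pairwise_distances <- function(m) {
  if (anyNA(m)) stop("distance computation requires a complete matrix")
  d <- as.matrix(stats::dist(t(m)))
  d <- (d + t(d)) / 2  # enforce exact symmetry
  diag(d) <- 0
  d
}

#' Local scale of the scaled exponential similarity kernel
#'
#' For each sample pair (x, y) the kernel bandwidth is
#' \deqn{E(x,y) = [mean(dist(x, N_x)) + mean(dist(y, N_y)) + dist(x,y)] / 3}
#' where `N_x` is the set of the `n_neighbors` nearest samples to x
#' (excluding x itself; ties broken by sample index).  This adapts the
#' kernel to the local point density, as in similarity network fusion.
#'
#' @param d Symmetric distance matrix (n >= 2).
#' @param n_neighbors Neighborhood size N (default 20); clamped to n - 1
#'   with a warning when the cohort is smaller.
#' @return Symmetric n x n matrix of local scales E.
#' @export
local_scale <- function(d, n_neighbors = 20) {
  n <- nrow(d)
  if (n < 2L) stop("need at least two samples")
  if (n_neighbors >= n) {
    warning("n_neighbors = ", n_neighbors, " >= n = ", n,
            "; clamped to ", n - 1L)
    n_neighbors <- n - 1L
  }
  mean_nb <- vapply(seq_len(n), function(x) {
    dx <- d[x, -x]
    mean(dx[order(dx)[seq_len(n_neighbors)]])  # order() is stable: index ties
  }, numeric(1))
  e <- (outer(mean_nb, mean_nb, "+") + d) / 3
  (e + t(e)) / 2
}

#' Scaled exponential similarity network for one omics layer
#'
#' Converts a sample distance matrix into an affinity matrix with the
#' locally scaled Gaussian kernel
#' \deqn{S(x,y) = \exp(-dist^2(x,y) / (\mu E(x,y)))}
#' with E from [local_scale()].  Entries lie in (0, 1]; the diagonal is 1
#' (a sample is maximally similar to itself) and is kept by default since
#' the random-walk transition matrix consumes it as a self-loop.
#' Duplicate points (dist = 0, hence E = 0) get similarity 1 by the
#' limiting convention.
#'
#' @param d Symmetric distance matrix, e.g. from [pairwise_distances()].
#' @param mu Kernel scale hyper-parameter \eqn{\mu > 0} (default 0.5).
#' @param n_neighbors Neighborhood size N for the local scale (default 20).
#' @param zero_diagonal If `TRUE`, the diagonal is set to 0 instead of 1
#'   (for sensitivity analysis only).
#' @return Symmetric n x n similarity matrix with the `"local_scale"`
#'   matrix attached as an attribute.
#' @export
similarity_network <- function(d, mu = 0.5, n_neighbors = 20,
                               zero_diagonal = FALSE) {
  if (mu <= 0) stop("mu must be positive")
  e <- local_scale(d, n_neighbors)
  s <- matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
  pos <- e > 0
  s[pos] <- exp(-d[pos]^2 / (mu * e[pos]))
  # e == 0 implies d == 0 (E >= d/3), i.e. duplicate points: similarity 1
  s <- (s + t(s)) / 2
  diag(s) <- if (zero_diagonal) 0 else 1
  attr(s, "local_scale") <- e
  s
}

#' Similarity network straight from a feature matrix
#'
#' Convenience wrapper: [pairwise_distances()] then [similarity_network()].
#'
#' @inheritParams pairwise_distances
#' @inheritParams similarity_network
#' @export
similarity_from_features <- function(m, mu = 0.5, n_neighbors = 20,
                                     zero_diagonal = FALSE) {
  similarity_network(pairwise_distances(m), mu = mu,
                     n_neighbors = n_neighbors,
                     zero_diagonal = zero_diagonal)
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' Distances for distance-based cluster-validity statistics are derived
#' from a (fused) similarity matrix as `d = 1 - S / max(S)`, where the
#' maximum is taken over off-diagonal entries; the diagonal is set to 0.
#'
#' @param s Symmetric nonnegative similarity matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
similarity_to_distance <- function(s) {
  off <- s
  diag(off) <- NA
  mx <- max(off, na.rm = TRUE)
  if (mx <= 0) stop("similarity matrix has no positive off-diagonal entry")
  d <- 1 - s / mx
  d[d < 0] <- 0
  diag(d) <- 0
  (d + t(d)) / 2
}
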