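#' Identity inter-layer coupling (RWRF)
#'
#' Under RWRF every sample is connected only to its own mirror node in each
#' other layer, so each off-diagonal coupling block is the n x n identity.
#'
#' @param n Number of samples per layer.
#' @param L Number of layers (>= 2).
#' @return A nested list `couplings[[j]][[l]]` (j != l) of sparse identity
#'   matrices.
#' @export
build_rwrf_coupling <- function(n, L) {
  stopifnot(n >= 1L, L >= 2L)
  lapply(seq_len(L), function(j) {
    lapply(seq_len(L), function(l) {
      if (j == l) NULL else Matrix::Diagonal(n)
    })
  })
}

#' Directed neighbor coupling block (RWRNF)
#'
#' Builds the coupling block from a source layer to another layer: row x
#' places weight `beta` on x's own mirror node and weight `(1 - beta) / m`
#' on the mirrors of the `m` nearest neighbors of x *in the source layer*
#' (nearest = largest similarity, self excluded, ties broken by sample
#' index).  Every row sums to 1.
#'
#' @param s_source Similarity matrix of the source layer.
#' @param m Neighbor count (default 10); clamped to n - 1 with a warning.
#' @param beta Mirror weight in `[0, 1]` (default 0.9).  `beta = 1`
#'   reproduces the identity coupling of RWRF.
#' @return An n x n sparse row-stochastic matrix.
#' @export
build_rwrnf_coupling <- function(s_source, m = 10, beta = 0.9) {
  n <- nrow(s_source)
  stopifnot(beta >= 0, beta <= 1, m >= 1)
  if (beta == 1)
    return(Matrix::Diagonal(n))
  if (m >= n) {
    warning("m = ", m, " >= n = ", n, "; clamped to ", n - 1L)
    m <- n - 1L
  }
  nbrs <- t(vapply(seq_len(n), function(x) {
    sx <- s_source[x, ]
    sx[x] <- -Inf
    order(sx, decreasing = TRUE)[seq_len(m)]  # stable: ties by index
  }, integer(m)))
  a <- Matrix::sparseMatrix(
    i = c(seq_len(n), rep(seq_len(n), times = m)),
    j = c(seq_len(n), as.vector(nbrs)),
    x = c(rep(beta, n), rep((1 - beta) / m, n * m)),
    dims = c(n, n))
  rownames(a) <- colnames(a) <- rownames(s_source)
  a
}

#' Assemble an L-layer multiplex network
#'
#' Stacks per-omics similarity networks into a multiplex network whose
#' inter-layer blocks connect replicas of the same sample: identity
#' coupling for RWRF, weighted directed neighbor coupling (built from each
#' source layer's own neighborhoods) for RWRNF.  For more than two layers,
#' each ordered layer pair (j, l) receives its own block derived from
#' layer j.
#'
#' @param layers List of >= 2 symmetric similarity matrices on identical
#'   sample ids (same order).
#' @param variant `"RWRF"` or `"RWRNF"`.
#' @param m,beta RWRNF coupling parameters (ignored under RWRF); see
#'   [build_rwrnf_coupling()].
#' @return An object of class `multiplex_network`: a list with elements
#'   `layers`, `couplings` (nested list `[[j]][[l]]`), `variant`, `n`,
#'   `L`, `sample_ids`, `m`, `beta`.
#' @export
assemble_multiplex <- function(layers, variant = c("RWRF", "RWRNF"),
                               m = 10, beta = 0.9) {
  variant <- match.arg(variant)
  L <- length(layers)
  if (L < 2L) stop("need at least two layers")
  ids <- colnames(layers[[1L]])
  n <- nrow(layers[[1L]])
  for (l in seq_len(L)) {
    if (nrow(layers[[l]]) != n || ncol(layers[[l]]) != n)
      stop("layer ", l, " has mismatched dimensions")
    if (!is.null(ids) && !identical(colnames(layers[[l]]), ids))
      stop("layer ", l, " has mismatched sample ids")
  }
  couplings <- if (variant == "RWRF") {
    build_rwrf_coupling(n, L)
  } else {
    lapply(seq_len(L), function(j) {
      a_j <- build_rwrnf_coupling(layers[[j]], m = m, beta = beta)
      lapply(seq_len(L), function(l) if (j == l) NULL else a_j)
    })
  }
  structure(list(layers = layers, couplings = couplings, variant = variant,
                 n = n, L = L, sample_ids = ids, m = m, beta = beta),
            class = "multiplex_network")
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat("Multiplex network (", x$variant, "): ", x$L, " layers x ",
      x$n, " samples\n", sep = "")
  if (x$variant == "RWRNF")
    cat("  neighbor coupling: m = ", x$m, ", beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

#' Dense block matrix of a multiplex network (debugging aid)
#'
#' @param mx A `multiplex_network`.
#' @return The (L n) x (L n) dense adjacency matrix with similarity layers
#'   on the diagonal blocks and coupling matrices off-diagonal.
#' @export
multiplex_block_matrix <- function(mx) {
  n <- mx$n; L <- mx$L
  out <- matrix(0, L * n, L * n)
  for (j in seq_len(L)) {
    rows <- (j - 1L) * n + seq_len(n)
    for (l in seq_len(L)) {
      cols <- (l - 1L) * n + seq_len(n)
      out[rows, cols] <- if (j == l) mx$layers[[j]]
                         else as.matrix(mx$couplings[[j]][[l]])
    }
  }
  out
}
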