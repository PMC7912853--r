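#' Row-stochastic transition matrix of a multiplex network
#'
#' Block (j, l) of the walk's transition matrix is the row-normalized
#' layer-j similarity matrix (when j = l) or the row-normalized coupling
#' block from layer j to layer l (when j != l), scaled by the target-layer
#' weight `lambdas[l]`.  With the default equal weights 1/L the walker
#' spends probability 1/L on staying in its layer and 1/L on each of the
#' L - 1 jump targets, which for two layers is the familiar
#' stay/jump split lambda_1 + lambda_2 = 1.
#'
#' @param mx A `multiplex_network` from [assemble_multiplex()].
#' @param lambdas Numeric vector of L nonnegative layer weights summing
#'   to 1; default `rep(1/L, L)`.
#' @return The dense (L n) x (L n) transition matrix W; every row sums
#'   to 1.
#' @export
transition_matrix <- function(mx, lambdas = NULL) {
  n <- mx$n; L <- mx$L
  if (is.null(lambdas)) lambdas <- rep(1 / L, L)
  stopifnot(length(lambdas) == L, all(lambdas >= 0),
            abs(sum(lambdas) - 1) < 1e-12)
  w <- matrix(0, L * n, L * n)
  for (j in seq_len(L)) {
    rows <- (j - 1L) * n + seq_len(n)
    for (l in seq_len(L)) {
      cols <- (l - 1L) * n + seq_len(n)
      blk <- if (j == l) mx$layers[[j]] else as.matrix(mx$couplings[[j]][[l]])
      rs <- rowSums(blk)
      if (any(rs <= 0)) stop("zero row sum in block (", j, ",", l, ")")
      w[rows, cols] <- lambdas[l] * blk / rs
    }
  }
  attr(w, "n") <- n
  attr(w, "L") <- L
  w
}

#' Initial (restart) distribution for one seed node
#'
#' For seed sample x in layer j: under RWRF every layer l receives the
#' indicator at x (the seed or its mirror node) scaled by the layer weight
#' `alphas[l]`.  Under RWRNF the seed layer receives the indicator scaled
#' by the seed-layer weight `alpha`, and each other layer l receives row x
#' of the coupling block from layer j to l (mirror plus nearest-neighbor
#' mirrors) scaled by `(1 - alpha) / (L - 1)`.
#'
#' @param mx A `multiplex_network`.
#' @param seed_layer Layer index of the seed (1-based).
#' @param seed_sample Sample index (1-based) or sample id.
#' @param alphas RWRF layer weights (sum 1); default `rep(1/L, L)`.
#' @param alpha RWRNF seed-layer weight in `[0, 1]` (default 0.9).
#' @return A length-(L n) probability vector summing to 1.
#' @export
initial_distribution <- function(mx, seed_layer, seed_sample,
                                 alphas = NULL, alpha = 0.9) {
  n <- mx$n; L <- mx$L
  if (is.character(seed_sample)) {
    seed_sample <- match(seed_sample, mx$sample_ids)
    if (is.na(seed_sample)) stop("unknown seed sample id")
  }
  stopifnot(seed_layer >= 1L, seed_layer <= L,
            seed_sample >= 1L, seed_sample <= n)
  p0 <- numeric(L * n)
  if (mx$variant == "RWRF") {
    if (is.null(alphas)) alphas <- rep(1 / L, L)
    stopifnot(length(alphas) == L, abs(sum(alphas) - 1) < 1e-12)
    for (l in seq_len(L))
      p0[(l - 1L) * n + seed_sample] <- alphas[l]
  } else {
    stopifnot(alpha >= 0, alpha <= 1)
    p0[(seed_layer - 1L) * n + seed_sample] <- alpha
    for (l in setdiff(seq_len(L), seed_layer)) {
      a_row <- as.numeric(mx$couplings[[seed_layer]][[l]][seed_sample, ])
      p0[(l - 1L) * n + seq_len(n)] <- (1 - alpha) / (L - 1) * a_row
    }
  }
  p0
}

#' Random walk with restart by fixed-point iteration
#'
#' Iterates `p_{t+1} = (1 - gamma) W^T p_t + gamma p_0` until the L1
#' difference between successive iterates falls below `tol`.  Because W is
#' row-stochastic, every iterate remains a probability vector.
#'
#' @param w Row-stochastic transition matrix from [transition_matrix()].
#' @param p0 Initial/restart probability vector.
#' @param gamma Restart probability in `(0, 1]` (default 0.7).
#' @param tol L1 convergence threshold (default 1e-10).
#' @param max_iter Iteration cap (default 1000); exceeding it is an error
#'   that reports the last residual.
#' @return A list with `p_stable` (the stationary distribution) and
#'   `iterations` (number of updates performed).
#' @seealso [rwr_direct()] for the closed-form solution.
#' @export
rwr <- function(w, p0, gamma = 0.7, tol = 1e-10, max_iter = 1000) {
  stopifnot(gamma > 0, gamma <= 1)
  wt <- t(w)
  p <- p0
  for (it in seq_len(max_iter)) {
    pn <- as.numeric((1 - gamma) * (wt %*% p)) + gamma * p0
    delta <- sum(abs(pn - p))
    p <- pn
    if (delta < tol)
      return(list(p_stable = p, iterations = it))
  }
  stop("RWR did not converge within ", max_iter,
       " iterations (last L1 residual ", format(delta), ")")
}

#' Closed-form stationary distribution of the restart walk
#'
#' Solves the linear fixed-point system
#' `p = gamma (I - (1 - gamma) W^T)^{-1} p_0` directly; used as an exact
#' oracle for the iterative solver.
#'
#' @inheritParams rwr
#' @return The stationary probability vector.
#' @export
rwr_direct <- function(w, p0, gamma = 0.7) {
  stopifnot(gamma > 0, gamma <= 1)
  nn <- nrow(w)
  as.numeric(solve(diag(nn) - (1 - gamma) * t(w), gamma * p0))
}

#' Fuse a multiplex network into one integrated similarity network
#'
#' Runs the restart walk once from every node of the multiplex (L n seeds).
#' The stationary distribution of the seed (layer j, sample x) fills row x
#' of the layer-j proximity matrix S'_j (its within-layer block) and row x
#' of each cross block A'_{jl}.  The integrated network is the
#' symmetrized average of the per-layer blocks,
#' \deqn{S_{fusion} = \sum_j (S'_j + S'^T_j) / (2L),}
#' which for two layers is (S'_1 + S'_2 + S'_1^T + S'_2^T) / 4.  Seeds are
#' mutually independent, so the all-seed iteration is carried out as one
#' matrix iteration with converged columns frozen — bit-identical to
#' looping [rwr()] over seeds, only faster.
#'
#' @param mx A `multiplex_network`.
#' @param gamma Restart probability (default 0.7).
#' @param lambdas Layer stay/jump weights, see [transition_matrix()].
#' @param alphas,alpha Seed weights, see [initial_distribution()].
#' @param tol,max_iter Convergence control, see [rwr()].
#' @return An object of class `fused_network`: list with `s_fusion`
#'   (n x n symmetric), `s_prime` (list of L within-layer blocks),
#'   `cross` (nested list of A'_{jl} blocks), `iterations` (per-seed
#'   counts, length L n), `variant`, `sample_ids`, and the parameters.
#' @export
fuse_networks <- function(mx, gamma = 0.7, lambdas = NULL, alphas = NULL,
                          alpha = 0.9, tol = 1e-10, max_iter = 1000) {
  n <- mx$n; L <- mx$L; nn <- L * n
  w <- transition_matrix(mx, lambdas)
  wt <- t(w)

  # restart matrix: column (j-1)n + x is the seed distribution for (j, x)
  p0 <- matrix(0, nn, nn)
  for (j in seq_len(L)) {
    cols <- (j - 1L) * n + seq_len(n)
    for (l in seq_len(L)) {
      rows <- (l - 1L) * n + seq_len(n)
      if (mx$variant == "RWRF") {
        a_l <- if (is.null(alphas)) 1 / L else alphas[l]
        p0[cbind(rows, cols)] <- a_l
      } else {
        if (l == j) {
          p0[cbind(rows, cols)] <- alpha
        } else {
          p0[rows, cols] <- (1 - alpha) / (L - 1) *
            t(as.matrix(mx$couplings[[j]][[l]]))
        }
      }
    }
  }
  if (mx$variant == "RWRF" && !is.null(alphas))
    stopifnot(length(alphas) == L, abs(sum(alphas) - 1) < 1e-12)

  p <- p0
  iters <- integer(nn)
  active <- seq_len(nn)
  for (it in seq_len(max_iter)) {
    pn <- (1 - gamma) * (wt %*% p[, active, drop = FALSE]) +
      gamma * p0[, active, drop = FALSE]
    delta <- colSums(abs(pn - p[, active, drop = FALSE]))
    p[, active] <- pn
    iters[active] <- it
    active <- active[delta >= tol]
    if (length(active) == 0L) break
  }
  if (length(active) > 0L)
    stop("RWR failed to converge for seed(s) ",
         paste(utils::head(active, 5L), collapse = ", "),
         " within ", max_iter, " iterations")

  blk <- function(i) (i - 1L) * n + seq_len(n)
  s_prime <- lapply(seq_len(L), function(j) {
    m <- t(p[blk(j), blk(j), drop = FALSE])
    dimnames(m) <- list(mx$sample_ids, mx$sample_ids)
    m
  })
  cross <- lapply(seq_len(L), function(j) {
    lapply(seq_len(L), function(l) {
      if (j == l) return(NULL)
      t(p[blk(l), blk(j), drop = FALSE])
    })
  })
  s_fusion <- Reduce(`+`, lapply(s_prime, function(m) m + t(m))) / (2 * L)
  dimnames(s_fusion) <- list(mx$sample_ids, mx$sample_ids)

  structure(list(s_fusion = s_fusion, s_prime = s_prime, cross = cross,
                 iterations = iters, variant = mx$variant,
                 sample_ids = mx$sample_ids,
                 gamma = gamma, lambdas = lambdas, alphas = alphas,
                 alpha = alpha, tol = tol),
            class = "fused_network")
}

#' @export
print.fused_network <- function(x, ...) {
  cat("Fused similarity network (", x$variant, "): ",
      nrow(x$s_fusion), " samples\n", sep = "")
  cat("  RWR iterations per seed: median ",
      stats::median(x$iterations), ", max ", max(x$iterations), "\n",
      sep = "")
  invisible(x)
}
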