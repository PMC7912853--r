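# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's vectorized code paths.

# naive double-loop Euclidean distances (features x samples input)
oracle_distances <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    ss <- 0
    for (f in seq_len(nrow(m))) ss <- ss + (m[f, x] - m[f, y])^2
    d[x, y] <- sqrt(ss)
  }
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

# naive locally scaled exponential kernel
oracle_similarity <- function(m, mu = 0.5, n_neighbors = 20) {
  d <- oracle_distances(m)
  n <- ncol(m)
  nn <- min(n_neighbors, n - 1)
  mean_nb <- numeric(n)
  for (x in seq_len(n)) {
    dx <- sort(d[x, -x])
    mean_nb[x] <- mean(dx[seq_len(nn)])
  }
  s <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    e <- (mean_nb[x] + mean_nb[y] + d[x, y]) / 3
    s[x, y] <- if (e == 0) 1 else exp(-d[x, y]^2 / (mu * e))
  }
  diag(s) <- 1
  s
}

# exhaustive double-loop Dunn index
oracle_dunn <- function(labels, d) {
  ks <- unique(labels)
  diam <- 0
  for (k in ks) {
    idx <- which(labels == k)
    for (a in idx) for (b in idx) diam <- max(diam, d[a, b])
  }
  sep <- Inf
  for (k1 in ks) for (k2 in ks) {
    if (k1 == k2) next
    for (a in which(labels == k1)) for (b in which(labels == k2))
      sep <- min(sep, d[a, b])
  }
  sep / diam
}

# from-scratch multi-group log-rank chi-square (observed vs expected with
# the hypergeometric tie-corrected variance), two-group form
oracle_logrank_2g <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - e1)^2 / v
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

# random similarity-like layers: symmetric, positive entries, unit diagonal
random_layers <- function(n, L, seed) {
  set.seed(seed)
  lapply(seq_len(L), function(l) {
    a <- matrix(stats::runif(n * n, 0.05, 1), n, n)
    s <- (a + t(a)) / 2
    diag(s) <- 1
    rownames(s) <- colnames(s) <- sprintf("s%02d", seq_len(n))
    s
  })
}

# strip non-dimnames attributes (e.g. the kernel's local_scale) for
# comparisons against plain matrices
unclass_attr <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

# three well-separated Gaussian blobs in the plane, features x samples
blob_data <- function(n_per = 20, sep = 12, sd = 0.6, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(sep / 2, sep))
  labels <- rep(1:3, each = n_per)
  m <- t(centers[labels, ] + matrix(stats::rnorm(2 * 3 * n_per, sd = sd),
                                    ncol = 2))
  dimnames(m) <- list(c("f1", "f2"), sprintf("s%03d", seq_along(labels)))
  list(m = m, labels = labels)
}
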