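# Cluster-validity statistics, standard definitions from the
# cluster-validity literature.  Each function takes integer labels plus
# either a dissimilarity matrix `d` or a coordinate matrix `x`.
# Direction (maximize/minimize) is handled by the caller.

# sums of squares from pairwise distances: W_k via the identity
# sum_{i<j in c} d_ij^2 / n_c ; usable for non-Euclidean dissimilarities.
pooled_within_ss <- function(labels, d) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) < 2L) return(0)
    sum(d[idx, idx]^2) / (2 * length(idx))
  }, numeric(1)))
}

# Calinski-Harabasz pseudo-F (maximize)
index_calinski_harabasz <- function(labels, d) {
  n <- length(labels)
  k <- length(unique(labels))
  tot <- sum(d^2) / (2 * n)
  wk <- pooled_within_ss(labels, d)
  bk <- tot - wk
  if (wk <= 0) return(Inf)
  (bk / (k - 1)) / (wk / (n - k))
}

# mean silhouette width (maximize)
index_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
  mean(sil[, "sil_width"])
}

# Hubert & Levin C-index (minimize):
# (S_w - S_min) / (S_max - S_min), S_w = sum of within-cluster distances,
# S_min/S_max = sums of the n_w smallest/largest distances overall.
index_c <- function(labels, d) {
  n <- length(labels)
  ut <- upper.tri(d)
  all_d <- d[ut]
  same <- outer(labels, labels, "==")[ut]
  nw <- sum(same)
  if (nw == 0L) return(NA_real_)
  sw <- sum(all_d[same])
  sorted <- sort(all_d)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq.int(length(sorted) - nw + 1L, length(sorted))])
  if (smax == smin) return(0)
  (sw - smin) / (smax - smin)
}

# Rohlf's Tau (maximize): Kendall-type concordance between the pairwise
# distance vector and the within/between indicator.  s(+) counts
# (within, between) distance pairs where the within distance is smaller.
# Counting uses a sorted between-distance vector, so it is O(N log N).
index_tau <- function(labels, d) {
  ut <- upper.tri(d)
  all_d <- d[ut]
  same <- outer(labels, labels, "==")[ut]
  dw <- all_d[same]
  db <- sort(all_d[!same])
  nw <- length(dw); nb <- length(db)
  if (nw == 0L || nb == 0L) return(NA_real_)
  n_less <- findInterval(dw, db, left.open = TRUE)  # b strictly below w
  n_leq <- findInterval(dw, db)
  s_plus <- sum(nb - n_leq)   # within < between: concordant
  s_minus <- sum(n_less)      # within > between: discordant
  nt <- nw + nb
  v0 <- nt * (nt - 1) / 2
  (s_plus - s_minus) / sqrt(as.numeric(nw) * nb * v0)
}

# Ratkowsky-Lance (maximize): sqrt(mean_j(BGSS_j / TSS_j) / k)
index_ratkowsky_lance <- function(labels, x) {
  k <- length(unique(labels))
  grand <- colMeans(x)
  tss <- colSums((x - rep(grand, each = nrow(x)))^2)
  bgss <- numeric(ncol(x))
  for (idx in split(seq_len(nrow(x)), labels)) {
    cm <- colMeans(x[idx, , drop = FALSE])
    bgss <- bgss + length(idx) * (cm - grand)^2
  }
  keep <- tss > .Machine$double.eps
  if (!any(keep)) return(NA_real_)
  sqrt(mean(bgss[keep] / tss[keep]) / k)
}

# SD index, average-scattering component (minimize):
# mean over clusters of ||var(cluster)|| / ||var(all)||
index_sd_scat <- function(labels, x) {
  pop_var <- function(m) colSums((m - rep(colMeans(m), each = nrow(m)))^2) /
    nrow(m)
  total <- sqrt(sum(pop_var(x)^2))
  if (total == 0) return(NA_real_)
  scat <- vapply(split(seq_len(nrow(x)), labels), function(idx) {
    sqrt(sum(pop_var(x[idx, , drop = FALSE])^2))
  }, numeric(1))
  mean(scat) / total
}

# SD index, total-separation component (minimize):
# (Dmax / Dmin) * sum_k 1 / sum_z ||c_k - c_z||
index_sd_dis <- function(labels, x) {
  cents <- do.call(rbind, lapply(split(seq_len(nrow(x)), labels),
                                 function(idx)
                                   colMeans(x[idx, , drop = FALSE])))
  dc <- as.matrix(stats::dist(cents))
  off <- dc[upper.tri(dc)]
  if (any(off == 0)) return(Inf)
  (max(off) / min(off)) * sum(1 / rowSums(dc))
}
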