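#' Dunn index of a partition
#'
#' The Dunn index is the smallest between-cluster nearest-pair distance
#' divided by the largest within-cluster diameter,
#' \deqn{DI = \min_{k \ne l} dist(C_k, C_l) / \max_m diam(C_m),}
#' ranging over `[0, Inf)`; larger is better.
#'
#' @param labels Integer/factor cluster labels (or a `spectral_clustering`
#'   object), >= 2 nonempty clusters.
#' @param d Symmetric dissimilarity matrix on the same samples, e.g. from
#'   [similarity_to_distance()] or [pairwise_distances()].
#' @param singleton What to do when every cluster has zero diameter
#'   (e.g. all-singleton partitions): `"error"` (default) or `"inf"`.
#' @return Scalar Dunn index.
#' @export
dunn_index <- function(labels, d, singleton = c("error", "inf")) {
  singleton <- match.arg(singleton)
  if (inherits(labels, "spectral_clustering")) labels <- labels$labels
  groups <- split(seq_along(labels), labels)
  if (length(groups) < 2L) stop("need at least two clusters")
  diam <- max(vapply(groups, function(idx) {
    if (length(idx) < 2L) 0 else max(d[idx, idx])
  }, numeric(1)))
  if (diam == 0) {
    if (singleton == "inf") return(Inf)
    stop("maximum intra-cluster diameter is zero")
  }
  ks <- seq_along(groups)
  sep <- Inf
  for (a in ks) for (b in ks) {
    if (a < b)
      sep <- min(sep, min(d[groups[[a]], groups[[b]]]))
  }
  sep / diam
}

#' Normalized mutual information between two labelings
#'
#' Mutual information of the joint label contingency table, normalized to
#' `[0, 1]`.  The default normalization divides by the arithmetic mean of
#' the two label entropies; `variant = "sqrt"` divides by their geometric
#' mean.  NMI is 1 exactly when the partitions coincide up to renaming of
#' labels, and 0 when they are independent.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @param variant `"mean"` (default) or `"sqrt"` normalization.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(a, b, variant = c("mean", "sqrt")) {
  variant <- match.arg(variant)
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- ent(pi_); hb <- ent(p_j)
  if (ha == 0 && hb == 0) return(1)  # both trivial partitions: identical
  denom <- if (variant == "mean") (ha + hb) / 2 else sqrt(ha * hb)
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}

#' Log-rank test for survival differences between clusters
#'
#' Standard multi-group log-rank chi-square test (with the usual tie
#' correction in the variance), wrapping [survival::survdiff()].  The
#' paper-style significance call uses threshold 0.05.
#'
#' @param labels Cluster labels named by sample id (or a
#'   `spectral_clustering` object).
#' @param surv Data frame with columns `sample_id`, `time`, `event`
#'   (see [read_survival_table()]).
#' @param threshold Significance threshold (default 0.05).
#' @return List with `chisq`, `df`, `p_value` and `significant`.
#' @export
logrank_test <- function(labels, surv, threshold = 0.05) {
  if (inherits(labels, "spectral_clustering")) labels <- labels$labels
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by sample id")
  hit <- match(ids, surv$sample_id)
  if (anyNA(hit))
    stop("samples missing from survival table: ",
         paste(utils::head(ids[is.na(hit)], 5L), collapse = ", "))
  df <- data.frame(time = surv$time[hit], event = surv$event[hit],
                   group = factor(labels))
  if (nlevels(df$group) < 2L) stop("need at least two groups")
  if (sum(df$event) == 0L) stop("no events observed")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = df)
  dfree <- length(sd_fit$n) - 1L
  p <- stats::pchisq(sd_fit$chisq, df = dfree, lower.tail = FALSE)
  list(chisq = unname(sd_fit$chisq), df = dfree, p_value = p,
       significant = p < threshold)
}

#' Rank individual features by agreement with a reference partition
#'
#' For every feature of every omics layer, a single-feature similarity
#' network is built with the same locally scaled exponential kernel as the
#' full pipeline, spectrally clustered with the reference partition's k,
#' and scored by NMI against the reference labels.  Features whose
#' one-dimensional structure reproduces the integrated subtypes rank
#' highest.
#'
#' @param omics Named list of feature-by-sample matrices (no missing
#'   values) on the reference partition's samples.
#' @param reference A `spectral_clustering` object or an integer label
#'   vector; its number of distinct labels fixes k.
#' @param mu,n_neighbors Kernel parameters, as in [similarity_network()].
#' @param seed RNG seed forwarded to each [spectral_clustering()] call.
#' @param constant How to score constant (zero-variance) features:
#'   `"drop"` (default, omitted from the ranking with a warning) or
#'   `"zero"` (kept with NMI 0).
#' @return A data.frame (`layer`, `feature`, `nmi`) sorted by decreasing
#'   NMI; ties broken by layer then feature order, so the ranking is
#'   deterministic.
#' @seealso [select_top_features()]
#' @export
rank_features <- function(omics, reference, mu = 0.5, n_neighbors = 20,
                          seed = 42, constant = c("drop", "zero")) {
  constant <- match.arg(constant)
  if (inherits(reference, "spectral_clustering"))
    reference <- reference$labels
  k <- length(unique(reference))
  if (is.null(names(omics)))
    names(omics) <- paste0("layer", seq_along(omics))
  out <- list()
  n_const <- 0L
  for (lname in names(omics)) {
    m <- omics[[lname]]
    if (ncol(m) != length(reference))
      stop("layer '", lname, "' sample count mismatch")
    feats <- rownames(m)
    if (is.null(feats)) feats <- paste0("f", seq_len(nrow(m)))
    scores <- rep(NA_real_, nrow(m))
    for (i in seq_len(nrow(m))) {
      v <- m[i, , drop = FALSE]
      if (stats::sd(v) < .Machine$double.eps^0.5) {
        n_const <- n_const + 1L
        if (constant == "zero") scores[i] <- 0
        next
      }
      s1 <- similarity_from_features(v, mu = mu, n_neighbors = n_neighbors)
      cl <- spectral_clustering(s1, k, seed = seed)
      scores[i] <- nmi(cl$labels, reference)
    }
    keep <- !is.na(scores)
    out[[lname]] <- data.frame(layer = rep(lname, sum(keep)),
                               feature = feats[keep],
                               nmi = scores[keep],
                               stringsAsFactors = FALSE)
  }
  if (n_const > 0L && constant == "drop")
    warning(n_const, " constant feature(s) dropped from the ranking")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab[order(-tab$nmi, seq_len(nrow(tab))), , drop = FALSE]
}

#' Select the top-ranked features
#'
#' Cuts a [rank_features()] table either to the `n` best features overall
#' or to the best `frac` fraction, optionally within one layer — the
#' selection rules used for marker reporting (e.g. top 200 overall, or the
#' top 5\% of one omics layer).
#'
#' @param ranking Data frame from [rank_features()].
#' @param n Number of features to keep (mutually exclusive with `frac`).
#' @param frac Fraction in (0, 1] of features to keep.
#' @param layer Optional layer name to restrict to before cutting.
#' @return The subset of `ranking`, still sorted by decreasing NMI.
#' @export
select_top_features <- function(ranking, n = NULL, frac = NULL,
                                layer = NULL) {
  if (!is.null(layer)) ranking <- ranking[ranking$layer == layer, ,
                                          drop = FALSE]
  if (is.null(n) == is.null(frac))
    stop("give exactly one of n or frac")
  if (is.null(n)) n <- ceiling(frac * nrow(ranking))
  utils::head(ranking, n)
}
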