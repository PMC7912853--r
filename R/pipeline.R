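#' Run the full integration pipeline
#'
#' Orchestrates preprocess -> similarity -> multiplex -> fuse -> cluster
#' -> evaluate, and (optionally) writes all artifacts plus a
#' machine-readable run manifest to an output directory.  Stage failures
#' are re-signalled with the stage name attached.
#'
#' @param matrices Named list of feature-by-sample matrices, or a
#'   character vector of paths readable by [read_feature_matrix()].
#' @param variant `"RWRF"` (default) or `"RWRNF"`.
#' @param preprocess If `TRUE` (default) run [preprocess_layers()] first;
#'   set to `FALSE` for matrices that are already aligned, complete and
#'   standardized.
#' @param mu,n_neighbors Similarity-kernel parameters (defaults 0.5, 20).
#' @param m,beta RWRNF coupling parameters (defaults 10, 0.9).
#' @param gamma,lambdas,alphas,alpha,tol,max_iter Walk parameters, see
#'   [fuse_networks()].
#' @param k Number of clusters; if `NULL`, the first recommendation of the
#'   validity-index vote over `k_range` is used.
#' @param k_range Candidate cluster numbers scanned when `k` is `NULL`
#'   (default `2:8`).
#' @param survival Optional survival data frame (or path) for the
#'   log-rank evaluation.
#' @param seed RNG seed for clustering (default 42).
#' @param outdir Optional output directory; when given, writes
#'   `s_fusion.tsv`, `labels.tsv`, `validity_table.tsv` (if scanned),
#'   `metrics.json` and `manifest.json`.
#' @return List with `s_fusion`, `fused` (the full `fused_network`),
#'   `clustering`, `validity` (or `NULL`), `metrics` and `manifest`.
#' @export
run_pipeline <- function(matrices,
                         variant = c("RWRF", "RWRNF"),
                         preprocess = TRUE,
                         mu = 0.5, n_neighbors = 20,
                         m = 10, beta = 0.9,
                         gamma = 0.7, lambdas = NULL, alphas = NULL,
                         alpha = 0.9, tol = 1e-10, max_iter = 1000,
                         k = NULL, k_range = 2:8,
                         survival = NULL, seed = 42, outdir = NULL) {
  variant <- match.arg(variant)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  mats <- stage("input", {
    if (is.character(matrices)) {
      nm <- if (!is.null(names(matrices))) names(matrices)
            else tools::file_path_sans_ext(basename(matrices))
      matrices <- lapply(matrices, read_feature_matrix)
      names(matrices) <- nm
    }
    if (length(matrices) < 2L) stop("need at least two omics layers")
    if (is.null(names(matrices)))
      names(matrices) <- paste0("layer", seq_along(matrices))
    matrices
  })

  if (preprocess) mats <- stage("preprocess", preprocess_layers(mats))
  else mats <- stage("preprocess", align_samples(mats))

  sims <- stage("similarity", lapply(mats, similarity_from_features,
                                     mu = mu, n_neighbors = n_neighbors))
  mx <- stage("multiplex", assemble_multiplex(sims, variant = variant,
                                              m = m, beta = beta))
  fused <- stage("fuse", fuse_networks(mx, gamma = gamma,
                                       lambdas = lambdas, alphas = alphas,
                                       alpha = alpha, tol = tol,
                                       max_iter = max_iter))

  validity <- NULL
  if (is.null(k)) {
    validity <- stage("cluster",
                      validity_index_table(fused$s_fusion,
                                           k_range = k_range, seed = seed))
    k <- validity$recommended[1L]
  }
  cl <- stage("cluster", spectral_clustering(fused$s_fusion, k,
                                             seed = seed))

  metrics <- stage("evaluate", {
    d_fused <- similarity_to_distance(fused$s_fusion)
    out <- list(k = k,
                dunn = dunn_index(cl$labels, d_fused),
                rwr_iterations_median = stats::median(fused$iterations),
                rwr_iterations_max = max(fused$iterations))
    if (!is.null(survival)) {
      if (is.character(survival)) survival <- read_survival_table(survival)
      lr <- logrank_test(cl$labels, survival)
      out$logrank_p <- lr$p_value
      out$logrank_significant <- lr$significant
    }
    if (!is.null(validity))
      out$recommended_k <- as.integer(validity$recommended)
    out
  })

  manifest <- list(
    variant = variant, mu = mu, n_neighbors = n_neighbors,
    m = m, beta = beta, gamma = gamma,
    lambdas = if (is.null(lambdas)) rep(1 / length(mats), length(mats))
              else lambdas,
    alphas = alphas, alpha = alpha, tol = tol, max_iter = max_iter,
    k = k, k_range = k_range, seed = seed,
    layers = names(mats),
    n_samples = ncol(mats[[1L]]),
    n_features = vapply(mats, nrow, integer(1)),
    preprocess = preprocess,
    iterations_per_seed = fused$iterations)

  if (!is.null(outdir)) {
    stage("output", {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      write_feature_matrix(fused$s_fusion,
                           file.path(outdir, "s_fusion.tsv"),
                           id_col = "sample_id")
      utils::write.table(
        data.frame(sample_id = names(cl$labels),
                   cluster = as.integer(cl$labels)),
        file.path(outdir, "labels.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(validity))
        utils::write.table(validity$table,
                           file.path(outdir, "validity_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  list(s_fusion = fused$s_fusion, fused = fused, clustering = cl,
       validity = validity, metrics = metrics, manifest = manifest)
}
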