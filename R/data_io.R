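#' Read a feature-by-sample omics matrix from delimited text
#'
#' Reads one omics layer (e.g. mRNA expression, DNA methylation beta values,
#' miRNA expression) from a TSV or CSV file with a header row and an id
#' column.  The delimiter is chosen from the file extension (`.csv` means
#' comma, anything else tab).  Empty cells and `NA` tokens
#' (case-insensitive) become missing values; any other non-numeric cell is
#' an error naming the offending row and column.
#'
#' @param path Path to a delimited text file.  The first column (or the
#'   implicit row-name column) holds ids, the header holds the other
#'   dimension's ids.
#' @param orientation Either `"features-by-samples"` (rows are features,
#'   the layout used throughout this package) or `"samples-by-features"`,
#'   in which case the matrix is transposed after reading.
#' @param layer_name Optional name for the omics layer, stored as the
#'   `"layer_name"` attribute.
#' @param na_tokens Character vector of cell values (matched
#'   case-insensitively after trimming whitespace) treated as missing.
#' @param sep Field separator; `NULL` (default) auto-detects from the
#'   extension.
#' @return A numeric matrix, features in rows and samples in columns, with
#'   dimnames taken from the file in file order.
#' @seealso [write_feature_matrix()], [preprocess_layers()]
#' @export
read_feature_matrix <- function(path,
                                orientation = c("features-by-samples",
                                                "samples-by-features"),
                                layer_name = NULL,
                                na_tokens = c("", "NA"),
                                sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  rn <- rownames(raw)
  if (identical(rn, as.character(seq_len(nrow(raw))))) {
    # ids live in the first (named) column
    ids <- raw[[1L]]
    vals <- as.matrix(raw[, -1L, drop = FALSE])
  } else {
    # header was one field short: read.table already used column 1 as names
    ids <- rn
    vals <- as.matrix(raw)
  }
  if (anyDuplicated(ids))
    stop("duplicate row ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(vals)
  if (anyDuplicated(cn))
    stop("duplicate column ids in '", path, "': ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  missing_mask <- is.na(vals) |
    matrix(tolower(trimws(vals)) %in% tolower(na_tokens),
           nrow = nrow(vals))
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !missing_mask, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in '%s'",
                 vals[bad[1L, , drop = FALSE]], ids[bad[1L, 1L]],
                 cn[bad[1L, 2L]], path))
  num[missing_mask] <- NA_real_
  dimnames(num) <- list(ids, cn)
  if (orientation == "samples-by-features") num <- t(num)
  if (!is.null(layer_name)) attr(num, "layer_name") <- layer_name
  num
}

#' Write a feature-by-sample matrix as delimited text
#'
#' Inverse of [read_feature_matrix()]: writes a header row of sample ids and
#' an id column of feature ids.  Missing values are written as empty cells.
#'
#' @param m Numeric matrix with dimnames (features x samples).
#' @param path Output path; `.csv` selects comma separation, otherwise tab.
#' @param id_col Name for the id column header.
#' @param digits Number of significant digits written (`NA` for full
#'   precision via R's default formatting).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, id_col = "feature_id",
                                 digits = NA) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- m
  if (!is.na(digits)) out <- signif(out, digits)
  df <- data.frame(rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a survival table
#'
#' Expects a delimited text file with columns `sample_id`, `time` and
#' `event` (1 = event observed, 0 = censored).
#'
#' @param path Path to a TSV/CSV file.
#' @return A data.frame with columns `sample_id` (character), `time`
#'   (numeric, non-negative) and `event` (integer 0/1).
#' @export
read_survival_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  if (any(df$time < 0)) stop("negative survival times")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df$event <- as.integer(df$event)
  df
}

#' Restrict omics layers to their shared samples
#'
#' Only samples profiled on every layer are retained; each matrix is
#' reduced to the ordered intersection of all sample id sets (order taken
#' from the first matrix) with columns reordered consistently.
#'
#' @param matrices List of at least two feature-by-sample matrices with
#'   sample ids as column names.
#' @return List of matrices, all with identical `colnames`.
#' @export
align_samples <- function(matrices) {
  if (length(matrices) < 2L) stop("need at least two matrices")
  common <- Reduce(intersect, lapply(matrices, colnames))
  if (length(common) == 0L) stop("no samples shared by all layers")
  lapply(matrices, function(m) m[, common, drop = FALSE])
}

#' Drop samples and features with excessive missingness
#'
#' Samples (columns) whose missing fraction exceeds `sample_thresh` are
#' removed first; features (rows) whose missing fraction over the
#' *remaining* samples exceeds `feature_thresh` are removed second.
#' Comparisons are strict (`>`), so a fraction exactly at the threshold is
#' kept.  Row and column order is otherwise preserved.
#'
#' @param m Feature-by-sample matrix, possibly with `NA` entries.
#' @param sample_thresh,feature_thresh Maximum tolerated missing fraction,
#'   in `(0, 1]`.  Default 0.2 (drop above 20\% missing).
#' @return The filtered matrix.
#' @export
filter_missingness <- function(m, sample_thresh = 0.2,
                               feature_thresh = 0.2) {
  stopifnot(sample_thresh > 0, sample_thresh <= 1,
            feature_thresh > 0, feature_thresh <= 1)
  keep_s <- colMeans(is.na(m)) <= sample_thresh
  if (!any(keep_s)) stop("all samples exceed the missingness threshold")
  m <- m[, keep_s, drop = FALSE]
  keep_f <- rowMeans(is.na(m)) <= feature_thresh
  if (!any(keep_f)) stop("all features exceed the missingness threshold")
  m[keep_f, , drop = FALSE]
}

#' Impute missing entries by the per-feature mean
#'
#' Each missing cell is replaced by the mean of that feature's observed
#' values across the other samples.  Observed cells are never changed.
#'
#' @param m Feature-by-sample matrix.
#' @return The matrix with no remaining `NA`s.
#' @export
impute_missing <- function(m) {
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(m)
  means <- rowMeans(m, na.rm = TRUE)
  fully_missing <- !is.finite(means) & rowSums(!is.na(m)) == 0L
  if (any(fully_missing))
    stop("feature(s) with no observed value: ",
         paste(utils::head(rownames(m)[fully_missing], 5L), collapse = ", "),
         " (filter them first)")
  m[idx] <- means[idx[, 1L]]
  m
}

#' Standardize every feature to mean 0 and standard deviation 1
#'
#' Rows are centred and scaled so each feature has mean 0 and standard
#' deviation 1.  The population convention (divide by n) is the default;
#' `sd_type = "sample"` divides by n-1.  Features with zero variance carry
#' no between-sample information and are dropped with a warning.
#'
#' @param m Feature-by-sample matrix with no missing values.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The standardized matrix, possibly with fewer rows.
#' @export
normalize_features <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (anyNA(m)) stop("normalize_features requires a complete matrix")
  centred <- m - rowMeans(m)
  n <- ncol(m)
  denom <- if (sd_type == "population") n else n - 1L
  sds <- sqrt(rowSums(centred^2) / denom)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance feature(s): ",
            paste(utils::head(rownames(m)[zero], 5L), collapse = ", "))
    centred <- centred[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  if (nrow(centred) == 0L) stop("no features left after dropping zero variance")
  centred / sds
}

#' Full preprocessing chain for a set of omics layers
#'
#' Applies, in order: (1) restriction to the samples present on every
#' layer, (2) per-layer missingness filtering of samples then features,
#' (3) re-alignment (the filter may drop different samples per layer),
#' (4) per-feature mean imputation of the remaining missing cells, and
#' (5) per-feature standardization.
#'
#' @param matrices List of feature-by-sample matrices.
#' @param sample_thresh,feature_thresh Passed to [filter_missingness()].
#' @param sd_type Passed to [normalize_features()].
#' @return List of complete, standardized matrices on a common sample set.
#' @export
preprocess_layers <- function(matrices, sample_thresh = 0.2,
                              feature_thresh = 0.2,
                              sd_type = "population") {
  mats <- align_samples(matrices)
  mats <- lapply(mats, filter_missingness,
                 sample_thresh = sample_thresh,
                 feature_thresh = feature_thresh)
  mats <- align_samples(mats)
  mats <- lapply(mats, impute_missing)
  lapply(mats, normalize_features, sd_type = sd_type)
}
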