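test_that("reading a delimited matrix preserves ids, orientation and NAs", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tA\tB",
               "g1\t1.5\t2",
               "g2\t\t4",
               "g3\t-1\t0.25"), tsv)
  m <- read_feature_matrix(tsv)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("g1", "g2", "g3"))
  expect_identical(colnames(m), c("A", "B"))
  expect_identical(sum(is.na(m)), 1L)
  expect_true(is.na(m["g2", "A"]))
  expect_equal(m["g3", "B"], 0.25)

  # samples-by-features file yields the transposed matrix
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2\tg3",
               "A\t1.5\t\t-1",
               "B\t2\t4\t0.25"), tsv2)
  m2 <- read_feature_matrix(tsv2, orientation = "samples-by-features")
  expect_equal(m2, m)
})

test_that("write -> read round trip reproduces values", {
  set.seed(11)
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  m[2, 3] <- NA
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(m, path)
  m2 <- read_feature_matrix(path)
  expect_equal(m2, m, tolerance = 1e-12)
})

test_that("malformed input is rejected with informative errors", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tA\tB", "g1\t1\t2", "g1\t3\t4"), tsv)
  expect_error(read_feature_matrix(tsv), "duplicate")
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tA\tB", "g1\t1\tx2"), tsv2)
  expect_error(read_feature_matrix(tsv2), "g1.*B|B.*g1")
})

test_that("sample alignment takes the ordered intersection", {
  mk <- function(ids) matrix(seq_along(ids), 1, length(ids),
                             dimnames = list("f", ids))
  out <- align_samples(list(mk(c("A", "B", "C")), mk(c("B", "C", "D"))))
  expect_identical(colnames(out[[1]]), c("B", "C"))
  expect_identical(colnames(out[[2]]), c("B", "C"))

  same <- align_samples(list(mk(c("A", "B")), mk(c("A", "B"))))
  expect_identical(colnames(same[[1]]), c("A", "B"))

  expect_error(align_samples(list(mk(c("A")), mk(c("B")))), "no samples")

  # three layers sharing 76 of 100 ids
  ids <- sprintf("p%03d", 1:100)
  set.seed(3)
  subsets <- lapply(1:3, function(i) {
    drop <- sample(setdiff(ids, ids[1:76]), 8)
    mk(setdiff(ids, drop))
  })
  shared <- Reduce(intersect, lapply(subsets, colnames))
  aligned <- align_samples(subsets)
  expect_true(all(vapply(aligned, ncol, integer(1)) == length(shared)))
  expect_gte(length(shared), 76L)
})

test_that("missingness filter drops samples first, then features, strictly", {
  m <- matrix(rnorm(25), 5, 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:5)))
  expect_identical(filter_missingness(m), m)  # no missing: no-op

  # a sample with 3 of 10 features missing (30% > 20%) is dropped
  m10 <- matrix(rnorm(30), 10, 3,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:3)))
  m10[1:3, 2] <- NA
  expect_identical(colnames(filter_missingness(m10)), c("s1", "s3"))

  # 5x5 toy: one 40%-missing sample and one feature missing on 3 of the
  # 4 remaining samples -> 4x4
  toy <- m
  toy[1, 1:3] <- NA      # feature f1 missing for s1..s3 (20% per sample)
  toy[2:3, 5] <- NA      # sample s5 missing 2/5 = 40%
  out <- filter_missingness(toy)
  expect_identical(dim(out), c(4L, 4L))
  expect_false("s5" %in% colnames(out))
  expect_false("f1" %in% rownames(out))
  # one pass reaches a fixed point here
  expect_identical(filter_missingness(out), out)
})

test_that("mean imputation fills exactly the missing cells", {
  m <- rbind(f1 = c(1, 3, NA), f2 = c(2, 2, 2))
  colnames(m) <- paste0("s", 1:3)
  out <- impute_missing(m)
  expect_equal(out["f1", "s3"], 2)
  expect_false(anyNA(out))

  expect_identical(impute_missing(m[, 1:2]), m[, 1:2])  # complete: identity

  # random masking: imputed values equal the observed per-feature means,
  # observed cells untouched
  set.seed(42)
  full <- matrix(rnorm(300), 15, 20,
                 dimnames = list(paste0("f", 1:15), paste0("s", 1:20)))
  masked <- full
  holes <- sample(length(full), 30)
  masked[holes] <- NA
  out2 <- impute_missing(masked)
  expect_equal(out2[-holes], full[-holes])
  mns <- rowMeans(masked, na.rm = TRUE)
  idx <- which(is.na(masked), arr.ind = TRUE)
  expect_equal(out2[idx], unname(mns[idx[, 1]]))

  allna <- rbind(f1 = c(NA_real_, NA_real_), f2 = c(1, 2))
  expect_error(impute_missing(allna), "no observed")
})

test_that("feature standardization hits mean 0 / sd 1 and drops constants", {
  m <- rbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(-4, 0, 9))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(out <- normalize_features(m), "zero-variance")
  expect_identical(rownames(out), c("f1", "f3"))
  expect_equal(unname(rowMeans(out)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(out^2))), c(1, 1), tolerance = 1e-12)
  # idempotence on an already standardized matrix
  expect_equal(normalize_features(out), out, tolerance = 1e-12)
  # sample-sd convention
  out2 <- normalize_features(m[c(1, 3), ], sd_type = "sample")
  expect_equal(unname(apply(out2, 1, stats::sd)), c(1, 1), tolerance = 1e-12)
})

test_that("the full preprocessing chain yields aligned, complete, standardized layers", {
  set.seed(7)
  ids <- sprintf("p%02d", 1:40)
  mats <- lapply(1:3, function(l) {
    keep <- sort(sample(40, 34 + l))
    m <- matrix(rnorm(25 * length(keep)), 25, length(keep),
                dimnames = list(sprintf("l%d_f%02d", l, 1:25), ids[keep]))
    m[sample(length(m), 20)] <- NA
    m
  })
  out <- preprocess_layers(mats)
  ids_out <- colnames(out[[1]])
  for (m in out) {
    expect_identical(colnames(m), ids_out)
    expect_false(anyNA(m))
    expect_lt(max(abs(rowMeans(m))), 1e-10)
    expect_lt(max(abs(sqrt(rowMeans(m^2)) - 1)), 1e-10)
  }
})
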