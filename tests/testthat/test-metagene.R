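make_track <- function(depth) {
  structure(list(
    chrom_lengths = vapply(depth, length, integer(1)),
    depth = depth, n_counted = 0L, n_skipped = 0L),
    class = "coverage_track")
}

feat <- function(id = "f1", chrom = "chrI", start = 1L, end = 5L,
                 strand = "+") {
  structure(data.frame(id = id, chrom = chrom, start = start, end = end,
                       strand = strand, feature_type = "CDS",
                       stringsAsFactors = FALSE),
            class = c("genomic_features", "data.frame"))
}

test_that("extract_raw slices 1-based inclusive and reverses minus strand", {
  tr <- make_track(list(chrI = c(0, 0, 1, 2, 3, 0)))
  expect_equal(extract_raw(tr, feat(start = 3L, end = 5L)), c(1, 2, 3))
  expect_equal(extract_raw(tr, feat(start = 3L, end = 5L, strand = "-")),
               c(3, 2, 1))
  expect_equal(extract_raw(tr, feat(start = 3L, end = 5L, strand = "-"),
                           reverse_minus = FALSE), c(1, 2, 3))
  expect_warning(out <- extract_raw(tr, feat(start = 4L, end = 9L)),
                 "out of bounds")
  expect_null(out)
})

test_that("normalize_length matches hand-computed and oracle values", {
  expect_equal(normalize_length(c(2, 4, 6, 8), 2), c(3, 7))
  # r = 1.5: windows [0,1.5) and [1.5,3) of the step function
  expect_equal(normalize_length(c(1, 2, 3), 2), c(4 / 3, 8 / 3))
  expect_equal(mean(normalize_length(c(1, 2, 3), 2)), 2)
  # constants map to constants for up- and downsampling
  expect_equal(normalize_length(rep(7, 13), 5), rep(7, 5))
  expect_equal(normalize_length(rep(7, 3), 11), rep(7, 11))
  expect_error(normalize_length(numeric(0), 5), "m >= 1")

  set.seed(99)
  for (i in 1:25) {
    m <- sample(1:40, 1)
    L <- sample(1:40, 1)
    raw <- round(runif(m, 0, 20), 3)
    expect_equal(normalize_length(raw, L), oracle_normalize(raw, L),
                 tolerance = 1e-12)
  }
})

test_that("normalize_length preserves the mean and the identity", {
  set.seed(123)
  worst <- 0
  for (i in 1:1000) {
    m <- sample(1:200, 1)
    L <- sample(1:200, 1)
    raw <- runif(m, 0, 50)
    out <- normalize_length(raw, L)
    expect_length(out, L)
    worst <- max(worst, abs(mean(out) - mean(raw)))
  }
  expect_lt(worst, 1e-9)
  raw <- runif(37)
  expect_identical(normalize_length(raw, 37), raw)
})

test_that("downsampling composes when the ratios are integral", {
  set.seed(7)
  raw <- runif(120, 0, 10)
  via <- normalize_length(normalize_length(raw, 24), 8)
  direct <- normalize_length(raw, 8)
  expect_equal(via, direct, tolerance = 1e-9)
})

test_that("build_matrix composes rows in annotation order and logs skips", {
  tr <- make_track(list(chrI = c(1, 2, 3, 4, 5, 6, 7, 8),
                        chrII = c(0, 0, 0, 0)))
  feats <- rbind(feat("a", start = 1L, end = 4L),
                 feat("b", start = 5L, end = 8L),
                 feat("z", chrom = "chrII", start = 1L, end = 4L))
  mat <- build_matrix(tr, feats, L = 4)
  expect_equal(rownames(mat), c("a", "b", "z"))
  expect_equal(unname(mat["a", ]), c(1, 2, 3, 4))
  expect_equal(unname(mat["z", ]), rep(0, 4)) # zero coverage retained
  expect_equal(attr(mat, "skipped"), 0L)

  # out-of-bounds features are dropped; chromosomes absent from the track too
  feats2 <- rbind(feats, feat("oob", start = 6L, end = 99L),
                  feat("nochrom", chrom = "chrX"))
  warns <- capture_warnings(mat2 <- build_matrix(tr, feats2, L = 4))
  expect_equal(rownames(mat2), c("a", "b", "z"))
  expect_equal(attr(mat2, "skipped"), 2L)
  expect_match(warns, "absent from the alignment", all = FALSE)

  expect_error(suppressWarnings(
    build_matrix(tr, feat("only", start = 7L, end = 99L))), "all features")
})

test_that("log2-ratio mode applies the pseudocount per base before binning", {
  tr <- make_track(list(chrI = rep(3, 8)))
  ctrl <- make_track(list(chrI = rep(1, 8)))
  mat <- build_matrix(tr, feat(start = 1L, end = 8L), L = 4, control = ctrl)
  expect_equal(unname(mat[1, ]), rep(1, 4)) # log2(4/2) = 1 everywhere
  # negative values are allowed in ratio mode
  ctrl2 <- make_track(list(chrI = rep(7, 8)))
  mat2 <- build_matrix(tr, feat(start = 1L, end = 8L), L = 4,
                       control = ctrl2)
  expect_true(all(mat2 < 0))
})

test_that("row scaling divides by the row mean and spares zero rows", {
  tr <- make_track(list(chrI = c(2, 4, 6, 8, 0, 0, 0, 0)))
  feats <- rbind(feat("a", start = 1L, end = 4L),
                 feat("zero", start = 5L, end = 8L))
  mat <- build_matrix(tr, feats, L = 4, scale_rows = TRUE)
  expect_equal(unname(rowMeans(mat)), c(1, 0))
  expect_equal(unname(mat["a", ]), c(2, 4, 6, 8) / 5)
})
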