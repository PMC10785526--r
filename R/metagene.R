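# Metagene core: slice per-feature coverage out of coverage tracks and
# length-normalize every vector to a common number of bins, producing the
# matrix handed to the clustering step.

#' Extract the raw coverage vector of one feature
#'
#' Slices `depth[start..end]` (1-based, inclusive) for the feature's
#' chromosome. With `reverse_minus = TRUE` (default) minus-strand features
#' are reversed so that index 1 is always the 5' end, the usual metagene
#' orientation.
#'
#' @param track a `coverage_track` from [build_coverage()].
#' @param feature one-row `genomic_features` data frame (or any list with
#'   `chrom`, `start`, `end`, `strand`).
#' @param reverse_minus reverse minus-strand vectors? Default `TRUE`.
#' @return numeric vector of length `end - start + 1`, or `NULL` (with a
#'   warning) when the feature lies outside its chromosome's bounds.
#' @export
extract_raw <- function(track, feature, reverse_minus = TRUE) {
  chrom <- feature$chrom
  if (!chrom %in% names(track$depth)) {
    warning("feature ", feature$id, " on chromosome absent from alignment: ",
            chrom)
    return(NULL)
  }
  n <- track$chrom_lengths[[chrom]]
  if (feature$start < 1L || feature$end > n) {
    warning("feature ", feature$id, " out of bounds for ", chrom,
            " (LN=", n, "); skipped")
    return(NULL)
  }
  v <- as.numeric(track$depth[[chrom]][feature$start:feature$end])
  if (reverse_minus && identical(feature$strand, "-")) {
    v <- rev(v)
  }
  v
}

#' Length-normalize a coverage vector to L bins
#'
#' Resamples a per-base vector of length `m` to `L` bins by averaging over
#' consecutive windows of real-valued width `r = m / L` (the normalization
#' ratio), weighting boundary positions by their fractional overlap with
#' each window. This is the exact extension of "average over windows of
#' size r" to non-integer ratios: it preserves the overall shape and the
#' mean of the input (`mean(output) == mean(input)` up to floating point),
#' and works for upsampling (`r < 1`), identity (`r = 1`) and downsampling
#' (`r > 1`).
#'
#' @param raw numeric vector, length `m >= 1`.
#' @param L target number of bins, `>= 1`.
#' @return numeric vector of length `L`.
#' @export
#' @examples
#' normalize_length(c(2, 4, 6, 8), 2) # c(3, 7)
#' normalize_length(c(1, 2, 3), 2)    # c(4/3, 8/3); mean stays 2
normalize_length <- function(raw, L) {
  m <- length(raw)
  if (m < 1L || L < 1L) {
    stop("normalize_length needs m >= 1 and L >= 1")
  }
  if (L == m) {
    return(as.numeric(raw))
  }
  # F(x) = integral over [0, x) of the depth step function: piecewise
  # linear with knots at integer positions. Bin j is (F((j+1)r) - F(jr))/r;
  # the telescoping sum makes mean preservation exact.
  edges <- seq.int(0, m, length.out = L + 1L)
  cum <- c(0, cumsum(as.numeric(raw)))
  fe <- stats::approx(0:m, cum, xout = edges, rule = 2)$y
  diff(fe) / (m / L)
}

#' Build the feature-by-position matrix to be clustered
#'
#' Composes [extract_raw()] and [normalize_length()] over a feature table:
#' one row per retained feature, in annotation order, `L` columns. In
#' log2-ratio mode (a `control` track supplied) each per-base value becomes
#' `log2((treatment + pseudocount) / (control + pseudocount))` before
#' normalization, the usual treatment-vs-input comparison for ChIP signal.
#'
#' Features on chromosomes absent from the track, or extending past the
#' chromosome end, are skipped with a warning and counted in the
#' `"skipped"` attribute. Zero-coverage features are retained as rows of
#' zeros so that cluster composition is not silently changed.
#'
#' @param track treatment `coverage_track`.
#' @param features `genomic_features` data frame from [parse_annotation()].
#' @param L number of bins (columns); default 100.
#' @param control optional control `coverage_track` enabling log2-ratio mode.
#' @param reverse_minus reverse minus-strand features? Default `TRUE`.
#' @param scale_rows divide each row by its mean (shape-only clustering)?
#'   Default `FALSE`: clustering sees absolute depth. Zero-mean rows are
#'   left untouched.
#' @param pseudocount added to both samples in log2-ratio mode; default 1.
#' @return numeric matrix of class `feature_matrix`, rownames = feature
#'   ids, with attributes `L` and `skipped`.
#' @export
build_matrix <- function(track, features, L = 100L, control = NULL,
                         reverse_minus = TRUE, scale_rows = FALSE,
                         pseudocount = 1) {
  if (nrow(features) == 0L) {
    stop("no features supplied to build_matrix")
  }
  absent <- !features$chrom %in% names(track$depth)
  if (any(absent)) {
    warning(sprintf(
      "dropped %d feature(s) on chromosome(s) absent from the alignment: %s",
      sum(absent), paste(unique(features$chrom[absent]), collapse = ", ")))
  }
  kept_features <- features[!absent, , drop = FALSE]
  n_skipped <- sum(absent)

  rows <- vector("list", nrow(kept_features))
  keep <- logical(nrow(kept_features))
  for (i in seq_len(nrow(kept_features))) {
    feat <- kept_features[i, , drop = FALSE]
    raw <- extract_raw(track, feat, reverse_minus = reverse_minus)
    if (is.null(raw)) next
    if (!is.null(control)) {
      raw_c <- extract_raw(control, feat, reverse_minus = reverse_minus)
      if (is.null(raw_c)) next
      raw <- log2((raw + pseudocount) / (raw_c + pseudocount))
    }
    rows[[i]] <- normalize_length(raw, L)
    keep[i] <- TRUE
  }
  n_skipped <- n_skipped + sum(!keep)
  if (!any(keep)) {
    stop("all features were skipped; nothing to cluster")
  }
  if (n_skipped > 0L) {
    log_msg("info", n_skipped, " feature(s) skipped while building the matrix")
  }

  mat <- do.call(rbind, rows[keep])
  rownames(mat) <- kept_features$id[keep]
  if (scale_rows) {
    mu <- rowMeans(mat)
    nz <- mu != 0
    mat[nz, ] <- mat[nz, , drop = FALSE] / mu[nz]
  }
  stopifnot(all(is.finite(mat)))
  structure(mat, L = as.integer(L), skipped = n_skipped,
            class = c("feature_matrix", class(mat)))
}
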