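# Synthetic SAM + GFF3 fixture pairs with planted per-feature coverage
# trends. Reads are simulated (start positions drawn from a trend-shaped
# density), so fixtures exercise the real SAM -> coverage -> matrix path
# with genuine Poisson-like counting noise rather than hand-written depths.

#' Describe one planted coverage trend
#'
#' A trend is a smooth expected-depth profile along a feature (5' to 3'):
#' a uniform baseline plus, for the peaked shapes, a Gaussian bump whose
#' center sits at 10% (`five_prime_peak`), 50% (`center_peak`) or 90%
#' (`three_prime_peak`) of the feature length. These emulate the
#' conflicting signal shapes that destroy a single averaged metagene
#' curve: a spike at the start of the gene body, one at the end, one in
#' the middle, or none at all.
#'
#' @param name one of `"five_prime_peak"`, `"three_prime_peak"`,
#'   `"center_peak"`, `"flat"`.
#' @param peak_height mean depth at the peak summit; default 30.
#' @param baseline mean depth away from the peak; default 5.
#' @param peak_width_fraction peak standard deviation as a fraction of the
#'   feature length (times 1/2); default 0.2.
#' @return an object of class `trend_spec`.
#' @export
trend_spec <- function(name = c("five_prime_peak", "three_prime_peak",
                                "center_peak", "flat"),
                       peak_height = 30, baseline = 5,
                       peak_width_fraction = 0.2) {
  name <- match.arg(name)
  if (baseline < 0 || peak_height < baseline) {
    stop("need peak_height >= baseline >= 0")
  }
  if (peak_width_fraction <= 0 || peak_width_fraction > 1) {
    stop("peak_width_fraction must be in (0, 1]")
  }
  structure(list(name = name, peak_height = peak_height,
                 baseline = baseline,
                 peak_width_fraction = peak_width_fraction),
            class = "trend_spec")
}

# Expected per-base depth profile of a trend, 5'->3', length len.
trend_profile <- function(trend, len) {
  x <- seq_len(len)
  if (trend$name == "flat") {
    return(rep(trend$baseline, len))
  }
  center <- switch(trend$name,
                   five_prime_peak = 0.10 * len,
                   center_peak = 0.50 * len,
                   three_prime_peak = 0.90 * len)
  sigma <- trend$peak_width_fraction * len / 2
  trend$baseline +
    (trend$peak_height - trend$baseline) * exp(-0.5 * ((x - center) / sigma)^2)
}

#' Generate a SAM + GFF3 fixture with planted coverage trends
#'
#' Writes a valid GFF3 with `CDS` features of varied lengths, spread over
#' `n_chroms` chromosomes and both strands, and a matching SAM whose reads
#' are placed so each feature's expected depth follows its assigned trend:
#' the number of reads matches the trend's total signal and read start
#' positions are sampled from the trend density (evaluated at the read
#' midpoint). Minus-strand features carry the mirrored genomic profile so
#' that 5'-end peaks stay at the 5' end after strand reversal. Output is
#' byte-identical for a fixed seed.
#'
#' @param trends list of [trend_spec()] objects (>= 1).
#' @param features_per_trend features generated per trend; default 100.
#' @param feature_length_range integer `(min, max)` feature lengths;
#'   default `c(200, 1000)`. `min` must be at least `read_length`.
#' @param seed integer seed; default 1.
#' @param dir output directory (created if needed); default a fresh
#'   temporary directory.
#' @param read_length simulated read length; default 50.
#' @param n_chroms number of chromosomes to spread features over; default 2.
#' @return list with `sam` and `gff` file paths, `labels` (named integer
#'   vector, feature id -> 1-based trend index) and `features` (the
#'   generated `genomic_features` table).
#' @export
generate_fixture <- function(trends, features_per_trend = 100L,
                             feature_length_range = c(200L, 1000L),
                             seed = 1L, dir = tempfile("fixture"),
                             read_length = 50L, n_chroms = 2L) {
  if (length(trends) < 1L || features_per_trend < 1L) {
    stop("need at least one trend and one feature per trend")
  }
  if (inherits(trends, "trend_spec")) trends <- list(trends)
  if (feature_length_range[1] < read_length) {
    stop("minimum feature length (", feature_length_range[1],
         ") must be >= read length (", read_length, ")")
  }
  ensure_dir(dir)

  with_seed(seed, {
    n_feat <- length(trends) * features_per_trend
    trend_idx <- rep(seq_along(trends), each = features_per_trend)
    # interleave trends along the genome so clusters are not blocks
    ord <- sample.int(n_feat)
    trend_idx <- trend_idx[ord]
    lens <- sample(seq.int(feature_length_range[1], feature_length_range[2]),
                   n_feat, replace = TRUE)
    chroms <- paste0("chr", rep_len(seq_len(n_chroms), n_feat))
    strands <- rep_len(c("+", "-"), n_feat)
    ids <- sprintf("f%04d", seq_len(n_feat))

    # lay features end to end per chromosome with a 100 bp gap
    start <- integer(n_feat)
    cursor <- stats::setNames(rep(101L, n_chroms), paste0("chr", 1:n_chroms))
    for (i in seq_len(n_feat)) {
      start[i] <- cursor[[chroms[i]]]
      cursor[[chroms[i]]] <- start[i] + lens[i] + 100L
    }
    end <- start + lens - 1L
    chrom_lengths <- cursor + 99L # last end + 200 (or 200 if chrom unused)

    features <- data.frame(id = ids, chrom = chroms, start = start,
                           end = end, strand = strands,
                           feature_type = "CDS", stringsAsFactors = FALSE)
    class(features) <- c("genomic_features", class(features))

    sam_records <- vector("list", n_feat)
    read_no <- 0L
    for (i in seq_len(n_feat)) {
      profile <- trend_profile(trends[[trend_idx[i]]], lens[i])
      if (strands[i] == "-") profile <- rev(profile) # genomic orientation
      n_reads <- stats::rpois(1L, sum(profile) / read_length)
      if (n_reads == 0L) {
        sam_records[[i]] <- character(0)
        next
      }
      # read start offsets within the feature, weighted by the profile at
      # the read midpoint; reads stay fully inside the feature
      max_off <- lens[i] - read_length
      w <- profile[seq.int(0L, max_off) + read_length %/% 2L + 1L]
      offs <- sample.int(max_off + 1L, n_reads, replace = TRUE, prob = w) - 1L
      offs <- sort(offs)
      qnames <- sprintf("r%07d", read_no + seq_len(n_reads))
      read_no <- read_no + n_reads
      sam_records[[i]] <- sprintf(
        "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
        qnames, if (strands[i] == "+") 0L else 16L, chroms[i],
        start[i] + offs, read_length)
    }

    sam_path <- file.path(dir, "fixture.sam")
    gff_path <- file.path(dir, "fixture.gff3")
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                        chrom_lengths))
    writeLines(c(header, unlist(sam_records, use.names = FALSE)), sam_path)
    write_gff3(features, gff_path)

    list(sam = sam_path, gff = gff_path,
         labels = stats::setNames(trend_idx, ids), features = features)
  })
}
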