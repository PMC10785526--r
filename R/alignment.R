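# SAM reading: one pass over the file, one per-base depth array per
# chromosome. Reads are parsed in bulk (vectorized CIGAR decomposition plus
# a difference-array accumulator), so memory is bounded by chromosome count
# times chromosome length, not by read count.

#' Decide whether a SAM record is counted from its FLAG
#'
#' Records flagged unmapped (0x4), secondary (0x100) or supplementary
#' (0x800) are skipped; everything else is counted. Duplicate marking
#' (0x400) is ignored here and handled by `build_coverage(keep_duplicates=)`.
#'
#' @param flag integer SAM FLAG value (vectorized).
#' @return logical: `TRUE` when the record contributes to coverage.
#' @export
#' @examples
#' filter_record(c(0L, 4L, 256L, 2048L)) # TRUE FALSE FALSE FALSE
filter_record <- function(flag) {
  bitwAnd(as.integer(flag), bitwOr(bitwOr(0x4L, 0x100L), 0x800L)) == 0L
}

#' Build per-chromosome coverage arrays from a SAM file
#'
#' Streams a SAM 1.x file and returns, for every chromosome declared in an
#' `@SQ` header line, an integer array of per-base read depth. For each
#' counted read, every reference position consumed by CIGAR operations
#' `M`, `=` or `X` is incremented by one; `N` and `D` consume reference
#' without being counted as covered, and `I`, `S`, `H`, `P` consume no
#' reference.
#'
#' @param path path to a SAM file with `@SQ SN:/LN:` header lines for every
#'   reference used by alignment records.
#' @param keep_duplicates count records flagged as PCR/optical duplicates
#'   (0x400)? Default `TRUE`: no filtering beyond unmapped/secondary/
#'   supplementary.
#' @param min_mapq minimum MAPQ to count a record; default 0 (no filter).
#' @return an object of class `coverage_track`: a list with
#'   `chrom_lengths` (named integer vector from the `@SQ` lines), `depth`
#'   (named list of integer vectors, one per chromosome, 0-based position
#'   `i` stored at R index `i + 1`), and `n_counted` / `n_skipped` record
#'   tallies.
#' @export
build_coverage <- function(path, keep_duplicates = TRUE, min_mapq = 0L) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, "@")

  sq <- lines[is_header & startsWith(lines, "@SQ")]
  chrom_lengths <- parse_sq_headers(sq)
  if (length(chrom_lengths) == 0L) {
    stop("SAM file has no @SQ header lines: ", path)
  }

  recs <- lines[!is_header]
  recs <- recs[nzchar(recs)]
  depth <- lapply(chrom_lengths, function(n) integer(n))
  track <- structure(
    list(chrom_lengths = chrom_lengths, depth = depth,
         n_counted = 0L, n_skipped = 0L),
    class = "coverage_track")
  if (length(recs) == 0L) {
    return(track)
  }

  fields <- strsplit(recs, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) {
    stop("SAM record with fewer than 6 mandatory fields in ", path)
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4L))
  mapq <- as.integer(vapply(fields, `[[`, character(1), 5L))
  cigar <- vapply(fields, `[[`, character(1), 6L)

  counted <- filter_record(flag)
  if (!keep_duplicates) {
    counted <- counted & bitwAnd(flag, 0x400L) == 0L
  }
  if (min_mapq > 0L) {
    counted <- counted & mapq >= min_mapq
  }

  missing_cigar <- counted & cigar == "*"
  if (any(missing_cigar)) {
    warning(sprintf("skipped %d mapped record(s) with CIGAR '*'",
                    sum(missing_cigar)))
    counted <- counted & !missing_cigar
  }

  undeclared <- counted & !(rname %in% names(chrom_lengths))
  if (any(undeclared)) {
    stop("alignment record references chromosome absent from @SQ headers: ",
         paste(unique(rname[undeclared]), collapse = ", "))
  }

  n_counted <- sum(counted)
  track$n_counted <- n_counted
  track$n_skipped <- length(recs) - n_counted
  if (n_counted == 0L) {
    return(track)
  }

  blocks <- cigar_reference_blocks(cigar[counted], pos[counted])
  bchrom <- rname[counted][blocks$record]

  # difference-array accumulation: +1 at block start, -1 past block end,
  # then cumulative sum per chromosome
  for (chrom in unique(bchrom)) {
    sel <- bchrom == chrom
    n <- chrom_lengths[[chrom]]
    if (any(blocks$end[sel] > n) || any(blocks$start[sel] < 1L)) {
      stop("alignment extends beyond @SQ LN for chromosome ", chrom)
    }
    delta <- integer(n + 1L)
    add <- tabulate(blocks$start[sel], nbins = n + 1L)
    subtr <- tabulate(blocks$end[sel] + 1L, nbins = n + 1L)
    delta <- add - subtr
    track$depth[[chrom]] <- cumsum(delta)[seq_len(n)]
  }
  track
}

parse_sq_headers <- function(sq_lines) {
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq_lines)
  ln <- suppressWarnings(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq_lines)))
  if (length(sq_lines) && (any(is.na(ln)) || any(sn == sq_lines))) {
    stop("malformed @SQ header line (need SN: and LN: tags)")
  }
  stats::setNames(ln, sn)
}

# Decompose CIGAR strings into covered reference blocks (1-based inclusive).
# M/=/X blocks are returned; N and D advance the reference cursor without
# producing a block; I/S/H/P advance nothing on the reference.
cigar_reference_blocks <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  rebuilt <- vapply(ops, paste, character(1), collapse = "")
  if (any(rebuilt != cigar)) {
    bad <- which(rebuilt != cigar)
    stop("malformed CIGAR string(s): ",
         paste(utils::head(cigar[bad], 3L), collapse = ", "))
  }
  n_ops <- lengths(ops)
  flat <- unlist(ops, use.names = FALSE)
  oplen <- as.integer(sub("[MIDNSHP=X]$", "", flat))
  opchr <- substr(flat, nchar(flat), nchar(flat))
  record <- rep.int(seq_along(cigar), n_ops)

  consumes_ref <- opchr %in% c("M", "D", "N", "=", "X")
  ref_advance <- ifelse(consumes_ref, oplen, 0L)
  # reference offset of each op within its record (0-based, before the op)
  cum <- cumsum(ref_advance)
  first_of_rec <- c(TRUE, record[-1L] != record[-length(record)])
  base <- rep.int(c(0, cum[which(first_of_rec)[-1L] - 1L]),
                  n_ops)
  offset <- cum - ref_advance - base

  covered <- opchr %in% c("M", "=", "X")
  start <- pos[record[covered]] + offset[covered]
  list(record = record[covered],
       start = as.integer(start),
       end = as.integer(start + oplen[covered] - 1L))
}
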