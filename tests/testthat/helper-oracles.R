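# Independent brute-force oracles. These deliberately share no code with
# the implementation: naive per-read / per-position / per-partition loops.

# SAM -> depth by expanding each record's CIGAR one operation at a time and
# incrementing covered positions in a plain loop.
oracle_coverage <- function(sam_path) {
  lines <- readLines(sam_path)
  sq <- lines[grepl("^@SQ", lines)]
  depth <- list()
  for (h in sq) {
    sn <- sub(".*SN:([^\t]+).*", "\\1", h)
    ln <- as.integer(sub(".*LN:([0-9]+).*", "\\1", h))
    depth[[sn]] <- integer(ln)
  }
  for (line in lines[!startsWith(lines, "@")]) {
    if (!nzchar(line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0 || bitwAnd(flag, 256L) != 0 ||
        bitwAnd(flag, 2048L) != 0) next
    cigar <- f[6]
    if (cigar == "*") next
    pos <- as.integer(f[4]) # 1-based cursor on the reference
    ops <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
    for (op in ops) {
      len <- as.integer(sub(".$", "", op))
      ch <- substring(op, nchar(op))
      if (ch %in% c("M", "=", "X")) {
        for (p in pos:(pos + len - 1)) {
          depth[[f[3]]][p] <- depth[[f[3]]][p] + 1L
        }
        pos <- pos + len
      } else if (ch %in% c("D", "N")) {
        pos <- pos + len
      } # I, S, H, P: no reference movement
    }
  }
  depth
}

# Fractional-overlap binning by explicit integration of the step function:
# for each output bin walk every input position and accumulate its overlap
# with the bin's real-valued window.
oracle_normalize <- function(raw, L) {
  m <- length(raw)
  r <- m / L
  out <- numeric(L)
  for (j in seq_len(L)) {
    lo <- (j - 1) * r
    hi <- j * r
    acc <- 0
    for (i in seq_len(m)) {
      overlap <- max(0, min(hi, i) - max(lo, i - 1))
      acc <- acc + raw[i] * overlap
    }
    out[j] <- acc / r
  }
  out
}

# Optimal 2-cluster objective by enumerating every bipartition into two
# non-empty groups and scoring squared distance to group means.
oracle_best_bipartition <- function(X) {
  n <- nrow(X)
  sse <- function(rows) {
    if (length(rows) == 0L) return(0)
    mu <- colMeans(X[rows, , drop = FALSE])
    sum(sweep(X[rows, , drop = FALSE], 2L, mu, "-")^2)
  }
  best <- Inf
  # fix row 1 in group A to halve the enumeration
  for (mask in 0:(2^(n - 1) - 1)) {
    in_a <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:(n - 2))) > 0))
    if (all(in_a)) next # group B must be non-empty
    obj <- sse(which(in_a)) + sse(which(!in_a))
    if (obj < best) best <- obj
  }
  best
}
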