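# Tiny hand-written SAM / GFF builders for unit tests.

write_sam <- function(path, sq, records = character(0)) {
  # sq: named integer vector chrom -> length
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname = "r1", flag = 0L, rname = "chrI", pos = 1L,
                       mapq = 60L, cigar = "4M") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
          qname, flag, rname, pos, mapq, cigar)
}

write_gff_lines <- function(path, lines, header = "##gff-version 3") {
  writeLines(c(header, lines), path)
  path
}

gff_line <- function(chrom = "chrI", type = "CDS", start = 1L, end = 10L,
                     strand = "+", attrs = "ID=g1", source = "src") {
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t0\t%s",
          chrom, source, type, start, end, strand, attrs)
}

# lowest objective over `restarts` seeded k=2 runs of the package k-means
best_of_restarts_objective <- function(X, restarts, base_seed) {
  min(vapply(seq_len(restarts), function(r) {
    run_kmeans(X, 2, seed = base_seed * 1009L + r)$total_distance
  }, numeric(1)))
}

# standard 3-trend spec set used across tests
three_trends <- function(peak_height = 30, baseline = 5) {
  list(trend_spec("five_prime_peak", peak_height, baseline),
       trend_spec("center_peak", peak_height, baseline),
       trend_spec("three_prime_peak", peak_height, baseline))
}
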