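# GFF3/GTF parsing: extract coordinates of all features of a chosen type.

#' Parse a GFF3 or GTF annotation and extract features of one type
#'
#' Reads a tab-separated annotation file and returns every record whose
#' feature type (column 3) equals `feature_type`, with coordinates taken
#' verbatim from columns 4-5 (1-based, inclusive) and order of appearance
#' preserved.
#'
#' Identifier resolution is dialect-aware, decided per line from the
#' attribute column: `key "value";` pairs are treated as GTF and the
#' `gene_id` attribute is used; `key=value` pairs are treated as GFF3 and
#' `ID=` is used, falling back to `Name=`, then `gene_id=`. When nothing
#' resolves the id is synthesized as `chrom:start-end`. Duplicate ids get
#' suffixes `.2`, `.3`, ... in order of appearance (with a warning) so that
#' membership files identify every row uniquely.
#'
#' Malformed lines (fewer than 8 tab-separated columns, or non-numeric /
#' inverted coordinates) are skipped with a warning naming the line number.
#'
#' @param path path to a GFF3 or GTF file. `#`-prefixed lines are ignored.
#' @param feature_type feature type to keep, e.g. `"CDS"` or `"gene"`.
#' @return a data frame of class `genomic_features` with columns
#'   `id`, `chrom`, `start`, `end`, `strand`, `feature_type`.
#' @export
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'              "chrI\tsrc\tCDS\t11\t20\t.\t+\t0\tID=gene1"), gff)
#' parse_annotation(gff, "CDS")
parse_annotation <- function(path, feature_type) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no features of type ", feature_type, " in ", path)
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- nfield < 8L
  if (any(bad)) {
    warning(sprintf("skipped %d malformed annotation line(s): %s",
                    sum(bad),
                    paste(utils::head(lineno[bad], 5L), collapse = ", ")))
    fields <- fields[!bad]
    lineno <- lineno[!bad]
  }

  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else "",
                            character(1))
  type <- col(3L)
  sel <- type == feature_type
  fields <- fields[sel]
  lineno <- lineno[sel]
  if (length(fields) == 0L) {
    stop("no features of type ", feature_type, " in ", path)
  }

  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  strand <- vapply(fields, `[[`, character(1), 7L)
  attrs <- vapply(fields, function(f) if (length(f) >= 9L) f[[9L]] else "",
                  character(1))

  bad_coord <- is.na(start) | is.na(end) | start < 1L | end < start
  if (any(bad_coord)) {
    warning(sprintf("skipped %d line(s) with invalid coordinates: %s",
                    sum(bad_coord),
                    paste(utils::head(lineno[bad_coord], 5L), collapse = ", ")))
    chrom <- chrom[!bad_coord]
    start <- start[!bad_coord]
    end <- end[!bad_coord]
    strand <- strand[!bad_coord]
    attrs <- attrs[!bad_coord]
  }
  if (length(chrom) == 0L) {
    stop("no features of type ", feature_type, " in ", path)
  }
  strand[!strand %in% c("+", "-", ".")] <- "."

  ids <- mapply(resolve_feature_id, attrs, chrom, start, end,
                USE.NAMES = FALSE)
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("%d duplicate feature id(s) suffixed .2, .3, ...",
                    sum(dup)))
    ids <- make_unique_ids(ids)
  }

  out <- data.frame(id = ids, chrom = chrom, start = start, end = end,
                    strand = strand, feature_type = feature_type,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_features", class(out))
  out
}

# Per-line dialect rule: GTF when the attribute column holds `key "value"`
# pairs, GFF3 when it holds `key=value` pairs; synthesize chrom:start-end
# when no id attribute resolves.
resolve_feature_id <- function(attr, chrom, start, end) {
  if (nzchar(attr)) {
    if (grepl("[A-Za-z_]+\\s+\"", attr)) { # GTF: key "value"; pairs
      m <- regmatches(attr, regexec("gene_id\\s+\"([^\"]*)\"", attr))[[1]]
      if (length(m) == 2L && nzchar(m[[2]])) return(m[[2]])
    } else if (grepl("=", attr, fixed = TRUE)) { # GFF3: key=value pairs
      for (key in c("ID", "Name", "gene_id")) {
        m <- regmatches(attr,
                        regexec(paste0("(^|;)\\s*", key, "=([^;]*)"), attr))[[1]]
        if (length(m) == 3L && nzchar(m[[3]])) return(m[[3]])
      }
    }
  }
  sprintf("%s:%d-%d", chrom, start, end)
}

make_unique_ids <- function(ids) {
  counts <- new.env(parent = emptyenv())
  vapply(ids, function(id) {
    n <- if (is.null(counts[[id]])) 1L else counts[[id]] + 1L
    counts[[id]] <- n
    if (n == 1L) id else paste0(id, ".", n)
  }, character(1), USE.NAMES = FALSE)
}

#' Write features as a GFF3 file
#'
#' Inverse of [parse_annotation()] for round-trip testing and fixture
#' generation: each feature becomes one GFF3 line with an `ID=` attribute.
#'
#' @param features a `genomic_features` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tclustagene\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                     features$chrom, features$feature_type,
                     features$start, features$end,
                     features$strand, features$id))
  writeLines(lines, path)
  invisible(path)
}
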